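#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with det = +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4g deg, translation (%.4g, %.4g, %.4g) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a 3x3 rotation matrix (radians)
#' @param R 3x3 rotation matrix.
#' @export
rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

#' Rotation matrix from Euler angles (degrees, applied x then y then z)
#' @param angles length-3 numeric, rotations about x, y, z in degrees.
#' @export
rotation_from_euler <- function(angles) {
  a <- angles * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_points(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return the composition as a [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Convert a rigid transform to a 4x4 homogeneous matrix (and back)
#' @param transform a [rigid_transform()].
#' @return 4x4 numeric matrix.
#' @export
transform_to_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname transform_to_matrix
#' @param m a 4x4 homogeneous matrix.
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write / read a rigid transform as JSON (4x4 homogeneous matrix)
#' @param transform a [rigid_transform()].
#' @param path JSON path.
#' @return `path` invisibly (write); a [rigid_transform()] (read).
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(matrix = transform_to_matrix(transform)), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  transform_from_matrix(matrix(unlist(m), 4, 4))
}

as_points <- function(x) {
  if (inherits(x, "surface_mesh")) return(x$vertices)
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be n x 3", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Closest point on a mesh surface
#'
#' Exact closest point over all triangles (vertex, edge, or face interior),
#' accelerated by a uniform spatial grid over triangle bounding boxes.
#'
#' @param query n x 3 matrix of query points (a single point may be given as
#'   a length-3 vector).
#' @param mesh a [surface_mesh()].
#' @return list with `point` (n x 3 closest surface points), `distance`
#'   (unsigned, mm) and `triangle` (1-based face index).
#' @export
closest_point <- function(query, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces", call. = FALSE)
  if (is.numeric(query) && is.null(dim(query)) && length(query) == 3L)
    query <- matrix(query, 1L, 3L)
  query <- as_points(query)
  res <- cpp_closest_points(query, mesh$vertices, mesh$faces)
  list(point = res$point, distance = res$distance, triangle = res$triangle)
}

# least-squares rigid fit (Kabsch / cross-covariance SVD with det guard)
fit_rigid <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' Iterative closest point rigid registration
#'
#' Alternates point-to-surface closest-point correspondence with a
#' least-squares rigid fit (cross-covariance SVD, reflection-guarded),
#' minimising the sum of squared distances from the transformed source points
#' to the target surface. The objective is non-increasing across iterations;
#' iteration stops when the RMS improvement drops below `tol` or after
#' `max_iter` iterations.
#'
#' @param source n x 3 point matrix or a [surface_mesh()] (vertices are
#'   used); needs at least 3 non-collinear points.
#' @param target a [surface_mesh()].
#' @param max_iter maximum number of iterations (default 100).
#' @param tol RMS improvement (mm) below which iteration stops
#'   (default 1e-6).
#' @param init optional initial [rigid_transform()].
#' @param trim optional fraction in `[0, 1)`: discard this worst fraction of
#'   correspondences in each fit for robustness (off by default).
#' @param max_points registration uses at most this many source points
#'   (an evenly strided, deterministic subsample; default 5000). The final
#'   RMS is still reported over the subsample; set to `Inf` to use all
#'   points.
#' @return list with `transform` (a [rigid_transform()]), `rms` (final RMS
#'   point-to-surface distance, mm), `rms_history`, `iterations`,
#'   `converged`.
#' @export
icp_register <- function(source, target, max_iter = 100, tol = 1e-6,
                         init = NULL, trim = NULL, max_points = 5000) {
  stopifnot(inherits(target, "surface_mesh"))
  pts0 <- as_points(source)
  if (nrow(pts0) < 3L) stop("need at least 3 source points", call. = FALSE)
  if (is.finite(max_points) && nrow(pts0) > max_points)
    pts0 <- pts0[unique(round(seq(1, nrow(pts0), length.out = max_points))), ,
                 drop = FALSE]
  sv <- svd(sweep(pts0, 2, colMeans(pts0)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("source points are collinear or coincident; rigid fit is rank-deficient",
         call. = FALSE)
  transform <- if (is.null(init)) rigid_transform() else init
  rms_history <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cur <- apply_transform(transform, pts0)
    cp <- cpp_closest_points(cur, target$vertices, target$faces)
    d <- cp$distance
    keep <- seq_along(d)
    if (!is.null(trim) && trim > 0)
      keep <- order(d)[seq_len(max(3L, floor(length(d) * (1 - trim))))]
    rms <- sqrt(mean(d[keep]^2))
    rms_history <- c(rms_history, rms)
    if (prev_rms - rms < tol) { converged <- TRUE; break }
    prev_rms <- rms
    step <- fit_rigid(cur[keep, , drop = FALSE], cp$point[keep, , drop = FALSE])
    transform <- compose_transform(step, transform)
  }
  list(transform = transform, rms = rms_history[length(rms_history)],
       rms_history = rms_history, iterations = it, converged = converged)
}

#' Signed deviation of a test mesh from a reference surface
#'
#' For every test-mesh vertex, the signed distance (mm) to the reference
#' surface: positive outside the reference, negative inside, with the sign
#' taken from the reference's angle-weighted pseudonormal at the closest
#' point (well defined on faces, edges and vertices). When `register = TRUE`
#' the test mesh is first rigidly aligned to the reference with
#' [icp_register()].
#'
#' @param test a [surface_mesh()] to evaluate.
#' @param reference the reference [surface_mesh()].
#' @param register run ICP alignment first (default TRUE).
#' @param ... passed to [icp_register()].
#' @return A `deviation_field`: tibble with `vertex_id` and `d_mm`, plus
#'   attributes `transform` and `icp` when registration ran.
#' @export
deviation_map <- function(test, reference, register = TRUE, ...) {
  stopifnot(inherits(test, "surface_mesh"), inherits(reference, "surface_mesh"))
  if (nrow(test$faces) == 0L || nrow(reference$faces) == 0L)
    stop("meshes must be non-empty", call. = FALSE)
  icp <- NULL
  pts <- test$vertices
  if (register) {
    icp <- icp_register(test, reference, ...)
    pts <- apply_transform(icp$transform, pts)
  }
  sd <- cpp_signed_distance(pts, reference$vertices, reference$faces)
  out <- tibble::tibble(vertex_id = seq_len(nrow(pts)),
                        d_mm = sd$signed_distance)
  class(out) <- c("deviation_field", class(out))
  attr(out, "icp") <- icp
  attr(out, "transform") <- if (is.null(icp)) rigid_transform() else icp$transform
  out
}

#' Summarise a deviation field
#'
#' Mean signed deviation, a binned distribution over fixed edges, and the
#' coverage: the percentage of vertices whose absolute deviation does not
#' exceed `threshold`. Deviations outside the bin span are clamped into the
#' outermost bins so the percentages always total 100.
#'
#' @param field a `deviation_field` (from [deviation_map()]) or a numeric
#'   vector of signed deviations in mm.
#' @param bin_edges increasing numeric vector of bin boundaries (mm);
#'   default 13 equal bins across -1..1 mm.
#' @param threshold coverage threshold in mm (default 0.227).
#' @return A `deviation_summary`: list with `mean`, `bins` (tibble with
#'   `lower`, `upper`, `percent`), `coverage`, `threshold`, `n`.
#' @export
summarize_deviation <- function(field, bin_edges = seq(-1, 1, length.out = 14),
                                threshold = 0.227) {
  d <- if (is.data.frame(field)) field$d_mm else as.numeric(field)
  if (length(d) == 0L) stop("deviation field is empty", call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0)
    stop("`threshold` must be non-negative", call. = FALSE)
  dc <- pmin(pmax(d, bin_edges[1]), bin_edges[length(bin_edges)])
  cuts <- cut(dc, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  # right = FALSE leaves the exact upper edge out; include it in the last bin
  cuts[dc == bin_edges[length(bin_edges)]] <- levels(cuts)[nlevels(cuts)]
  pct <- as.numeric(table(cuts)) / length(d) * 100
  structure(list(
    mean = mean(d),
    bins = tibble::tibble(lower = bin_edges[-length(bin_edges)],
                          upper = bin_edges[-1], percent = pct),
    coverage = mean(abs(d) <= threshold) * 100,
    threshold = threshold,
    n = length(d)), class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("<deviation_summary> n = %d vertices\n", x$n))
  cat(sprintf("  mean signed deviation: %.4f mm\n", x$mean))
  cat(sprintf("  coverage |d| <= %.3f mm: %.2f%%\n", x$threshold, x$coverage))
  invisible(x)
}

#' @export
tidy.deviation_summary <- function(x, ...) x$bins

#' @export
glance.deviation_summary <- function(x, ...) {
  tibble::tibble(mean_mm = x$mean, coverage_pct = x$coverage,
                 threshold_mm = x$threshold, n = x$n)
}

#' Map deviations to diverging vertex colors
#'
#' Two-sided linear color map used for deviation inspection: `-range` maps
#' to pure blue, 0 to pure green, `+range` to pure red; values beyond the
#' range are clamped.
#'
#' @param field a `deviation_field` or numeric vector of deviations (mm).
#' @param range spectrum half-width in mm (default 1).
#' @return tibble with `d_mm`, `r`, `g`, `b` in `[0, 1]` and `hex`.
#' @export
colorize_deviation <- function(field, range = 1) {
  if (!is.finite(range) || range <= 0)
    stop("`range` must be positive", call. = FALSE)
  d <- if (is.data.frame(field)) field$d_mm else as.numeric(field)
  t <- pmin(pmax(d / range, -1), 1)
  r <- pmax(t, 0)
  b <- pmax(-t, 0)
  g <- 1 - abs(t)
  tibble::tibble(d_mm = d, r = r, g = g, b = b,
                 hex = grDevices::rgb(r, g, b))
}

#' Write a deviation report (per-vertex CSV + JSON summary)
#'
#' @param field a `deviation_field`.
#' @param summary a `deviation_summary` for the same field.
#' @param csv_path,json_path output paths; either may be NULL to skip.
#' @return invisibly, the paths written.
#' @export
write_deviation_report <- function(field, summary, csv_path = NULL,
                                   json_path = NULL) {
  if (!is.null(csv_path))
    readr::write_csv(tibble::as_tibble(field)[c("vertex_id", "d_mm")], csv_path)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      mean_mm = summary$mean, coverage_pct = summary$coverage,
      threshold_mm = summary$threshold, n = summary$n,
      bins = summary$bins), json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}
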