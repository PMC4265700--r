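#' Ordered stack of per-slice contour sets
#'
#' @param slices list of [contour_set()] objects; reordered by `z` if needed.
#' @param slice_spacing distance between adjacent slices in mm (> 0).
#' @return A `contour_stack` object.
#' @export
contour_stack <- function(slices, slice_spacing) {
  if (!all(vapply(slices, inherits, logical(1), "contour_set")))
    stop("`slices` must be a list of contour_set objects", call. = FALSE)
  if (!is.finite(slice_spacing) || slice_spacing <= 0)
    stop("`slice_spacing` must be positive", call. = FALSE)
  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyDuplicated(z)) stop("duplicate slice z positions", call. = FALSE)
  structure(list(slices = slices[order(z)], slice_spacing = slice_spacing),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  n <- vapply(x$slices, function(s) length(s$contours), integer(1))
  cat(sprintf("<contour_stack> %d slices (%d with contours), spacing %.3g mm\n",
              length(x$slices), sum(n > 0), x$slice_spacing))
  invisible(x)
}

#' Rasterize stacked contours into a binary volume
#'
#' A voxel is inside when its center lies within the contours of its slice
#' under the even-odd rule, so inner contours (e.g. a medullary canal) cut
#' holes. Slices of the grid with no matching contour set are empty.
#'
#' @param stack a [contour_stack()].
#' @param origin,spacing,dim grid specification: physical position of voxel
#'   (0,0,0) center, per-axis spacing (mm), and integer dimensions. When
#'   omitted, a grid covering all contours with a one-voxel margin is built
#'   from the stack's slice positions and `spacing`.
#' @return list with `mask` (logical 3D array), `origin`, `spacing`.
#' @export
rasterize_contours <- function(stack, origin = NULL, spacing = c(1, 1, NA),
                               dim = NULL) {
  stopifnot(inherits(stack, "contour_stack"))
  zs <- vapply(stack$slices, function(s) s$z, numeric(1))
  if (is.na(spacing[3])) spacing[3] <- stack$slice_spacing
  all_xy <- do.call(rbind, unlist(lapply(stack$slices, function(s) s$contours),
                                  recursive = FALSE))
  if (is.null(origin) || is.null(dim)) {
    if (is.null(all_xy))
      return(list(mask = array(FALSE, c(3, 3, max(3, length(zs)))),
                  origin = c(0, 0, if (length(zs)) min(zs) else 0),
                  spacing = spacing))
    lo <- c(apply(all_xy, 2, min), min(zs)) - c(spacing[1:2], 0)
    hi <- c(apply(all_xy, 2, max), max(zs)) + c(spacing[1:2], 0)
    origin <- lo
    dim <- pmax(3L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  if (!is.null(all_xy)) {
    lim_x <- origin[1] + c(-0.5, dim[1] - 0.5) * spacing[1]
    lim_y <- origin[2] + c(-0.5, dim[2] - 0.5) * spacing[2]
    if (min(all_xy[, 1]) < lim_x[1] || max(all_xy[, 1]) > lim_x[2] ||
        min(all_xy[, 2]) < lim_y[1] || max(all_xy[, 2]) > lim_y[2])
      stop("contours extend outside the rasterisation grid", call. = FALSE)
  }
  mask <- array(FALSE, dim)
  for (s in stack$slices) {
    if (length(s$contours) == 0L) next
    k <- round((s$z - origin[3]) / spacing[3]) + 1
    if (k < 1 || k > dim[3]) stop("slice z outside grid", call. = FALSE)
    mask[, , k] <- cpp_rasterize_polygons(s$contours, origin[1:2],
                                          spacing[1:2], as.integer(dim[1:2]))
  }
  list(mask = mask, origin = origin, spacing = spacing)
}

#' Shape-based interpolation between slices
#'
#' Each slice of the binary volume is converted to a signed Euclidean
#' distance map (positive inside), distance maps of adjacent slices are
#' linearly interpolated along the slice axis, and the result is
#' re-thresholded at zero. Intermediate shapes therefore morph smoothly
#' between the neighbouring cross-sections instead of switching abruptly.
#'
#' @param volume list as returned by [rasterize_contours()], or a logical 3D
#'   array.
#' @param factor integer >= 1; the output has `(n-1)*factor + 1` slices and
#'   slice spacing divided by `factor`.
#' @return same structure as the input, interpolated.
#' @export
interpolate_slices <- function(volume, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1 || factor != round(factor))
    stop("`factor` must be an integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  vol <- if (is.list(volume)) volume$mask else volume
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  if (factor == 1L) return(volume)
  nz <- dim(vol)[3]
  sd_slices <- lapply(seq_len(nz), function(k) signed_dist2d(vol[, , k]))
  out <- array(FALSE, c(dim(vol)[1:2], (nz - 1L) * factor + 1L))
  for (k in seq_len(nz - 1L)) {
    for (s in 0:(factor - 1L)) {
      t <- s / factor
      out[, , (k - 1L) * factor + s + 1L] <-
        ((1 - t) * sd_slices[[k]] + t * sd_slices[[k + 1L]]) > 0
    }
  }
  out[, , (nz - 1L) * factor + 1L] <- sd_slices[[nz]] > 0
  if (is.list(volume)) {
    volume$mask <- out
    volume$spacing[3] <- volume$spacing[3] / factor
    volume
  } else out
}

#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise when viewed from outside.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices must be n x 3 and faces m x 3", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3, signed)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive when faces
#' wind counter-clockwise viewed from outside.
#' @param mesh a [surface_mesh()].
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh a [surface_mesh()].
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  F <- mesh$faces
  if (nrow(F) == 0L) return(FALSE)
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a [surface_mesh()].
#' @export
euler_characteristic <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  n_edges <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  length(unique(as.vector(F))) - n_edges + nrow(F)
}

# flip all faces if the total signed volume is negative (inward winding)
orient_outward <- function(mesh) {
  if (nrow(mesh$faces) > 0 && mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0L) return(mesh)
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  mesh$faces <- F[area2 > tol, , drop = FALSE]
  mesh
}

#' Extract an isosurface mesh from a volume
#'
#' Marching tetrahedra over the voxel grid (each cube split into six
#' tetrahedra sharing the main diagonal), producing a closed, consistently
#' outward-oriented triangle mesh in physical mm coordinates. Binary input is
#' first smoothed with a small Gaussian (sigma 0.5 voxels by default) and
#' contoured at 0.5, which suppresses the staircase terracing a hard binary
#' isosurface would show.
#'
#' @param volume logical/numeric 3D array, or a list with `mask`/`origin`/
#'   `spacing` as returned by [rasterize_contours()].
#' @param iso_level iso value (default 0.5, the binary midpoint).
#' @param spacing,origin physical geometry when `volume` is a bare array.
#' @param smooth_sigma Gaussian sigma in voxels applied to binary input;
#'   set to 0 to disable.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(volume, iso_level = 0.5, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), smooth_sigma = 0.5) {
  if (is.list(volume) && !is.null(volume$mask)) {
    spacing <- volume$spacing; origin <- volume$origin; volume <- volume$mask
  }
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  v <- volume
  is_binary <- is.logical(v) || all(v %in% c(0, 1))
  storage.mode(v) <- "double"
  if (max(v) <= iso_level || min(v) > iso_level)
    stop("volume has no crossing of the iso level; no surface to extract",
         call. = FALSE)
  # pad with a one-voxel below-iso shell so solids touching the array
  # boundary still close into watertight surfaces
  vp <- array(min(v), dim(v) + 2L)
  vp[2:(dim(v)[1] + 1L), 2:(dim(v)[2] + 1L), 2:(dim(v)[3] + 1L)] <- v
  v <- vp
  origin <- origin - spacing
  if (is_binary && smooth_sigma > 0)
    v <- cpp_gauss_smooth3(v, dim(v), rep(smooth_sigma, 3))
  res <- cpp_marching_tets(as.vector(v), dim(v), iso_level)
  if (nrow(res$vertices) == 0L)
    stop("volume has no crossing of the iso level; no surface to extract",
         call. = FALSE)
  verts <- sweep(sweep(res$vertices, 2, spacing, "*"), 2, origin, "+")
  mesh <- surface_mesh(verts, res$faces)
  orient_outward(drop_degenerate_faces(mesh))
}

#' Reconstruct a surface mesh from a contour stack
#'
#' Convenience wrapper: rasterize, interpolate along the slice axis towards
#' near-isotropic voxels, and extract the isosurface.
#'
#' @param stack a [contour_stack()].
#' @param spacing in-plane voxel size (mm) for rasterisation.
#' @param factor slice interpolation factor; default
#'   `round(slice_spacing / min(in-plane spacing))` targets near-isotropic
#'   voxels.
#' @return A [surface_mesh()].
#' @export
reconstruct_mesh <- function(stack, spacing = c(0.5, 0.5), factor = NULL) {
  stopifnot(inherits(stack, "contour_stack"))
  if (is.null(factor))
    factor <- max(1L, as.integer(round(stack$slice_spacing / min(spacing))))
  vol <- rasterize_contours(stack, spacing = c(spacing, NA))
  vol <- interpolate_slices(vol, factor)
  extract_surface(vol)
}
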