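#' 2D convolution with reflect padding
#'
#' True convolution (kernel flipped relative to correlation), computed by FFT
#' on a reflect-padded image and cropped back to the input size. Reflection
#' padding avoids fabricated gradients at the image border.
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix, same size as `x`.
#' @keywords internal
conv2d <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop("kernel dimensions must be odd", call. = FALSE)
  if (nrow(x) < nrow(kernel) || ncol(x) < ncol(kernel))
    stop("image is smaller than the kernel", call. = FALSE)
  xp <- pad_reflect(x, kr, kc)
  # small kernels: direct shift-and-add (exact, e.g. flat input -> exact 0);
  # large kernels: FFT
  if (nrow(kernel) * ncol(kernel) <= 25L) {
    out <- matrix(0, nrow(x), ncol(x))
    for (u in -kr:kr) for (v in -kc:kc) {
      w <- kernel[u + kr + 1L, v + kc + 1L]
      if (w == 0) next
      out <- out + w * xp[(1L + kr - u):(nrow(x) + kr - u),
                          (1L + kc - v):(ncol(x) + kc - v), drop = FALSE]
    }
    return(out)
  }
  n1 <- nextn(nrow(xp) + nrow(kernel) - 1L, 2L)
  n2 <- nextn(ncol(xp) + ncol(kernel) - 1L, 2L)
  A <- matrix(0, n1, n2); A[seq_len(nrow(xp)), seq_len(ncol(xp))] <- xp
  B <- matrix(0, n1, n2); B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (n1 * n2)
  # linear-convolution index algebra: output pixel i of x sits at C[i + 2*kr]
  C[(2L * kr + 1L):(2L * kr + nrow(x)), (2L * kc + 1L):(2L * kc + ncol(x)),
    drop = FALSE]
}

pad_reflect <- function(x, m, n) {
  nr <- nrow(x); nc <- ncol(x)
  if (m >= nr || n >= nc)
    stop("reflection pad wider than the image", call. = FALSE)
  ri <- c(rev(seq_len(m) + 1L), seq_len(nr), nr - seq_len(m))
  ci <- c(rev(seq_len(n) + 1L), seq_len(nc), nc - seq_len(n))
  x[ri, ci, drop = FALSE]
}

shift_mat <- function(x, di, dj, fill = 0) {
  # value of x at (i - di, j - dj); out-of-range -> fill
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  i_dst <- max(1L, 1L + di):min(nr, nr + di)
  j_dst <- max(1L, 1L + dj):min(nc, nc + dj)
  out[i_dst, j_dst] <- x[i_dst - di, j_dst - dj]
  out
}

#' Sobel gradient kernels
#'
#' The two 3x3 first-derivative kernels. Note the orientation convention:
#' `row` responds to intensity change along the first (row) index and `col`
#' along the second (column) index. Both are antisymmetric, so using true
#' convolution rather than correlation only flips the sign, which the
#' magnitude discards.
#'
#' @return list with matrices `row` and `col`.
#' @export
sobel_kernels <- function() {
  k_row <- matrix(c(-1, -2, -1,
                     0,  0,  0,
                     1,  2,  1), nrow = 3, byrow = TRUE)
  list(row = k_row, col = t(k_row))
}

#' Sobel gradient of a slice
#'
#' Convolves the slice with the two 3x3 Sobel kernels and combines them into
#' the gradient magnitude `sqrt(gx^2 + gy^2)`. `gx` is the response of the
#' row-direction kernel and `gy` of the column-direction kernel.
#'
#' @param slice numeric matrix, at least 3x3.
#' @return A `gradient_field`: list with `gx`, `gy`, `magnitude`.
#' @examples
#' g <- sobel_gradient(matrix(rep(0:1, each = 8), 4, 4))
#' range(g$magnitude)
#' @export
sobel_gradient <- function(slice) {
  slice <- as_slice(slice)
  if (nrow(slice) < 3L || ncol(slice) < 3L)
    stop("slice must be at least 3x3", call. = FALSE)
  k <- sobel_kernels()
  gx <- conv2d(slice, k$row)
  gy <- conv2d(slice, k$col)
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

as_slice <- function(slice) {
  if (inherits(slice, "ct_volume"))
    stop("pass a single 2D slice (see get_slice()), not a volume", call. = FALSE)
  if (!is.matrix(slice)) slice <- as.matrix(slice)
  storage.mode(slice) <- "double"
  slice
}

#' Laplacian-of-Gaussian kernel
#'
#' Discrete LoG kernel
#' `(1 / (pi * sigma^4)) * (1 - r^2 / (2 sigma^2)) * exp(-r^2 / (2 sigma^2))`
#' truncated at radius `ceiling(4 * sigma)`. With `dc_correct = TRUE`
#' (default) the kernel is shifted to sum exactly to zero so that constant
#' images produce an exactly zero response.
#'
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param dc_correct subtract the mean so the kernel sums to 0.
#' @param radius kernel half-width in pixels; default `ceiling(4 * sigma)`.
#' @return numeric matrix of size `2 * radius + 1` squared.
#' @export
log_kernel <- function(sigma, dc_correct = TRUE, radius = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  r <- if (is.null(radius)) ceiling(4 * sigma) else radius
  ix <- seq(-r, r)
  r2 <- outer(ix^2, ix^2, "+")
  k <- (1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  if (dc_correct) k <- k - mean(k)
  k
}

#' Laplacian-of-Gaussian response of a slice
#'
#' @param slice numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return numeric matrix of filter responses, same size as `slice`.
#' @export
log_response <- function(slice, sigma) {
  slice <- as_slice(slice)
  # truncate the kernel so it always fits the image (large sigma on a small
  # slice); the DC correction keeps the truncated kernel zero-sum
  r <- min(ceiling(4 * sigma), (min(dim(slice)) - 1L) %/% 2L)
  conv2d(slice, log_kernel(sigma, radius = r))
}

#' Laplacian-of-Gaussian edge map (zero crossings)
#'
#' A pixel is marked as an edge when its LoG response differs in sign from at
#' least one 4-neighbour and the response jump across that crossing exceeds
#' `threshold * max(abs(response))`. The relative threshold suppresses the
#' shallow zero crossings that plain sign changes would mark all over flat,
#' noisy regions.
#'
#' @param slice numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param threshold relative amplitude threshold in `[0, 1]` (default 0.04).
#' @param scale reference response amplitude the threshold is relative to;
#'   defaults to this slice's `max(abs(response))`. When segmenting a whole
#'   stack, pass the volume-wide maximum so bone-free slices do not
#'   renormalise onto their own noise (see [segment_volume()]).
#' @return logical matrix with attribute `method = "log"`.
#' @export
log_edges <- function(slice, sigma, threshold = 0.04, scale = NULL) {
  slice <- as_slice(slice)
  resp <- log_response(slice, sigma)
  mx <- if (is.null(scale)) max(abs(resp)) else scale
  if (near_zero_response(mx, slice) || max(abs(resp)) <= 1e-9 * mx)
    return(edge_map(matrix(FALSE, nrow(resp), ncol(resp)), "log"))
  edges <- matrix(FALSE, nrow(resp), ncol(resp))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(resp, d[1], d[2], fill = NA)
    cross <- !is.na(nb) & (sign(resp) * sign(nb) < 0) &
      (abs(resp - nb) > threshold * mx)
    edges <- edges | cross
  }
  edge_map(edges, "log")
}

# FFT convolution of a flat image leaves responses at machine-epsilon scale;
# treat anything that small (relative to the intensity scale) as zero
near_zero_response <- function(mx, slice) {
  mx == 0 || mx <= 1e-9 * max(abs(slice))
}

edge_map <- function(pixels, method) {
  stopifnot(is.logical(pixels), is.matrix(pixels))
  attr(pixels, "method") <- method
  pixels
}

#' Gaussian smoothing kernel
#' @param sigma standard deviation in pixels.
#' @return normalised (sums to 1) square kernel of radius `ceiling(4*sigma)`.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  ix <- seq(-r, r)
  k <- exp(-outer(ix^2, ix^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Canny detector parameters
#'
#' @param sigma Gaussian smoothing standard deviation in pixels (> 0).
#' @param low,high hysteresis thresholds as fractions of the maximum smoothed
#'   gradient magnitude, `0 <= low <= high <= 1`.
#' @return A `canny_params` list.
#' @export
canny_params <- function(sigma = 2, low = 0.10, high = 0.90) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (!is.finite(low) || !is.finite(high) || low < 0 || high > 1 || low > high)
    stop("thresholds must satisfy 0 <= low <= high <= 1", call. = FALSE)
  structure(list(sigma = sigma, low = low, high = high), class = "canny_params")
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradient, non-maximum suppression along the
#' quantised gradient direction, then double-threshold hysteresis: weak edge
#' pixels survive only in 8-connected components that contain at least one
#' strong pixel. Thresholds are relative to the maximum smoothed gradient
#' magnitude, which makes the detector invariant to positive intensity
#' scaling.
#'
#' @param slice numeric matrix.
#' @param params a [canny_params()] object (default sigma 2, thresholds
#'   0.10 / 0.90).
#' @param scale reference gradient magnitude the thresholds are relative to;
#'   defaults to this slice's maximum (see [segment_volume()] for the
#'   stack-global variant).
#' @return logical matrix with attribute `method = "canny"`.
#' @export
canny_edges <- function(slice, params = canny_params(), scale = NULL) {
  if (!inherits(params, "canny_params")) stop("`params` must be canny_params()")
  slice <- as_slice(slice)
  sm <- conv2d(slice, gaussian_kernel(params$sigma))
  g <- sobel_gradient(sm)
  mag <- g$magnitude
  mx <- if (is.null(scale)) max(mag) else scale
  if (near_zero_response(mx, slice) || max(mag) <= 1e-9 * mx)
    return(edge_map(matrix(FALSE, nrow(mag), ncol(mag)), "canny"))
  # quantise gradient direction into 4 sectors; gi = row-, gj = col-gradient
  phi <- atan2(g$gx, g$gy) %% pi
  sector <- as.integer(round(phi / (pi / 4))) %% 4L
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- offs[[s + 1L]]
    fwd <- shift_mat(mag, d[1], d[2], fill = -Inf)
    bwd <- shift_mat(mag, -d[1], -d[2], fill = -Inf)
    keep <- (sector == s) & (mag >= fwd) & (mag > bwd)
    nms <- nms | keep
  }
  weak <- nms & (mag >= params$low * mx)
  strong <- nms & (mag >= params$high * mx)
  if (!any(strong))
    return(edge_map(matrix(FALSE, nrow(mag), ncol(mag)), "canny"))
  lab <- cpp_label_components(weak, 8L)
  keep_labels <- unique(lab[strong])
  edge_map(matrix(lab %in% keep_labels[keep_labels > 0], nrow(mag)), "canny")
}

#' Thresholded Sobel edge map
#'
#' The Sobel operator yields a gradient magnitude, not a binary edge map; a
#' relative threshold converts it into one. The default keeps pixels whose
#' magnitude exceeds 20% of the slice maximum.
#'
#' @param slice numeric matrix.
#' @param threshold fraction of the maximum gradient magnitude.
#' @param scale reference gradient magnitude the threshold is relative to;
#'   defaults to this slice's maximum.
#' @return logical matrix with attribute `method = "sobel"`.
#' @export
sobel_edges <- function(slice, threshold = 0.2, scale = NULL) {
  slice <- as_slice(slice)
  mag <- sobel_gradient(slice)$magnitude
  mx <- if (is.null(scale)) max(mag) else scale
  if (near_zero_response(mx, slice) || max(mag) <= 1e-9 * mx)
    return(edge_map(matrix(FALSE, nrow(mag), ncol(mag)), "sobel"))
  edge_map(mag >= threshold * mx, "sobel")
}

#' Average gradient magnitude of a slice
#'
#' Arithmetic mean of `sqrt(gx^2 + gy^2)` over the interior pixels (the
#' one-pixel border is excluded so padded values never enter the statistic).
#'
#' @param slice numeric matrix, at least 3x3.
#' @return scalar mean gradient magnitude.
#' @export
average_gradient_magnitude <- function(slice) {
  g <- sobel_gradient(slice)
  m <- g$magnitude
  mean(m[2:(nrow(m) - 1L), 2:(ncol(m) - 1L)])
}

#' Edge-length density
#'
#' For every edge pixel, the size of its 8-connected component divided by the
#' size of the largest component; non-edge pixels map to 0. Exposed as an
#' optional post-filter for edge maps: components much shorter than the
#' longest one are usually noise.
#'
#' @param edges logical matrix (edge map).
#' @return numeric matrix in `[0, 1]`, same size as `edges`.
#' @export
edge_length_density <- function(edges) {
  stopifnot(is.logical(edges), is.matrix(edges))
  out <- matrix(0, nrow(edges), ncol(edges))
  if (!any(edges)) return(out)
  lab <- cpp_label_components(edges, 8L)
  sizes <- tabulate(lab[lab > 0])
  out[lab > 0] <- sizes[lab[lab > 0]] / max(sizes)
  out
}

#' Filter an edge map by edge-length density
#'
#' @param edges logical edge map.
#' @param min_density drop edge pixels whose component's relative length is
#'   below this value.
#' @return filtered logical edge map.
#' @export
filter_edges_by_density <- function(edges, min_density) {
  dens <- edge_length_density(edges)
  edge_map(edges & (dens >= min_density), attr(edges, "method"))
}

#' Closed contour set for one slice
#'
#' @param contours list of n x 2 matrices of vertex coordinates in mm (closed
#'   polygons; the last vertex connects back to the first).
#' @param z physical slice position in mm.
#' @return A `contour_set` object.
#' @export
contour_set <- function(contours = list(), z = 0) {
  for (p in contours) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L || any(!is.finite(p)))
      stop("each contour must be a finite n x 2 matrix with n >= 3", call. = FALSE)
  }
  structure(list(contours = contours, z = as.numeric(z)), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> z = %.3g mm, %d contour(s)\n",
              x$z, length(x$contours)))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$contours)

# Moore-neighbour boundary tracing of one labelled component.
# Returns the closed boundary pixel path as a k x 2 matrix of (row, col)
# 1-based indices. `mask` must contain a single 4-connected component.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  # start: smallest column, then smallest row -> entered from the left
  start_j <- (idx[1] - 1L) %/% nr + 1L
  cand <- idx[(idx - 1L) %/% nr + 1L == start_j]
  start_i <- min((cand - 1L) %% nr + 1L)
  if (sum(mask) == 1L) return(matrix(c(start_i, start_j), 1L, 2L))
  # clockwise Moore neighbourhood starting from W
  moore <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                    0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                  ncol = 2L, byrow = TRUE)
  inside <- function(i, j) i >= 1L && i <= nr && j >= 1L && j <= nc && mask[i, j]
  path <- matrix(0L, 4L * sum(mask) + 8L, 2L)
  np <- 1L
  path[1L, ] <- c(start_i, start_j)
  cur <- c(start_i, start_j)
  back <- 1L  # index into moore of the direction we came from (W)
  repeat {
    found <- FALSE
    for (s in seq_len(8L)) {
      k <- (back - 1L + s - 1L) %% 8L + 1L
      ni <- cur[1] + moore[k, 1]; nj <- cur[2] + moore[k, 2]
      if (inside(ni, nj)) {
        # next backtrack: the neighbour just before this one, viewed from the
        # new pixel
        prevk <- (k - 2L) %% 8L + 1L
        pi <- cur[1] + moore[prevk, 1]; pj <- cur[2] + moore[prevk, 2]
        back <- which(moore[, 1] == pi - ni & moore[, 2] == pj - nj)
        cur <- c(ni, nj)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur[1] == start_i && cur[2] == start_j) break
    np <- np + 1L
    if (np > nrow(path)) break  # safety
    path[np, ] <- cur
  }
  unique_rows(path[seq_len(np), , drop = FALSE])
}

unique_rows <- function(m) {
  m[!duplicated(m[, 1] * (max(m[, 2]) + 1) + m[, 2]), , drop = FALSE]
}

#' Segment one CT slice into closed bone contours
#'
#' Runs the selected edge detector, then morphological closing (3x3 square),
#' hole filling, and connected-component selection, and finally traces each
#' retained region into a closed polygon in physical (mm) coordinates.
#'
#' Edge detectors respond on a band that straddles the true boundary, so the
#' filled region extends to the outer side of that band. To place the traced
#' contour on the band midline, the region boundary is corrected by averaging
#' the signed distance fields of the filled region and of the filled region
#' with the edge band removed, and re-thresholding at zero.
#'
#' @param slice numeric matrix of intensities.
#' @param method one of `"sobel"`, `"log"`, `"canny"`.
#' @param sigma Gaussian standard deviation in pixels (LoG default 4, Canny
#'   default 2).
#' @param low,high Canny hysteresis thresholds (defaults 0.10 / 0.90).
#' @param sobel_threshold relative magnitude threshold for the Sobel edge map.
#' @param log_threshold relative zero-crossing amplitude threshold for LoG.
#' @param min_area discard filled components smaller than this many pixels.
#' @param spacing in-plane pixel size in mm, length 2.
#' @param origin physical coordinate of pixel (0,0), length 2.
#' @param z physical slice position in mm.
#' @param scale reference response amplitude for the relative thresholds
#'   (see the individual detectors); per-slice maximum when NULL.
#' @param contour_smoothing window (vertices) of the circular moving average
#'   applied to traced contours to remove the pixel staircase; 1 disables.
#' @return A [contour_set()] (empty, with a warning, if nothing survives).
#' @export
segment_slice <- function(slice, method = c("canny", "log", "sobel"),
                          sigma = NULL, low = 0.10, high = 0.90,
                          sobel_threshold = 0.2, log_threshold = 0.04,
                          min_area = 50, spacing = c(1, 1), origin = c(0, 0),
                          z = 0, scale = NULL, contour_smoothing = 5L) {
  method <- match.arg(method)
  slice <- as_slice(slice)
  edges <- switch(method,
    sobel = sobel_edges(slice, threshold = sobel_threshold, scale = scale),
    log   = log_edges(slice, sigma = if (is.null(sigma)) 4 else sigma,
                      threshold = log_threshold, scale = scale),
    canny = canny_edges(slice, canny_params(if (is.null(sigma)) 2 else sigma,
                                            low, high), scale = scale))
  polys <- contours_from_edges(edges, min_area = min_area,
                               smoothing = contour_smoothing)
  if (length(polys) == 0L) {
    warning("no region survived filtering; returning an empty contour set",
            call. = FALSE)
    return(contour_set(list(), z = z))
  }
  polys_mm <- lapply(polys, function(p)
    cbind(origin[1] + (p[, 1] - 1) * spacing[1],
          origin[2] + (p[, 2] - 1) * spacing[2]))
  contour_set(polys_mm, z = z)
}

# edge map -> closing -> fill -> band-midline correction -> component
# selection -> traced outer boundaries (pixel indices, 1-based)
contours_from_edges <- function(edges, min_area = 50, smoothing = 5L) {
  if (!any(edges)) return(list())
  closed <- ebi_binary(EBImage::closing(mat01(edges),
                                        EBImage::makeBrush(3, "box")))
  filled <- ebi_binary(EBImage::fillHull(mat01(closed)))
  interior <- filled & !closed
  if (any(interior)) {
    field <- (signed_dist2d(filled) + signed_dist2d(interior)) / 2
  } else field <- signed_dist2d(filled)
  region <- field > 0
  if (!any(region)) return(list())
  lab <- cpp_label_components(region, 4L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  polys <- list()
  for (k in keep) {
    comp <- lab == k
    # re-fill per component: the midline correction can nick small holes
    comp <- ebi_binary(EBImage::fillHull(mat01(comp)))
    path <- trace_boundary(comp)
    if (!is.null(path) && nrow(path) >= 3L)
      polys[[length(polys) + 1L]] <-
        smooth_polygon(refine_to_zero(path, field), smoothing)
  }
  polys
}

# sub-pixel contour placement: move each traced boundary pixel onto the zero
# level of the signed band-midline field by one Newton step along the local
# field gradient (central differences); the step is clamped to one pixel
refine_to_zero <- function(path, field) {
  nr <- nrow(field); nc <- ncol(field)
  i <- path[, 1]; j <- path[, 2]
  f <- field[cbind(i, j)]
  gi <- (field[cbind(pmin(i + 1L, nr), j)] -
           field[cbind(pmax(i - 1L, 1L), j)]) / 2
  gj <- (field[cbind(i, pmin(j + 1L, nc))] -
           field[cbind(i, pmax(j - 1L, 1L))]) / 2
  g2 <- gi^2 + gj^2
  g2[g2 < 1e-12] <- 1
  di <- pmin(pmax(-f * gi / g2, -1), 1)
  dj <- pmin(pmax(-f * gj / g2, -1), 1)
  cbind(i + di, j + dj)
}

# circular moving average along the polygon: removes the one-pixel staircase
# of traced boundaries; for windows much shorter than the local curvature
# radius the induced shrink is negligible
smooth_polygon <- function(path, window) {
  n <- nrow(path)
  if (window <= 1L || n <= window) return(path)
  half <- (window - 1L) %/% 2L
  idx <- c((n - half + 1L):n, seq_len(n), seq_len(half))
  apply(path, 2, function(v) {
    as.numeric(stats::filter(v[idx], rep(1 / window, window),
                             sides = 2))[half + seq_len(n)]
  })
}

mat01 <- function(x) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}

ebi_binary <- function(x) {
  m <- if (is.matrix(x)) x else EBImage::imageData(x)
  matrix(m > 0.5, nrow(m), ncol(m))
}

# signed Euclidean distance (pixels): positive inside, negative outside;
# clamped to a finite range so all-foreground / all-background slices
# (where distmap is infinite) stay well behaved under interpolation
signed_dist2d <- function(mask) {
  fg <- mat01(mask)
  d_in <- EBImage::imageData(EBImage::distmap(fg))
  d_out <- EBImage::imageData(EBImage::distmap(1 - fg))
  lim <- nrow(mask) + ncol(mask)
  matrix(pmin(pmax(d_in - d_out, -lim), lim), nrow(mask), ncol(mask))
}

#' Segment every slice of a CT volume
#'
#' Applies [segment_slice()] to each axial slice, carrying the volume's
#' physical geometry into the contour coordinates.
#'
#' The detectors normalise their thresholds to each slice's maximum
#' response, which is the right behaviour within a slice that contains bone
#' but turns bone-free slices into pure noise detectors. A stack-level gate
#' therefore skips slices whose maximum response falls below `slice_gate`
#' times the volume-wide maximum: those slices contain no significant edges
#' and yield empty contour sets.
#'
#' @param vol a [ct_volume()].
#' @param method,... passed to [segment_slice()].
#' @param sigma detector Gaussian sigma in pixels (LoG default 4, Canny 2).
#' @param slice_gate fraction of the volume-wide maximum response a slice
#'   must reach to be segmented at all (default 0.2).
#' @return A [contour_stack()].
#' @export
segment_volume <- function(vol, method = c("canny", "log", "sobel"),
                           sigma = NULL, slice_gate = 0.2, ...) {
  stopifnot(inherits(vol, "ct_volume"))
  method <- match.arg(method)
  nz <- dim(vol$voxels)[3]
  resp_max <- vapply(seq_len(nz), function(i) {
    sl <- get_slice(vol, i)
    switch(method,
      sobel = max(sobel_gradient(sl)$magnitude),
      log   = max(abs(log_response(sl, if (is.null(sigma)) 4 else sigma))),
      canny = max(sobel_gradient(
        conv2d(sl, gaussian_kernel(if (is.null(sigma)) 2 else sigma))
      )$magnitude))
  }, numeric(1))
  gate <- slice_gate * max(resp_max)
  sets <- vector("list", nz)
  for (i in seq_len(nz)) {
    sets[[i]] <- if (resp_max[i] < gate) {
      contour_set(list(), z = slice_z(vol, i))
    } else {
      suppressWarnings(segment_slice(
        get_slice(vol, i), method = method, sigma = sigma,
        spacing = vol$spacing[1:2], origin = vol$origin[1:2],
        z = slice_z(vol, i), ...))
    }
  }
  contour_stack(sets, slice_spacing = vol$spacing[3])
}

#' Flatten contours to a tibble
#'
#' One row per polygon vertex, with columns `slice_z`, `contour_id`,
#' `vertex_index`, `x_mm`, `y_mm`.
#'
#' @param x a [contour_set()] or [contour_stack()].
#' @return a tibble.
#' @export
contours_to_tibble <- function(x) {
  sets <- if (inherits(x, "contour_stack")) x$slices else list(x)
  rows <- purrr::map_dfr(sets, function(cs) {
    if (length(cs$contours) == 0L) return(tibble::tibble())
    purrr::imap_dfr(cs$contours, function(p, id) {
      tibble::tibble(slice_z = cs$z, contour_id = id,
                     vertex_index = seq_len(nrow(p)),
                     x_mm = p[, 1], y_mm = p[, 2])
    })
  })
  if (nrow(rows) == 0L)
    rows <- tibble::tibble(slice_z = numeric(), contour_id = integer(),
                           vertex_index = integer(), x_mm = numeric(),
                           y_mm = numeric())
  rows
}

#' Write contours to CSV or JSON
#' @param x a [contour_set()] or [contour_stack()].
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_contours <- function(x, path) {
  tb <- contours_to_tibble(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") readr::write_csv(tb, path)
  else if (ext == "json") jsonlite::write_json(tb, path, digits = NA)
  else stop("unsupported contour format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read contours from a CSV written by [write_contours()]
#' @param path CSV path.
#' @param slice_spacing slice spacing in mm for the resulting stack.
#' @return a [contour_stack()].
#' @export
read_contours <- function(path, slice_spacing = 1) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("slice_z", "contour_id", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(tb)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sets <- tb |>
    dplyr::arrange(.data$slice_z, .data$contour_id, .data$vertex_index) |>
    dplyr::group_by(.data$slice_z) |>
    dplyr::group_map(function(df, key) {
      polys <- df |>
        dplyr::group_by(.data$contour_id) |>
        dplyr::group_map(function(p, k) cbind(p$x_mm, p$y_mm))
      contour_set(polys, z = key$slice_z[[1]])
    })
  contour_stack(sets, slice_spacing = slice_spacing)
}
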