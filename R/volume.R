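#' CT volume container
#'
#' A `ct_volume` wraps a 3D voxel intensity array together with its physical
#' geometry: per-axis spacing in mm and the physical coordinate of the center
#' of voxel (0,0,0). Voxel indices are 0-based; the physical position of a
#' voxel center is `origin + index * spacing`. The third array dimension is
#' the slice axis (axial stacking direction).
#'
#' @param voxels 3D numeric array of intensities (Hounsfield-like units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return A `ct_volume` object.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 3)), spacing = c(0.5, 0.5, 1))
#' dim(vol)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 3L))
    stop("grid dimensions must be at least 3 in each axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Extract one axial slice from a CT volume
#'
#' @param vol a [ct_volume()].
#' @param index 1-based slice index along the third (slice) axis.
#' @return A numeric matrix (first axis x, second axis y).
#' @export
get_slice <- function(vol, index) {
  stopifnot(inherits(vol, "ct_volume"))
  if (index < 1 || index > dim(vol$voxels)[3])
    stop("slice index out of range", call. = FALSE)
  vol$voxels[, , index]
}

#' Physical z position of a slice (mm)
#' @param vol a [ct_volume()].
#' @param index 1-based slice index.
#' @export
slice_z <- function(vol, index) {
  stopifnot(inherits(vol, "ct_volume"))
  vol$origin[3] + (index - 1) * vol$spacing[3]
}

#' Read a CT volume from a NIfTI file or a multi-page TIFF stack
#'
#' Intensities are passed through unchanged. For NIfTI, spacing is taken from
#' the pixdim header; for TIFF the spacing must be supplied.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param spacing voxel spacing in mm, required for TIFF input.
#' @param origin physical origin, defaults to (0,0,0).
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI volumes", call. = FALSE)
    img <- RNifti::readNifti(path)
    sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:3] else spacing
    return(ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp, origin))
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF stacks", call. = FALSE)
    if (is.null(spacing))
      stop("`spacing` must be given for TIFF input", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    # readTIFF returns row-major images: rows are y. Transpose to x,y order.
    arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- t(pages[[i]])
    return(ct_volume(arr, spacing, origin))
  }
  stop("unsupported volume format: .", ext, call. = FALSE)
}

#' Write a CT volume to a NIfTI file or TIFF stack
#'
#' @param vol a [ct_volume()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to write NIfTI volumes", call. = FALSE)
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF stacks", call. = FALSE)
    v <- vol$voxels
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(0, 1)
    pages <- lapply(seq_len(dim(v)[3]), function(i) t((v[, , i] - rng[1]) / diff(rng)))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}
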