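#' Write a surface mesh to STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(F)
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "kneeseg binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    # 12 floats + uint16 attribute per facet
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(nrm[i, ], V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ])),
               con, size = 4L, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid kneeseg", con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                V[F[i, 1:3], 1], V[F[i, 1:3], 2], V[F[i, 1:3], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid kneeseg", con)
  }
  invisible(path)
}

#' Read a surface mesh from STL (binary or ASCII, auto-detected)
#'
#' STL stores an unindexed triangle soup; vertices repeated across facets are
#' welded back into a shared index on read.
#'
#' @param path STL file path.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15)
    stop("STL parse error: file too short (", sz, " bytes)", call. = FALSE)
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(sz, 84))
  close(con)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  tris <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  weld_triangles(tris)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4L, endian = "little")
  tri <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2)
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^\\s*vertex\\s", lines)
  if (length(vidx) == 0L || length(vidx) %% 3L != 0L)
    stop("STL parse error: expected facets of 3 vertex lines (found ",
         length(vidx), " vertex lines)", call. = FALSE)
  parts <- strsplit(trimws(lines[vidx]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad))
    stop("STL parse error at line ", vidx[bad[1]], call. = FALSE)
  m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(m)))
    stop("STL parse error: non-numeric vertex near line ",
         vidx[which(!is.finite(rowSums(m)))[1]], call. = FALSE)
  m
}

# triangle soup (3k x 3, consecutive triples) -> indexed mesh
weld_triangles <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "/")
  uid <- !duplicated(key)
  idx <- match(key, key[uid])
  V <- tri[uid, , drop = FALSE]
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

#' Write a surface mesh to ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param colors optional n x 3 matrix of per-vertex RGB in `[0, 1]`, stored
#'   as uchar properties.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, colors = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", "comment kneeseg",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (!is.null(colors)) {
    stopifnot(nrow(colors) == nrow(V), ncol(colors) == 3L)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(colors)) {
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  } else {
    cb <- round(pmin(pmax(colors, 0), 1) * 255)
    writeLines(sprintf("%.9g %.9g %.9g %d %d %d", V[, 1], V[, 2], V[, 3],
                       cb[, 1], cb[, 2], cb[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

#' Read a surface mesh from ASCII PLY
#'
#' @param path PLY file path.
#' @return A [surface_mesh()]; per-vertex colors, if present, are attached as
#'   attribute `colors` (RGB in `[0, 1]`).
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic", call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY parse error: no end_header", call. = FALSE)
  hdr <- trimws(lines[seq_len(endh)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    stop("PLY parse error: vertex/face element counts missing", call. = FALSE)
  vprops <- sub("^property\\s+\\S+\\s+", "",
                hdr[grepl("^property ", hdr) & !grepl("list", hdr)])
  has_col <- all(c("red", "green", "blue") %in% vprops)
  vlines <- lines[(endh + 1):(endh + nv)]
  vm <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                 function(p) as.numeric(p), numeric(length(vprops))))
  V <- vm[, match(c("x", "y", "z"), vprops), drop = FALSE]
  flines <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- t(vapply(strsplit(trimws(flines), "\\s+"), function(p) {
    p <- as.numeric(p)
    if (p[1] != 3) stop("PLY parse error: only triangle faces are supported",
                        call. = FALSE)
    p[2:4]
  }, numeric(3)))
  mesh <- surface_mesh(V, fm + 1L)
  if (has_col) {
    attr(mesh, "colors") <-
      vm[, match(c("red", "green", "blue"), vprops), drop = FALSE] / 255
  }
  mesh
}

#' Read a mesh by file extension (.stl or .ply)
#' @param path mesh file path.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}

#' Write a mesh by file extension (.stl or .ply)
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param ... passed to the format writer.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, ...),
         ply = write_ply(mesh, path, ...),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}
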