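# shared fixtures and independent oracles, all built in code

# binary/level disk image; center defaults to the image center
disk_image <- function(n, r, inside = 1, outside = 0, cx = (n + 1) / 2,
                       cy = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+"))
  m <- matrix(outside, n, n)
  m[d <= r] <- inside
  m
}

# annular bone-like cross-section: cortical ring with soft background
annulus_slice <- function(n, r_out, r_in, levels = c(bg = 40, cortical = 1200,
                                                     trabecular = 300),
                          cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+"))
  m <- matrix(levels[["bg"]], n, n)
  m[d <= r_out] <- levels[["cortical"]]
  m[d <= r_in] <- levels[["trabecular"]]
  m
}

# voxelised solid sphere mask centered in an odd cube
sphere_volume <- function(r, half = 13, step = 1) {
  xs <- seq(-half, half, by = step)
  n <- length(xs)
  v <- array(FALSE, c(n, n, n))
  for (k in seq_len(n))
    v[, , k] <- outer(xs, xs, function(x, y) sqrt(x^2 + y^2 + xs[k]^2)) <= r
  v
}

sphere_mesh <- function(r, half = 13, step = 1) {
  extract_surface(sphere_volume(r, half, step), spacing = rep(step, 3),
                  origin = rep(-half, 3))
}

# small asymmetric mesh for registration tests (triaxial ellipsoid)
ellipsoid_mesh <- function() {
  xs <- seq(-15, 15, by = 1)
  v <- array(0, c(31, 31, 31))
  for (k in seq_len(31))
    v[, , k] <- outer(xs, xs,
                      function(x, y) (x / 12)^2 + (y / 8)^2 + (xs[k] / 5)^2) <= 1
  extract_surface(v, spacing = c(1, 1, 1), origin = c(-15, -15, -15))
}

# small single-tube phantom for fast end-to-end tests
small_phantom_spec <- function(seed = 1L, noise_sd = 20) {
  phantom_spec(
    bones = list(list(type = "tube", center = c(14, 14), radius = 10,
                      thickness = 4, zlim = c(3, 13))),
    dim = c(56L, 56L, 16L), spacing = c(0.5, 0.5, 1),
    soft_zlim = c(1, 15), seed = seed, noise_sd = noise_sd)
}

table1_path <- function() {
  system.file("extdata", "table1_fe_summary.csv", package = "kneeseg")
}

# ---- independent oracles ----------------------------------------------------

# edge-length density by recursive flood fill (8-connectivity)
edge_density_oracle <- function(edges) {
  nr <- nrow(edges); nc <- ncol(edges)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (sj in seq_len(nc)) for (si in seq_len(nr)) {
    if (!edges[si, sj] || lab[si, sj] > 0L) next
    cur <- cur + 1L
    stack <- list(c(si, sj)); lab[si, sj] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            edges[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- cur
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  out <- matrix(0, nr, nc)
  if (cur == 0L) return(out)
  sizes <- tabulate(lab[lab > 0L])
  out[lab > 0L] <- sizes[lab[lab > 0L]] / max(sizes)
  out
}

# exact closest point on one triangle by exhaustive feature enumeration:
# plane projection (if its barycentrics are admissible), the three edge
# segments, and the three vertices
closest_point_triangle_oracle <- function(q, a, b, c) {
  cands <- list(a, b, c)
  seg <- function(p0, p1) {
    t <- sum((q - p0) * (p1 - p0)) / sum((p1 - p0)^2)
    p0 + min(max(t, 0), 1) * (p1 - p0)
  }
  cands <- c(cands, list(seg(a, b), seg(b, c), seg(c, a)))
  e1 <- b - a; e2 <- c - a
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  if (sum(nrm^2) > 0) {
    proj <- q - sum((q - a) * nrm) / sum(nrm^2) * nrm
    M <- cbind(e1, e2)
    uv <- tryCatch(solve(crossprod(M), crossprod(M, proj - a)),
                   error = function(e) NULL)
    if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cands <- c(cands, list(a + uv[1] * e1 + uv[2] * e2))
  }
  d <- vapply(cands, function(p) sqrt(sum((q - p)^2)), numeric(1))
  list(point = cands[[which.min(d)]], distance = min(d))
}

closest_point_mesh_oracle <- function(q, mesh) {
  best <- Inf
  for (f in seq_len(nrow(mesh$faces))) {
    r <- closest_point_triangle_oracle(q, mesh$vertices[mesh$faces[f, 1], ],
                                       mesh$vertices[mesh$faces[f, 2], ],
                                       mesh$vertices[mesh$faces[f, 3], ])
    if (r$distance < best) best <- r$distance
  }
  best
}

# direct loop-based Sobel magnitude mean over interior pixels (Eq-style
# oracle, independent of the convolution machinery)
avg_gradient_oracle <- function(slice) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE)
  ky <- t(kx)
  nr <- nrow(slice); nc <- ncol(slice)
  acc <- 0; n <- 0
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    gx <- 0; gy <- 0
    for (u in -1:1) for (v in -1:1) {
      gx <- gx + kx[u + 2, v + 2] * slice[i - u, j - v]
      gy <- gy + ky[u + 2, v + 2] * slice[i - u, j - v]
    }
    acc <- acc + sqrt(gx^2 + gy^2); n <- n + 1
  }
  acc / n
}
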