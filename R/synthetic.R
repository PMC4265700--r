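#' Phantom specification for synthetic CT volumes
#'
#' Describes a bone-like phantom: geometric primitives with a bright
#' cortical shell, four tissue intensity levels, partial-volume Gaussian
#' blur, additive noise, and the voxel grid. All geometry is in mm.
#'
#' Primitives (each a list):
#' \describe{
#'   \item{tube}{`center = c(x, y)`, `radius`, `thickness`, `zlim = c(z0, z1)`;
#'     an axis-aligned cylinder with cortical shell `thickness` (also capping
#'     the ends).}
#'   \item{cone}{as tube, but `radius = c(r0, r1)` varying linearly from `z0`
#'     to `z1`.}
#'   \item{sphere}{`center = c(x, y, z)`, `radius`, `thickness`.}
#' }
#'
#' The soft-tissue compartment fills the whole field of view for
#' `z` in `soft_zlim` (as in a clinical scan whose in-plane field of view
#' lies inside the limb), with background (air) beyond.
#'
#' @param bones list of primitive specifications.
#' @param intensities named numeric vector with `background`, `soft`,
#'   `trabecular`, `cortical` levels (Hounsfield-like; defaults -100, 40,
#'   300, 1200).
#' @param blur_sigma partial-volume Gaussian blur, mm (default 0.4).
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   units (default 20).
#' @param dim integer grid dimensions.
#' @param spacing voxel spacing in mm (default 0.5 x 0.5 x 1: thin-slice CT
#'   with sub-millimetre pixels).
#' @param origin physical position of voxel (0,0,0).
#' @param soft_zlim z range (mm) of the soft-tissue compartment.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(bones,
                         intensities = c(background = -100, soft = 40,
                                         trabecular = 300, cortical = 1200),
                         blur_sigma = 0.4, noise_sd = 20,
                         dim = c(96, 96, 40), spacing = c(0.5, 0.5, 1),
                         origin = c(0, 0, 0), soft_zlim = NULL, seed = 1L) {
  need <- c("background", "soft", "trabecular", "cortical")
  if (!all(need %in% names(intensities)) || any(!is.finite(intensities)))
    stop("`intensities` must contain finite levels: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  for (b in bones) {
    if (!b$type %in% c("tube", "cone", "sphere"))
      stop("unknown primitive type: ", b$type, call. = FALSE)
    if (any(b$thickness >= min(b$radius)))
      stop("cortical thickness must be smaller than the outer radius",
           call. = FALSE)
  }
  structure(list(bones = bones, intensities = intensities[need],
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 dim = as.integer(dim), spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 soft_zlim = soft_zlim, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default knee-scale phantom: two parallel cortical tubes
#'
#' A femur/tibia analogue — two cortical tubes (outer radii 22 and 18 mm,
#' 6 mm cortical wall, 30 mm long) separated by an 8 mm gap, on a
#' 0.5 x 0.5 x 1 mm grid, matching thin-slice knee CT geometry.
#'
#' @param seed RNG seed for the noise.
#' @param noise_sd additive noise level (default 20).
#' @param blur_sigma partial-volume blur in mm (default 0.4).
#' @return A [phantom_spec()].
#' @export
knee_phantom_spec <- function(seed = 1L, noise_sd = 20, blur_sigma = 0.4) {
  phantom_spec(
    bones = list(
      list(type = "tube", center = c(26, 27), radius = 22, thickness = 6,
           zlim = c(6, 36)),
      list(type = "tube", center = c(74, 27), radius = 18, thickness = 6,
           zlim = c(6, 36))),
    dim = c(196L, 108L, 40L), spacing = c(0.5, 0.5, 1),
    soft_zlim = c(2, 38), seed = seed, noise_sd = noise_sd,
    blur_sigma = blur_sigma)
}

# signed distance (mm, negative inside) from points to a primitive's outer
# surface, optionally shrunk by `shrink` (used for the inner cortical wall)
sdf_primitive <- function(b, pts, shrink = 0) {
  if (b$type == "sphere") {
    d <- sqrt((pts[, 1] - b$center[1])^2 + (pts[, 2] - b$center[2])^2 +
                (pts[, 3] - b$center[3])^2)
    return(d - (b$radius - shrink))
  }
  rho <- sqrt((pts[, 1] - b$center[1])^2 + (pts[, 2] - b$center[2])^2)
  if (b$type == "tube") {
    dr <- rho - (b$radius - shrink)
  } else {
    t <- pmin(pmax((pts[, 3] - b$zlim[1]) / diff(b$zlim), 0), 1)
    rad <- b$radius[1] + (b$radius[length(b$radius)] - b$radius[1]) * t
    slope <- (b$radius[length(b$radius)] - b$radius[1]) / diff(b$zlim)
    dr <- (rho - (rad - shrink)) * cos(atan(slope))
  }
  dz <- pmax(b$zlim[1] + shrink - pts[, 3], pts[, 3] - (b$zlim[2] - shrink))
  # capped-cylinder signed distance
  pmin(pmax(dr, dz), 0) + sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
}

# inside test at arbitrary points (n x 3, mm)
inside_primitive <- function(b, pts, shrink = 0) {
  sdf_primitive(b, pts, shrink) <= 0
}

primitive_extent <- function(b) {
  if (b$type == "tube")
    rbind(c(b$center - b$radius, b$zlim[1]), c(b$center + b$radius, b$zlim[2]))
  else if (b$type == "cone") {
    r <- max(b$radius)
    rbind(c(b$center - r, b$zlim[1]), c(b$center + r, b$zlim[2]))
  } else
    rbind(b$center - b$radius, b$center + b$radius)
}

#' Generate a synthetic CT phantom with analytic ground truth
#'
#' Renders the phantom into a voxel volume (crisp tissue labels from the
#' analytic geometry, then Gaussian partial-volume blur, then seeded additive
#' Gaussian noise), and builds the exact ground-truth surface mesh of the
#' noise-free outer bone surfaces by parametric triangulation. The global RNG
#' state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [ct_volume()]), `mesh` (ground-truth
#'   [surface_mesh()]), `inside` (vectorised analytic inside test,
#'   `function(pts)`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lo <- spec$origin
  hi <- spec$origin + (spec$dim - 1) * spec$spacing
  for (b in spec$bones) {
    ext <- primitive_extent(b)
    if (any(ext[1, ] < lo) || any(ext[2, ] > hi))
      stop("bone extends outside the voxel grid", call. = FALSE)
  }
  xs <- lo[1] + (seq_len(spec$dim[1]) - 1) * spec$spacing[1]
  ys <- lo[2] + (seq_len(spec$dim[2]) - 1) * spec$spacing[2]
  zs <- lo[3] + (seq_len(spec$dim[3]) - 1) * spec$spacing[3]
  lv <- spec$intensities
  # partial volume is modelled analytically: each tissue boundary contributes
  # through a Gaussian-CDF ramp of its signed distance with width blur_sigma,
  # so sub-voxel surface positions survive sampling instead of being snapped
  # to the voxel lattice (blur_sigma = 0 gives crisp levels)
  wgt <- function(d) {
    if (spec$blur_sigma > 0) stats::pnorm(-d / spec$blur_sigma)
    else as.numeric(d <= 0)
  }
  vol <- array(lv[["background"]], spec$dim)
  grid_xy <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  for (k in seq_along(zs)) {
    sl <- rep(lv[["background"]], nrow(grid_xy))
    if (!is.null(spec$soft_zlim)) {
      d_slab <- max(spec$soft_zlim[1] - zs[k], zs[k] - spec$soft_zlim[2])
      sl <- sl + (lv[["soft"]] - lv[["background"]]) * wgt(d_slab)
    } else sl <- rep(lv[["soft"]], nrow(grid_xy))
    pts <- cbind(grid_xy, zs[k])
    for (b in spec$bones) {
      w_out <- wgt(sdf_primitive(b, pts))
      if (all(w_out < 1e-12)) next
      w_in <- wgt(sdf_primitive(b, pts, shrink = b$thickness))
      sl <- sl * (1 - w_out) + lv[["cortical"]] * w_out
      sl <- sl * (1 - w_in) + lv[["trabecular"]] * w_in
    }
    vol[, , k] <- sl
  }
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  }
  meshes <- lapply(spec$bones, primitive_mesh)
  list(volume = ct_volume(vol, spec$spacing, spec$origin),
       mesh = merge_meshes(meshes),
       inside = function(pts) {
         pts <- as_points(pts)
         Reduce(`|`, lapply(spec$bones, inside_primitive, pts = pts))
       },
       spec = spec)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
}

# parametric ground-truth meshes ---------------------------------------------

primitive_mesh <- function(b, ds = 1) {
  if (b$type == "sphere") return(mesh_uv_sphere(b$center, b$radius, ds))
  radii <- if (b$type == "tube") c(b$radius, b$radius)
           else c(b$radius[1], b$radius[length(b$radius)])
  mesh_revolution(b$center, radii, b$zlim, ds)
}

# closed surface of revolution (cylinder / truncated cone) with end caps
# triangulated as fans over the rim vertices, so every vertex lies exactly on
# the analytic outer surface
mesh_revolution <- function(center, radii, zlim, ds = 1) {
  nt <- max(24L, ceiling(2 * pi * max(radii) / ds))
  nz <- max(2L, ceiling(diff(zlim) / ds) + 1L)
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  zs <- seq(zlim[1], zlim[2], length.out = nz)
  rs <- radii[1] + (radii[2] - radii[1]) * (zs - zlim[1]) / diff(zlim)
  V <- do.call(rbind, lapply(seq_len(nz), function(i)
    cbind(center[1] + rs[i] * cos(theta), center[2] + rs[i] * sin(theta), zs[i])))
  vid <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  F <- list()
  for (i in seq_len(nz - 1L)) for (j in seq_len(nt)) {
    F[[length(F) + 1L]] <- c(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L))
    F[[length(F) + 1L]] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j))
  }
  for (j in 2:(nt - 1L)) {                       # bottom cap (normal -z)
    F[[length(F) + 1L]] <- c(vid(1L, 1L), vid(1L, j + 1L), vid(1L, j))
  }
  for (j in 2:(nt - 1L)) {                       # top cap (normal +z)
    F[[length(F) + 1L]] <- c(vid(nz, 1L), vid(nz, j), vid(nz, j + 1L))
  }
  orient_outward(surface_mesh(V, do.call(rbind, F)))
}

mesh_uv_sphere <- function(center, radius, ds = 1) {
  nt <- max(16L, ceiling(2 * pi * radius / ds))
  np <- max(8L, ceiling(pi * radius / ds))
  theta <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  phi <- seq(0, pi, length.out = np + 1L)[2:np]   # exclude poles
  V <- do.call(rbind, lapply(phi, function(p)
    cbind(center[1] + radius * sin(p) * cos(theta),
          center[2] + radius * sin(p) * sin(theta),
          center[3] + radius * cos(p))))
  north <- nrow(V) + 1L; south <- nrow(V) + 2L
  V <- rbind(V, c(center[1], center[2], center[3] + radius),
                c(center[1], center[2], center[3] - radius))
  vid <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  F <- list()
  nb <- length(phi)
  for (j in seq_len(nt)) {
    F[[length(F) + 1L]] <- c(north, vid(1L, j), vid(1L, j + 1L))
    F[[length(F) + 1L]] <- c(south, vid(nb, j + 1L), vid(nb, j))
  }
  for (i in seq_len(nb - 1L)) for (j in seq_len(nt)) {
    F[[length(F) + 1L]] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
    F[[length(F) + 1L]] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  }
  orient_outward(surface_mesh(V, do.call(rbind, F)))
}

#' Concatenate several meshes into one
#' @param meshes list of [surface_mesh()] objects.
#' @return a single [surface_mesh()].
#' @export
merge_meshes <- function(meshes) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  surface_mesh(do.call(rbind, lapply(meshes, function(m) m$vertices)),
               do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                                  offs[-length(offs)])))
}

#' Rigidly transformed, noised point cloud with its true transform
#'
#' Test harness for ICP: applies an exact rigid transform to the mesh
#' vertices, then perturbs them with seeded isotropic Gaussian noise.
#'
#' @param mesh a [surface_mesh()] (or n x 3 point matrix).
#' @param angles Euler rotation angles about x, y, z in degrees.
#' @param translation length-3 translation in mm.
#' @param noise_sigma isotropic Gaussian noise sd in mm (default 0).
#' @param seed RNG seed.
#' @return list with `points` (n x 3) and `transform` (the exact
#'   [rigid_transform()] applied).
#' @export
generate_transformed_cloud <- function(mesh, angles = c(0, 0, 0),
                                       translation = c(0, 0, 0),
                                       noise_sigma = 0, seed = 1L) {
  pts <- as_points(mesh)
  tr <- rigid_transform(rotation_from_euler(angles), translation)
  out <- apply_transform(tr, pts)
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sigma),
                        nrow(out), 3L)
  }
  list(points = out, transform = tr)
}

#' Synthetic uniaxial stress-strain curve from known Ogden parameters
#'
#' @param params an [ogden_parameters()] object (ligament-like default:
#'   order 1, mu 1.5 MPa, alpha 8 — a stiffening toe-region curve; these are
#'   generator conventions, not measured ligament constants).
#' @param stretch_range range of stretches sampled (default 1 to 1.6).
#' @param n number of evenly spaced points (default 30).
#' @param noise_sigma additive Gaussian noise sd in MPa (default 0).
#' @param seed RNG seed.
#' @return a [stress_strain_curve()].
#' @export
generate_stress_strain <- function(params = ogden_parameters(1.5, 8),
                                   stretch_range = c(1, 1.6), n = 30,
                                   noise_sigma = 0, seed = 1L) {
  stretch <- seq(stretch_range[1], stretch_range[2], length.out = n)
  stress <- uniaxial_stress(stretch, params)
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    stress <- stress + stats::rnorm(n, 0, noise_sigma)
  }
  stress_strain_curve(stretch = stretch, stress_mpa = stress)
}

#' Synthetic per-angle FE summary tables with known error rates
#'
#' Builds a reference series and per-method test series offset from it, so
#' the error rate of each method is known in closed form
#' (`sum(abs(offsets))`).
#'
#' @param offsets named list: per test method, a numeric vector of per-angle
#'   offsets added to the reference values.
#' @param reference_values reference-method values per angle.
#' @param angles flexion angles in degrees.
#' @param quantity quantity label.
#' @param reference_method name of the reference method.
#' @return list with `table` (an `angle_table` tibble) and `eta` (named
#'   vector of exact error rates per method).
#' @export
generate_angle_tables <- function(offsets,
                                  reference_values = c(10, 8, 7, 8),
                                  angles = c(0, 45, 90, 135),
                                  quantity = "von_mises",
                                  reference_method = "Method 1") {
  stopifnot(is.list(offsets), !is.null(names(offsets)))
  rows <- list(tibble::tibble(method = reference_method, quantity = quantity,
                              angle_deg = angles, value = reference_values))
  eta <- numeric(0)
  for (m in names(offsets)) {
    off <- as.numeric(offsets[[m]])
    if (length(off) == 1L) off <- rep(off, length(angles))
    stopifnot(length(off) == length(angles))
    rows[[length(rows) + 1L]] <-
      tibble::tibble(method = m, quantity = quantity, angle_deg = angles,
                     value = reference_values + off)
    eta[m] <- sum(abs(off))
  }
  tb <- dplyr::bind_rows(rows)
  class(tb) <- c("angle_table", class(tb))
  list(table = tb, eta = eta)
}
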