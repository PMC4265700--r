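#' Ogden hyperelastic model parameters
#'
#' The order-N Ogden strain-energy density in principal stretches,
#' `W = sum_i mu_i/alpha_i * (l1^a_i + l2^a_i + l3^a_i - 3)` for
#' incompressible materials, plus a volumetric term
#' `sum_i (1/d_i) (J - 1)^(2i)` in the compressible form. Near the reference
#' state the model is stable when `sum(mu * alpha) > 0` (twice the
#' small-strain shear modulus).
#'
#' @param mu numeric vector of shear-like moduli (MPa).
#' @param alpha numeric vector of dimensionless exponents, same length.
#' @param d optional vector of volume-change parameters (1/MPa) for the
#'   compressible form.
#' @return An `ogden_parameters` object with order `N = length(mu)`.
#' @examples
#' ogden_parameters(mu = 1.5, alpha = 8)
#' @export
ogden_parameters <- function(mu, alpha, d = NULL) {
  mu <- as.numeric(mu); alpha <- as.numeric(alpha)
  if (length(mu) != length(alpha) || length(mu) == 0L)
    stop("`mu` and `alpha` must have equal, positive length", call. = FALSE)
  if (any(!is.finite(mu)) || any(!is.finite(alpha)))
    stop("parameters must be finite", call. = FALSE)
  if (sum(mu * alpha) <= 0)
    stop("unstable parameter set: sum(mu * alpha) must be positive",
         call. = FALSE)
  if (!is.null(d)) {
    d <- as.numeric(d)
    if (length(d) != length(mu) || any(!is.finite(d)) || any(d <= 0))
      stop("`d` must be positive and match the model order", call. = FALSE)
  }
  structure(list(N = length(mu), mu = mu, alpha = alpha, d = d),
            class = "ogden_parameters")
}

#' @export
print.ogden_parameters <- function(x, ...) {
  cat(sprintf("<ogden_parameters> order %d\n", x$N))
  for (i in seq_len(x$N))
    cat(sprintf("  mu_%d = %.6g MPa, alpha_%d = %.6g%s\n", i, x$mu[i], i,
                x$alpha[i],
                if (!is.null(x$d)) sprintf(", d_%d = %.6g 1/MPa", i, x$d[i]) else ""))
  invisible(x)
}

#' Principal stretches of a deformation gradient
#'
#' The principal stretches are the square roots of the eigenvalues of the
#' right Cauchy-Green tensor `C = t(F) %*% F`, returned in descending order.
#' (Equivalently the singular values of `F`; this keeps the identity
#' `J = det(F) = l1*l2*l3`.)
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return numeric length-3 vector of principal stretches.
#' @examples
#' principal_stretches(diag(c(2, 1, 0.5)))
#' @export
principal_stretches <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) stop("F must be 3x3", call. = FALSE)
  if (det(F) <= 0)
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  ev <- eigen(crossprod(F), symmetric = TRUE, only.values = TRUE)$values
  sort(sqrt(pmax(ev, 0)), decreasing = TRUE)
}

check_stretches <- function(lambda) {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 3L || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("principal stretches must be 3 positive numbers", call. = FALSE)
  lambda
}

#' Ogden strain-energy density
#'
#' Incompressible form (`J = l1*l2*l3 = 1` required within 1e-6):
#' `W = sum_i mu_i/alpha_i * (l1^a_i + l2^a_i + l3^a_i - 3)`.
#' Compressible form adds `sum_i (1/d_i) * (J - 1)^(2i)` and requires `d`.
#'
#' @param lambda length-3 vector of principal stretches.
#' @param params an [ogden_parameters()] object.
#' @param incompressible use the reduced incompressible form (default TRUE).
#' @return scalar energy density (MPa).
#' @export
ogden_energy <- function(lambda, params, incompressible = TRUE) {
  stopifnot(inherits(params, "ogden_parameters"))
  lambda <- check_stretches(lambda)
  J <- prod(lambda)
  iso <- sum(params$mu / params$alpha *
               (colSums(outer(lambda, params$alpha, "^")) - 3))
  if (incompressible) {
    if (abs(J - 1) > 1e-6)
      stop(sprintf("incompressibility violated: J = %.8g (|J - 1| > 1e-6)", J),
           call. = FALSE)
    return(iso)
  }
  if (is.null(params$d))
    stop("compressible form requires volume-change parameters `d`",
         call. = FALSE)
  iso + sum((1 / params$d) * (J - 1)^(2 * seq_len(params$N)))
}

#' Principal Cauchy stresses of the incompressible Ogden model
#'
#' The raw principal stresses `sigma_k = lambda_k * dW/dlambda_k =
#' sum_i mu_i * lambda_k^alpha_i` are defined only up to a hydrostatic
#' pressure under incompressibility. With `eliminate_pressure = TRUE`
#' (default) the pressure is removed by referencing the third direction,
#' returning `sigma_k - sigma_3` — the mechanically meaningful differences
#' when direction 3 is traction-free.
#'
#' @param lambda length-3 vector of principal stretches with
#'   `prod(lambda) = 1` within 1e-6.
#' @param params an [ogden_parameters()] object.
#' @param eliminate_pressure subtract `sigma_3` (default TRUE); FALSE returns
#'   the raw formula.
#' @return length-3 vector of principal stresses (MPa).
#' @export
principal_stress <- function(lambda, params, eliminate_pressure = TRUE) {
  stopifnot(inherits(params, "ogden_parameters"))
  lambda <- check_stretches(lambda)
  if (abs(prod(lambda) - 1) > 1e-6)
    stop("principal_stress requires an incompressible stretch triple",
         call. = FALSE)
  raw <- vapply(lambda, function(l) sum(params$mu * l^params$alpha), numeric(1))
  if (eliminate_pressure) raw - raw[3] else raw
}

#' Uniaxial Cauchy stress of the incompressible Ogden model
#'
#' Uniaxial loading of an incompressible material with traction-free lateral
#' faces: `l2 = l3 = l^(-1/2)` and
#' `sigma(l) = sum_i mu_i * (l^alpha_i - l^(-alpha_i/2))`.
#'
#' @param lambda scalar or vector of axial stretches (> 0).
#' @param params an [ogden_parameters()] object.
#' @return stress in MPa, same length as `lambda`.
#' @examples
#' uniaxial_stress(c(1, 1.2, 1.5), ogden_parameters(1.5, 8))
#' @export
uniaxial_stress <- function(lambda, params) {
  stopifnot(inherits(params, "ogden_parameters"))
  lambda <- as.numeric(lambda)
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("stretches must be positive", call. = FALSE)
  vapply(lambda, function(l)
    sum(params$mu * (l^params$alpha - l^(-params$alpha / 2))), numeric(1))
}

#' Stress-strain curve container
#'
#' @param stretch strictly increasing positive stretches (lambda), or pass
#'   `strain` instead (engineering strain, `lambda = 1 + strain`).
#' @param stress_mpa uniaxial stress observations (MPa).
#' @param strain optional engineering strain alternative to `stretch`.
#' @return tibble of class `stress_strain_curve` with columns `stretch`,
#'   `stress_mpa`.
#' @export
stress_strain_curve <- function(stretch = NULL, stress_mpa, strain = NULL) {
  if (is.null(stretch)) {
    if (is.null(strain)) stop("give `stretch` or `strain`", call. = FALSE)
    stretch <- 1 + as.numeric(strain)
  }
  stretch <- as.numeric(stretch)
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("stretches must be positive and finite", call. = FALSE)
  if (is.unsorted(stretch, strictly = TRUE))
    stop("stretches must be strictly increasing", call. = FALSE)
  if (length(stress_mpa) != length(stretch))
    stop("`stress_mpa` must match `stretch` in length", call. = FALSE)
  out <- tibble::tibble(stretch = stretch, stress_mpa = as.numeric(stress_mpa))
  class(out) <- c("stress_strain_curve", class(out))
  out
}

#' Read / write a stress-strain curve CSV
#'
#' Two-column CSV with header `stretch,stress_mpa` or `strain,stress_mpa`
#' (the strain convention is declared by the header name).
#'
#' @param path CSV path.
#' @return a [stress_strain_curve()].
#' @export
read_stress_strain <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("stretch", "stress_mpa") %in% names(tb)))
    stress_strain_curve(stretch = tb$stretch, stress_mpa = tb$stress_mpa)
  else if (all(c("strain", "stress_mpa") %in% names(tb)))
    stress_strain_curve(strain = tb$strain, stress_mpa = tb$stress_mpa)
  else stop("curve CSV must have columns stretch,stress_mpa or strain,stress_mpa",
            call. = FALSE)
}

#' @rdname read_stress_strain
#' @param curve a [stress_strain_curve()].
#' @export
write_stress_strain <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve)[c("stretch", "stress_mpa")], path)
  invisible(path)
}

#' Fit an Ogden model to a uniaxial stress-strain curve
#'
#' Nonlinear least squares of [uniaxial_stress()] against the observed curve
#' using the Levenberg-Marquardt trust-region algorithm (minpack.lm), with
#' bounds `mu > 0` and `0.1 < alpha < 40`.
#'
#' @param curve a [stress_strain_curve()] (or data frame with `stretch` and
#'   `stress_mpa`).
#' @param N model order (default 1); needs at least `2 * N` data points.
#' @param initial optional [ogden_parameters()] starting point; default
#'   `mu = 1, alpha = 5` per term (alphas spread for higher orders).
#' @return An `ogden_fit`: list with `params` ([ogden_parameters()]), `rms`
#'   (residual RMS, MPa), `fitted`, `curve`, and the underlying `nls` object.
#' @export
fit_ogden <- function(curve, N = 1, initial = NULL) {
  curve <- tibble::as_tibble(curve)
  stopifnot(all(c("stretch", "stress_mpa") %in% names(curve)))
  if (nrow(curve) < 2 * N)
    stop("need at least 2N data points to fit an order-N model", call. = FALSE)
  if (is.null(initial)) {
    start_mu <- rep(1, N)
    start_alpha <- if (N == 1) 5 else seq(2, 12, length.out = N)
  } else {
    stopifnot(inherits(initial, "ogden_parameters"), initial$N == N)
    start_mu <- initial$mu; start_alpha <- initial$alpha
  }
  start <- stats::setNames(c(start_mu, start_alpha),
                           c(paste0("mu", seq_len(N)), paste0("alpha", seq_len(N))))
  terms <- paste(sprintf("mu%d * (stretch^alpha%d - stretch^(-alpha%d/2))",
                         seq_len(N), seq_len(N), seq_len(N)), collapse = " + ")
  fml <- stats::as.formula(paste("stress_mpa ~", terms))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = curve, start = start,
                      lower = c(rep(1e-8, N), rep(0.1, N)),
                      upper = c(rep(Inf, N), rep(40, N)),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15,
                                                           ptol = 1e-15)),
    error = function(e)
      stop("Ogden fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  params <- ogden_parameters(mu = cf[paste0("mu", seq_len(N))],
                             alpha = cf[paste0("alpha", seq_len(N))])
  resid <- curve$stress_mpa - uniaxial_stress(curve$stretch, params)
  structure(list(params = params, rms = sqrt(mean(resid^2)),
                 fitted = uniaxial_stress(curve$stretch, params),
                 curve = curve, nls = fit),
            class = "ogden_fit")
}

#' @export
print.ogden_fit <- function(x, ...) {
  cat(sprintf("<ogden_fit> order %d, residual RMS %.4g MPa on %d points\n",
              x$params$N, x$rms, nrow(x$curve)))
  print(x$params)
  invisible(x)
}

#' @export
tidy.ogden_fit <- function(x, ...) {
  tibble::tibble(term = c(paste0("mu", seq_len(x$params$N)),
                          paste0("alpha", seq_len(x$params$N))),
                 estimate = c(x$params$mu, x$params$alpha))
}

#' @export
glance.ogden_fit <- function(x, ...) {
  tibble::tibble(order = x$params$N, rms_mpa = x$rms, n = nrow(x$curve),
                 shear_modulus_mpa = sum(x$params$mu * x$params$alpha) / 2)
}

#' @export
predict.ogden_fit <- function(object, newdata = NULL, ...) {
  stretch <- if (is.null(newdata)) object$curve$stretch else newdata$stretch
  uniaxial_stress(stretch, object$params)
}

#' Write fitted Ogden parameters to JSON
#' @param params an [ogden_parameters()] or [fit_ogden()] result.
#' @param path JSON path.
#' @export
write_ogden_json <- function(params, path) {
  if (inherits(params, "ogden_fit")) params <- params$params
  stopifnot(inherits(params, "ogden_parameters"))
  jsonlite::write_json(list(order = params$N, mu_mpa = params$mu,
                            alpha = params$alpha, d = params$d),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
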