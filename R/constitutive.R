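#' Material parameters of the anisotropic modified Mooney-Rivlin model
#'
#' Builds a parameter set for the anisotropic modified Mooney-Rivlin strain
#' energy
#' \deqn{W = c_1(I_1-3) + c_2(I_2-3) + D_1[\exp(D_2(I_1-3)) - 1] +
#'       (K_1/K_2)\{\exp[K_2(I_4-1)^2] - 1\},}
#' where \eqn{I_1, I_2} are the isotropic invariants of the right
#' Cauchy-Green tensor and \eqn{I_4} is the squared stretch along the fiber
#' direction (circumferential by default, capturing the circumferential
#' stiffening of aortic tissue).
#'
#' `c1`, `c2`, `D1`, `K1` carry stress units (kPa); `D2` and `K2` are
#' dimensionless exponents. The default values are the baseline aortic set
#' obtained from fits to human aortic stress-stretch data:
#' c1 = -525.16, c2 = 165.9, D1 = 231.8, D2 = 3.5, K1 = 33.4, K2 = 12.6.
#'
#' Because the baseline `c1` is negative, the constructor checks that the
#' incremental stiffness of the uniaxial response along the fiber is positive
#' over stretches 1 to 1.3 and emits a warning (not an error) when it is not.
#'
#' @param c1,c2,D1,K1 stress-like constants, kPa.
#' @param D2,K2 dimensionless exponents; must be positive.
#' @param fiber_direction unit 3-vector; defaults to the circumferential
#'   direction `c(0, 1, 0)` in the (radial, circumferential, axial) frame.
#' @param check_stability logical; run the uniaxial stability check.
#' @return an object of class `material_params`.
#' @examples
#' mp <- material_params()
#' scale_params(mp, 1.5)
#' @export
material_params <- function(c1 = -525.16, c2 = 165.9, D1 = 231.8, D2 = 3.5,
                            K1 = 33.4, K2 = 12.6,
                            fiber_direction = c(0, 1, 0),
                            check_stability = TRUE) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(D1), is.numeric(D2),
            is.numeric(K1), is.numeric(K2), length(fiber_direction) == 3)
  if (D2 <= 0) stop("D2 must be positive")
  if (K2 <= 0) stop("K2 must be positive")
  nrm <- sqrt(sum(fiber_direction^2))
  if (abs(nrm - 1) > 1e-8) stop("fiber_direction must have unit norm")
  p <- structure(
    list(c1 = c1, c2 = c2, D1 = D1, D2 = D2, K1 = K1, K2 = K2,
         fiber_direction = fiber_direction / nrm),
    class = "material_params"
  )
  if (check_stability && !is_uniaxially_stable(p)) {
    warning("material parameters give non-positive incremental uniaxial ",
            "stiffness somewhere on stretch [1, 1.3]; response may be unstable")
  }
  p
}

#' @export
print.material_params <- function(x, ...) {
  cat("Anisotropic modified Mooney-Rivlin parameters (kPa):\n")
  cat(sprintf("  c1 = %.4g  c2 = %.4g  D1 = %.4g  D2 = %.4g  K1 = %.4g  K2 = %.4g\n",
              x$c1, x$c2, x$D1, x$D2, x$K1, x$K2))
  cat("  fiber direction:", paste(signif(x$fiber_direction, 4), collapse = " "), "\n")
  invisible(x)
}

#' Strain invariants of the right Cauchy-Green tensor
#'
#' Computes \eqn{I_1 = \mathrm{tr}(C)},
#' \eqn{I_2 = \frac{1}{2}[(\mathrm{tr}\,C)^2 - C_{ij}C_{ij}]} and the fiber
#' invariant \eqn{I_4 = C_{ij} (n_f)_i (n_f)_j} (squared fiber stretch).
#'
#' @param C symmetric positive definite 3x3 right Cauchy-Green tensor.
#' @param fiber_direction unit 3-vector.
#' @return named numeric vector `c(I1, I2, I4)`.
#' @examples
#' strain_invariants(diag(3), c(0, 1, 0))
#' @export
strain_invariants <- function(C, fiber_direction) {
  .check_cauchy_green(C)
  n <- fiber_direction / sqrt(sum(fiber_direction^2))
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  I4 <- drop(t(n) %*% C %*% n)
  out <- c(I1 = I1, I2 = I2, I4 = I4)
  if (!all(is.finite(out))) stop("non-finite strain invariants")
  out
}

.check_cauchy_green <- function(C) {
  if (!is.matrix(C) || !all(dim(C) == c(3, 3)))
    stop("invalid kinematics: C must be a 3x3 matrix")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("invalid kinematics: C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("invalid kinematics: C must be positive definite")
  invisible(TRUE)
}

#' Strain energy density
#'
#' Evaluates the anisotropic modified Mooney-Rivlin strain energy at a
#' deformation state given by the right Cauchy-Green tensor. Returns kPa
#' (energy per unit reference volume). The exponential terms are guarded:
#' arguments beyond 500 raise an out-of-range-deformation error naming the
#' offending invariant.
#'
#' @param params a [material_params()] object.
#' @param C symmetric positive definite 3x3 tensor.
#' @return scalar energy density, kPa.
#' @examples
#' strain_energy(material_params(), diag(3)) # 0 at the reference state
#' @export
strain_energy <- function(params, C) {
  iv <- strain_invariants(C, params$fiber_direction)
  .energy_from_invariants(params, iv[["I1"]], iv[["I2"]], iv[["I4"]])
}

.energy_from_invariants <- function(p, I1, I2, I4) {
  e1 <- p$D2 * (I1 - 3)
  e4 <- p$K2 * (I4 - 1)^2
  if (e1 > 500) stop("out-of-range deformation: exp overflow, I1 = ", I1)
  if (e4 > 500) stop("out-of-range deformation: exp overflow, I4 = ", I4)
  p$c1 * (I1 - 3) + p$c2 * (I2 - 3) +
    p$D1 * (expm1(e1)) + p$K1 / p$K2 * expm1(e4)
}

# Energy restricted to incompressible principal stretches with the fiber
# circumferential: lambda_r = 1/(lambda_t * lambda_z), I4 = lambda_t^2.
.energy_incompressible <- function(p, lt, lz) {
  lr2 <- 1 / (lt^2 * lz^2)
  I1 <- lt^2 + lz^2 + lr2
  I2 <- lt^2 * lz^2 + 1 / lz^2 + 1 / lt^2
  I4 <- lt^2
  .energy_from_invariants(p, I1, I2, I4)
}

#' Pressure-eliminated stress differences
#'
#' For an incompressible axisymmetric state with principal stretches
#' \eqn{(\lambda_r, \lambda_\theta, \lambda_z)},
#' \eqn{\lambda_r = 1/(\lambda_\theta \lambda_z)}, and circumferential fiber,
#' the Cauchy stress is determined only up to a hydrostatic pressure; the
#' differences
#' \eqn{\sigma_{\theta\theta} - \sigma_{rr} = \lambda_\theta\,
#'   \partial \hat W / \partial \lambda_\theta} and
#' \eqn{\sigma_{zz} - \sigma_{rr} = \lambda_z\,
#'   \partial \hat W / \partial \lambda_z}
#' are pressure-free and are the quantities the inflation solver integrates.
#' Derivatives are analytic; both arguments are vectorised over
#' `lambda_theta`.
#'
#' @param params a [material_params()] object.
#' @param lambda_theta circumferential stretch(es), > 0.
#' @param lambda_z axial stretch, > 0 (scalar).
#' @return a list with vectors `dtheta` (\eqn{\sigma_{\theta\theta} -
#'   \sigma_{rr}}) and `dz` (\eqn{\sigma_{zz} - \sigma_{rr}}), kPa.
#' @examples
#' stress_difference(material_params(), 1.1, 1.0)
#' @export
stress_difference <- function(params, lambda_theta, lambda_z) {
  if (any(lambda_theta <= 0) || any(lambda_z <= 0))
    stop("invalid kinematics: stretches must be positive")
  if (length(lambda_z) != 1) stop("lambda_z must be scalar")
  lt <- lambda_theta
  lz <- lambda_z
  I1 <- lt^2 + lz^2 + 1 / (lt^2 * lz^2)
  I4 <- lt^2
  e1 <- params$D2 * (I1 - 3)
  e4 <- params$K2 * (I4 - 1)^2
  if (any(e1 > 500) || any(e4 > 500))
    stop("out-of-range deformation: exp overflow in stress_difference")
  W1 <- params$c1 + params$D1 * params$D2 * exp(e1)
  W2 <- params$c2
  W4 <- 2 * params$K1 * (I4 - 1) * exp(e4)
  dI1_dlt <- 2 * lt - 2 / (lt^3 * lz^2)
  dI1_dlz <- 2 * lz - 2 / (lt^2 * lz^3)
  dI2_dlt <- 2 * lt * lz^2 - 2 / lt^3
  dI2_dlz <- 2 * lt^2 * lz - 2 / lz^3
  dI4_dlt <- 2 * lt
  list(
    dtheta = lt * (W1 * dI1_dlt + W2 * dI2_dlt + W4 * dI4_dlt),
    dz     = lz * (W1 * dI1_dlz + W2 * dI2_dlz)
  )
}

#' Scale the stress-dimensioned material constants by one ratio
#'
#' Multiplies `c1`, `c2`, `D1` and `K1` by `ratio`, leaving the
#' dimensionless exponents `D2`, `K2` and the fiber direction untouched.
#' This is the single-ratio stiffness adjustment used for patient-specific
#' calibration: it rescales the stress magnitude of the response without
#' changing its shape, so energy and all stress differences scale exactly
#' linearly with `ratio`.
#'
#' @param params a [material_params()] object.
#' @param ratio positive scalar.
#' @return a new `material_params` object.
#' @export
scale_params <- function(params, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0)
    stop("ratio must be a positive scalar")
  material_params(c1 = params$c1 * ratio, c2 = params$c2 * ratio,
                  D1 = params$D1 * ratio, D2 = params$D2,
                  K1 = params$K1 * ratio, K2 = params$K2,
                  fiber_direction = params$fiber_direction,
                  check_stability = FALSE)
}

# Uniaxial incompressible extension along the fiber, lateral stresses zero:
# axial stretch l, lateral 1/sqrt(l). Returns Cauchy stress (kPa), vectorised.
.uniaxial_stress <- function(p, l) {
  I1 <- l^2 + 2 / l
  I4 <- l^2
  e1 <- pmin(p$D2 * (I1 - 3), 500)
  e4 <- pmin(p$K2 * (I4 - 1)^2, 500)
  W1 <- p$c1 + p$D1 * p$D2 * exp(e1)
  W2 <- p$c2
  W4 <- 2 * p$K1 * (I4 - 1) * exp(e4)
  dI1 <- 2 * l - 2 / l^2
  dI2 <- 2 - 2 / l^3
  dI4 <- 2 * l
  l * (W1 * dI1 + W2 * dI2 + W4 * dI4)
}

#' Uniaxial stability of a parameter set
#'
#' Checks that the incremental stiffness d(stress)/d(stretch) of the
#' incompressible uniaxial response along the fiber is positive over
#' stretches in `[1, 1.3]`. Parameter sets with a strongly negative `c1`
#' can fail this; the check is advisory (the constructor warns).
#'
#' @param params a [material_params()] object.
#' @param lambda_range stretch interval to scan.
#' @param n number of scan points.
#' @return logical.
#' @export
is_uniaxially_stable <- function(params, lambda_range = c(1, 1.3), n = 61) {
  l <- seq(lambda_range[1], lambda_range[2], length.out = n)
  s <- .uniaxial_stress(params, l)
  all(diff(s) > 0)
}

# regression basis of the uniaxial response: sigma is linear in
# (c1, c2, D1, K1) once the exponents (D2, K2) are fixed
.uniaxial_basis <- function(l, D2, K2) {
  I1 <- l^2 + 2 / l
  I4 <- l^2
  dI1 <- 2 * l - 2 / l^2
  dI2 <- 2 - 2 / l^3
  dI4 <- 2 * l
  e1 <- pmin(D2 * (I1 - 3), 500)
  e4 <- pmin(K2 * (I4 - 1)^2, 500)
  cbind(c1 = l * dI1,
        c2 = l * dI2,
        D1 = l * D2 * exp(e1) * dI1,
        K1 = l * 2 * (I4 - 1) * exp(e4) * dI4)
}

#' Fit baseline material parameters to uniaxial stress-stretch data
#'
#' Least-squares fit of the incompressible uniaxial (circumferential-strip,
#' lateral stresses zero) stress response to experimental
#' `(stretch, stress)` pairs. The response is linear in the four
#' stress-dimensioned constants once the exponents are fixed, so the fit is
#' separable: an inner linear least-squares solve for
#' `(c1, c2, D1, K1)` profiled over a Nelder-Mead search on
#' `(log D2, log K2)` started from `init`. Returns the fitted parameters
#' and the coefficient of determination.
#'
#' @param data a data.frame or matrix with columns `stretch`
#'   (dimensionless) and `stress` (kPa); at least 6 points with some
#'   stretch > 1.
#' @param init a [material_params()] object supplying the starting
#'   exponents and the fiber direction.
#' @return list with `params` (fitted [material_params()]), `r_squared`,
#'   and `rss` (residual sum of squares).
#' @export
fit_baseline_params <- function(data, init = material_params()) {
  data <- as.data.frame(data)
  if (!all(c("stretch", "stress") %in% names(data)))
    stop("data must have columns 'stretch' and 'stress'")
  if (nrow(data) < 6) stop("need at least 6 data points")
  if (!any(data$stretch > 1)) stop("data must span stretches > 1")
  tss <- sum((data$stress - mean(data$stress))^2)
  if (tss == 0)
    stop("degenerate data: stress has zero variance, R^2 undefined")
  inner <- function(logexp) {
    B <- .uniaxial_basis(data$stretch, exp(logexp[1]), exp(logexp[2]))
    ls <- stats::lm.fit(B, data$stress)
    list(rss = sum(ls$residuals^2), coef = ls$coefficients)
  }
  obj <- function(logexp) inner(logexp)$rss
  opt <- stats::optim(log(c(init$D2, init$K2)), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  best <- inner(opt$par)
  if (!all(is.finite(best$coef)))
    stop("fit failure: singular design; residual sum of squares ",
         signif(best$rss, 4))
  cf <- best$coef
  list(
    params = material_params(cf[["c1"]], cf[["c2"]],
                             cf[["D1"]], exp(opt$par[1]),
                             cf[["K1"]], exp(opt$par[2]),
                             fiber_direction = init$fiber_direction,
                             check_stability = FALSE),
    r_squared = 1 - best$rss / tss,
    rss = best$rss
  )
}
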