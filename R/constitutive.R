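#' Ogden hyperelastic material
#'
#' Constructs an incompressible N-term Ogden material for intestinal wall
#' tissue. The strain-energy convention is
#' \deqn{W = \sum_p \frac{\mu_p}{\alpha_p}\,(\lambda_1^{\alpha_p} +
#'   \lambda_2^{\alpha_p} + \lambda_3^{\alpha_p} - 3),}
#' the convention used by the major commercial FE solvers. The alternative
#' \eqn{2\mu/\alpha^2} convention is deliberately not supported: with the
#' default porcine-colon constants it would contradict the observed safe
#' compression band (see the methods vignette).
#'
#' All stresses are in MPa (1 MPa = 1 N/mm^2) and lengths in mm. The default
#' constants are the porcine colonic wall fit
#' \eqn{\mu = (8300, 200, 6200)} Pa, \eqn{\alpha = (7.625, 13.875, 7.625)};
#' pass `mu_pa` in Pa, conversion to MPa is internal.
#'
#' The near-incompressibility penalty bulk modulus is used only by the FE
#' engine; the closed-form responses treat the material as exactly
#' incompressible. Default `penalty_bulk = 1000 * mu0` keeps the volumetric
#' strain below about 1e-3 at the stress levels of interest without
#' ill-conditioning the tangent.
#'
#' @param mu_pa numeric vector of shear-like moduli, Pa.
#' @param alpha numeric vector of dimensionless exponents, same length.
#' @param penalty_bulk penalty bulk modulus in MPa, or `NULL` for
#'   `1000 * initial_shear_modulus()`.
#' @return An object of class `ogden_material` with fields `mu` (MPa),
#'   `alpha`, `penalty_bulk` (MPa).
#' @examples
#' mat <- ogden_material()
#' initial_shear_modulus(mat)  # 0.05666875 MPa
#' uniaxial_cauchy_stress(mat, 0.4)
#' @export
ogden_material <- function(mu_pa = c(8300, 200, 6200),
                           alpha = c(7.625, 13.875, 7.625),
                           penalty_bulk = NULL) {
  if (length(mu_pa) < 1L)
    stop("an Ogden material needs at least one (mu, alpha) term")
  if (length(mu_pa) != length(alpha))
    stop("mu_pa and alpha must have the same length")
  if (!all(is.finite(mu_pa)) || !all(is.finite(alpha)))
    stop("non-finite Ogden constants")
  mu <- mu_pa / 1e6  # Pa -> MPa
  mu0 <- 0.5 * sum(mu * alpha)
  if (!(mu0 > 0))
    stop("initial shear modulus (1/2) * sum(mu * alpha) must be positive")
  if (is.null(penalty_bulk)) penalty_bulk <- 1000 * mu0
  if (penalty_bulk < 100 * mu0)
    stop("penalty_bulk must be at least 100 x the initial shear modulus")
  structure(list(mu = mu, alpha = alpha, penalty_bulk = penalty_bulk),
            class = "ogden_material")
}

#' @export
print.ogden_material <- function(x, ...) {
  cat("Ogden material,", length(x$mu), "term(s)\n")
  cat("  mu    [MPa]:", paste(signif(x$mu, 6), collapse = ", "), "\n")
  cat("  alpha      :", paste(x$alpha, collapse = ", "), "\n")
  cat(sprintf("  mu0 = %.6g MPa, penalty bulk = %.6g MPa\n",
              initial_shear_modulus(x), x$penalty_bulk))
  invisible(x)
}

#' Initial (small-strain) shear modulus
#'
#' Consistency statistic \eqn{\mu_0 = \frac{1}{2}\sum_p \mu_p \alpha_p}.
#'
#' @param mat an [ogden_material()].
#' @return shear modulus in MPa.
#' @export
initial_shear_modulus <- function(mat) {
  stopifnot(inherits(mat, "ogden_material"))
  0.5 * sum(mat$mu * mat$alpha)
}

#' Ogden strain-energy density
#'
#' Energy per unit reference volume (MPa = N mm / mm^3) at the given
#' principal stretches, incompressible convention (no volumetric term).
#'
#' @param mat an [ogden_material()].
#' @param stretches numeric length-3 vector of principal stretches
#'   (lam1, lam2, lam3), all positive.
#' @return energy density, MPa.
#' @export
strain_energy <- function(mat, stretches) {
  stopifnot(inherits(mat, "ogden_material"))
  if (length(stretches) != 3L || !all(is.finite(stretches)) ||
      any(stretches <= 0))
    stop("stretches must be three finite positive numbers")
  sum(mat$mu / mat$alpha *
        (stretches[1]^mat$alpha + stretches[2]^mat$alpha +
           stretches[3]^mat$alpha - 3))
}

#' Uniaxial Cauchy stress of the incompressible Ogden model
#'
#' Closed form for incompressible uniaxial loading with free lateral faces:
#' lateral stretches are \eqn{\lambda^{-1/2}} and
#' \deqn{\sigma(\lambda) = \sum_p \mu_p (\lambda^{\alpha_p} -
#'   \lambda^{-\alpha_p/2}).}
#' Negative for compression (`lam < 1`).
#'
#' @param mat an [ogden_material()].
#' @param lam axial stretch(es), > 0; vectorised.
#' @return axial Cauchy stress, MPa.
#' @export
uniaxial_cauchy_stress <- function(mat, lam) {
  stopifnot(inherits(mat, "ogden_material"))
  if (!all(is.finite(lam)) || any(lam <= 0))
    stop("stretch must be finite and positive")
  vapply(lam, function(l) sum(mat$mu * (l^mat$alpha - l^(-mat$alpha / 2))),
         numeric(1))
}

#' Axisymmetric Cauchy stress carrier
#'
#' @param s_rr,s_zz,s_tt,s_rz stress components, MPa (vectorised).
#' @return a data.frame with columns `s_rr`, `s_zz`, `s_tt`, `s_rz` and
#'   class `cauchy_axisym`.
#' @export
cauchy_axisym <- function(s_rr = 0, s_zz = 0, s_tt = 0, s_rz = 0) {
  d <- data.frame(s_rr = s_rr, s_zz = s_zz, s_tt = s_tt, s_rz = s_rz)
  if (!all(vapply(d, function(x) all(is.finite(x)), logical(1))))
    stop("stress components must be finite")
  class(d) <- c("cauchy_axisym", class(d))
  d
}

#' von Mises equivalent stress
#'
#' \deqn{\sigma_{vM} = \sqrt{\tfrac12[(s_{rr}-s_{zz})^2 + (s_{zz}-s_{tt})^2 +
#'   (s_{tt}-s_{rr})^2] + 3 s_{rz}^2}}
#' Invariant under addition of a hydrostatic component; this is the
#' "equivalent stress" used for the fixation/damage band classification.
#'
#' @param stress a [cauchy_axisym()] (or any data.frame with the four
#'   component columns).
#' @return nonnegative equivalent stress, MPa (vectorised).
#' @export
von_mises <- function(stress) {
  sqrt(0.5 * ((stress$s_rr - stress$s_zz)^2 +
                (stress$s_zz - stress$s_tt)^2 +
                (stress$s_tt - stress$s_rr)^2) + 3 * stress$s_rz^2)
}
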