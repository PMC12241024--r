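# Seeded generators standing in for unpublished inputs: a reference
# force-compression curve (the ex vivo validation data is not deposited)
# and toy stress fields for exercising the band classifier without a solve.

# Run fn with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Synthetic reference force-compression curve
#'
#' Generates a noisy stand-in for an ex vivo compression experiment: the
#' closed-form uniform-engine force curve of the given material and stack,
#' perturbed by seeded multiplicative log-normal noise (so forces stay
#' positive). With `sigma_log = 0` it is exactly the closed-form curve; the
#' same seed always regenerates the same curve bit for bit.
#'
#' @param mat an [ogden_material()].
#' @param stack a [tissue_stack()].
#' @param seed integer RNG seed (recorded in the output).
#' @param sigma_log standard deviation of the log-noise, in `[0, 0.5]`.
#' @param ratios compression-ratio grid; default 0.05 to 0.75 (the gap-1 mm
#'   endpoint of a 2+2 mm stack) in steps of 0.05.
#' @return object of class `synthetic_reference`: data.frame columns
#'   `ratio`, `force_n`, plus attributes `seed`, `sigma_log` and the
#'   noise-free `force_true`.
#' @export
make_reference_curve <- function(mat, stack, seed, sigma_log = 0.2,
                                 ratios = seq(0.05, 0.75, by = 0.05)) {
  stopifnot(inherits(mat, "ogden_material"), inherits(stack, "tissue_stack"))
  if (!(sigma_log >= 0 && sigma_log <= 0.5))
    stop("sigma_log must lie in [0, 0.5]")
  if (any(ratios <= 0 | ratios > 0.95)) stop("ratios must lie in (0, 0.95]")
  a <- effective_area(default_footprints(stack)$anvil)
  f_true <- abs(uniaxial_cauchy_stress(mat, 1 - ratios)) * a
  noise <- with_seed(seed, function()
    exp(stats::rnorm(length(ratios), 0, sigma_log)))
  out <- data.frame(ratio = ratios, force_n = f_true * noise)
  attr(out, "seed") <- seed
  attr(out, "sigma_log") <- sigma_log
  attr(out, "force_true") <- f_true
  class(out) <- c("synthetic_reference", class(out))
  out
}

#' Toy stress field fixture
#'
#' Builds a `step_result`-shaped object from explicit (volume, von Mises)
#' pairs so the band statistic and classifier can be tested without running
#' a solver. The von Mises value is placed in the axial stress component
#' (a uniaxial state with exactly that equivalent stress).
#'
#' @param elements data.frame with columns `volume` (mm^3, positive), `vm`
#'   (MPa, nonnegative) and optionally `layer` (`"upper"`/`"lower"`,
#'   default all `"upper"`).
#' @param d,total nominal displacement and thickness for the carrier fields.
#' @return a `step_result` consumable by [band_fractions()].
#' @export
make_toy_stress_field <- function(elements, d = 0, total = 4) {
  elements <- as.data.frame(elements)
  if (!nrow(elements)) {
    elements <- data.frame(volume = numeric(0), vm = numeric(0),
                           layer = character(0))
  }
  stopifnot(all(c("volume", "vm") %in% names(elements)))
  if (any(elements$volume <= 0)) stop("volumes must be positive")
  if (is.null(elements$layer)) elements$layer <- rep("upper", nrow(elements))
  stack <- tissue_stack(total / 2, total / 2)
  stress <- cauchy_axisym(s_rr = rep(0, nrow(elements)), s_zz = -elements$vm,
                          s_tt = rep(0, nrow(elements)),
                          s_rz = rep(0, nrow(elements)))
  new_step_result(step = 1L, d = d, stack = stack, stress = stress,
                  vol_cur = elements$volume, vol_ref = elements$volume,
                  layer = elements$layer, force = 0)
}
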