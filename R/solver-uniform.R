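#' Quasi-static compression load program
#'
#' Displacement-controlled stepping of the anvil toward the fixed cartridge:
#' 0.1 mm per step (pseudo-time 1 per step), default total travel
#' 0.8 x (t_upper + t_lower), i.e. an 80% compression ratio.
#'
#' @param stack a [tissue_stack()].
#' @param step_size step increment, mm.
#' @param total_travel total anvil travel, mm; default `0.8 * total`.
#' @return object of class `load_program` with the step count and the
#'   displacement of every step. If `total_travel` is not an integer
#'   multiple of `step_size` the count is rounded down with a warning.
#' @export
load_program <- function(stack, step_size = 0.1, total_travel = NULL) {
  stopifnot(inherits(stack, "tissue_stack"))
  if (!(step_size > 0)) stop("step_size must be positive")
  if (is.null(total_travel)) total_travel <- 0.8 * stack$total
  if (!(total_travel > 0)) stop("total_travel must be positive")
  n <- total_travel / step_size
  n_int <- floor(n + 1e-9)
  if (abs(n - n_int) > 1e-9)
    warning(sprintf(
      "total_travel %.4g is not a multiple of step_size %.4g; using %d steps",
      total_travel, step_size, n_int))
  structure(list(step_size = step_size, n_steps = as.integer(n_int),
                 d = step_size * seq_len(n_int), total = stack$total),
            class = "load_program")
}

# Internal constructor for one converged load step.
new_step_result <- function(step, d, stack, stress, vol_cur, vol_ref,
                            layer, force, n_iter = NA_integer_) {
  vm <- von_mises(stress)
  # layer mean = arithmetic mean over element values, matching how the
  # commercial postprocessors' stress probes average (band fractions, in
  # contrast, are volume-weighted by construction)
  stats <- do.call(rbind, lapply(c("upper", "lower"), function(ly) {
    i <- layer == ly
    data.frame(layer = ly,
               max_vm = if (any(i)) max(vm[i]) else NA_real_,
               mean_vm = if (any(i)) mean(vm[i]) else NA_real_)
  }))
  structure(list(step = step, d = d, ratio = d / stack$total,
                 stress = stress, vm = vm,
                 vol_cur = vol_cur, vol_ref = vol_ref, layer = layer,
                 layer_stats = stats, force = force, n_iter = n_iter),
            class = "step_result")
}

#' @export
print.step_result <- function(x, ...) {
  cat(sprintf("Load step %d: d = %.2f mm (ratio %.2f), force %.3g N\n",
              x$step, x$d, x$ratio, x$force))
  print(x$layer_stats, row.names = FALSE)
  invisible(x)
}

#' Uniform (semi-analytic) compression engine
#'
#' Idealises the clamped stack as a laterally free, full-contact column in
#' homogeneous incompressible uniaxial compression: at anvil travel `d` the
#' axial stretch is \eqn{\lambda_z = 1 - d/(t_u + t_l)}, identical in both
#' layers by series equilibrium, and the stress state is the closed-form
#' [uniaxial_cauchy_stress()]. The reaction force is `|sigma| x` the anvil's
#' [effective_area()]. This engine is the analytic oracle for the FE engine
#' and is exact in its own idealisation (no volume change, no layer
#' asymmetry).
#'
#' @param mat an [ogden_material()].
#' @param stack a [tissue_stack()].
#' @param program a [load_program()]; default 0.1 mm steps to 80% ratio.
#' @param footprints platen footprints (for the anvil area); default
#'   [default_footprints()].
#' @return list of [step_result][run_fem()] objects, one per step. Each has
#'   two "elements": the upper and lower layer volumes. Aborts if
#'   \eqn{\lambda_z \le 0.05} (unphysical crush).
#' @export
run_uniform <- function(mat, stack, program = load_program(stack),
                        footprints = default_footprints(stack)) {
  stopifnot(inherits(mat, "ogden_material"), inherits(stack, "tissue_stack"),
            inherits(program, "load_program"))
  a_anvil <- effective_area(footprints$anvil)
  ring <- pi * (stack$r_outer^2 - stack$r_inner^2)
  vol <- c(upper = ring * stack$t_upper, lower = ring * stack$t_lower)
  layer <- c("upper", "lower")
  lapply(seq_len(program$n_steps), function(k) {
    d <- program$d[k]
    lam <- 1 - d / stack$total
    if (lam <= 0.05)
      stop(sprintf("step %d: axial stretch %.3g <= 0.05, unphysical crush",
                   k, lam))
    sig <- uniaxial_cauchy_stress(mat, lam)
    stress <- cauchy_axisym(s_rr = c(0, 0), s_zz = rep(sig, 2),
                            s_tt = c(0, 0), s_rz = c(0, 0))
    new_step_result(step = k, d = d, stack = stack, stress = stress,
                    vol_cur = unname(vol), vol_ref = unname(vol),
                    layer = layer, force = abs(sig) * a_anvil)
  })
}

#' Platen reaction force of a solved step
#'
#' Magnitude of the axial force on the anvil, N. Nondecreasing in the
#' applied displacement for both engines.
#'
#' @param step a `step_result`.
#' @return force, N.
#' @export
reaction_force <- function(step) {
  stopifnot(inherits(step, "step_result"))
  abs(step$force)
}
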