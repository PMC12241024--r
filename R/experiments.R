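#' Thickness sweep configuration
#'
#' @param pairs list of `c(t_upper, t_lower)` in mm; default the five study
#'   pairs: 2.5-2.5, 2.0-2.0, 1.5-1.5, 2.5-1.5, 1.5-2.5.
#' @param engine `"uniform"` or `"fem"`.
#' @param thr a [thresholds()].
#' @param element_size FE mesh size, mm (ignored by the uniform engine).
#' @param max_ratio final compression ratio, in (0, 0.95].
#' @param step_size load step, mm.
#' @param r_inner,r_outer annulus radii, mm.
#' @param fem_options options list passed to [run_fem()].
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(pairs = list(c(2.5, 2.5), c(2.0, 2.0), c(1.5, 1.5),
                                      c(2.5, 1.5), c(1.5, 2.5)),
                         engine = c("uniform", "fem"), thr = thresholds(),
                         element_size = 0.5, max_ratio = 0.8,
                         step_size = 0.1, r_inner = 10, r_outer = 16,
                         fem_options = list()) {
  engine <- match.arg(engine)
  if (!(max_ratio > 0 && max_ratio <= 0.95))
    stop("max_ratio must lie in (0, 0.95]")
  structure(list(pairs = pairs, engine = engine, thr = thr,
                 element_size = element_size, max_ratio = max_ratio,
                 step_size = step_size, r_inner = r_inner,
                 r_outer = r_outer, fem_options = fem_options),
            class = "sweep_config")
}

#' Thickness sweep over wall-thickness pairs
#'
#' Runs the full compression program for every thickness pair and derives,
#' per pair: per-step layer statistics (max/mean von Mises, reaction force),
#' the per-step band-fraction series (the volumetric fixation/damage
#' statistic), and the safe distance/ratio/gap table. Solver failures are
#' captured per pair without aborting the sweep.
#'
#' @param mat an [ogden_material()].
#' @param cfg a [sweep_config()].
#' @return object of class `thickness_sweep`: per pair a list with
#'   `stack`, `layer_stats` (data.frame), `bands` (data.frame),
#'   `safety` ([safety_table()]) or an `error` string.
#' @export
thickness_sweep <- function(mat = ogden_material(), cfg = sweep_config()) {
  stopifnot(inherits(cfg, "sweep_config"))
  out <- lapply(cfg$pairs, function(p) {
    stack <- tissue_stack(p[1], p[2], cfg$r_inner, cfg$r_outer)
    prog <- load_program(stack, cfg$step_size,
                         total_travel = cfg$max_ratio * stack$total)
    res <- tryCatch({
      if (cfg$engine == "uniform") run_uniform(mat, stack, prog)
      else run_fem(mat, stack, program = prog,
                   mesh = build_mesh(stack, cfg$element_size),
                   options = cfg$fem_options)
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(list(stack = stack, error = conditionMessage(res)))
    list(stack = stack,
         layer_stats = sweep_layer_stats(res, stack),
         bands = sweep_band_series(res, cfg$thr, stack),
         safety = safety_table(res, cfg$thr, stack))
  })
  names(out) <- vapply(cfg$pairs, function(p)
    sprintf("%.1f-%.1f", p[1], p[2]), character(1))
  structure(list(pairs = out, engine = cfg$engine), class = "thickness_sweep")
}

sweep_layer_stats <- function(results, stack) {
  do.call(rbind, lapply(results, function(st) {
    data.frame(step = st$step, d = st$d,
               ratio = compression_ratio(st$d, stack$total),
               layer = st$layer_stats$layer,
               max_vm = st$layer_stats$max_vm,
               mean_vm = st$layer_stats$mean_vm,
               force_n = st$force)
  }))
}

sweep_band_series <- function(results, thr, stack) {
  do.call(rbind, lapply(results, function(st) {
    bf <- band_fractions(st, thr)
    cl <- classify(bf, thr)
    cbind(data.frame(step = st$step, d = st$d,
                     ratio = compression_ratio(st$d, stack$total)),
          as.data.frame(bf), state = unname(cl))
  }))
}

#' Pure convergence bookkeeping
#'
#' Given monitored means at strictly decreasing mesh sizes, computes the
#' percent change of each refinement from the preceding value and selects
#' the first size whose change is below the criterion. If none qualifies
#' the smallest size is selected and the report is flagged unconverged.
#'
#' @param sizes strictly decreasing element sizes, mm (at least 2).
#' @param means monitored quantity per size (here: mean von Mises, MPa).
#' @param criterion percent threshold (default 3).
#' @return object of class `convergence_report`: `sizes`, `means`,
#'   `pct_change` (length `length(sizes) - 1`), `selected`, `converged`.
#' @export
convergence_report <- function(sizes, means, criterion = 3) {
  if (length(sizes) < 2L) stop("need at least two mesh sizes")
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  if (length(means) != length(sizes)) stop("one mean per size required")
  pct <- abs(diff(means)) / abs(means[-length(means)]) * 100
  ok <- which(pct < criterion)
  converged <- length(ok) > 0
  selected <- if (converged) sizes[ok[1] + 1L] else sizes[length(sizes)]
  structure(list(sizes = sizes, means = means, pct_change = pct,
                 selected = selected, converged = converged,
                 criterion = criterion),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Mesh convergence report (criterion", x$criterion, "%)\n")
  print(data.frame(size_mm = x$sizes, mean_vm = x$means,
                   pct_change = c(NA, x$pct_change)), row.names = FALSE)
  cat(if (x$converged) sprintf("selected size: %.2g mm\n", x$selected)
      else sprintf("NOT converged; falling back to smallest size %.2g mm\n",
                   x$selected))
  invisible(x)
}

#' Mesh convergence study
#'
#' Compresses the stack with the FE engine on successively finer meshes to
#' the reference state (anvil advanced until the platen gap reaches
#' `gap_target`, default 1 mm, on the 2.5 + 2.5 mm stack) and monitors the
#' volume-weighted mean von Mises stress of the whole tissue. Convergence is
#' declared at the first size whose change from the preceding size is below
#' `criterion` percent.
#'
#' @param stack a [tissue_stack()]; default 2.5 + 2.5 mm.
#' @param mat an [ogden_material()].
#' @param sizes strictly decreasing element sizes, mm.
#' @param criterion percent change threshold (default 3).
#' @param gap_target remaining platen gap defining the reference state, mm.
#' @param step_size load step, mm.
#' @param options FE options (see [run_fem()]).
#' @return a [convergence_report()].
#' @export
mesh_convergence <- function(stack = tissue_stack(2.5, 2.5),
                             mat = ogden_material(),
                             sizes = c(2, 1.6, 1.2, 0.8, 0.4),
                             criterion = 3, gap_target = 1,
                             step_size = 0.1, options = list()) {
  if (gap_target < 0) stop("gap_target must be nonnegative")
  d_total <- stack$total - gap_target
  if (d_total <= 0) stop("gap_target leaves no compression travel")
  prog <- load_program(stack, step_size, total_travel = d_total)
  means <- vapply(sizes, function(sz) {
    mesh <- build_mesh(stack, min(sz, min(stack$t_upper, stack$t_lower)))
    res <- run_fem(mat, stack, program = prog, mesh = mesh,
                   options = options)
    fin <- res[[length(res)]]
    sum(fin$vm * fin$vol_cur) / sum(fin$vol_cur)
  }, numeric(1))
  convergence_report(sizes, means, criterion)
}

#' Force-compression validation against a reference curve
#'
#' Compares the model's force-compression curve for the 2 + 2 mm stack
#' (compressed until the platen gap reaches 1 mm, i.e. ratios up to 0.75)
#' with a reference curve. The contract is two-regime: every ratio-wise
#' quotient model/reference must stay within one order of magnitude
#' (`[0.1, 10]`), and below a 60% compression ratio the agreement should be
#' close (quotient in `[0.5, 2]`).
#'
#' @param reference data.frame with columns `ratio` (in (0, 0.75]) and
#'   `force_n`, e.g. a [make_reference_curve()].
#' @param mat an [ogden_material()].
#' @param stack a [tissue_stack()]; default 2 + 2 mm.
#' @param engine `"uniform"` or `"fem"`.
#' @param gap_target platen gap ending the model curve, mm; must be >= 0.
#' @param ... passed to [run_fem()] (`mesh`, `options`) for the FE engine.
#' @return object of class `validation_report`: data.frame with `ratio`,
#'   `force_ref`, `force_model`, `quotient`, `within_magnitude`,
#'   `close_regime`; attribute `pass` (all quotients in `[0.1, 10]`).
#' @export
validation_curve <- function(reference, mat = ogden_material(),
                             stack = tissue_stack(2, 2),
                             engine = c("uniform", "fem"), gap_target = 1,
                             ...) {
  engine <- match.arg(engine)
  if (gap_target < 0) stop("gap_target must be nonnegative")
  stopifnot(all(c("ratio", "force_n") %in% names(reference)))
  if (any(reference$ratio <= 0 | reference$ratio > 0.75))
    stop("reference ratios must lie in (0, 0.75]")
  d_total <- stack$total - gap_target
  max_ratio <- d_total / stack$total
  if (engine == "uniform") {
    a <- effective_area(default_footprints(stack)$anvil)
    model <- function(rt) abs(uniaxial_cauchy_stress(mat, 1 - rt)) * a
    f_model <- model(reference$ratio)
  } else {
    prog <- load_program(stack, total_travel = d_total)
    res <- run_fem(mat, stack, program = prog, ...)
    rts <- vapply(res, function(s) s$ratio, numeric(1))
    fs <- vapply(res, reaction_force, numeric(1))
    f_model <- stats::approx(c(0, rts), c(0, fs), xout = reference$ratio,
                             rule = 2)$y
  }
  keep <- reference$ratio <= max_ratio + 1e-9
  rep <- data.frame(ratio = reference$ratio[keep],
                    force_ref = reference$force_n[keep],
                    force_model = f_model[keep])
  rep$quotient <- rep$force_model / rep$force_ref
  rep$within_magnitude <- rep$quotient >= 0.1 & rep$quotient <= 10
  rep$close_regime <- rep$ratio >= 0.60 |
    (rep$quotient >= 0.5 & rep$quotient <= 2)
  attr(rep, "pass") <- all(rep$within_magnitude)
  class(rep) <- c("validation_report", class(rep))
  rep
}
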