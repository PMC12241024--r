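#' Stress-band safety thresholds
#'
#' Decision constants of the volumetric tissue-state statistic. Fixed-tissue
#' volume is all element volume with von Mises stress strictly above
#' `tau_low`; the effective-fixation band is `fix_band` (inclusive at both
#' ends, so 0.6 MPa counts as fixation); damage is strictly above `tau_dmg`.
#' A layer is safe when the fixation fraction strictly exceeds `f_fix_min`
#' (20%) and the damage fraction does not strictly exceed `f_dmg_max` (5%).
#'
#' @param tau_low fixed-tissue threshold, MPa.
#' @param fix_band length-2 effective-fixation band, MPa; its upper end must
#'   equal `tau_dmg`.
#' @param tau_dmg damage threshold, MPa.
#' @param f_fix_min minimum fixation volume fraction.
#' @param f_dmg_max maximum damage volume fraction.
#' @return object of class `thresholds`.
#' @export
thresholds <- function(tau_low = 0.1, fix_band = c(0.3, 0.6), tau_dmg = 0.6,
                       f_fix_min = 0.20, f_dmg_max = 0.05) {
  if (length(fix_band) != 2L) stop("fix_band must have two elements")
  if (!(0 < tau_low && tau_low < fix_band[1] && fix_band[1] < fix_band[2]))
    stop("require 0 < tau_low < fix_band[1] < fix_band[2]")
  if (abs(fix_band[2] - tau_dmg) > 1e-12)
    stop("fix_band[2] must equal tau_dmg")
  if (!(0 < f_dmg_max && f_dmg_max < f_fix_min && f_fix_min < 1))
    stop("require 0 < f_dmg_max < f_fix_min < 1")
  structure(list(tau_low = tau_low, fix_band = fix_band, tau_dmg = tau_dmg,
                 f_fix_min = f_fix_min, f_dmg_max = f_dmg_max),
            class = "thresholds")
}

#' Volumetric stress-band fractions of a load step
#'
#' Sums element volumes into stress bands by centroid von Mises value, per
#' layer and for the whole tissue: `v_total` (vM > tau_low, the fixed-tissue
#' volume), `v_fix` (vM in the fixation band, inclusive), `v_dmg`
#' (vM strictly above the damage threshold), and the fractions
#' `f_fix = v_fix / v_total`, `f_dmg = v_dmg / v_total`. When no volume is
#' above `tau_low` the fractions are undefined and the row is flagged
#' `fixed = FALSE` (an explicit "no fixation" state rather than 0/0).
#'
#' @param step a `step_result` (from [run_uniform()], [run_fem()] or
#'   [make_toy_stress_field()]).
#' @param thr a [thresholds()].
#' @param volume `"current"` (deformed, default) or `"reference"` element
#'   volumes for the sums.
#' @return object of class `band_fractions`: a data.frame with one row per
#'   layer plus a `"tissue"` row.
#' @export
band_fractions <- function(step, thr = thresholds(),
                           volume = c("current", "reference")) {
  stopifnot(inherits(step, "step_result"), inherits(thr, "thresholds"))
  volume <- match.arg(volume)
  vol <- if (volume == "current") step$vol_cur else step$vol_ref
  vm <- step$vm
  one <- function(sel, name) {
    v <- vol[sel]; s <- vm[sel]
    v_total <- sum(v[s > thr$tau_low])
    v_fix <- sum(v[s >= thr$fix_band[1] & s <= thr$fix_band[2]])
    v_dmg <- sum(v[s > thr$tau_dmg])
    fixed <- v_total > 0
    data.frame(layer = name, v_total = v_total, v_fix = v_fix,
               v_dmg = v_dmg,
               f_fix = if (fixed) v_fix / v_total else NA_real_,
               f_dmg = if (fixed) v_dmg / v_total else NA_real_,
               fixed = fixed)
  }
  out <- rbind(one(step$layer == "upper", "upper"),
               one(step$layer == "lower", "lower"),
               one(rep(TRUE, length(vm)), "tissue"))
  class(out) <- c("band_fractions", class(out))
  out
}

#' Per-layer safety classification
#'
#' Applies the volumetric decision rule to band fractions: a layer is
#' `safe` when its fixation fraction strictly exceeds `f_fix_min` and its
#' damage fraction is at most `f_dmg_max`; `not_fixed` when fixation is
#' insufficient (including the explicit no-fixation state); `damaged` when
#' the damage fraction strictly exceeds `f_dmg_max`; and
#' `damaged_and_not_fixed` when both fail.
#'
#' @param bf a [band_fractions()].
#' @param thr a [thresholds()].
#' @return named character vector (one entry per row of `bf`).
#' @export
classify <- function(bf, thr = thresholds()) {
  stopifnot(inherits(bf, "band_fractions"), inherits(thr, "thresholds"))
  out <- vapply(seq_len(nrow(bf)), function(i) {
    if (!bf$fixed[i]) return("not_fixed")
    fix_ok <- bf$f_fix[i] > thr$f_fix_min
    dmg_ok <- bf$f_dmg[i] <= thr$f_dmg_max
    if (fix_ok && dmg_ok) "safe"
    else if (fix_ok) "damaged"
    else if (dmg_ok) "not_fixed"
    else "damaged_and_not_fixed"
  }, character(1))
  names(out) <- bf$layer
  out
}

#' Compression ratio with exact decimal rounding
#'
#' `d / total` rounded half-up to two decimals, computed in integer tenths
#' of a millimetre so that e.g. `2.3 / 4.0` yields `0.58` (binary floating
#' point would give 0.5749999... and round to 0.57). Distances and totals
#' must be representable in tenths of mm, as produced by the 0.1 mm load
#' stepping.
#'
#' @param d compression distance(s), mm.
#' @param total total undeformed thickness, mm.
#' @return ratio(s) rounded to 2 decimals.
#' @export
compression_ratio <- function(d, total) {
  if (!(total > 0)) stop("total thickness must be positive")
  d10 <- round(d * 10); t10 <- round(total * 10)
  if (any(abs(d * 10 - d10) > 1e-6) || abs(total * 10 - t10) > 1e-6)
    stop("d and total must be multiples of 0.1 mm")
  if (any(d10 < 0) || any(d10 > t10)) stop("require 0 <= d <= total")
  # round-half-up(100 * d10 / t10) in integer arithmetic
  ((200 * d10 + t10) %/% (2 * t10)) / 100
}

#' Joint safe staple-gap set
#'
#' Gaps `total - d` over the intersection of the two layers' safe-distance
#' sets, in tenths-of-mm arithmetic.
#'
#' @param upper_safe,lower_safe safe compression distances per layer, mm.
#' @param total total undeformed thickness, mm.
#' @return gap values in mm (decreasing in d; empty if the sets are
#'   disjoint).
#' @export
gap_set <- function(upper_safe, lower_safe, total) {
  u10 <- round(upper_safe * 10); l10 <- round(lower_safe * 10)
  t10 <- round(total * 10)
  joint <- sort(intersect(u10, l10))
  (t10 - joint) / 10
}

#' Safe compression distance / ratio / gap table
#'
#' Scans a solved load program: a step is safe for a layer when that layer's
#' [classify()] result is `"safe"`. Reports, per layer, the safe distance
#' set (multiples of the step size), the matching [compression_ratio()]s,
#' and the joint safe gap set derived from the intersection of the two
#' layers' safe distances.
#'
#' @param results list of `step_result`s covering the load program.
#' @param thr a [thresholds()].
#' @param stack the [tissue_stack()] that was compressed.
#' @param volume volume convention passed to [band_fractions()].
#' @return object of class `safety_table`: list with `upper`, `lower`
#'   (each: `distances`, `ratios`), `gaps`, `total`, and a tidy `table`
#'   data.frame. Empty sets are a valid outcome.
#' @export
safety_table <- function(results, thr = thresholds(), stack,
                         volume = c("current", "reference")) {
  stopifnot(inherits(stack, "tissue_stack"))
  volume <- match.arg(volume)
  safe <- list(upper = numeric(0), lower = numeric(0))
  for (st in results) {
    cl <- classify(band_fractions(st, thr, volume), thr)
    for (ly in c("upper", "lower"))
      if (cl[[ly]] == "safe") safe[[ly]] <- c(safe[[ly]], st$d)
  }
  gaps <- gap_set(safe$upper, safe$lower, stack$total)
  tab <- do.call(rbind, lapply(c("upper", "lower"), function(ly) {
    ds <- safe[[ly]]
    data.frame(layer = ly,
               distances_mm = paste(sprintf("%.1f", ds), collapse = ", "),
               ratios = paste(sprintf("%.2f",
                 if (length(ds)) compression_ratio(ds, stack$total)
                 else numeric(0)), collapse = ", "),
               gaps_mm = paste(sprintf("%.1f", gaps), collapse = ", "))
  }))
  structure(list(
    upper = list(distances = safe$upper,
                 ratios = if (length(safe$upper))
                   compression_ratio(safe$upper, stack$total) else numeric(0)),
    lower = list(distances = safe$lower,
                 ratios = if (length(safe$lower))
                   compression_ratio(safe$lower, stack$total) else numeric(0)),
    gaps = gaps, total = stack$total, table = tab),
    class = "safety_table")
}

#' @export
print.safety_table <- function(x, ...) {
  cat(sprintf("Safe compression table (total thickness %.1f mm)\n", x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}
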