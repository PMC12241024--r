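#' Default run configuration
#'
#' All defaults: porcine-colon Ogden constants (Pa), 10-16 mm annulus,
#' surrogate footprints, 0.1/0.3-0.6/0.6 MPa thresholds with 20%/5%
#' volume-fraction criteria, 0.1 mm steps to an 80% ratio, uniform engine.
#'
#' @return a named list (the `run_config` structure).
#' @export
default_config <- function() {
  list(
    material = list(mu_pa = c(8300, 200, 6200),
                    alpha = c(7.625, 13.875, 7.625),
                    penalty_bulk_factor = 1000),
    geometry = list(t_upper = 2.0, t_lower = 2.0,
                    r_inner = 10, r_outer = 16, element_size = 0.5),
    footprints = list(anvil = NULL, cartridge = NULL),  # NULL = defaults
    thresholds = list(tau_low = 0.1, fix_low = 0.3, fix_high = 0.6,
                      tau_dmg = 0.6, f_fix_min = 0.20, f_dmg_max = 0.05),
    load = list(step_mm = 0.1, max_ratio = 0.8),
    engine = "uniform",
    seed = 1L,
    out_dir = "staplecomp-out")
}

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s) at %s: %s", path,
                 paste(bad, collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills every omitted block with the
#' defaults of [default_config()], validates all invariants before any
#' computation, and rejects unknown keys with their key path. An empty file
#' yields the full default configuration. Material moduli are given in Pa
#' (converted to MPa internally).
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return object of class `run_config`: the validated list plus realised
#'   `objects` (`mat`, `stack`, `footprints`, `thr`).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    check_keys(user, names(cfg), "top level")
    for (blk in names(user)) {
      if (is.list(cfg[[blk]]) && !is.null(names(cfg[[blk]]))) {
        if (!blk %in% c("footprints"))
          check_keys(user[[blk]], names(cfg[[blk]]), blk)
        cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
      } else cfg[[blk]] <- user[[blk]]
    }
  }
  m <- cfg$material
  if (length(m$mu_pa) != length(m$alpha))
    stop("material: mu_pa and alpha must have the same length")
  t <- cfg$thresholds
  if (abs(t$fix_high - t$tau_dmg) > 1e-12)
    stop("thresholds: fix_high must equal tau_dmg")
  if (!cfg$engine %in% c("uniform", "fem"))
    stop("engine must be 'uniform' or 'fem'")
  mat <- ogden_material(m$mu_pa, m$alpha)
  mat$penalty_bulk <- m$penalty_bulk_factor * initial_shear_modulus(mat)
  g <- cfg$geometry
  stack <- tissue_stack(g$t_upper, g$t_lower, g$r_inner, g$r_outer)
  fp <- default_footprints(stack)
  for (side in c("anvil", "cartridge"))
    if (!is.null(cfg$footprints[[side]]))
      fp[[side]] <- contact_footprint(
        side, as.data.frame(do.call(rbind, lapply(cfg$footprints[[side]],
                                                  as.data.frame))), stack)
  thr <- thresholds(t$tau_low, c(t$fix_low, t$fix_high), t$tau_dmg,
                    t$f_fix_min, t$f_dmg_max)
  cfg$objects <- list(mat = mat, stack = stack, footprints = fp, thr = thr)
  class(cfg) <- "run_config"
  cfg
}

# Config echo without realised objects, for the manifest.
config_echo <- function(cfg) {
  cfg$objects <- NULL
  unclass(cfg)
}
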