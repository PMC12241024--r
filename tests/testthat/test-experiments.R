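test_that("uniform-engine sweep recovers the published safe maxima", {
  sw <- thickness_sweep(ogden_material(), sweep_config(engine = "uniform"))
  expect_named(sw$pairs, c("2.5-2.5", "2.0-2.0", "1.5-1.5",
                           "2.5-1.5", "1.5-2.5"))
  st20 <- sw$pairs[["2.0-2.0"]]$safety
  expect_equal(max(st20$lower$distances), 2.4)
  expect_equal(max(st20$lower$ratios), 0.60)
  expect_equal(max(sw$pairs[["1.5-1.5"]]$safety$lower$distances), 1.8)
  expect_equal(max(sw$pairs[["2.5-2.5"]]$safety$lower$distances), 3.0)
})

test_that("safe ratio sets are scale-invariant across symmetric pairs", {
  sw <- thickness_sweep(ogden_material(), sweep_config(
    pairs = list(c(1.5, 1.5), c(2.0, 2.0), c(2.5, 2.5)), engine = "uniform"))
  # stress depends only on lambda, so the safe stretch interval is shared;
  # on the 0.1 mm grid this means every safe ratio of every pair falls in
  # the same lambda window, the largest safe ratio is 60% throughout, and
  # the absolute distance ranges widen with total thickness
  lam_lo <- 1 - max(unlist(lapply(sw$pairs,
    function(p) p$safety$lower$distances / p$stack$total)))
  expect_gt(abs(uniaxial_cauchy_stress(ogden_material(), lam_lo)), 0.3 - 0.02)
  for (p in sw$pairs) {
    expect_equal(max(p$safety$lower$ratios), 0.60)
    sig <- abs(uniaxial_cauchy_stress(ogden_material(),
                                      1 - p$safety$lower$distances /
                                        p$stack$total))
    expect_true(all(sig >= 0.3 & sig <= 0.6))
  }
  dists <- vapply(sw$pairs, function(p)
    length(p$safety$lower$distances), numeric(1))
  expect_true(all(diff(dists) >= 0))
})

test_that("a zero-travel sweep yields empty results without error", {
  sw <- thickness_sweep(ogden_material(), sweep_config(
    pairs = list(c(2, 2)), engine = "uniform", max_ratio = 0.025))
  expect_equal(nrow(sw$pairs[[1]]$layer_stats), 2)  # single step, 2 layers
  expect_length(sw$pairs[[1]]$safety$gaps, 0)
})

test_that("solver failures are reported per pair without aborting the sweep", {
  # element_size too coarse for the thin pair -> per-pair error entry
  sw <- thickness_sweep(ogden_material(), sweep_config(
    pairs = list(c(0.4, 0.4), c(2, 2)), engine = "fem", element_size = 0.5,
    max_ratio = 0.125))
  expect_true(!is.null(sw$pairs[[1]]$error))
  expect_null(sw$pairs[[2]]$error)
})

test_that("convergence bookkeeping selects the first sub-criterion size", {
  r <- convergence_report(c(2, 1.6, 1.2), c(1.00, 0.90, 0.872))
  expect_equal(round(r$pct_change, 1), c(10, 3.1))
  expect_false(r$converged)
  expect_equal(r$selected, 1.2)   # flagged fallback to the smallest size
  r2 <- convergence_report(c(2, 1.6), c(1.00, 0.99))
  expect_true(r2$converged)
  expect_equal(r2$selected, 1.6)
  expect_error(convergence_report(c(1, 2), c(1, 1)), "decreasing")
  expect_error(convergence_report(2, 1), "at least two")
})

test_that("FE mesh convergence study runs and reports refinement changes", {
  rep <- mesh_convergence(tissue_stack(2.5, 2.5), fe_study_material(),
                          sizes = c(1.25, 1.0), gap_target = 3.5)
  expect_s3_class(rep, "convergence_report")
  expect_length(rep$pct_change, 1)
  expect_true(all(rep$means > 0))
  expect_true(rep$selected %in% rep$sizes)
})

test_that("validation against the model's own curve gives unit quotients", {
  mat <- ogden_material()
  stack <- tissue_stack(2, 2)
  a <- effective_area(default_footprints(stack)$anvil)
  self_ref <- make_reference_curve(mat, stack, seed = 1, sigma_log = 0)
  rep <- validation_curve(self_ref, mat, stack)
  expect_equal(rep$quotient, rep(1, nrow(rep)))
  expect_true(attr(rep, "pass"))
  # the ratio grid ends where the platen gap reaches 1 mm (d = 3.0 mm)
  expect_equal(max(rep$ratio), 0.75)
  expect_error(validation_curve(self_ref, mat, stack, gap_target = -1),
               "nonnegative")
})

test_that("seeded synthetic references stay within the validation contract", {
  mat <- ogden_material()
  stack <- tissue_stack(2, 2)
  for (seed in c(2, 17, 101)) {
    ref <- make_reference_curve(mat, stack, seed, sigma_log = 0.3)
    rep <- validation_curve(ref, mat, stack)
    expect_true(attr(rep, "pass"))
    expect_true(all(rep$within_magnitude))
  }
})
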