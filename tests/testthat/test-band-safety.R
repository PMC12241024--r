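test_that("band fractions follow the volumetric accounting rules", {
  thr <- thresholds()
  # 10 equal-volume elements: 7 low-stressed, 2 in the fixation band, 1 hot
  step <- make_toy_stress_field(data.frame(
    volume = rep(1, 10), vm = c(rep(0.2, 7), 0.45, 0.45, 0.7)))
  bf <- band_fractions(step, thr)
  up <- bf[bf$layer == "upper", ]
  expect_equal(up$f_fix, 0.2)
  expect_equal(up$f_dmg, 0.1)
  # all elements in the band
  bf2 <- band_fractions(make_toy_stress_field(
    data.frame(volume = rep(2, 4), vm = rep(0.45, 4))), thr)
  expect_equal(bf2$f_fix[bf2$layer == "upper"], 1)
  expect_equal(bf2$f_dmg[bf2$layer == "upper"], 0)
  # everything below tau_low: explicit no-fixation state, not 0/0
  bf3 <- band_fractions(make_toy_stress_field(
    data.frame(volume = rep(1, 3), vm = rep(0.05, 3))), thr)
  expect_false(bf3$fixed[bf3$layer == "upper"])
  expect_true(is.na(bf3$f_fix[bf3$layer == "upper"]))
  expect_identical(unname(classify(bf3, thr)["upper"]), "not_fixed")
})

test_that("band boundaries are inclusive for fixation and strict for damage", {
  thr <- thresholds()
  bf <- band_fractions(make_toy_stress_field(data.frame(
    volume = c(1, 1, 1), vm = c(0.3, 0.6, 0.6000001))), thr)
  up <- bf[bf$layer == "upper", ]
  expect_equal(up$v_fix, 2)   # 0.3 and 0.6 both count as fixation
  expect_equal(up$v_dmg, 1)   # only strictly above 0.6 is damage
})

test_that("classification applies strict 20% / 5% rules", {
  thr <- thresholds()
  mk <- function(f_fix, f_dmg) {
    bf <- data.frame(layer = "upper", v_total = 1, v_fix = f_fix,
                     v_dmg = f_dmg, f_fix = f_fix, f_dmg = f_dmg,
                     fixed = TRUE)
    class(bf) <- c("band_fractions", class(bf))
    unname(classify(bf, thr))
  }
  expect_equal(mk(0.25, 0.04), "safe")
  expect_equal(mk(0.20, 0.00), "not_fixed")     # exactly 20% is not enough
  expect_equal(mk(0.30, 0.05), "safe")          # exactly 5% is tolerated
  expect_equal(mk(0.30, 0.051), "damaged")
  expect_equal(mk(0.10, 0.30), "damaged_and_not_fixed")
})

test_that("threshold invariants are enforced", {
  expect_error(thresholds(fix_band = c(0.3, 0.5)), "fix_band\\[2\\]")
  expect_error(thresholds(tau_low = 0.4), "tau_low")
  expect_error(thresholds(f_fix_min = 0.04, f_dmg_max = 0.05), "f_dmg_max")
})

test_that("compression ratio uses exact decimal half-up rounding", {
  expect_equal(compression_ratio(1.8, 3.0), 0.60)
  expect_equal(compression_ratio(1.9, 3.0), 0.63)
  expect_equal(compression_ratio(2.3, 4.0), 0.58)  # 0.575 rounds half-up
  expect_equal(compression_ratio(2.5, 4.0), 0.63)  # 0.625 rounds half-up
  expect_equal(compression_ratio(0, 4.0), 0)
  expect_equal(compression_ratio(c(2.9, 3.0, 3.1, 3.2), 5.0),
               c(0.58, 0.60, 0.62, 0.64))
  expect_error(compression_ratio(1, 0), "positive")
  expect_error(compression_ratio(5, 4), "<= total")
})

test_that("band partition closes exactly on random stress fields", {
  thr <- thresholds()
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    spec <- data.frame(volume = stats::runif(n, 0.1, 5),
                       vm = stats::runif(n, 0, 1.2),
                       layer = sample(c("upper", "lower"), n, replace = TRUE))
    bf <- band_fractions(make_toy_stress_field(spec), thr)
    for (j in seq_len(nrow(bf))) {
      if (!bf$fixed[j]) next
      v <- spec$vm[if (bf$layer[j] == "tissue") TRUE
                   else spec$layer == bf$layer[j]]
      w <- spec$volume[if (bf$layer[j] == "tissue") TRUE
                       else spec$layer == bf$layer[j]]
      v_low <- sum(w[v > thr$tau_low & v < thr$fix_band[1]])
      # low + fixation + damage bands partition the fixed-tissue volume
      expect_equal(v_low + bf$v_fix[j] + bf$v_dmg[j], bf$v_total[j],
                   tolerance = 1e-12)
    }
  }
})

test_that("classification is monotone under uniform stress increase", {
  thr <- thresholds()
  set.seed(11)
  rank <- c(safe = 1, not_fixed = 2, damaged = 3, damaged_and_not_fixed = 3)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    spec <- data.frame(volume = stats::runif(n, 0.5, 2),
                       vm = stats::runif(n, 0, 0.8))
    c1 <- classify(band_fractions(make_toy_stress_field(spec), thr), thr)
    spec2 <- spec
    spec2$vm <- spec$vm * 1.5
    c2 <- classify(band_fractions(make_toy_stress_field(spec2), thr), thr)
    # a damaged layer can never become safe when every stress increases
    if (c1[["upper"]] %in% c("damaged", "damaged_and_not_fixed"))
      expect_true(c2[["upper"]] != "safe")
  }
})

test_that("joint gap sets reproduce the intersection rule", {
  expect_equal(gap_set(c(2.4, 2.5), c(2.3, 2.4), 4.0), 1.6)
  expect_equal(gap_set(c(2.9, 3.0, 3.1, 3.2), c(2.9, 3.0), 5.0), c(2.1, 2.0))
  expect_equal(gap_set(c(1.0), c(2.0), 3.0), numeric(0))
})

test_that("printed safe-distance sets reproduce every published ratio and gap cell", {
  # pure-logic regression over all five thickness pairs (solver not involved)
  rows <- list(
    list(total = 3.0, upper = c(1.8, 1.9), lower = 1.8,
         r_up = c(0.60, 0.63), r_lo = 0.60, gaps = 1.2),
    list(total = 4.0, upper = c(2.4, 2.5), lower = c(2.3, 2.4, 2.5),
         r_up = c(0.60, 0.63), r_lo = c(0.58, 0.60, 0.63),
         gaps = c(1.6, 1.5)),
    list(total = 4.0, upper = c(2.4, 2.5), lower = c(2.3, 2.4),
         r_up = c(0.60, 0.63), r_lo = c(0.58, 0.60), gaps = 1.6),
    list(total = 4.0, upper = c(2.4, 2.5), lower = c(2.3, 2.4),
         r_up = c(0.60, 0.63), r_lo = c(0.58, 0.60), gaps = 1.6),
    list(total = 5.0, upper = c(2.9, 3.0, 3.1, 3.2), lower = c(2.9, 3.0),
         r_up = c(0.58, 0.60, 0.62, 0.64), r_lo = c(0.58, 0.60),
         gaps = c(2.1, 2.0)))
  for (row in rows) {
    expect_equal(compression_ratio(row$upper, row$total), row$r_up)
    expect_equal(compression_ratio(row$lower, row$total), row$r_lo)
    expect_setequal(gap_set(row$upper, row$lower, row$total), row$gaps)
  }
})

test_that("safety_table scans step results and intersects layer-safe sets", {
  mat <- ogden_material()
  stack <- tissue_stack(2, 2)
  res <- run_uniform(mat, stack, load_program(stack))
  st <- safety_table(res, thresholds(), stack)
  # uniform engine: both layers identical by homogeneity
  expect_identical(st$upper$distances, st$lower$distances)
  expect_equal(max(st$upper$distances), 2.4)
  expect_equal(max(st$upper$ratios), 0.60)
  expect_equal(min(st$gaps), 4.0 - 2.4)
  # disjoint / empty sets are a valid outcome
  st0 <- safety_table(res[1:3], thresholds(), stack)
  expect_length(st0$gaps, 0)
})
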