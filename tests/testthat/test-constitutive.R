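test_that("strain energy vanishes at the reference state and matches closed forms", {
  mat <- ogden_material()
  expect_equal(strain_energy(mat, c(1, 1, 1)), 0)
  # single-term alpha = 2 reduces to incompressible neo-Hooke
  nh <- ogden_material(mu_pa = 2e6, alpha = 2)
  expect_equal(strain_energy(nh, c(2, 1 / sqrt(2), 1 / sqrt(2))), 2.0)
  # independently computed term-by-term sum at 60% uniaxial compression
  lam <- c(0.4, 0.4^-0.5, 0.4^-0.5)
  expect_equal(strain_energy(mat, lam), oracle_energy(lam[1], lam[2], lam[3]),
               tolerance = 1e-12)
  expect_equal(strain_energy(mat, lam), 0.1359835, tolerance = 1e-6)
  expect_error(strain_energy(mat, c(-1, 1, 1)), "positive")
})

test_that("uniaxial Cauchy stress matches the energy derivative and closed forms", {
  mat <- ogden_material()
  expect_equal(uniaxial_cauchy_stress(mat, 1), 0)
  nh <- ogden_material(mu_pa = 2e6, alpha = 2)
  expect_equal(uniaxial_cauchy_stress(nh, 2), 2 * (4 - 1 / 2))
  # sigma = lambda dW/dlambda along the incompressible uniaxial path
  for (lam in c(0.3, 0.4, 0.7, 1.3, 2.5))
    expect_equal(uniaxial_cauchy_stress(mat, lam), oracle_uniaxial_fd(lam),
                 tolerance = 1e-6)
  expect_equal(uniaxial_cauchy_stress(mat, 0.4), -0.5922581,
               tolerance = 1e-6)
  expect_error(uniaxial_cauchy_stress(mat, 0), "positive")
})

test_that("uniaxial stress has the sign of lambda - 1 and is monotone", {
  mat <- ogden_material()
  lam <- seq(0.2, 5, by = 0.01)
  sig <- uniaxial_cauchy_stress(mat, lam)
  expect_true(all(sign(sig) == sign(lam - 1)))
  expect_true(all(diff(sig) > 0))
})

test_that("initial shear modulus is the half mu-alpha sum", {
  expect_equal(initial_shear_modulus(ogden_material()), 0.05666875)
  expect_equal(initial_shear_modulus(ogden_material(2e6, 2)), 2)
  expect_error(ogden_material(numeric(0), numeric(0)), "at least one")
})

test_that("material invariants are enforced", {
  expect_error(ogden_material(c(8300, 200), c(7.625)), "same length")
  expect_error(ogden_material(-8300, 7.625), "positive")
  expect_error(ogden_material(penalty_bulk = 0.001), "100 x")
  # duplicate exponents are kept verbatim
  mat <- ogden_material()
  expect_identical(mat$alpha, c(7.625, 13.875, 7.625))
})

test_that("von Mises stress is hydrostatic-invariant and matches closed forms", {
  expect_equal(von_mises(cauchy_axisym(-5, -5, -5, 0)), 0)
  expect_equal(von_mises(cauchy_axisym(0, -0.592, 0, 0)), 0.592)
  expect_equal(von_mises(cauchy_axisym(1, -1, 0, 0)), sqrt(3))
  # adding a hydrostatic component never changes the equivalent stress
  set.seed(42)
  for (i in 1:20) {
    s <- stats::rnorm(4)
    p <- stats::rnorm(1, sd = 10)
    base <- cauchy_axisym(s[1], s[2], s[3], s[4])
    shifted <- cauchy_axisym(s[1] + p, s[2] + p, s[3] + p, s[4])
    expect_equal(von_mises(base), von_mises(shifted), tolerance = 1e-10)
  }
  expect_error(cauchy_axisym(Inf, 0, 0, 0), "finite")
})
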