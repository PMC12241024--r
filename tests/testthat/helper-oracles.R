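# Independent closed-form oracles, written against the algebra directly so
# they share no code path with the package internals.

# Porcine colonic wall constants (MPa).
oracle_mu <- c(8300, 200, 6200) / 1e6
oracle_alpha <- c(7.625, 13.875, 7.625)

# Term-by-term strain energy, loop form.
oracle_energy <- function(l1, l2, l3, mu = oracle_mu, al = oracle_alpha) {
  w <- 0
  for (p in seq_along(mu))
    w <- w + mu[p] / al[p] * (l1^al[p] + l2^al[p] + l3^al[p] - 3)
  w
}

# Uniaxial incompressible Cauchy stress as lambda * dW/dlambda along the
# isochoric uniaxial path, by central finite difference.
oracle_uniaxial_fd <- function(lam, h = 1e-6) {
  path <- function(l) oracle_energy(l, 1 / sqrt(l), 1 / sqrt(l))
  lam * (path(lam + h) - path(lam - h)) / (2 * h)
}

# Compressible (penalty) uniaxial state: lateral stretch minimises the
# total energy at fixed axial stretch; returns principal Cauchy stresses.
oracle_uniaxial_penalty <- function(lam_z, kappa,
                                    mu = oracle_mu, al = oracle_alpha) {
  wtot <- function(lr) {
    J <- lam_z * lr^2
    lb <- J^(-1 / 3) * c(lam_z, lr, lr)
    oracle_energy(lb[1], lb[2], lb[3], mu, al) + kappa / 2 * (J - 1)^2
  }
  lr <- stats::optimize(wtot, c(0.5, 4), tol = 1e-12)$minimum
  J <- lam_z * lr^2
  lb <- J^(-1 / 3) * c(lam_z, lr, lr)
  dev <- numeric(3)
  for (p in seq_along(mu)) {
    w <- mu[p] * lb^al[p]
    dev <- dev + (w - mean(w))
  }
  list(sig = dev / J + kappa * (J - 1), lam_r = lr, J = J)
}

# Hand-built single-element axisymmetric mesh (bypasses build_mesh's
# minimum-resolution rules) for patch tests.
single_element_mesh <- function(r0 = 10, r1 = 11, h = 1) {
  stack <- tissue_stack(h / 2, h / 2, r0, r1)
  nodes <- cbind(r = c(r0, r1, r1, r0), z = c(0, 0, h, h))
  elems <- matrix(c(1L, 2L, 3L, 4L), 1, 4)
  structure(list(nodes = nodes, elems = elems, layer = "lower",
                 vol_ref = 2 * pi * (r0 + r1) / 2 * (r1 - r0) * h,
                 stack = stack, element_size = max(r1 - r0, h),
                 nr = 1L, nz_lower = 1L, nz_upper = 0L),
            class = "axisym_mesh")
}

# Study material: spec constants with the penalty level used for the
# footprint-mode finite-element runs (augmented-Lagrangian configuration).
fe_study_material <- function() {
  base <- ogden_material()
  ogden_material(penalty_bulk = 2000 * initial_shear_modulus(base))
}
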