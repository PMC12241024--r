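test_that("mesh volume matches the analytic annulus volume at every size", {
  for (p in list(c(1.5, 1.5), c(2.5, 2.5), c(2.5, 1.5))) {
    stack <- tissue_stack(p[1], p[2])
    exact <- pi * (stack$r_outer^2 - stack$r_inner^2) * stack$total
    for (sz in c(1.2, 0.8, 0.4)) {
      mesh <- build_mesh(stack, sz)
      expect_lt(abs(mesh_volume(mesh) - exact) / exact, 0.005)
    }
  }
})

test_that("volume is stable under refinement and layers are tagged", {
  stack <- tissue_stack(2.5, 2.5)
  v1 <- mesh_volume(build_mesh(stack, 0.8))
  v2 <- mesh_volume(build_mesh(stack, 0.4))
  expect_lt(abs(v2 - v1) / v1, 0.001)
  mesh <- build_mesh(stack, 0.8)
  expect_setequal(unique(mesh$layer), c("upper", "lower"))
  expect_equal(sum(mesh$layer == "upper"), sum(mesh$layer == "lower"))
  # asymmetric stack: layer volumes in thickness proportion
  m2 <- build_mesh(tissue_stack(2.5, 1.5), 0.5)
  vu <- sum(m2$vol_ref[m2$layer == "upper"])
  vl <- sum(m2$vol_ref[m2$layer == "lower"])
  expect_equal(vu / vl, 2.5 / 1.5, tolerance = 1e-9)
})

test_that("too-coarse meshes are rejected with refinement advice", {
  expect_error(build_mesh(tissue_stack(1.5, 2.5), 2.0), "refine")
})

test_that("effective area is the fraction-weighted annulus sum", {
  fp <- contact_footprint("anvil",
    data.frame(r_in = 10, r_out = 16, area_fraction = 1))
  expect_equal(effective_area(fp), pi * (256 - 100))
  fp2 <- contact_footprint("anvil",
    data.frame(r_in = 10, r_out = 16, area_fraction = 0.5))
  expect_equal(effective_area(fp2), effective_area(fp) / 2)
  empty <- contact_footprint("cartridge",
    data.frame(r_in = numeric(0), r_out = numeric(0),
               area_fraction = numeric(0)))
  expect_equal(effective_area(empty), 0)
  # invariant under band re-ordering
  b <- data.frame(r_in = c(13, 10), r_out = c(15, 12),
                  area_fraction = c(0.7, 1))
  expect_equal(effective_area(contact_footprint("anvil", b)),
               effective_area(contact_footprint("anvil", b[2:1, ])))
})

test_that("footprint invariants are enforced", {
  stack <- tissue_stack(2, 2)
  expect_error(contact_footprint("anvil",
    data.frame(r_in = 10, r_out = 17, area_fraction = 1), stack),
    "within")
  expect_error(contact_footprint("anvil",
    data.frame(r_in = c(10, 11), r_out = c(12, 13),
               area_fraction = c(1, 1))), "overlap")
  expect_error(contact_footprint("anvil",
    data.frame(r_in = 10, r_out = 12, area_fraction = 0)), "area_fraction")
})

test_that("default footprints give the cartridge less contact than the anvil", {
  stack <- tissue_stack(2, 2)
  fp <- default_footprints(stack)
  a <- effective_area(fp$anvil)
  ca <- effective_area(fp$cartridge)
  expect_gt(a, ca)
  expect_gt(ca / a, 0.5)
  expect_lt(ca / a, 0.7)
  # bands stay inside the tissue annulus
  expect_gte(min(fp$anvil$bands$r_in, fp$cartridge$bands$r_in),
             stack$r_inner)
  expect_lte(max(fp$anvil$bands$r_out, fp$cartridge$bands$r_out),
             stack$r_outer)
  # symmetric custom footprints have equal areas
  b <- data.frame(r_in = 11, r_out = 15, area_fraction = 1)
  expect_equal(effective_area(contact_footprint("anvil", b, stack)),
               effective_area(contact_footprint("cartridge", b, stack)))
})
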