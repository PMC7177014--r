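# Zone classification, direction constant and the harmonic squeeze force.

test_that("zone scaling ramps linearly from thin to normal zone", {
  geom <- ref_geom()   # X_box 55, A_thin 10, A_buffer 10
  expect_equal(zone_scaling(27.5, geom), 1.0)            # thin-zone centre
  expect_equal(zone_scaling(27.5 + 5, geom), 1.0)        # thin-zone edge
  expect_equal(zone_scaling(27.5 + 15, geom), 0.0)       # buffer/normal edge
  expect_equal(zone_scaling(27.5 - 15, geom), 0.0)
  expect_equal(zone_scaling(27.5 + 10, geom), 0.5)       # ramp midpoint
  expect_equal(zone_scaling(27.5 - 10, geom), 0.5)
  # periodic wrap: x = 0 is deep inside the normal zone
  expect_equal(zone_scaling(0, geom), 0.0)
  expect_equal(zone_scaling(55 - 1e-9, geom), 0.0)
})

test_that("zone classification labels all three zones", {
  geom <- ref_geom()
  expect_identical(zone_of(c(27.5, 35, 2), geom),
                   c("thin", "buffer", "normal"))
})

test_that("geometry invariants are enforced", {
  expect_error(zone_geometry(10, 5, 5), "fit")
  expect_error(zone_geometry(10, -1, 2), "A_thin")
  expect_error(zone_geometry(10, 1, 0), "A_buffer")
  expect_error(thinning_params(k = -1), "k")
  expect_error(thinning_params(D = 0), "D")
})

test_that("direction constant selects the leaflet", {
  expect_identical(direction_constant(1.5, 1), 1L)
  expect_identical(direction_constant(0.3, 1), 0L)
  expect_identical(direction_constant(-1.5, 1), -1L)
  expect_identical(direction_constant(c(0.5, -0.5), 1), c(0L, 0L))
})

test_that("thinning force matches hand-evaluated cases", {
  geom <- ref_geom()
  par <- thinning_params(k = 20, D = 1)
  # tail bead in the thin-zone centre, z = +1.5: d=+1, C=1, 20*(0.5-1.5)
  expect_equal(thinning_force(27.5, 1.5, geom, par), -20.0)
  expect_equal(thinning_force(27.5, -1.5, geom, par), 20.0)
  # head beads feel nothing
  expect_equal(thinning_force(27.5, 1.5, geom, par, is_tail = FALSE), 0.0)
})

test_that("field invariants hold on an (x, z) grid", {
  geom <- ref_geom()
  par <- thinning_params(k = 20, D = 1)
  xs <- seq(0, geom$X_box - 1e-9, length.out = 201)
  zs <- seq(-2.5, 2.5, length.out = 101)
  g <- expand.grid(x = xs, z = zs)
  f <- thinning_force(g$x, g$z, geom, par)
  f_mirror <- thinning_force(g$x, -g$z, geom, par)
  # antisymmetry in z
  expect_equal(f, -f_mirror, tolerance = 1e-12)
  # dead zone: |z| <= D/2 or C = 0
  C <- zone_scaling(g$x, geom)
  dead <- abs(g$z) <= 0.5 | C == 0
  expect_true(all(f[dead] == 0))
  # restoring: sign(F) = -sign(z) wherever nonzero
  nz <- f != 0
  expect_true(all(sign(f[nz]) == -sign(g$z[nz])))
  # linear scaling in k
  f2 <- thinning_force(g$x, g$z, geom, thinning_params(k = 40, D = 1))
  expect_equal(f2, 2 * f, tolerance = 1e-12)
  # linear in C: force at the ramp midpoint is half the thin-zone force
  expect_equal(thinning_force(27.5 + 10, 1.5, geom, par),
               0.5 * thinning_force(27.5, 1.5, geom, par))
})

test_that("zone scaling and force are continuous across boundaries", {
  geom <- ref_geom()
  par <- thinning_params(k = 20, D = 1)
  eps <- 1e-9
  for (xb in c(22.5, 32.5, 7.5, 47.5)) {    # thin and normal edges
    expect_equal(zone_scaling(xb - eps, geom), zone_scaling(xb + eps, geom),
                 tolerance = 1e-6)
  }
  # continuity in z at the dead-zone edge
  expect_equal(thinning_force(27.5, 0.5 + 1e-10, geom, par), 0,
               tolerance = 1e-8)
  # C continuous across the periodic boundary
  expect_equal(zone_scaling(1e-10, geom), zone_scaling(55 - 1e-10, geom),
               tolerance = 1e-6)
})

test_that("non-finite coordinates are rejected", {
  geom <- ref_geom()
  par <- thinning_params()
  expect_error(thinning_force(NaN, 1, geom, par), "non-finite")
  expect_error(zone_scaling(Inf, geom), "non-finite")
})
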