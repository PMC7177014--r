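# Force correctness, integrator behaviour and mechanical diagnostics.

small_sys <- function(seed = 1) {
  cached(paste0("sys_small_", seed),
         build_bilayer(small_geom(), c(POPC = 1), box_y = 6, seed = seed))
}

test_that("internal forces obey Newton's third law; field forces do not cancel", {
  sys <- small_sys()
  f <- compute_forces(sys)
  expect_equal(colSums(f$force), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(colSums(f$force_external), c(0, 0, 0), tolerance = 1e-12)
  f2 <- compute_forces(sys, field = thinning_params(k = 20, D = 0.5))
  expect_equal(colSums(f2$force), c(0, 0, 0), tolerance = 1e-8)
  # the field is external: the total force sum reduces to the field sum
  total <- f2$force + f2$force_external
  expect_equal(colSums(total), colSums(f2$force_external), tolerance = 1e-8)
  expect_equal(sum(f2$force_external[, 1]), 0)
  expect_gt(sum(abs(f2$force_external[, 3])), 1)   # field engages tail beads
  # field matches the reference implementation bead by bead
  z <- sys$pos[, 3] - f2$midplane
  fz_ref <- thinning_force(sys$pos[, 1], z, sys$geom,
                           thinning_params(k = 20, D = 0.5),
                           is_tail = sys$is_tail)
  expect_equal(f2$force_external[, 3], fz_ref, tolerance = 1e-9)
})

test_that("an isolated bonded pair at rest length feels no bond force", {
  sys <- small_sys()
  # pull one bond to exact rest length in an otherwise empty copy
  m <- thinmem::model_constants()
  solo <- sys
  solo$pos <- matrix(c(3, 3, 6, 3, 3, 6 + m$bond_r0), 2, 3, byrow = TRUE)
  solo$vel <- matrix(0, 2, 3)
  solo$sigma <- rep(m$sigma_tail, 2); solo$att <- c(2L, 2L)
  solo$eps <- c(0, 0); solo$is_tail <- c(TRUE, TRUE)
  solo$is_lipid <- c(TRUE, TRUE); solo$lipid_id <- c(1L, 1L)
  solo$leaflet <- c(1L, 1L); solo$species_of_lipid <- "POPC"
  solo$bonds <- matrix(c(1, 2, m$bond_k, m$bond_r0), 1)
  solo$angles <- matrix(0, 0, 4); solo$probe_idx <- integer(0)
  f <- compute_forces(solo)
  expect_equal(f$force, matrix(0, 2, 3), tolerance = 1e-10)
})

test_that("zero force, zero friction, zero temperature gives straight-line motion", {
  m <- thinmem::model_constants()
  sys <- small_sys()
  solo <- sys
  solo$pos <- matrix(c(3, 3, 6), 1, 3)
  solo$vel <- matrix(c(0.1, 0.05, -0.02), 1, 3)
  solo$sigma <- m$sigma_tail; solo$att <- 2L; solo$eps <- 0
  solo$is_tail <- TRUE; solo$is_lipid <- TRUE; solo$lipid_id <- 1L
  solo$leaflet <- 1L; solo$species_of_lipid <- "POPC"
  solo$bonds <- matrix(0, 0, 4); solo$angles <- matrix(0, 0, 4)
  solo$probe_idx <- integer(0)
  st <- run_settings(dt = 0.02, T = 1e-12, friction = 0, n_steps = 100,
                     seed = 1)
  tr <- run_dynamics(solo, st, log_stride = 0)
  expect_equal(tr$system$pos[1, ],
               c(3 + 0.1 * 2, 3 + 0.05 * 2, 6 - 0.02 * 2),
               tolerance = 1e-10)
  expect_equal(tr$system$vel[1, ], c(0.1, 0.05, -0.02), tolerance = 1e-12)
})

test_that("trajectories are bitwise deterministic for a fixed seed", {
  sys <- small_sys()
  st <- run_settings(n_steps = 300, seed = 17)
  a <- run_dynamics(sys, st, field = thinning_params(k = 20, D = 0.5))
  b <- run_dynamics(sys, st, field = thinning_params(k = 20, D = 0.5))
  expect_identical(a$system$pos, b$system$pos)
  expect_identical(a$log, b$log)
})

test_that("the field at k = 0 reproduces the field-off trajectory exactly", {
  sys <- small_sys()
  st <- run_settings(n_steps = 300, seed = 23)
  off <- run_dynamics(sys, st, field = NULL)
  on0 <- run_dynamics(sys, st, field = thinning_params(k = 0, D = 1))
  expect_identical(off$system$pos, on0$system$pos)
  expect_identical(off$system$vel, on0$system$vel)
})

test_that("kinetic temperature equilibrates to the target within 3 SE", {
  tr <- cached("equi_traj", {
    sys <- small_sys()
    # small dt keeps the BAOAB kinetic-temperature discretization bias
    # well below the statistical resolution
    run_dynamics(sys, run_settings(dt = 0.01, n_steps = 8000, seed = 31),
                 log_stride = 40)
  })
  kt <- kinetic_temperature(tr, discard_frac = 0.3)
  expect_lt(abs(kt$T - 310), 3 * kt$se + 3)
})

test_that("an ideal gas is tensionless and overlapping beads blow up", {
  m <- thinmem::model_constants()
  sys <- small_sys()
  set.seed(5)
  n <- 400
  gas <- sys
  gas$pos <- cbind(runif(n, 0, 12), runif(n, 0, 6), runif(n, 3, 9))
  gas$vel <- matrix(rnorm(3 * n, sd = sqrt(8.31446e-3 * 310 / m$mass)), n, 3)
  gas$sigma <- rep(1e-3, n)          # effectively non-interacting
  gas$att <- rep(0L, n); gas$eps <- rep(0, n)
  gas$is_tail <- rep(FALSE, n); gas$is_lipid <- rep(TRUE, n)
  gas$lipid_id <- seq_len(n); gas$leaflet <- rep(1L, n)
  gas$species_of_lipid <- rep("POPC", n)
  gas$bonds <- matrix(0, 0, 4); gas$angles <- matrix(0, 0, 4)
  gas$probe_idx <- integer(0)
  tr <- run_dynamics(gas, run_settings(n_steps = 3000, seed = 3),
                     log_stride = 20)
  g <- measure_lateral_tension(tr, discard_frac = 0.2)
  expect_lt(abs(g$tension), 4 * g$se)
  # overlap blow-up is reported with a step reference
  bad <- gas
  bad$sigma <- rep(0.65, n)
  bad$pos[2, ] <- bad$pos[1, ] + 1e-4
  expect_error(run_dynamics(bad, run_settings(n_steps = 10, seed = 1)),
               "blow-up|non-finite")
})

test_that("tension window shorter than the block count errors", {
  sys <- small_sys()
  tr <- run_dynamics(sys, run_settings(n_steps = 200, seed = 2),
                     log_stride = 100)
  expect_error(measure_lateral_tension(tr, n_blocks = 10), "blocks")
})
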