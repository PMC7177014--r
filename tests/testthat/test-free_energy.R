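# Umbrella window planning, WHAM unbiasing, the sensing force and unit
# conversions.

test_that("window ladders are inclusive arithmetic sequences", {
  w <- plan_windows(27.5, 5.5, 0.2)
  expect_identical(length(w), 111L)
  expect_equal(w[1], 27.5)
  expect_equal(w[111], 5.5)
  expect_equal(unique(round(diff(w), 12)), -0.2)
  expect_equal(plan_windows(0, 1, 0.5), c(0, 0.5, 1))
  expect_identical(length(plan_windows(5, 5.2, 0.2)), 2L)
  expect_error(plan_windows(0, 1, 0.3), "commensurate")
  expect_error(plan_windows(1, 1, 0.1), "differ")
  expect_error(plan_windows(0, 1, -0.1), "positive")
})

test_that("molar force converts to piconewtons via Avogadro", {
  expect_equal(round(convert_force(6.89), 2), 11.44)
  expect_equal(convert_force(0), 0)
  expect_equal(round(convert_force(1), 4), 1.6605)
})

test_that("energies convert to kBT units", {
  expect_equal(round(to_kbt(25, 310)), 10)
  expect_equal(to_kbt(25, 310), 9.70, tolerance = 0.005)
  expect_equal(to_kbt(0, 200), 0)
  expect_equal(to_kbt(8.31446261815324e-3 * 310, 310), 1, tolerance = 1e-12)
  expect_error(to_kbt(1, -5), "positive")
})

test_that("WHAM recovers a harmonic landscape from biased samples", {
  fx <- make_fixture("umbrella_harmonic",
                     list(c = 5, x0 = 5, centers = seq(1, 9, length.out = 20),
                          k_u = 30, n_samples = 1e4, T = 310), seed = 7)
  prof <- wham(fx$windows, grid = 0.05, T = 310)
  ok <- prof$support > 50
  d <- prof$F[ok] - fx$truth$landscape(prof$x[ok])
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.2)
  # curvature recovered within 5% by a quadratic fit
  q <- lm(prof$F[ok] ~ poly(prof$x[ok], 2, raw = TRUE))
  expect_equal(2 * unname(coef(q)[3]), 5, tolerance = 0.05 * 5)
  expect_equal(min(prof$F, na.rm = TRUE), 0)
})

test_that("degenerate single-window WHAM equals the anchored log-histogram", {
  set.seed(9)
  w <- list(list(center = 0, k_u = 1e-12, series = rnorm(5000, 2, 0.5)))
  prof <- suppressWarnings(wham(w, grid = 0.1, T = 310))
  h <- hist(w[[1]]$series, breaks = seq(min(prof$x) - 0.05,
                                        max(prof$x) + 0.051, by = 0.1),
            plot = FALSE)
  kB <- 8.31446261815324e-3
  Fref <- -kB * 310 * log(h$counts / sum(h$counts))
  Fref <- Fref - min(Fref[is.finite(Fref)])
  ok <- h$counts > 0
  expect_equal(prof$F[ok], Fref[ok], tolerance = 1e-6)
})

test_that("WHAM is invariant to uniform sample-count scaling", {
  fx <- make_fixture("umbrella_harmonic",
                     list(c = 4, x0 = 4, centers = seq(2, 6, 0.5),
                          k_u = 40, n_samples = 2000, T = 310), seed = 3)
  p1 <- wham(fx$windows, grid = 0.05, T = 310)
  doubled <- lapply(fx$windows, function(w) {
    w$series <- rep(w$series, 2); w
  })
  p2 <- wham(doubled, grid = 0.05, T = 310)
  ok <- is.finite(p1$F) & is.finite(p2$F)
  expect_equal(p1$F[ok], p2$F[ok], tolerance = 1e-6)
})

test_that("sensing force is the buffer-zone OLS slope with sign toward thin", {
  geom <- ref_geom()
  # linear attraction toward the thin zone: F rises with distance s from x_c
  x <- seq(16, 27.5, by = 0.1)        # spans thin + right buffer
  s <- abs(x - geom$x_c)
  prof <- list(x = x, F = 6.89 * s - min(6.89 * s), support = rep(100, length(x)))
  sf <- sensing_force(prof, geom)
  expect_equal(sf$force, 6.89, tolerance = 1e-9)
  expect_equal(round(sf$force_pN, 2), 11.44)
  # flat profile: zero force
  prof$F <- rep(1, length(x))
  expect_equal(sensing_force(prof, geom)$force, 0, tolerance = 1e-12)
  # noisy linear profile: recovered within 2 SE
  set.seed(4)
  prof$F <- 3 * s + rnorm(length(x), sd = 0.5)
  sf <- sensing_force(prof, geom)
  expect_lt(abs(sf$force - 3), 2 * sf$se + 1e-9)
  expect_error(sensing_force(list(x = 1:3, F = 1:3), geom), "buffer")
})

test_that("thickness reparameterization preserves endpoint energies", {
  geom <- ref_geom()
  fit <- structure(list(L = -1.22, kappa = -19.14, x0 = 1.11, b = 4.08,
                        degenerate = FALSE), class = "sigmoid_fit")
  x <- seq(fit$x0 - 3, fit$x0 + 3, by = 0.05)
  prof <- list(x = x, F = 2 * (x - min(x)), support = rep(100, length(x)))
  fa <- reparameterize_thickness(prof, fit, T = 310)
  # endpoints map to the sigmoid asymptote region; dF across the range equal
  expect_equal(diff(range(fa$F)), diff(range(prof$F[prof$x >= min(fa$x) &
                                                      prof$x <= max(fa$x)])),
               tolerance = 0.2)
  expect_true(all(diff(fa$a) > 0))
  # identity-like mapping: steep sigmoid acts monotone; F(a) monotone too
  expect_true(all(diff(fa$F) >= -1e-9) || all(diff(fa$F) <= 1e-9))
})

test_that("jacobian correction adds the closed-form density term", {
  fit <- structure(list(L = -1, kappa = -4, x0 = 0, b = 4,
                        degenerate = FALSE), class = "sigmoid_fit")
  x <- seq(-2, 2, by = 0.02)
  prof <- list(x = x, F = rep(5, length(x)), support = rep(10, length(x)))
  fa <- reparameterize_thickness(prof, fit, T = 310,
                                 jacobian_correction = TRUE)
  kB <- 8.31446261815324e-3
  e <- exp(-fit$kappa * (fa$x - fit$x0))
  dadx <- fit$L * fit$kappa * e / (1 + e)^2
  expected <- -kB * 310 * log(abs(1 / dadx))
  expected <- expected - min(expected)
  expect_equal(fa$F, expected, tolerance = 1e-9)
})

test_that("non-monotone fits are rejected for reparameterization", {
  fit <- structure(list(L = 0, kappa = -4, x0 = 0, b = 4,
                        degenerate = TRUE), class = "sigmoid_fit")
  prof <- list(x = seq(-1, 1, 0.1), F = rep(0, 21), support = rep(1, 21))
  expect_error(reparameterize_thickness(prof, fit), "monotone")
})

test_that("the umbrella restraint acts on the probe COM as specified", {
  sys <- probe_only_system()
  centre <- sys$geom$x_c + 0.8
  f <- compute_forces(sys, restraint = list(k_u = 200, center = centre))
  com <- mean(sys$pos[sys$probe_idx, 1])
  # distribution contract: forces sum to -k_u (x_COM - centre), x only
  expect_equal(sum(f$force_external[, 1]), -200 * (com - centre),
               tolerance = 1e-9)
  expect_equal(sum(abs(f$force_external[, 2:3])), 0)
  # equal shares on equal-mass beads
  expect_equal(f$force_external[sys$probe_idx, 1],
               rep(-200 * (com - centre) / length(sys$probe_idx),
                   length(sys$probe_idx)), tolerance = 1e-9)
})

test_that("a restrained probe on a flat landscape samples kBT/k_u", {
  sys <- probe_only_system()
  k_u <- 100
  w <- cached("flat_window", {
    run_window(sys, center = sys$geom$x_c, k_u = k_u,
               settings = run_settings(n_steps = 30000, friction = 1,
                                       seed = 77),
               equil_steps = 2000, log_stride = 10)
  })
  kB <- 8.31446261815324e-3
  sig2 <- kB * 310 / k_u
  expect_gt(length(w$series), 100)
  # flat landscape: mean at the centre, variance near the closed form
  expect_lt(abs(mean(w$series) - sys$geom$x_c), 3 * sqrt(sig2))
  expect_gt(var(w$series) / sig2, 0.5)
  expect_lt(var(w$series) / sig2, 2.0)
})

test_that("windows warn when the COM cannot reach the centre", {
  sys <- probe_only_system()
  expect_warning(
    run_window(sys, center = sys$geom$x_c + 4, k_u = 50,
               settings = run_settings(n_steps = 400, friction = 1,
                                       seed = 5), log_stride = 10),
    "poor overlap")
})
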