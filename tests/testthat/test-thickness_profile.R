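# Thickness profiling, symmetrization, and the sigmoid fit.

test_that("flat leaflets give a constant profile with zero spread", {
  fx <- make_fixture("flat_membrane", list(thickness = 4, n_frames = 3))
  prof <- thickness_by_bin(fx, n_bins = 12)
  expect_true(all(is.finite(prof$mean)))
  expect_equal(prof$mean, rep(4, 12), tolerance = 1e-12)
  expect_equal(prof$sd, rep(0, 12), tolerance = 1e-12)
  expect_true(all(prof$n == 3))
})

test_that("single frame, single bin equals the direct head-gap average", {
  fx <- make_fixture("flat_membrane", list(thickness = 3.2))
  sys <- fx$system
  prof <- thickness_by_bin(sys, n_bins = 1)
  up <- sys$att == 1 & sys$leaflet == 1
  lo <- sys$att == 1 & sys$leaflet == -1
  expect_equal(prof$mean[1],
               mean(sys$pos[up, 3]) - mean(sys$pos[lo, 3]),
               tolerance = 1e-12)
})

test_that("profile reproduces a sigmoid-thinned membrane", {
  fx <- make_fixture("sigmoid_membrane", list(), seed = 4)
  prof <- thickness_by_bin(fx, n_bins = 110)
  half <- symmetrize(prof)
  tr <- fx$truth
  expected <- sigmoid_thickness(half$delta - tr$shift, tr$L, tr$kappa,
                                tr$x0, tr$b)
  # grid error only: bin width 0.5 nm across a steep transition
  ok <- is.finite(half$mean)
  expect_gt(mean(abs(half$mean[ok] - expected[ok]) < 0.08), 0.95)
  expect_equal(max(abs(range(half$mean, na.rm = TRUE) - c(tr$b + tr$L, tr$b))),
               0, tolerance = 0.05)
})

test_that("symmetrize averages mirror bins and cancels antisymmetric noise", {
  fx <- make_fixture("flat_membrane", list(thickness = 4))
  prof <- thickness_by_bin(fx, n_bins = 24)
  geom <- attr(prof, "geom")
  # inject antisymmetric perturbation about x_c
  d <- (prof$bin_center - geom$x_c)
  prof$mean <- prof$mean + 0.3 * sign(d) * (abs(d) < 5)
  half <- symmetrize(prof)
  expect_identical(nrow(half), 12L)
  expect_equal(half$mean, rep(4, 12), tolerance = 1e-12)
  # brute-force oracle on a random profile
  set.seed(11)
  prof$mean <- runif(24, 3, 5)
  half <- symmetrize(prof)
  for (j in seq_len(nrow(half))) {
    idx <- which(abs(abs((prof$bin_center - geom$x_c + geom$X_box / 2) %%
                           geom$X_box - geom$X_box / 2) - half$delta[j]) < 1e-9)
    expect_equal(half$mean[j], mean(prof$mean[idx]), tolerance = 1e-12)
  }
})

test_that("sigmoid fit recovers the reference parameter set from noiseless data", {
  L <- -1.22; kap <- -19.14; x0 <- 1.11; b <- 4.08
  xs <- seq(x0 - 5, x0 + 5, length.out = 200)
  y <- sigmoid_thickness(xs, L, kap, x0, b)
  f <- fit_sigmoid(xs, y, A_buffer = 10)
  expect_equal(f$L, L, tolerance = 1e-6)
  expect_equal(f$kappa, kap, tolerance = 1e-5)
  expect_equal(f$x0, x0, tolerance = 1e-6)
  expect_equal(f$b, b, tolerance = 1e-6)
  # closed-form midpoint: a(x0) = b + L/2
  expect_equal(predict(f, x0), b + L / 2, tolerance = 1e-6)
  expect_equal(b + L / 2, 3.47, tolerance = 1e-12)
})

test_that("flat profiles are flagged degenerate", {
  xs <- seq(0, 10, length.out = 50)
  f <- fit_sigmoid(xs, rep(3.5, 50))
  expect_true(f$degenerate)
  expect_equal(f$b, 3.5)
  expect_equal(f$L, 0)
})

test_that("refitting from the fitted curve converges to the same optimum", {
  L <- -1.22; kap <- -19.14; x0 <- 1.11; b <- 4.08
  xs <- seq(x0 - 5, x0 + 5, length.out = 100)
  set.seed(3)
  f1 <- fit_sigmoid(xs, sigmoid_thickness(xs, L, kap, x0, b) +
                      rnorm(100, sd = 0.05), A_buffer = 10)
  f2 <- fit_sigmoid(xs, predict(f1, xs), A_buffer = 10)
  expect_equal(f2$L, f1$L, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
  expect_equal(f2$kappa, f1$kappa, tolerance = 1e-3)
})

test_that("amplitude, midpoint and baseline recover within 5% under noise", {
  # 0.05 nm gaussian noise at 100 buffer-zone positions, 50 seeds; the
  # steepness is only weakly identified at this sampling (transition width
  # ~4/|kappa| = 0.2 nm vs 0.1 nm point spacing) and is checked loosely
  L <- -1.22; kap <- -19.14; x0 <- 1.11; b <- 4.08
  xs <- seq(x0 - 5, x0 + 5, length.out = 100)
  res <- sapply(1:50, function(s) {
    set.seed(s)
    y <- sigmoid_thickness(xs, L, kap, x0, b) + rnorm(100, sd = 0.05)
    f <- fit_sigmoid(xs, y, A_buffer = 10)
    c(f$L, f$x0, f$b, f$kappa)
  })
  expect_lt(abs(median(res[1, ]) - L) / abs(L), 0.05)
  expect_lt(abs(median(res[2, ]) - x0) / abs(x0), 0.05)
  expect_lt(abs(median(res[3, ]) - b) / b, 0.05)
  expect_lt(abs(median(res[4, ]) - kap) / abs(kap), 0.5)
})

test_that("fit errors on too few points", {
  expect_error(fit_sigmoid(1:5, rnorm(5)), "at least 8")
})
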