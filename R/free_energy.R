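# Umbrella sampling of the probe COM along x, WHAM unbiasing, the
# defect-sensing force as the buffer-zone slope of F(x), unit conversions
# and the thickness reparameterization F(x) -> F(a).

#' Plan umbrella window centres
#'
#' Inclusive arithmetic ladder from `x_start` to `x_end`; the range must be
#' commensurate with the spacing.
#'
#' @param x_start,x_end Endpoints (nm).
#' @param spacing Window spacing (nm).
#' @return Numeric vector of window centres, `round(|x_start - x_end| /
#'   spacing) + 1` of them.
#' @export
plan_windows <- function(x_start, x_end, spacing) {
  if (!(spacing > 0)) stop("spacing must be positive", call. = FALSE)
  if (x_start == x_end) stop("x_start and x_end must differ", call. = FALSE)
  span <- abs(x_start - x_end)
  n_int <- round(span / spacing)
  if (abs(span - n_int * spacing) > 1e-9)
    stop("window range is not commensurate with the spacing", call. = FALSE)
  seq(x_start, x_end, length.out = n_int + 1)
}

#' Run one umbrella window
#'
#' Adds a harmonic restraint `-k_u (x_COM - center)` on the probe's
#' mass-weighted COM x (minimum image in x; y and z unrestrained),
#' equilibrates, then samples the COM series during production.
#'
#' @param sys A `membrane_system` containing a probe.
#' @param center Window centre (nm).
#' @param k_u Restraint constant (kJ mol^-1 nm^-2); default 1e3.
#' @param settings [run_settings()] for the production run.
#' @param equil_steps Equilibration steps discarded before sampling.
#' @param log_stride COM sampling stride (steps).
#' @return Object of class `umbrella_window`: `center`, `k_u`, `series`
#'   (COM x samples, nm), `time`, final `system`.
#' @export
run_window <- function(sys, center, k_u = 1e3, settings = run_settings(),
                       equil_steps = 0, log_stride = 20) {
  stopifnot(inherits(sys, "membrane_system"))
  if (!length(sys$probe_idx)) stop("system has no probe", call. = FALSE)
  restraint <- list(k_u = k_u, center = center)
  if (equil_steps > 0) {
    eq <- run_dynamics(sys, run_settings(dt = settings$dt, T = settings$T,
                                         friction = settings$friction,
                                         n_steps = equil_steps,
                                         neighbor_skin = settings$neighbor_skin,
                                         seed = settings$seed),
                       field = attr(sys, "field"), restraint = restraint,
                       frame_stride = 0, log_stride = 0)
    sys <- eq$system
    settings$seed <- settings$seed + 1L
  }
  tr <- run_dynamics(sys, settings, field = attr(sys, "field"),
                     restraint = restraint, frame_stride = 0,
                     log_stride = log_stride)
  series <- tr$log[, "com_x"]
  series <- series[-1]                     # drop the initial state
  kB <- thinmem_constants$kB
  sig <- sqrt(kB * settings$T / k_u)
  drift <- abs(wrap_delta(series - center, sys$box[1]))
  if (mean(drift > 3 * sig) > 0.5)
    warning(sprintf(
      "window at %.2f nm: COM far from the centre for most of the run (poor overlap)",
      center))
  structure(list(center = center, k_u = k_u, series = series,
                 time = tr$log[-1, "time"], system = tr$system),
            class = "umbrella_window")
}

wrap_delta <- function(d, L) {
  d <- d %% L
  ifelse(d > L / 2, d - L, d)
}

#' WHAM unbiasing of umbrella windows
#'
#' Standard self-consistent weighted-histogram estimator: window samples
#' are histogrammed on a common grid, the unbiased probability
#' `P(x_b) = sum_i n_i(x_b) / sum_i N_i f_i exp(-U_i(x_b)/kBT)` and the
#' window normalizers `f_i` are iterated to convergence, and
#' `F(x) = -kBT ln P(x)` is reported anchored at its minimum.
#'
#' @param windows List of `umbrella_window` objects (or lists with
#'   `center`, `k_u`, `series`).
#' @param grid Bin width (nm) or vector of bin breaks.
#' @param T Temperature (K).
#' @param tol Convergence tolerance on the window free energies (kJ/mol).
#' @param max_iter Maximum iterations.
#' @param periodic_L Optional box length: restraint deviations are then
#'   minimum-imaged.
#' @return Object of class `free_energy_profile`: data.frame-like list
#'   with `x`, `F` (kJ/mol, min 0), `support` (total counts per bin), plus
#'   `f_window`, `n_iter`, `T`.
#' @export
wham <- function(windows, grid = 0.05, T = 310, tol = 1e-7, max_iter = 50000,
                 periodic_L = NULL) {
  stopifnot(length(windows) >= 1)
  kB <- thinmem_constants$kB
  beta <- 1 / (kB * T)
  samples <- lapply(windows, function(w) w$series)
  centers <- vapply(windows, function(w) w$center, numeric(1))
  kus <- vapply(windows, function(w) w$k_u, numeric(1))
  allx <- unlist(samples, use.names = FALSE)
  if (length(grid) == 1) {
    h <- grid
    lo <- floor(min(allx) / h) * h
    hi <- ceiling(max(allx) / h) * h
    breaks <- seq(lo, hi + h / 2, by = h)
  } else breaks <- grid
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids)
  nw <- length(windows)
  counts <- vapply(samples, function(s)
    graphics::hist(s, breaks = breaks, plot = FALSE, right = FALSE)$counts,
    numeric(nb))
  counts <- matrix(counts, nrow = nb)
  Ni <- colSums(counts)
  # adjacent-window overlap diagnostic
  if (nw > 1) {
    ord <- order(centers)
    for (t in seq_len(nw - 1)) {
      a <- counts[, ord[t]] > 0; b <- counts[, ord[t + 1]] > 0
      if (sum(pmin(counts[a & b, ord[t]], counts[a & b, ord[t + 1]])) < 10)
        warning(sprintf("windows at %.2f and %.2f nm share fewer than 10 counts",
                        centers[ord[t]], centers[ord[t + 1]]))
    }
  }
  dev <- outer(mids, centers, "-")
  if (!is.null(periodic_L)) dev <- wrap_delta(dev, periodic_L)
  U <- 0.5 * sweep(dev^2, 2, kus, "*")     # nb x nw bias energies
  expB <- exp(-beta * U)
  f <- rep(0, nw)                          # window free energies -kBT ln f_i
  nsum <- rowSums(counts)
  for (it in seq_len(max_iter)) {
    denom <- as.vector(expB %*% (Ni * exp(beta * f)))
    P <- nsum / denom
    P[!is.finite(P)] <- 0
    fn <- -log(as.vector(t(expB) %*% P)) / beta
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tol) break
    if (it == max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                   max_iter, delta), call. = FALSE)
  }
  denom <- as.vector(expB %*% (Ni * exp(beta * f)))
  P <- nsum / denom
  P[!is.finite(P)] <- 0
  P <- P / sum(P)
  Fv <- ifelse(nsum > 0, -log(P) / beta, NA_real_)
  Fv <- Fv - min(Fv, na.rm = TRUE)
  structure(list(x = mids, F = Fv, support = nsum, f_window = f,
                 n_iter = it, T = T),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  rng <- range(x$F, na.rm = TRUE)
  cat(sprintf(
    "free_energy_profile: %d bins over [%.2f, %.2f] nm, dF range %.2f kJ/mol (%d WHAM iterations)\n",
    length(x$x), min(x$x), max(x$x), diff(rng), x$n_iter))
  invisible(x)
}

#' Defect-sensing force from the buffer-zone slope of F(x)
#'
#' Ordinary least-squares line through the buffer-zone grid points of the
#' free-energy profile, reported as distance from the thin-zone centre so
#' that a positive force means attraction toward the thin zone.
#'
#' @param profile A [wham()] result (or list with `x`, `F`).
#' @param geom A [zone_geometry()] classifying the grid points.
#' @return List with `force` (kJ mol^-1 nm^-1; positive = attraction
#'   toward the thin zone), `force_pN`, `se`, `n_points`.
#' @export
sensing_force <- function(profile, geom) {
  x <- profile$x; Fv <- profile$F
  ok <- is.finite(Fv) & zone_of(x, geom) == "buffer"
  if (sum(ok) < 5)
    stop("fewer than 5 buffer-zone grid points in the profile", call. = FALSE)
  # distance from the thin-zone centre: F rising with s = attraction
  s <- abs(wrap_delta(x[ok] - geom$x_c, geom$X_box))
  fit <- stats::lm(Fv[ok] ~ s)
  slope <- unname(stats::coef(fit)[2])
  r <- stats::residuals(fit)
  se <- sqrt(sum(r^2) / (length(s) - 2) / sum((s - mean(s))^2))
  list(force = slope, force_pN = convert_force(slope), se = se,
       n_points = sum(ok))
}

#' Convert a molar force to piconewtons
#'
#' `1 kJ mol^-1 nm^-1 = 1e3 / (N_A * 1e-21) pN = 1.660539 pN`.
#'
#' @param f Force (kJ mol^-1 nm^-1).
#' @return Force in pN.
#' @export
convert_force <- function(f) {
  f * 1e3 / (thinmem_constants$NA_avogadro * 1e-21)
}

#' Express an energy in units of kBT
#'
#' @param F Energy (kJ/mol).
#' @param T Temperature (K).
#' @return `F / (R T)`, dimensionless.
#' @export
to_kbt <- function(F, T) {
  if (!(T > 0)) stop("T must be positive", call. = FALSE)
  F / (thinmem_constants$kB * T)
}

#' Reparameterize F(x) as a function of membrane thickness
#'
#' Uses the closed-form inverse of the sigmoid thickness model to map the
#' position coordinate onto local thickness `a`.  In the default mode
#' `F(a) = F(x(a))`; with `jacobian_correction = TRUE` the density term
#' `-kBT ln |dx/da|` is added.
#'
#' @param profile A [wham()] result; its `x` must be in the same
#'   coordinate as the sigmoid fit (e.g. distance from the thin-zone
#'   centre for a symmetrized fit).
#' @param fit A [fit_sigmoid()] result, strictly monotone over the range.
#' @param T Temperature (K), used for the correction term.
#' @param jacobian_correction Add `-kBT ln |dx/da|`.
#' @param n_grid Number of thickness grid points.
#' @return Data.frame with columns `a` (nm), `x` (nm), `F` (kJ/mol).
#' @export
reparameterize_thickness <- function(profile, fit, T = 310,
                                     jacobian_correction = FALSE,
                                     n_grid = 100) {
  if (isTRUE(fit$degenerate) || !is.finite(fit$kappa) ||
      fit$L == 0 || fit$kappa == 0)
    stop("sigmoid fit is not strictly monotone; cannot reparameterize",
         call. = FALSE)
  ok <- is.finite(profile$F)
  xr <- range(profile$x[ok])
  a_at <- function(x) sigmoid_thickness(x, fit$L, fit$kappa, fit$x0, fit$b)
  a_lo <- min(a_at(xr)); a_hi <- max(a_at(xr))
  # clip strictly inside the asymptotes so the inverse stays finite
  eps <- 1e-6 * abs(fit$L)
  a_lo <- max(a_lo, min(fit$b, fit$b + fit$L) + eps)
  a_hi <- min(a_hi, max(fit$b, fit$b + fit$L) - eps)
  a_grid <- seq(a_lo, a_hi, length.out = n_grid)
  # closed-form sigmoid inverse
  x_of_a <- fit$x0 - log(fit$L / (a_grid - fit$b) - 1) / fit$kappa
  Fx <- stats::approx(profile$x[ok], profile$F[ok], xout = x_of_a,
                      rule = 2)$y
  if (jacobian_correction) {
    e <- exp(-fit$kappa * (x_of_a - fit$x0))
    dadx <- fit$L * fit$kappa * e / (1 + e)^2
    Fx <- Fx - thinmem_constants$kB * T * log(abs(1 / dadx))
    Fx <- Fx - min(Fx)
  }
  data.frame(a = a_grid, x = x_of_a, F = Fx)
}
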