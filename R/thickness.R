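# Membrane thickness profiling along x and the sigmoid description of the
# thin-to-normal transition across the buffer zone.

# normalize trajectory-like inputs to list(frames = <list of N x 3>, sys = ...)
as_frames <- function(x) {
  if (inherits(x, "cg_trajectory")) {
    fr <- x$frames
    if (!length(fr)) fr <- list(x$system$pos)
    list(frames = fr, sys = x$system)
  } else if (inherits(x, "membrane_system")) {
    list(frames = list(x$pos), sys = x)
  } else if (is.list(x) && !is.null(x$frames) && !is.null(x$system)) {
    list(frames = x$frames, sys = x$system)
  } else {
    stop("expected a cg_trajectory, membrane_system or list(frames, system)",
         call. = FALSE)
  }
}

#' Binned membrane thickness profile along x
#'
#' Thickness is the head-to-head distance between leaflet surfaces: per
#' x-bin and frame, the mean z of upper-leaflet head beads minus the mean z
#' of lower-leaflet head beads.  Bins with no heads in either leaflet in a
#' frame contribute nothing to that bin; bins empty in all frames are
#' flagged `NA`.
#'
#' @param traj A `cg_trajectory`, `membrane_system`, or
#'   `list(frames, system)`.
#' @param n_bins Number of x bins; default gives a bin width of
#'   `X_box / 110`.
#' @param geom Zone geometry; defaults to the system's.
#' @return Object of class `thickness_profile`: a data.frame with columns
#'   `bin_center`, `mean`, `sd`, `n` (frames contributing), with the
#'   geometry attached as an attribute.
#' @export
thickness_by_bin <- function(traj, n_bins = NULL, geom = NULL) {
  tf <- as_frames(traj)
  sys <- tf$sys
  if (is.null(geom)) geom <- sys$geom
  if (is.null(n_bins)) n_bins <- 110L
  n_bins <- as.integer(n_bins)
  Lx <- geom$X_box
  w <- Lx / n_bins
  heads <- which(sys$att == 1L & sys$is_lipid)
  up <- heads[sys$leaflet[heads] == 1L]
  lo <- heads[sys$leaflet[heads] == -1L]
  if (!length(up) || !length(lo))
    stop("lipids are not assigned to leaflets", call. = FALSE)

  nf <- length(tf$frames)
  acc <- matrix(NA_real_, nf, n_bins)
  for (f in seq_len(nf)) {
    p <- tf$frames[[f]]
    bu <- pmin(n_bins, floor((p[up, 1] %% Lx) / w) + 1L)
    bl <- pmin(n_bins, floor((p[lo, 1] %% Lx) / w) + 1L)
    zu <- vapply(seq_len(n_bins), function(b) {
      zz <- p[up[bu == b], 3]; if (length(zz)) mean(zz) else NA_real_
    }, numeric(1))
    zl <- vapply(seq_len(n_bins), function(b) {
      zz <- p[lo[bl == b], 3]; if (length(zz)) mean(zz) else NA_real_
    }, numeric(1))
    acc[f, ] <- zu - zl
  }
  m <- colMeans(acc, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  s <- apply(acc, 2, stats::sd, na.rm = TRUE)
  n <- colSums(!is.na(acc))
  out <- data.frame(bin_center = (seq_len(n_bins) - 0.5) * w,
                    mean = m, sd = s, n = n)
  structure(out, class = c("thickness_profile", "data.frame"),
            geom = geom, n_bins = n_bins)
}

#' Symmetrize a thickness profile about the thin-zone centre
#'
#' Folds the profile about `x_c`: `out(delta) = (profile(x_c + delta) +
#' profile(x_c - delta)) / 2`, with periodic wrapping.  Mirror-image bins
#' pair up exactly on the uniform grid.
#'
#' @param profile A [thickness_by_bin()] result.
#' @param geom Zone geometry; defaults to the profile's.
#' @return Data.frame with columns `delta` (distance from the thin-zone
#'   centre), `mean`, `sd`, `n`; `ceiling(n_bins / 2)` rows.
#' @export
symmetrize <- function(profile, geom = attr(profile, "geom")) {
  stopifnot(inherits(profile, "thickness_profile"))
  Lx <- geom$X_box
  d <- (profile$bin_center - geom$x_c) %% Lx
  d <- ifelse(d > Lx / 2, d - Lx, d)
  key <- round(abs(d), 9)
  grp <- split(seq_len(nrow(profile)), key)
  res <- lapply(names(grp), function(k) {
    i <- grp[[k]]
    mm <- profile$mean[i]; ss <- profile$sd[i]; nn <- profile$n[i]
    data.frame(delta = as.numeric(k),
               mean = if (all(is.na(mm))) NA_real_ else mean(mm, na.rm = TRUE),
               sd = sqrt(mean(ss^2, na.rm = TRUE)),
               n = sum(nn))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sigmoid thickness model
#'
#' `a(x) = L / (1 + exp(-kappa (x - x0))) + b`.
#'
#' @param x Position (nm).
#' @param L Amplitude (nm).
#' @param kappa Steepness (nm^-1).
#' @param x0 Midpoint (nm).
#' @param b Baseline (nm).
#' @return Thickness values (nm).
#' @export
sigmoid_thickness <- function(x, L, kappa, x0, b) {
  L / (1 + exp(-kappa * (x - x0))) + b
}

#' Least-squares sigmoid fit to a thickness profile
#'
#' Fits `a(x) = L / (1 + exp(-kappa (x - x0))) + b` by Levenberg-Marquardt
#' least squares with multiple starts: the baseline is initialized from the
#' profile ends, the amplitude from their difference, the midpoint from the
#' range centre, and the steepness from a ladder of magnitudes tried with
#' both signs (the fitted steepness sign depends on the orientation of the
#' x axis).
#'
#' @param x Positions (nm), e.g. buffer-zone bin centres.
#' @param y Thickness values (nm).
#' @param weights Optional fit weights.
#' @param A_buffer Length scale used to seed the steepness ladder; defaults
#'   to the x range.
#' @return Object of class `sigmoid_fit`: list with `L`, `kappa`, `x0`,
#'   `b`, `cov` (parameter covariance), `rms` residual, `degenerate` flag
#'   and the fitted model.
#' @export
fit_sigmoid <- function(x, y, weights = NULL, A_buffer = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(x) < 8)
    stop("need at least 8 points with defined thickness for the sigmoid fit",
         call. = FALSE)
  if (is.null(A_buffer)) A_buffer <- diff(range(x))

  # flat-profile degenerate limit: amplitude indistinguishable from zero
  if (stats::sd(y) < 1e-12) {
    return(structure(list(L = 0, kappa = NA_real_, x0 = NA_real_, b = mean(y),
                          cov = NULL, rms = 0, degenerate = TRUE,
                          n_points = length(x), fit = NULL),
                     class = "sigmoid_fit"))
  }

  o <- order(x)
  lo_end <- mean(y[o][seq_len(max(1, length(x) %/% 10))])
  hi_end <- mean(rev(y[o])[seq_len(max(1, length(x) %/% 10))])
  dat <- data.frame(x = x, y = y)
  kmag <- c(1, 4, 16, 64) / A_buffer
  best <- NULL
  for (ks in c(kmag, -kmag)) {
    # orient the amplitude so the start matches the data ends
    L0 <- if (ks > 0) hi_end - lo_end else lo_end - hi_end
    b0 <- if (ks > 0) lo_end else hi_end
    st <- list(L = L0, kappa = ks, x0 = mean(range(x)), b = b0)
    args <- list(formula = y ~ L / (1 + exp(-kappa * (x - x0))) + b,
                 data = dat, start = st,
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from any start", call. = FALSE)
  cf <- stats::coef(best$fit)
  cv <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  # the sigmoid has two equivalent parameterizations,
  # (L, kappa, x0, b) == (-L, -kappa, x0, b + L); canonicalize to kappa < 0
  if (is.finite(cf["kappa"]) && cf["kappa"] > 0) {
    J <- rbind(c(-1, 0, 0, 0), c(0, -1, 0, 0), c(0, 0, 1, 0), c(1, 0, 0, 1))
    cf <- c(L = unname(-cf["L"]), kappa = unname(-cf["kappa"]),
            x0 = unname(cf["x0"]), b = unname(cf["b"] + cf["L"]))
    if (!is.null(cv)) cv <- J %*% cv %*% t(J)
  }
  structure(list(L = unname(cf["L"]), kappa = unname(cf["kappa"]),
                 x0 = unname(cf["x0"]), b = unname(cf["b"]),
                 cov = cv, rms = sqrt(best$rss / length(x)),
                 degenerate = abs(cf["L"]) < 1e-8,
                 n_points = length(x), fit = best$fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("sigmoid_fit (degenerate/flat): b = %.4f nm\n", x$b))
  } else {
    cat(sprintf(
      "sigmoid_fit: L = %.4f nm, kappa = %.4f nm^-1, x0 = %.4f nm, b = %.4f nm (rms %.4g)\n",
      x$L, x$kappa, x$x0, x$b, x$rms))
  }
  invisible(x)
}

#' Predict thickness from a sigmoid fit
#' @param object A `sigmoid_fit`.
#' @param x Positions (nm).
#' @param ... Unused.
#' @return Thickness values (nm).
#' @export
predict.sigmoid_fit <- function(object, x, ...) {
  if (isTRUE(object$degenerate)) return(rep(object$b, length(x)))
  sigmoid_thickness(x, object$L, object$kappa, object$x0, object$b)
}

#' Fit the buffer-zone sigmoid of a symmetrized thickness profile
#'
#' Convenience wrapper: symmetrizes the profile about the thin-zone centre
#' and fits the sigmoid to the bins whose distance from the centre lies in
#' the buffer zone.
#'
#' @param profile A [thickness_by_bin()] result.
#' @param geom Zone geometry; defaults to the profile's.
#' @param pad Extra margin (nm) included on both sides of the buffer zone.
#' @return A `sigmoid_fit` (coordinates: distance from the thin-zone
#'   centre).
#' @export
fit_buffer_sigmoid <- function(profile, geom = attr(profile, "geom"), pad = 0) {
  half <- symmetrize(profile, geom)
  lo <- geom$A_thin / 2 - pad
  hi <- geom$A_thin / 2 + geom$A_buffer + pad
  sel <- half$delta >= lo & half$delta <= hi
  fit_sigmoid(half$delta[sel], half$mean[sel], A_buffer = geom$A_buffer)
}
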