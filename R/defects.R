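# Lipid packing defect detection and the exponential size constant.
#
# A leaflet surface is rasterized on an xy grid; each cell is scanned from
# the solvent side toward the bilayer midplane and scored by the first bead
# whose projected disc covers the cell centre: a tail bead (or no covering
# bead at all) marks the cell as defect, a head bead as covered.
# 4-connected defect cells are clustered into defects.

# coverage radius per bead: the WCA minimum distance over 2
coverage_radius <- function(sigma) 0.5 * 2^(1 / 6) * sigma

zone_x_range <- function(zone, geom) {
  if (is.numeric(zone) && length(zone) == 2) {
    return(list(x0 = zone[1], width = zone[2],
                wrap = abs(zone[2] - geom$X_box) < 1e-9))
  }
  half_thin <- geom$A_thin / 2
  switch(zone,
    thin = list(x0 = geom$x_c - half_thin, width = geom$A_thin, wrap = FALSE),
    normal = {
      w <- geom$X_box - geom$A_thin - 2 * geom$A_buffer
      list(x0 = (geom$x_c + half_thin + geom$A_buffer) %% geom$X_box,
           width = w, wrap = abs(w - geom$X_box) < 1e-12)
    },
    buffer_right = list(x0 = geom$x_c + half_thin, width = geom$A_buffer,
                        wrap = FALSE),
    buffer_left = list(x0 = geom$x_c - half_thin - geom$A_buffer,
                       width = geom$A_buffer, wrap = FALSE),
    stop("unknown zone: ", zone, call. = FALSE)
  )
}

#' Detect packing defects on one leaflet of one zone
#'
#' @param sys A `membrane_system` providing bead typing; coordinates are
#'   taken from `frame` if given, otherwise from the system.
#' @param frame Optional N x 3 coordinate matrix.
#' @param leaflet `"upper"` or `"lower"`.
#' @param zone `"thin"`, `"normal"`, `"buffer_left"`, `"buffer_right"` or a
#'   numeric `c(x0, width)` interval (nm; may extend across the periodic
#'   boundary).
#' @param grid_spacing Grid cell edge (nm); default 0.1 nm (1 Angstrom).
#' @param midplane Bilayer midplane z (nm); default: mean z of lipid beads.
#' @param include_probe Include probe beads as covering material.
#' @param return_mask Also return the defect mask (integer matrix).
#' @return List with `areas` (defect areas, Angstrom^2), `n_cells`,
#'   `n_defect_cells`, `cell_area` (Angstrom^2) and optionally `mask`.
#' @export
detect_defects <- function(sys, frame = NULL, leaflet = c("upper", "lower"),
                           zone = "thin", grid_spacing = 0.1, midplane = NULL,
                           include_probe = FALSE, return_mask = FALSE) {
  stopifnot(inherits(sys, "membrane_system"))
  leaflet <- match.arg(leaflet)
  pos <- if (is.null(frame)) sys$pos else frame
  zr <- zone_x_range(zone, sys$geom)
  if (zr$width < 3 * grid_spacing)
    stop("zone narrower than 3 grid cells", call. = FALSE)
  if (is.null(midplane)) midplane <- mean(pos[sys$is_lipid, 3])
  consider <- sys$is_lipid | (include_probe & !sys$is_lipid)
  cpp_detect_defects(pos, coverage_radius(sys$sigma), consider, sys$is_tail,
                     if (leaflet == "upper") 1L else -1L, midplane,
                     zr$x0, zr$width, sys$box[1], sys$box[2],
                     grid_spacing, zr$wrap, return_mask)
}

#' Defect areas over a trajectory
#'
#' Applies [detect_defects()] to every saved frame and both leaflets.
#'
#' @param traj A `cg_trajectory` (run with `frame_stride > 0`).
#' @param zone,grid_spacing See [detect_defects()].
#' @param leaflets Character vector of leaflets to pool per frame.
#' @return List of per-frame numeric vectors of defect areas (Angstrom^2).
#' @export
defect_areas <- function(traj, zone = "thin", grid_spacing = 0.1,
                         leaflets = c("upper", "lower")) {
  tf <- as_frames(traj)
  lapply(tf$frames, function(p) {
    unlist(lapply(leaflets, function(lf) {
      detect_defects(tf$sys, frame = p, leaflet = lf, zone = zone,
                     grid_spacing = grid_spacing)$areas
    }), use.names = FALSE)
  })
}

# exponential-tail fit: count-weighted linear fit of ln p(A) vs A,
# implemented as a Poisson log-linear regression on the histogram counts so
# that sparsely populated tail bins (including empty ones inside the fit
# range) enter with their correct weight instead of being silently dropped
fit_tail_once <- function(areas, A_min, p_min, bin_area) {
  br <- seq(0, max(areas) + bin_area, by = bin_area)
  h <- graphics::hist(areas, breaks = br, plot = FALSE)
  n <- sum(h$counts)
  p <- h$counts / n
  # fit window: A >= A_min up to the last bin resolved at probability p_min
  resolved <- p >= p_min
  if (!any(resolved & h$mids >= A_min))
    stop("fewer than 4 usable histogram points after the A >= ",
         A_min, ", p >= ", p_min, " thresholds", call. = FALSE)
  A_max <- max(h$mids[resolved])
  use <- h$mids >= A_min & h$mids <= A_max
  n_pts <- sum(use & h$counts > 0)
  if (n_pts < 4)
    stop("fewer than 4 usable histogram points after the A >= ",
         A_min, ", p >= ", p_min, " thresholds", call. = FALSE)
  A <- h$mids[use]
  if (stats::sd(A) < 1e-12) {
    return(list(constant = NA_real_, degenerate = TRUE, n_points = n_pts))
  }
  fit <- stats::glm(h$counts[use] ~ A, family = stats::poisson())
  slope <- unname(stats::coef(fit)[2])
  list(constant = -1 / slope, slope = slope, degenerate = slope >= 0,
       n_points = n_pts, fit_range = range(A))
}

#' Exponential defect size constant with block-averaged error
#'
#' The defect-area distribution decays as `p(A) ~ exp(-A / pi_d)`; the size
#' constant `pi_d` is the negative inverse slope of a count-weighted linear
#' fit of `ln p(A)` against `A`, restricted to `A >= A_min` and
#' `p(A) >= p_min`.  The pooled areas are split into `n_blocks` consecutive
#' blocks; the reported constant is the block mean, its error the block
#' standard error.
#'
#' @param areas Numeric vector of defect areas (Angstrom^2), or a list of
#'   per-frame vectors (blocks then group consecutive frames).
#' @param A_min Minimal area entering the fit (Angstrom^2).
#' @param p_min Minimal probability entering the fit.
#' @param n_blocks Number of blocks for the standard error.
#' @param bin_area Histogram bin width (Angstrom^2); one grid cell by
#'   default.
#' @param zone Optional zone label stored in the result.
#' @return Object of class `defect_stats`: `size_constant`,
#'   `size_constant_se`, `block_constants`, `n_defects`, `fit_range`,
#'   `degenerate`.
#' @export
fit_size_constant <- function(areas, A_min = 15, p_min = 1e-4, n_blocks = 10,
                              bin_area = 1, zone = NA_character_) {
  if (is.list(areas)) {
    frame_blocks <- cut(seq_along(areas), n_blocks, labels = FALSE)
    block_areas <- lapply(seq_len(n_blocks), function(b)
      unlist(areas[frame_blocks == b], use.names = FALSE))
    pooled <- unlist(areas, use.names = FALSE)
  } else {
    pooled <- areas
    blocks <- cut(seq_along(pooled), n_blocks, labels = FALSE)
    block_areas <- split(pooled, blocks)
  }
  if (length(pooled) < 100)
    stop("need at least 100 defect areas", call. = FALSE)
  if (stats::sd(pooled) < 1e-12) {
    return(structure(list(size_constant = NA_real_, size_constant_se = NA_real_,
                          block_constants = rep(NA_real_, n_blocks),
                          n_defects = length(pooled), fit_range = NULL,
                          degenerate = TRUE, zone = zone),
                     class = "defect_stats"))
  }
  pooled_fit <- fit_tail_once(pooled, A_min, p_min, bin_area)
  bc <- vapply(block_areas, function(a) {
    r <- tryCatch(fit_tail_once(a, A_min, p_min, bin_area),
                  error = function(e) list(constant = NA_real_))
    r$constant
  }, numeric(1))
  ok <- is.finite(bc)
  structure(list(size_constant = mean(bc[ok]),
                 size_constant_se = stats::sd(bc[ok]) / sqrt(sum(ok)),
                 block_constants = bc,
                 pooled_constant = pooled_fit$constant,
                 n_defects = length(pooled),
                 fit_range = pooled_fit$fit_range,
                 degenerate = isTRUE(pooled_fit$degenerate),
                 zone = zone),
            class = "defect_stats")
}

#' @export
print.defect_stats <- function(x, ...) {
  cat(sprintf(
    "defect_stats%s: size constant %.2f +/- %.2f A^2 (%d defects)%s\n",
    if (is.na(x$zone)) "" else paste0(" [", x$zone, "]"),
    x$size_constant, x$size_constant_se, x$n_defects,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}
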