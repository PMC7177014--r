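# Thinness-induced lipid sorting: composition histograms along x and
# zone-wise enrichment relative to the initial mole fraction.

#' Composition histogram along x
#'
#' Each lipid is located by its head-bead x coordinate (wrapped into the
#' box) and assigned to one of `n_bins` bins; counts are pooled over all
#' frames (frame-weighted averaging), then converted to per-bin mole
#' fractions.
#'
#' @param traj A `cg_trajectory`, `membrane_system` or `list(frames,
#'   system)`; or a list of several such objects (replicas), whose counts
#'   are pooled before normalization.
#' @param n_bins Number of x bins (default 50).
#' @param geom Zone geometry; defaults to the system's.
#' @return Object of class `composition_histogram`: data.frame with
#'   columns `bin`, `bin_center`, `species`, `count`, `fraction` (NA in
#'   empty bins), with `n_bins` and the geometry as attributes.
#' @export
composition_histogram <- function(traj, n_bins = 50, geom = NULL) {
  replicas <- if (is.list(traj) && !inherits(traj, c("cg_trajectory", "membrane_system")) &&
                  is.null(traj$frames)) traj else list(traj)
  n_bins <- as.integer(n_bins)
  counts <- NULL
  species_levels <- NULL
  for (rep in replicas) {
    tf <- as_frames(rep)
    sys <- tf$sys
    if (is.null(geom)) geom <- sys$geom
    Lx <- geom$X_box
    w <- Lx / n_bins
    heads <- which(sys$att == 1L & sys$is_lipid)
    sp <- sys$species_of_lipid[sys$lipid_id[heads]]
    if (is.null(species_levels)) species_levels <- sort(unique(sp))
    species_levels <- sort(union(species_levels, sp))
    spf <- factor(sp, levels = species_levels)
    for (p in tf$frames) {
      b <- pmin(n_bins, floor((p[heads, 1] %% Lx) / w) + 1L)
      tab <- table(factor(b, levels = seq_len(n_bins)), spf)
      m <- unclass(tab)
      if (is.null(counts)) counts <- m
      else if (!identical(dim(counts), dim(m))) {
        stop("replicas have inconsistent species sets", call. = FALSE)
      } else counts <- counts + m
    }
  }
  tot <- rowSums(counts)
  frac <- sweep(counts, 1, tot, "/")
  frac[tot == 0, ] <- NA_real_
  Lx <- geom$X_box
  out <- data.frame(
    bin = rep(seq_len(n_bins), times = ncol(counts)),
    bin_center = rep((seq_len(n_bins) - 0.5) * Lx / n_bins, times = ncol(counts)),
    species = rep(colnames(counts), each = n_bins),
    count = as.vector(counts),
    fraction = as.vector(frac),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("composition_histogram", "data.frame"),
            n_bins = n_bins, geom = geom)
}

# overlap length of bin [lo, hi) with a set of (possibly wrapped) zone
# intervals on the periodic x axis
interval_overlap <- function(lo, hi, ivs, Lx) {
  total <- 0
  for (iv in ivs) {
    a <- iv[1] %% Lx; b <- a + iv[2]
    segs <- if (b <= Lx) list(c(a, b)) else list(c(a, Lx), c(0, b - Lx))
    for (s in segs) total <- total + max(0, min(hi, s[2]) - max(lo, s[1]))
  }
  total
}

zone_intervals <- function(geom) {
  ht <- geom$A_thin / 2
  list(
    thin = list(c(geom$x_c - ht, geom$A_thin)),
    buffer = list(c(geom$x_c - ht - geom$A_buffer, geom$A_buffer),
                  c(geom$x_c + ht, geom$A_buffer)),
    normal = list(c(geom$x_c + ht + geom$A_buffer,
                    geom$X_box - geom$A_thin - 2 * geom$A_buffer))
  )
}

#' Zone-wise enrichment relative to the initial mole fraction
#'
#' For each species and zone, the count-weighted mean mole fraction over
#' the bins of that zone is divided by the species' initial fraction:
#' 1 means no sorting, below 1 depletion, above 1 enrichment.  Bins that
#' straddle a zone boundary are split by overlap length.
#'
#' @param histogram A [composition_histogram()].
#' @param geom Zone geometry; defaults to the histogram's.
#' @param initial_fraction Named vector of initial mole fractions (or a
#'   single value recycled over species).
#' @return Data.frame with columns `species`, `zone`, `fraction`,
#'   `enrichment`.
#' @export
zone_enrichment <- function(histogram, geom = attr(histogram, "geom"),
                            initial_fraction) {
  stopifnot(inherits(histogram, "composition_histogram"))
  if (any(initial_fraction == 0))
    stop("initial_fraction must be non-zero", call. = FALSE)
  n_bins <- attr(histogram, "n_bins")
  Lx <- geom$X_box
  w <- Lx / n_bins
  ivs <- zone_intervals(geom)
  species <- unique(histogram$species)
  f0 <- if (length(initial_fraction) == 1)
    stats::setNames(rep(initial_fraction, length(species)), species)
  else initial_fraction
  missing_f0 <- setdiff(species, names(f0))
  if (length(missing_f0))
    stop("initial_fraction missing for: ", paste(missing_f0, collapse = ", "),
         call. = FALSE)

  res <- list()
  for (zn in names(ivs)) {
    ov <- vapply(seq_len(n_bins), function(b)
      interval_overlap((b - 1) * w, b * w, ivs[[zn]], Lx), numeric(1))
    for (sp in species) {
      hs <- histogram[histogram$species == sp, ]
      hs <- hs[order(hs$bin), ]
      tots <- vapply(seq_len(n_bins), function(b)
        sum(histogram$count[histogram$bin == b]), numeric(1))
      num <- sum(ov * hs$count)
      den <- sum(ov * tots)
      frac <- if (den > 0) num / den else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        species = sp, zone = zn, fraction = frac,
        enrichment = frac / f0[[sp]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
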