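# Seeded synthetic fixtures with embedded ground truth: every analysis
# operation can be tested as parameter recovery without running dynamics.

# minimal system carrying only the bead metadata the analysis code reads
pseudo_system <- function(pos, att, leaflet, is_tail, lipid_id, species,
                          geom, box) {
  structure(list(
    pos = pos, vel = matrix(0, nrow(pos), 3),
    sigma = rep(.model$sigma_head, nrow(pos)),
    att = att, eps = rep(0, nrow(pos)),
    is_tail = is_tail, is_lipid = rep(TRUE, nrow(pos)),
    lipid_id = lipid_id, leaflet = leaflet,
    species_of_lipid = species,
    bonds = matrix(0, 0, 4), angles = matrix(0, 0, 4),
    box = box, geom = geom, composition = NULL,
    probe_idx = integer(0), head_height = max(abs(pos[, 3] - box[3] / 2))
  ), class = "membrane_system")
}

# heads-only leaflet pair on a dense lattice; thickness_fn(x) gives the
# head-to-head distance at box coordinate x
head_sheet_system <- function(geom, box_y, thickness_fn, spacing = 0.25,
                              box_z = 12, noise_sd = 0, n_frames = 1) {
  Lx <- geom$X_box
  nx <- max(3L, round(Lx / spacing)); ny <- max(3L, round(box_y / spacing))
  gx <- (seq_len(nx) - 0.5) * Lx / nx
  gy <- (seq_len(ny) - 0.5) * box_y / ny
  g <- expand.grid(x = gx, y = gy)
  n <- nrow(g)
  h <- thickness_fn(g$x)
  pos <- rbind(cbind(g$x, g$y, box_z / 2 + h / 2),
               cbind(g$x, g$y, box_z / 2 - h / 2))
  sys <- pseudo_system(pos,
                       att = rep(1L, 2 * n),
                       leaflet = rep(c(1L, -1L), each = n),
                       is_tail = rep(FALSE, 2 * n),
                       lipid_id = seq_len(2 * n),
                       species = rep("POPC", 2 * n),
                       geom = geom, box = c(Lx, box_y, box_z))
  frames <- lapply(seq_len(n_frames), function(f) {
    p <- sys$pos
    if (noise_sd > 0) p[, 3] <- p[, 3] + stats::rnorm(nrow(p), sd = noise_sd)
    p
  })
  list(system = sys, frames = frames)
}

#' Generate a synthetic fixture with known ground truth
#'
#' @param kind One of `"flat_membrane"`, `"sigmoid_membrane"`,
#'   `"defect_lattice"`, `"sorted_mix"`, `"umbrella_harmonic"`.
#' @param params Named list of generator parameters (see Details).
#' @param seed Integer seed.
#' @param path Optional directory; if given, coordinate/series files and a
#'   `truth.json` sidecar are written there.
#'
#' @details
#' * `flat_membrane`: heads of both leaflets on a lattice at constant
#'   separation. Params: `geom`, `thickness` (nm), `box_y`, `noise_sd`,
#'   `n_frames`. Truth: the thickness.
#' * `sigmoid_membrane`: head-to-head distance follows the sigmoid
#'   `a(s) = L/(1+exp(-kappa (s - x0))) + b` of the distance `s` from the
#'   thin-zone centre. Params: `geom`, `L`, `kappa`, `x0`, `b`, `box_y`,
#'   `noise_sd`, `n_frames`. Truth: the four parameters.
#' * `defect_lattice`: a dense head lattice with tail beads underneath;
#'   listed lattice sites are stripped of their head, exposing the tail.
#'   Params: `geom`, `box_y`, `spacing`, `holes` (vector of site indices
#'   or count). Truth: hole sites and count.
#' * `sorted_mix`: one frame of head positions with species labels drawn
#'   per zone. Params: `geom`, `n`, `fraction` (minority fraction),
#'   `mode` (`"uniform"` or `"thin_only"`), `box_y`. Truth: per-zone
#'   composition.
#' * `umbrella_harmonic`: umbrella windows sampled exactly from the
#'   Boltzmann distribution of a harmonic landscape `0.5 c (x - x0)^2`
#'   under each window bias. Params: `c`, `x0`, `centers`, `k_u`,
#'   `n_samples`, `T`. Truth: `c`, `x0` and the landscape function.
#' @return List with fixture objects and a `truth` element.
#' @export
make_fixture <- function(kind, params = list(), seed = 1, path = NULL) {
  out <- switch(kind,
    flat_membrane = with_seed(seed, {
      p <- utils::modifyList(list(geom = zone_geometry(12, 3, 2.5),
                                  thickness = 4, box_y = 6, noise_sd = 0,
                                  n_frames = 1), params)
      fx <- head_sheet_system(p$geom, p$box_y, function(x) rep(p$thickness,
                                                               length(x)),
                              noise_sd = p$noise_sd, n_frames = p$n_frames)
      fx$truth <- list(thickness = p$thickness)
      fx
    }),
    sigmoid_membrane = with_seed(seed, {
      p <- utils::modifyList(list(geom = zone_geometry(55, 10, 10),
                                  L = -1.22, kappa = -19.14, x0 = 1.11,
                                  b = 4.08, box_y = 10, noise_sd = 0,
                                  n_frames = 1, shift = NULL), params)
      # place the sigmoid midpoint mid-buffer: s = distance from the thin
      # zone centre, u = s shifted so the transition sits at the fitted x0
      shift <- if (is.null(p$shift))
        (p$geom$A_thin / 2 + p$geom$A_buffer / 2) - p$x0 else p$shift
      thick_fn <- function(x) {
        s <- abs(wrap_delta(x - p$geom$x_c, p$geom$X_box))
        sigmoid_thickness(s - shift, p$L, p$kappa, p$x0, p$b)
      }
      fx <- head_sheet_system(p$geom, p$box_y, thick_fn,
                              noise_sd = p$noise_sd, n_frames = p$n_frames)
      fx$truth <- list(L = p$L, kappa = p$kappa, x0 = p$x0, b = p$b,
                       shift = shift)
      fx
    }),
    defect_lattice = with_seed(seed, {
      # spacing/coverage chosen so a single missing head uncovers one
      # connected patch: heads cover r = 0.505 nm on a 0.6 nm lattice
      p <- utils::modifyList(list(geom = zone_geometry(12, 3, 2.5),
                                  box_y = 6, spacing = 0.6, holes = 1,
                                  box_z = 12, head_sigma = 0.9), params)
      Lx <- p$geom$X_box
      nx <- round(Lx / p$spacing); ny <- round(p$box_y / p$spacing)
      g <- expand.grid(x = (seq_len(nx) - 0.5) * Lx / nx,
                       y = (seq_len(ny) - 0.5) * p$box_y / ny)
      n <- nrow(g)
      holes <- if (length(p$holes) == 1 && p$holes < n / 2 &&
                   p$holes == round(p$holes) && length(params$holes) <= 1 &&
                   is.null(params$hole_sites))
        sample(n, p$holes) else p$holes
      if (!is.null(params$hole_sites)) holes <- params$hole_sites
      keep <- setdiff(seq_len(n), holes)
      z0 <- p$box_z / 2
      # upper leaflet: heads on kept sites, tails under every site
      pos <- rbind(cbind(g$x[keep], g$y[keep], z0 + 2.0),
                   cbind(g$x, g$y, z0 + 1.4),
                   cbind(g$x, g$y, z0 - 1.4),
                   cbind(g$x, g$y, z0 - 2.0))
      nk <- length(keep)
      att <- c(rep(1L, nk), rep(2L, n), rep(2L, n), rep(1L, n))
      is_tail <- att == 2L
      leaflet <- c(rep(1L, nk + n), rep(-1L, 2 * n))
      sys <- pseudo_system(pos, att, leaflet, is_tail,
                           lipid_id = seq_along(att),
                           species = rep("POPC", length(att)),
                           geom = p$geom, box = c(Lx, p$box_y, p$box_z))
      sys$sigma <- rep(p$head_sigma, length(att))
      list(system = sys, frames = list(sys$pos),
           truth = list(hole_sites = holes, n_holes = length(holes),
                        site_xy = g, spacing = p$spacing))
    }),
    sorted_mix = with_seed(seed, {
      p <- utils::modifyList(list(geom = zone_geometry(12, 3, 2.5), n = 500,
                                  fraction = 0.3, mode = "uniform",
                                  box_y = 6, minority = "LPC",
                                  majority = "POPC"), params)
      Lx <- p$geom$X_box
      x <- stats::runif(p$n, 0, Lx); y <- stats::runif(p$n, 0, p$box_y)
      species <- rep(p$majority, p$n)
      if (p$mode == "uniform") {
        species[stats::runif(p$n) < p$fraction] <- p$minority
      } else if (p$mode == "thin_only") {
        zl <- zone_of(x, p$geom)
        thin_idx <- which(zl == "thin")
        species[sample(thin_idx, round(p$fraction * length(thin_idx)))] <-
          p$minority
      } else stop("unknown sorted_mix mode: ", p$mode, call. = FALSE)
      pos <- cbind(x, y, 6 + 2)
      sys <- pseudo_system(pos, att = rep(1L, p$n),
                           leaflet = rep(1L, p$n),
                           is_tail = rep(FALSE, p$n),
                           lipid_id = seq_len(p$n), species = species,
                           geom = p$geom, box = c(Lx, p$box_y, 12))
      zl <- zone_of(x, p$geom)
      truth_frac <- vapply(c(thin = "thin", buffer = "buffer",
                             normal = "normal"), function(z)
        mean(species[zl == z] == p$minority), numeric(1))
      list(system = sys, frames = list(pos),
           truth = list(zone_fraction = truth_frac, minority = p$minority,
                        overall = mean(species == p$minority)))
    }),
    umbrella_harmonic = with_seed(seed, {
      p <- utils::modifyList(list(c = 5, x0 = 5, centers = seq(2, 8, 0.5),
                                  k_u = 100, n_samples = 2000, T = 310),
                             params)
      kB <- thinmem_constants$kB
      windows <- lapply(p$centers, function(ci) {
        prec <- p$c + p$k_u
        mu <- (p$c * p$x0 + p$k_u * ci) / prec
        sd <- sqrt(kB * p$T / prec)
        structure(list(center = ci, k_u = p$k_u,
                       series = stats::rnorm(p$n_samples, mu, sd)),
                  class = "umbrella_window")
      })
      list(windows = windows,
           truth = list(c = p$c, x0 = p$x0, T = p$T,
                        landscape = function(x) 0.5 * p$c * (x - p$x0)^2))
    }),
    stop("unregistered fixture kind: ", kind, call. = FALSE)
  )
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    truth <- out$truth
    truth$landscape <- NULL
    truth$site_xy <- NULL
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(out$frames))
      write_xyz(out$frames, file.path(path, "frames.xyz"))
    if (!is.null(out$windows)) {
      for (i in seq_along(out$windows)) {
        w <- out$windows[[i]]
        write_tsv(data.frame(sample = seq_along(w$series), x_com = w$series),
                  file.path(path, sprintf("window_%03d.tsv", i)))
      }
      write_tsv(data.frame(window = seq_along(out$windows),
                           center = vapply(out$windows, `[[`, numeric(1),
                                           "center"),
                           k_u = vapply(out$windows, `[[`, numeric(1), "k_u")),
                file.path(path, "windows.tsv"))
    }
  }
  out
}
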