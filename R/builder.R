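# Membrane and probe construction: seeded lattice bilayers of mixed
# composition and the rigid two-row amphipathic probe.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# integer species counts from fractions by largest remainder
species_counts <- function(composition, n) {
  frac <- composition / sum(composition)
  raw <- frac * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

# near-square lattice of exactly n sites on an Lx x Ly patch (rows may
# differ by one site so the target count is met without holes)
leaflet_lattice <- function(n, Lx, Ly) {
  n_rows <- max(1L, round(sqrt(n * Ly / Lx)))
  base <- n %/% n_rows
  extra <- n - base * n_rows
  sites_per_row <- rep(base, n_rows)
  if (extra > 0) sites_per_row[seq_len(extra)] <- base + 1L
  xy <- matrix(0, n, 2)
  t <- 1L
  for (j in seq_len(n_rows)) {
    m <- sites_per_row[j]
    shift <- 0.5 * (j %% 2)                    # stagger alternate rows
    xs <- ((seq_len(m) - 0.5 + shift) %% m) * (Lx / m)
    ys <- rep((j - 0.5) * Ly / n_rows, m)
    xy[t:(t + m - 1L), ] <- cbind(sort(xs), ys)
    t <- t + m
  }
  xy
}

#' Build a mixed-composition bilayer on a lattice
#'
#' Places `floor(leaflet_area / area_per_lipid)` lipids per leaflet on a
#' near-square staggered lattice, assigns species to lattice sites by a
#' seeded random permutation (counts match the requested mole fractions to
#' within one lipid per leaflet), and draws Maxwell-Boltzmann initial
#' velocities.  Deterministic for a fixed seed.
#'
#' @param geom A [zone_geometry()]; its `X_box` is the box length in x.
#' @param composition Named numeric vector of mole fractions (names must be
#'   registered in `species_table`); normalized to sum to 1.
#' @param area_per_lipid Area per lipid (nm^2).
#' @param box_y,box_z Box dimensions in y and z (nm).
#' @param species_table Species definitions, see [default_species()].
#' @param T Temperature for initial velocities (K).
#' @param seed Integer seed.
#' @return An object of class `membrane_system`.
#' @export
build_bilayer <- function(geom, composition = c(POPC = 1), area_per_lipid = 0.475,
                          box_y = 10, box_z = 12, species_table = default_species(),
                          T = 310, seed = 1) {
  stopifnot(inherits(geom, "zone_geometry"))
  if (!(area_per_lipid > 0)) stop("area_per_lipid must be positive", call. = FALSE)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector", call. = FALSE)
  unknown <- setdiff(names(composition), species_table$name)
  if (length(unknown) > 0)
    stop("unregistered species: ", paste(unknown, collapse = ", "), call. = FALSE)
  composition <- composition / sum(composition)

  Lx <- geom$X_box; Ly <- box_y
  n_lip <- floor(Lx * Ly / area_per_lipid)
  if (n_lip < 100)
    stop("box too small: fewer than 100 lipids per leaflet at the requested ",
         "area per lipid", call. = FALSE)

  m <- .model
  sp <- species_table[match(names(composition), species_table$name), ]
  counts <- species_counts(composition, n_lip)

  # chain extent below the head determines the leaflet head height
  off <- ifelse(sp$n_chains == 2, 0.18, 0)
  dz1 <- sqrt(m$bond_r0^2 - off^2)
  extent <- dz1 + (sp$n_tail_beads - 1) * m$bond_r0
  h0 <- max(extent) + 0.30           # head plane height above midplane (nm)

  xy <- leaflet_lattice(n_lip, Lx, Ly)
  n_total_lipids <- 2L * n_lip

  build <- with_seed(seed, {
    pos <- list(); lip_species <- character(0)
    lipid_id <- integer(0); leaflet <- integer(0); is_tail <- logical(0)
    att <- integer(0); eps <- numeric(0); sigma <- numeric(0)
    bonds <- list(); angles <- list()
    next_bead <- 0L; lip <- 0L

    for (side in c(1L, -1L)) {
      species_idx <- sample(rep.int(seq_along(counts), counts))
      for (s in seq_len(n_lip)) {
        lip <- lip + 1L
        k <- species_idx[s]
        xh <- xy[s, 1] + if (side == -1L) 0.5 * sqrt(area_per_lipid) else 0
        yh <- xy[s, 2]
        yh_wrap <- function(y) y %% Ly
        zh <- side * h0
        nb_chain <- sp$n_tail_beads[k]; nch <- sp$n_chains[k]
        beads <- list(c(xh %% Lx, yh, zh))   # head first
        b_att <- 1L; b_eps <- sp$head_epsilon[k]; b_sig <- m$sigma_head
        b_tail <- FALSE
        head_id <- next_bead + 1L
        for (ch in seq_len(nch)) {
          yo <- if (nch == 2) c(-off[k], off[k])[ch] else 0
          prev <- head_id
          for (tb in seq_len(nb_chain)) {
            zo <- if (tb == 1) dz1[k] else dz1[k] + (tb - 1) * m$bond_r0
            beads[[length(beads) + 1L]] <- c(xh %% Lx, yh_wrap(yh + yo), zh - side * zo)
            b_att <- c(b_att, 2L); b_eps <- c(b_eps, sp$tail_epsilon[k])
            b_sig <- c(b_sig, m$sigma_tail); b_tail <- c(b_tail, TRUE)
            this <- next_bead + length(beads)
            bonds[[length(bonds) + 1L]] <- c(prev, this, m$bond_k, m$bond_r0)
            prev <- this
          }
          # straightening angles along head-T1-T2-... of this chain
          chain_ids <- c(head_id, next_bead + 1L + (ch - 1L) * nb_chain + seq_len(nb_chain))
          if (length(chain_ids) >= 3 && sp$bend_k[k] > 0) {
            for (a in seq_len(length(chain_ids) - 2L)) {
              angles[[length(angles) + 1L]] <-
                c(chain_ids[a], chain_ids[a + 1L], chain_ids[a + 2L], sp$bend_k[k])
            }
          }
        }
        nb <- length(beads)
        pos[[length(pos) + 1L]] <- do.call(rbind, beads)
        lip_species <- c(lip_species, sp$name[k])
        lipid_id <- c(lipid_id, rep(lip, nb))
        leaflet <- c(leaflet, rep(side, nb))
        is_tail <- c(is_tail, b_tail)
        att <- c(att, b_att); eps <- c(eps, b_eps); sigma <- c(sigma, b_sig)
        next_bead <- next_bead + nb
      }
    }
    pos <- do.call(rbind, pos)
    n <- nrow(pos)
    vel <- matrix(rnorm(3 * n, sd = sqrt(thinmem_constants$kB * T / m$mass)), n, 3)
    list(pos = pos, vel = vel, att = att, eps = eps, sigma = sigma,
         is_tail = is_tail, lipid_id = lipid_id, leaflet = leaflet,
         species = lip_species,
         bonds = do.call(rbind, bonds),
         angles = if (length(angles)) do.call(rbind, angles) else
           matrix(0, 0, 4))
  })

  sys <- structure(list(
    pos = build$pos, vel = build$vel,
    sigma = build$sigma, att = build$att, eps = build$eps,
    is_tail = build$is_tail, is_lipid = rep(TRUE, nrow(build$pos)),
    lipid_id = build$lipid_id, leaflet = build$leaflet,
    species_of_lipid = build$species,
    bonds = build$bonds, angles = build$angles,
    box = c(Lx, Ly, box_z), geom = geom,
    composition = composition, area_per_lipid = area_per_lipid,
    probe_idx = integer(0), T_build = T, seed = seed,
    head_height = h0
  ), class = "membrane_system")
  # positions live with z centered on 0 at build; shift midplane to box mid
  sys$pos[, 3] <- sys$pos[, 3] + box_z / 2
  check_min_distance(sys)
  minimize_energy(sys)
}

#' Relax a system by steepest-descent energy minimization
#'
#' Displacement-capped steepest descent under the internal force field
#' (field and restraints off); removes build strain before dynamics.
#'
#' @param sys A `membrane_system`.
#' @param max_steps Iteration cap.
#' @param fmax_tol Convergence threshold on the largest bead force
#'   (kJ mol^-1 nm^-1).
#' @param max_disp Displacement cap per iteration (nm).
#' @return The relaxed system.
#' @export
minimize_energy <- function(sys, max_steps = 200, fmax_tol = 100,
                            max_disp = 0.02) {
  res <- cpp_minimize(sys$pos, sys$sigma, sys$att, sys$eps, sys$is_tail,
                      sys$is_lipid, mol_ids(sys), bonds_ij(sys),
                      sys$bonds[, 3], sys$bonds[, 4],
                      angles_ijk(sys), angle_kvec(sys), sys$box,
                      .model$eps_rep, .model$wc, 0.3,
                      as.integer(max_steps), fmax_tol, max_disp)
  sys$pos <- res$pos
  sys
}

# build-time sanity: no bead pair closer than 0.3 nm
check_min_distance <- function(sys, min_d = 0.3) {
  d <- cpp_min_distance(sys$pos, sys$box)
  if (d < min_d)
    stop(sprintf("build produced a bead pair at %.3f nm (< %.2f nm)", d, min_d),
         call. = FALSE)
  invisible(d)
}

# molecule ids for intramolecular exclusion: lipids keep their lipid_id,
# probe beads form one extra molecule
mol_ids <- function(sys) {
  m <- as.integer(sys$lipid_id)
  if (length(sys$probe_idx))
    m[sys$probe_idx] <- max(m) + 1L
  m
}

# 0-based bonded index helpers for the C++ core
bonds_ij <- function(sys) {
  if (nrow(sys$bonds) == 0) return(matrix(0L, 0, 2))
  matrix(as.integer(sys$bonds[, 1:2] - 1L), ncol = 2)
}
angles_ijk <- function(sys) {
  if (nrow(sys$angles) == 0) return(matrix(0L, 0, 3))
  matrix(as.integer(sys$angles[, 1:3] - 1L), ncol = 3)
}
angle_kvec <- function(sys) {
  if (nrow(sys$angles) == 0) return(numeric(0)) else sys$angles[, 4]
}

#' @export
print.membrane_system <- function(x, ...) {
  cat(sprintf("membrane_system: %d beads, %d lipids (%s), box %g x %g x %g nm\n",
              nrow(x$pos), length(x$species_of_lipid),
              paste(sprintf("%s %.0f%%", names(x$composition),
                            100 * x$composition), collapse = ", "),
              x$box[1], x$box[2], x$box[3]))
  if (length(x$probe_idx)) cat(sprintf("  + amphipathic probe (%d beads)\n",
                                       length(x$probe_idx)))
  invisible(x)
}

#' Build the rigid amphipathic probe
#'
#' Two parallel rows of beads: a hydrophobic row that attracts lipid tail
#' beads (the defect-binding face) and a purely repulsive polar row.  The
#' probe is held near-rigid by stiff bonds along rows, across rungs, along
#' both diagonals and between second neighbours.  Its centre of mass is
#' placed at the thin-zone centre `x_c`.
#'
#' @param geom A [zone_geometry()].
#' @param n_beads_per_row Number of beads per row (>= 3).
#' @param spacing Bead spacing along the row (nm).
#' @param hydrophobic_eps Attraction scale of the hydrophobic row (kJ/mol).
#' @param seed Integer seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return An object of class `amphipathic_probe`.
#' @export
build_probe <- function(geom, n_beads_per_row = 8, spacing = 0.5,
                        hydrophobic_eps = 4.5, seed = 1) {
  stopifnot(inherits(geom, "zone_geometry"))
  if (n_beads_per_row < 3) stop("n_beads_per_row must be >= 3", call. = FALSE)
  n <- as.integer(n_beads_per_row)
  ys <- (seq_len(n) - (n + 1) / 2) * spacing
  # row 1: hydrophobic (faces bilayer interior, z = 0); row 2: polar (z = +spacing)
  pos <- rbind(cbind(geom$x_c, ys, 0), cbind(geom$x_c, ys, spacing))
  pattern <- c(rep("hydrophobic", n), rep("polar", n))
  kb <- 8000
  bonds <- list()
  for (r in c(0L, n)) for (i in seq_len(n - 1L))
    bonds[[length(bonds) + 1L]] <- c(r + i, r + i + 1L, kb, spacing)       # rows
  for (i in seq_len(n))
    bonds[[length(bonds) + 1L]] <- c(i, n + i, kb, spacing)                # rungs
  for (i in seq_len(n - 1L)) {
    d <- sqrt(2) * spacing
    bonds[[length(bonds) + 1L]] <- c(i, n + i + 1L, kb, d)                 # diagonals
    bonds[[length(bonds) + 1L]] <- c(i + 1L, n + i, kb, d)
  }
  for (r in c(0L, n)) for (i in seq_len(max(0L, n - 2L)))
    bonds[[length(bonds) + 1L]] <- c(r + i, r + i + 2L, kb, 2 * spacing)   # 1-3
  structure(list(
    pos = pos, pattern = pattern, bonds = do.call(rbind, bonds),
    spacing = spacing, hydrophobic_eps = hydrophobic_eps, n_per_row = n,
    seed = seed
  ), class = "amphipathic_probe")
}

#' Insert a probe into a membrane system
#'
#' The probe is positioned above the upper leaflet of the membrane (polar
#' row toward the solvent, hydrophobic row toward the bilayer), centred in
#' y, at the probe's built x position.
#'
#' @param sys A `membrane_system`.
#' @param probe An [build_probe()] object.
#' @param clearance Gap between the upper head plane and the hydrophobic
#'   row (nm).
#' @return The combined `membrane_system`.
#' @export
add_probe <- function(sys, probe, clearance = 0.25) {
  stopifnot(inherits(sys, "membrane_system"), inherits(probe, "amphipathic_probe"))
  if (length(sys$probe_idx)) stop("system already contains a probe", call. = FALSE)
  n0 <- nrow(sys$pos)
  np <- nrow(probe$pos)
  # place above the instantaneous upper head plane, not the build-time one
  up_heads <- sys$att == 1L & sys$leaflet == 1L
  z_surface <- if (any(up_heads)) max(sys$pos[up_heads, 3])
               else sys$box[3] / 2 + sys$head_height
  ppos <- probe$pos
  ppos[, 2] <- ppos[, 2] + sys$box[2] / 2
  ppos[, 3] <- ppos[, 3] + z_surface + clearance
  m <- .model
  sys$pos <- rbind(sys$pos, ppos)
  sys$vel <- rbind(sys$vel, matrix(0, np, 3))
  sys$sigma <- c(sys$sigma, rep(m$sigma_tail, np))
  sys$att <- c(sys$att, ifelse(probe$pattern == "hydrophobic", 3L, 0L))
  sys$eps <- c(sys$eps, ifelse(probe$pattern == "hydrophobic",
                               probe$hydrophobic_eps, 0))
  sys$is_tail <- c(sys$is_tail, rep(FALSE, np))
  sys$is_lipid <- c(sys$is_lipid, rep(FALSE, np))
  sys$lipid_id <- c(sys$lipid_id, rep(0L, np))
  sys$leaflet <- c(sys$leaflet, rep(0L, np))
  pb <- probe$bonds
  pb[, 1:2] <- pb[, 1:2] + n0
  sys$bonds <- rbind(sys$bonds, pb)
  sys$probe_idx <- n0 + seq_len(np)
  sys$probe <- probe
  minimize_energy(sys, max_steps = 100)
}
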