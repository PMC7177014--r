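# shared geometry and cached expensive simulations
ref_geom <- function() zone_geometry(55, 10, 10)
small_geom <- function() zone_geometry(12, 3, 2.5)

# cache: expensive trajectories shared between test files (helpers are
# sourced once per test_dir session)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

# a system containing only the amphipathic probe: flat free-energy
# landscape for restraint statistics
probe_only_system <- function(geom = small_geom(), n = 6, box_y = 6) {
  pr <- build_probe(geom, n)
  np <- nrow(pr$pos)
  structure(list(
    pos = cbind(pr$pos[, 1], pr$pos[, 2] + box_y / 2, pr$pos[, 3] + 6),
    vel = matrix(0, np, 3),
    sigma = rep(0.65, np),
    att = ifelse(pr$pattern == "hydrophobic", 3L, 0L),
    eps = ifelse(pr$pattern == "hydrophobic", pr$hydrophobic_eps, 0),
    is_tail = rep(FALSE, np), is_lipid = rep(FALSE, np),
    lipid_id = rep(0L, np), leaflet = rep(0L, np),
    species_of_lipid = character(0),
    bonds = pr$bonds, angles = matrix(0, 0, 4),
    box = c(geom$X_box, box_y, 12), geom = geom,
    probe_idx = seq_len(np), head_height = 1.5, probe = pr
  ), class = "membrane_system")
}
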