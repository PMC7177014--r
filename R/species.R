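# Surrogate lipid species for the implicit-solvent bead model.
#
# Every lipid is one head bead plus one or two tail chains of n_tail_beads
# beads each.  Interactions: soft-core (WCA) repulsion between all beads,
# a smoothly truncated cosine^2 attraction between tail beads (strength
# tail_epsilon), the same form between head beads (head_epsilon, zero for
# the baseline), harmonic bonds along chains, and a cosine angle stiffness
# (bend_k) that straightens each chain.

# model-wide geometry and energy scales (MD units)
.model <- list(
  sigma_tail = 0.65,    # nm, tail bead WCA diameter
  sigma_head = 0.72,    # nm, head bead diameter (slightly larger: shields tails)
  bond_r0    = 0.65,    # nm, chain bond rest length
  bond_k     = 2500,    # kJ mol^-1 nm^-2
  eps_rep    = 2.8,     # kJ/mol, WCA strength
  wc         = 0.78,    # nm, attraction decay width (1.2 sigma_tail)
  mass       = 72       # amu per bead
)

#' Define a lipid species for the surrogate bead model
#'
#' @param name Species label.
#' @param n_tail_beads Tail beads per chain (>= 1).
#' @param n_chains 1 or 2 tail chains.
#' @param head_epsilon Head-head attraction scale (kJ/mol).
#' @param tail_epsilon Tail-tail attraction scale (kJ/mol).
#' @param bend_k Chain-straightening stiffness (kJ/mol; cosine angle
#'   potential, harmonic in the angle near the straight minimum).
#' @return A one-row data.frame.
#' @export
lipid_species <- function(name, n_tail_beads = 2, n_chains = 2,
                          head_epsilon = 0, tail_epsilon = 2.8, bend_k = 4) {
  stopifnot(n_tail_beads >= 1, n_chains %in% c(1L, 2L),
            head_epsilon >= 0, tail_epsilon >= 0, bend_k >= 0)
  data.frame(name = name, n_tail_beads = as.integer(n_tail_beads),
             n_chains = as.integer(n_chains), head_epsilon = head_epsilon,
             tail_epsilon = tail_epsilon, bend_k = bend_k,
             stringsAsFactors = FALSE)
}

#' Default species table
#'
#' Surrogate parameter sets for the five lipid classes studied with the
#' thinning protocol.  POPC is the baseline two-chain lipid; POPE raises
#' both the head-head attraction and the chain cohesion/stiffness
#' (stronger homogeneous interactions and a higher chain-melting point);
#' CHOL is a single long, stiff, strongly attracting chain (a rigid
#' elongated body that resists vertical compression); LPC (LysoPC-like)
#' has a single baseline chain; PLIPC (doubly unsaturated PC-like) lowers
#' the tail attraction and chain stiffness, favouring disordered packing.
#'
#' @return data.frame with one row per registered species.
#' @export
default_species <- function() {
  rbind(
    lipid_species("POPC"),
    lipid_species("POPE",  head_epsilon = 2.2, tail_epsilon = 3.2, bend_k = 8),
    lipid_species("CHOL",  n_chains = 1, n_tail_beads = 3, tail_epsilon = 4.2,
                  bend_k = 30),
    lipid_species("LPC",   n_chains = 1),
    lipid_species("PLIPC", tail_epsilon = 2.3, bend_k = 0.5)
  )
}

# internal: model constants accessor (exported for reporting/tests)
#' Surrogate model constants
#' @return Named list of bead diameters, bond parameters and energy scales.
#' @export
model_constants <- function() .model
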