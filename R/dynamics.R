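# Langevin dynamics driver and mechanical diagnostics.

#' Run settings for Langevin dynamics
#'
#' A BAOAB Langevin integrator is used: the implicit-solvent model has no
#' solvent degrees of freedom, so a stochastic thermostat doubles as the
#' heat bath.  Defaults mirror common coarse-grained practice: a 20 fs time
#' step and 310 K.
#'
#' @param dt Time step (ps).
#' @param T Temperature (K).
#' @param friction Langevin friction (ps^-1).
#' @param n_steps Number of steps.
#' @param neighbor_skin Verlet-list skin (nm); the list is rebuilt before
#'   any bead has moved more than skin/2.
#' @param seed Integer seed for the thermostat noise.
#' @return Object of class `run_settings`.
#' @export
run_settings <- function(dt = 0.02, T = 310, friction = 1, n_steps = 1000,
                         neighbor_skin = 0.45, seed = 1) {
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (!(T > 0)) stop("T must be positive", call. = FALSE)
  structure(list(dt = dt, T = T, friction = friction,
                 n_steps = as.integer(n_steps),
                 neighbor_skin = neighbor_skin, seed = as.integer(seed)),
            class = "run_settings")
}

field_args <- function(sys, field) {
  if (is.null(field)) {
    list(on = FALSE, k = 0, D = 1)
  } else {
    stopifnot(inherits(field, "thinning_params"))
    list(on = TRUE, k = field$k, D = field$D)
  }
}

#' Compute forces on every bead
#'
#' Total force decomposes into internal terms (nonbonded, bonds, angles;
#' Newton's third law holds, so they sum to zero) and external terms (the
#' thinning field on tail beads and, if requested, the umbrella restraint
#' on the probe).
#'
#' @param sys A `membrane_system`.
#' @param field A [thinning_params()] or `NULL` for no field.
#' @param restraint `NULL` or `list(k_u =, center =)` for a harmonic
#'   restraint on the probe COM x.
#' @return List with `force` (internal, N x 3), `force_external` (N x 3),
#'   `pe`, `virial` (xx, yy, zz), `midplane`, `com_x`.
#' @export
compute_forces <- function(sys, field = NULL, restraint = NULL) {
  stopifnot(inherits(sys, "membrane_system"))
  fa <- field_args(sys, field)
  ku <- 0; uc <- 0
  if (!is.null(restraint)) {
    if (!length(sys$probe_idx)) stop("no probe to restrain", call. = FALSE)
    ku <- restraint$k_u; uc <- restraint$center
  }
  cpp_compute_forces(sys$pos, sys$sigma, sys$att, sys$eps, sys$is_tail,
                     sys$is_lipid, mol_ids(sys), bonds_ij(sys),
                     sys$bonds[, 3], sys$bonds[, 4],
                     angles_ijk(sys), angle_kvec(sys), sys$box,
                     .model$eps_rep, .model$wc, 0.3,
                     fa$on, fa$k, fa$D, sys$geom$A_thin, sys$geom$A_buffer,
                     as.integer(sys$probe_idx - 1L), ku, uc)
}

#' Advance a system by Langevin dynamics
#'
#' @param sys A `membrane_system`.
#' @param settings A [run_settings()].
#' @param field A [thinning_params()] or `NULL` (field off).
#' @param restraint Optional probe COM restraint, `list(k_u =, center =)`.
#' @param frame_stride Save coordinates every this many steps (0 = none;
#'   the initial frame is always included when > 0).
#' @param log_stride Log energies/virial every this many steps.
#' @return Object of class `cg_trajectory`: `system` (final state),
#'   `frames` (list of N x 3 matrices), `log` (matrix with columns step,
#'   time, KE, PE, T_inst, kinetic and virial tensor diagonals, probe
#'   com_x), plus run metadata.
#' @export
run_dynamics <- function(sys, settings, field = NULL, restraint = NULL,
                         frame_stride = 0, log_stride = 100) {
  stopifnot(inherits(sys, "membrane_system"), inherits(settings, "run_settings"))
  fa <- field_args(sys, field)
  ku <- 0; uc <- 0
  if (!is.null(restraint)) {
    if (!length(sys$probe_idx)) stop("no probe to restrain", call. = FALSE)
    ku <- restraint$k_u; uc <- restraint$center
  }
  res <- with_seed(settings$seed,
    cpp_run_md(sys$pos, sys$vel, sys$sigma, sys$att, sys$eps, sys$is_tail,
               sys$is_lipid, mol_ids(sys), bonds_ij(sys),
               sys$bonds[, 3], sys$bonds[, 4],
               angles_ijk(sys), angle_kvec(sys), sys$box,
               .model$eps_rep, .model$wc, settings$neighbor_skin,
               fa$on, fa$k, fa$D, sys$geom$A_thin, sys$geom$A_buffer,
               as.integer(sys$probe_idx - 1L), ku, uc,
               settings$dt, settings$T, settings$friction, .model$mass,
               settings$n_steps, as.integer(frame_stride),
               as.integer(log_stride)))
  out <- sys
  out$pos <- res$pos
  out$vel <- res$vel
  structure(list(system = out, frames = res$frames, log = res$log,
                 settings = settings, field = field, restraint = restraint),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d saved frames, %d log rows, %d steps of %g ps\n",
              length(x$frames), nrow(x$log), x$settings$n_steps, x$settings$dt))
  invisible(x)
}

#' Lateral membrane tension from the virial pressure tensor
#'
#' Computes `gamma = Lz * (P_zz - (P_xx + P_yy)/2)` from the time-averaged
#' kinetic + virial pressure tensor of a trajectory window, with a
#' block-averaged standard error.  Positive tension = stretched membrane.
#'
#' @param traj A `cg_trajectory` (run with `log_stride > 0`).
#' @param discard_frac Fraction of log rows discarded as equilibration.
#' @param n_blocks Number of blocks for the standard error (>= 2); the
#'   window must contain at least `n_blocks` log rows.
#' @return List with `tension` and `se` (mN/m), plus per-block values.
#' @export
measure_lateral_tension <- function(traj, discard_frac = 0.3, n_blocks = 10) {
  stopifnot(inherits(traj, "cg_trajectory"))
  lg <- traj$log
  keep <- lg[, "step"] >= discard_frac * max(lg[, "step"])
  lg <- lg[keep, , drop = FALSE]
  if (nrow(lg) < n_blocks)
    stop("trajectory window shorter than ", n_blocks, " blocks", call. = FALSE)
  box <- traj$system$box
  # gamma in kJ/mol/nm^2: Lz cancels against the volume
  g <- ((lg[, "Kzz"] + lg[, "Wzz"]) -
          0.5 * (lg[, "Kxx"] + lg[, "Wxx"] + lg[, "Kyy"] + lg[, "Wyy"])) /
    (box[1] * box[2])
  to_mN_m <- 1e3 / (thinmem_constants$NA_avogadro * 1e-21)   # = 1.660539
  g <- g * to_mN_m
  blk <- split(g, cut(seq_along(g), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  list(tension = mean(bm), se = stats::sd(bm) / sqrt(n_blocks), blocks = bm)
}

#' Kinetic temperature of a trajectory window
#'
#' @inheritParams measure_lateral_tension
#' @return List with mean instantaneous temperature and its block SE (K).
#' @export
kinetic_temperature <- function(traj, discard_frac = 0.3, n_blocks = 10) {
  lg <- traj$log
  keep <- lg[, "step"] >= discard_frac * max(lg[, "step"])
  Ti <- lg[keep, "T_inst"]
  blk <- split(Ti, cut(seq_along(Ti), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  list(T = mean(bm), se = stats::sd(bm) / sqrt(n_blocks))
}
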