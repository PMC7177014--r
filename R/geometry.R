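# Zone geometry and the thinning external field.
#
# The box is partitioned along x into a centered "thin" zone, two flanking
# "buffer" zones and the remaining "normal" zone, connected through the
# periodic boundary in x.  Tail beads further than D/2 from the bilayer
# midplane feel a harmonic squeeze force toward the midplane,
#   F_z = d * C(x) * k * (D/2 - |z|),
# where d in {-1, 0, +1} selects the leaflet and C(x) in [0, 1] ramps the
# force down linearly across the buffer zones.

#' Define the thin/buffer/normal zone geometry along x
#'
#' @param X_box Box length along x (nm).
#' @param A_thin Length of the centered thin zone (nm).
#' @param A_buffer Length of each buffer zone (nm).
#'
#' @details The thin zone is centered at `x_c = X_box / 2`; the normal zone
#' is contiguous across the periodic boundary.  The three zones must fit in
#' the box: `A_thin + 2 * A_buffer <= X_box`.
#'
#' @return An object of class `zone_geometry` with fields `X_box`, `A_thin`,
#'   `A_buffer`, `x_c`.
#' @export
zone_geometry <- function(X_box, A_thin, A_buffer) {
  stopifnot(is.numeric(X_box), is.numeric(A_thin), is.numeric(A_buffer))
  if (!(X_box > 0)) stop("X_box must be positive", call. = FALSE)
  if (!(A_thin > 0)) stop("A_thin must be positive", call. = FALSE)
  if (!(A_buffer > 0)) stop("A_buffer must be positive", call. = FALSE)
  if (A_thin + 2 * A_buffer > X_box + 1e-12) {
    stop("zones do not fit: A_thin + 2*A_buffer must be <= X_box",
         call. = FALSE)
  }
  structure(
    list(X_box = as.numeric(X_box), A_thin = as.numeric(A_thin),
         A_buffer = as.numeric(A_buffer), x_c = as.numeric(X_box) / 2),
    class = "zone_geometry"
  )
}

#' @export
print.zone_geometry <- function(x, ...) {
  cat(sprintf(
    "zone_geometry: X_box = %g nm, thin = %g nm, buffer = 2 x %g nm, x_c = %g nm\n",
    x$X_box, x$A_thin, x$A_buffer, x$x_c))
  invisible(x)
}

#' Thinning field parameters
#'
#' @param k Harmonic force constant (kJ mol^-1 nm^-2). Default 20.
#' @param D Minimal-thickness parameter (nm); tail beads within D/2 of the
#'   bilayer midplane feel no force. Default 1.
#' @return An object of class `thinning_params`.
#' @export
thinning_params <- function(k = 20, D = 1) {
  if (!is.numeric(k) || k < 0) stop("k must be >= 0", call. = FALSE)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  structure(list(k = as.numeric(k), D = as.numeric(D)),
            class = "thinning_params")
}

#' Zone scaling factor C(x)
#'
#' Linearly ramps from 1 in the thin zone to 0 in the normal zone across the
#' buffer zones; continuous everywhere and periodic in x.
#'
#' @param x Numeric vector of x coordinates (nm); wrapped into `[0, X_box)`.
#' @param geom A [zone_geometry()].
#' @return Numeric vector of scale factors in `[0, 1]`.
#' @export
zone_scaling <- function(x, geom) {
  stopifnot(inherits(geom, "zone_geometry"))
  if (any(!is.finite(x))) stop("non-finite x coordinate", call. = FALSE)
  # signed distance to the thin-zone center under the minimum-image convention
  dx <- (x - geom$x_c) %% geom$X_box
  dx <- ifelse(dx > geom$X_box / 2, dx - geom$X_box, dx)
  adx <- abs(dx)
  half_thin <- geom$A_thin / 2
  C <- 1 - (adx - half_thin) / geom$A_buffer
  pmin(1, pmax(0, C))
}

#' Classify x coordinates into zones
#'
#' @inheritParams zone_scaling
#' @return Character vector with values `"thin"`, `"buffer"`, `"normal"`.
#' @export
zone_of <- function(x, geom) {
  C <- zone_scaling(x, geom)
  ifelse(C >= 1, "thin", ifelse(C <= 0, "normal", "buffer"))
}

#' Direction constant d(z)
#'
#' Selects the leaflet the bead sits in: +1 above the midplane slab, -1
#' below, 0 within the minimal-thickness slab of half-width D/2.
#'
#' @param z Signed distance to the bilayer midplane (nm).
#' @param D Minimal-thickness parameter (nm).
#' @return Integer vector in `{-1, 0, +1}`.
#' @export
direction_constant <- function(z, D) {
  ifelse(z > D / 2, 1L, ifelse(z < -D / 2, -1L, 0L))
}

#' Thinning force on tail beads
#'
#' The z-component of the external squeeze force,
#' `F_z = d(z) * C(x) * k * (D/2 - |z|)`, acting on lipid tail beads only.
#' The force always points toward the bilayer midplane and grows linearly
#' with the distance beyond D/2; x- and y-components are zero.
#'
#' @param x x coordinates of the beads (nm).
#' @param z Signed distances to the bilayer midplane (nm).
#' @param geom A [zone_geometry()].
#' @param params A [thinning_params()].
#' @param is_tail Logical vector; non-tail beads get exactly zero force.
#' @return Numeric vector of z-forces (kJ mol^-1 nm^-1).
#' @export
thinning_force <- function(x, z, geom, params, is_tail = TRUE) {
  stopifnot(inherits(params, "thinning_params"))
  if (any(!is.finite(x)) || any(!is.finite(z))) {
    stop("non-finite coordinates passed to thinning_force", call. = FALSE)
  }
  d <- direction_constant(z, params$D)
  C <- zone_scaling(x, geom)
  f <- d * C * params$k * (params$D / 2 - abs(z))
  f * as.numeric(rep_len(is_tail, length(f)))
}
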