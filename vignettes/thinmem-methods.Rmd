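---
title: "thinmem: membrane thinning, packing defects and defect sensing in a minimal coarse-grained bilayer model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thinmem methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peripheral membrane proteins with amphipathic motifs (the ALPS motif of
ArfGAP1 is the canonical example) bind preferentially to membranes whose
hydrophobic interior is locally exposed — lipid packing defects.  Packing
defects are usually produced in simulations by curving the membrane, which
convolves curvature and packing effects.  `thinmem` implements an
alternative: an external *thinning field* that squeezes a flat bilayer in a
chosen lateral zone.  Squeezing thins the membrane, thinning loosens head
group packing, and packing defects appear without any curvature.  The
package couples this protocol to the complete analysis chain needed to
study its consequences: thickness profiling with a sigmoid description of
the thin-to-normal transition, grid-based defect quantification,
composition histograms for thinness-induced lipid sorting, and umbrella
sampling with WHAM unbiasing to measure the attractive force that pulls an
amphipathic probe into the thin zone.

## The thinning field

The box is partitioned along x into a centred **thin** zone of length
$A_\mathrm{thin}$, two flanking **buffer** zones of length
$A_\mathrm{buffer}$, and the remaining **normal** zone, connected through
the periodic boundary.  Every lipid *tail* bead further than $D/2$ from the
bilayer midplane feels a z-directed harmonic squeeze

$$F_z = d \, C(x)\, k \, (D/2 - |z|),$$

where $d \in \{-1, 0, +1\}$ selects the leaflet (zero inside the
minimal-thickness slab $|z| \le D/2$), and $C(x)$ scales from 1 in the thin
zone linearly down to 0 at the buffer/normal boundary
($|x - x_c| \ge A_\mathrm{thin}/2 + A_\mathrm{buffer}$).  $D$ sets the
minimal thickness the field drives toward; $k$ (kJ mol$^{-1}$ nm$^{-2}$)
sets its strength.  Defaults are $k = 20$, $D = 1$ nm with
$A_\mathrm{thin} = A_\mathrm{buffer} = 10$ nm in a 55 nm box — the
reference setup for a full-size POPC membrane.

Two properties deserve emphasis:

* **The field is not conservative.**  $F_z$ depends on x through $C(x)$
  but has no x component, so it is not the gradient of any potential.  It
  is implemented exactly as defined (matching the original force-based
  protocol); it is excluded from the reported potential energy and from
  the virial, and the Langevin thermostat absorbs the small net work.
* **The midplane is recomputed every step** as the mean z of all lipid
  beads.  For a non-drifting membrane this coincides with a fixed
  midplane; recomputation removes slow drift without a COM-removal scheme.

## The surrogate lipid model

The protocol itself is force-field agnostic.  `thinmem` pairs it with a
minimal implicit-solvent bead model of the class long used for bilayer
self-assembly studies: every lipid is one head bead plus one or two tail
chains of two beads; all beads repel through a soft-core (WCA) potential,
tail beads attract through a smoothly truncated cosine-squared well of
width $w_c = 1.2\,\sigma_t$, chains are held by harmonic bonds and a cosine
angle stiffness.  Species differ only in chain count and interaction
scales:

| species | chains | distinguishing parameters | rationale |
|---|---|---|---|
| POPC | 2 | baseline (tail attraction 2.8, bend 4) | reference bilayer former |
| POPE | 2 | head attraction 2.2, tail 3.2, bend 8 | stronger homogeneous interactions, higher chain melting point |
| CHOL | 1 | three-bead chain, tail attraction 4.2, bend 30 | rigid elongated strongly cohesive body |
| LPC  | 1 | baseline, single chain | lyso-lipid: half the tail volume |
| PLIPC | 2 | tail attraction 2.3, bend 0.5 | doubly unsaturated: disorder-favouring |

Energy scales were calibrated **once** so the baseline forms a stable fluid
bilayer at 310 K ($k_BT/\varepsilon_{tt} \approx 0.92$): $\sigma_t = 0.65$
nm, $\sigma_h = 0.72$ nm, $\varepsilon_\mathrm{rep} = 2.8$ kJ/mol, bonds
0.65 nm at 2500 kJ mol$^{-1}$ nm$^{-2}$.  The attraction width was set to
$1.2\,\sigma_t$: wider wells (1.4--1.5 $\sigma_t$, the self-assembly
regime) produce a glassy, over-coordinated bilayer (~100 interacting
neighbours per bead) that neither diffuses nor responds cleanly to the
field; the narrower well keeps a pre-built bilayer cohesive while staying
fluid.  The tensionless area per lipid was then measured with
`measure_lateral_tension()` over an area scan; the lateral tension changes
sign near **0.475 nm² per lipid**, which is the builder default.  The resulting bilayer is ~3.0 nm head-to-head — thinner
than a real POPC membrane (4.03 nm), and its tail beads reach at most
~1 nm from the midplane, so the thinning field's minimal-thickness
parameter is scaled accordingly for surrogate runs ($D = 0.3$ nm leaves
the field a comparable lever arm over the tails).  Intramolecular nonbonded pairs are excluded entirely (molecule
shape is maintained by bonds and angles); with two splayed two-bead chains
per lipid, intramolecular excluded volume would otherwise dominate the
build energetics without changing the physics represented.

What the surrogate does *not* reproduce: chemical specificity (MARTINI
bead types), explicit solvent and its pressure contribution, realistic
absolute defect sizes (surrogate defects are several-fold smaller than
atomistic ones because bead coverage radii are), and quantitative
tensions.  Consequently all paper-anchored *magnitudes* are checked as
unit-conversion arithmetic or as parameter recovery on synthetic data,
while surrogate simulations are asked only for *signs and orderings*
(thin < normal thickness, thin > normal defect constant, sorting
directions, attraction of the probe).

## Dynamics

A BAOAB Langevin integrator advances the system (20 fs default step,
310 K).  The implicit solvent removes the solvent's thermostatting role, so
a stochastic thermostat is the physically sensible choice (the
velocity-rescaling thermostat of explicit-solvent practice assumes a
solvent bath).  The ensemble is fixed-box: instead of a semi-isotropic
barostat, the build area is calibrated once to the tensionless point —
the stated goal of the original pressure-coupling procedure — and runs
are analysed at fixed area.  Pair interactions are smoothly truncated
(forces continuous everywhere); a Verlet neighbour list with a 0.45 nm
skin is rebuilt before any bead moves half a skin.  Kinetic temperature
carries the usual $O(\Delta t^2)$ BAOAB discretization offset
(~2% at the default step); the equipartition check therefore runs at
10 fs where the offset is negligible.

The lateral tension is computed from the kinetic + virial pressure tensor,
$\gamma = L_z\,(P_{zz} - (P_{xx}+P_{yy})/2)$, with block-averaged errors;
$L_z$ cancels against the volume so the open z dimension is immaterial.

## Thickness profiles and the sigmoid description

Thickness is the head-to-head distance between leaflet surfaces: per x-bin
and frame, mean upper-head z minus mean lower-head z (leaflet-surface
differencing is robust at the lipid counts of desk-scale runs, where
nearest-neighbour pairing is noisy).  The default bin width is
$X_\mathrm{box}/110$ (0.5 nm at the reference geometry).  Profiles are
symmetrized about the thin-zone centre — mirror bins pair exactly on the
uniform grid — and the buffer-zone transition is fit with

$$a(x) = \frac{L}{1 + e^{-\kappa (x - x_0)}} + b.$$

Because $(L, \kappa, x_0, b)$ and $(-L, -\kappa, x_0, b+L)$ describe the
same curve, fits are canonicalized to $\kappa < 0$; with that convention
the reference parameter set is $L = -1.22$ nm, $\kappa = -19.14$
nm$^{-1}$, $x_0 = 1.11$ nm, $b = 4.08$ nm.  The reference fit's coordinate
origin is not recoverable from its published values alone; synthetic
profiles built from this set place the transition mid-buffer, and fitting
windows are centred on $x_0$.  Fitting uses Levenberg–Marquardt with a
ladder of steepness starts in both signs (baseline from the profile ends,
amplitude from their difference, midpoint from the range centre).  A
caveat worth knowing: at the reference steepness the transition is ~0.2 nm
wide, so with 0.1 nm point spacing and 0.05 nm noise the steepness itself
is only weakly identified (median relative error ~20–25%); the amplitude,
midpoint and baseline recover to a few percent.  Flat profiles are
returned as a degenerate fit ($L = 0$, $b$ = the mean) rather than an
error.

## Packing defects

A leaflet surface is rasterized on an xy grid (default 1 Å).  Each cell is
scanned from the solvent side toward the midplane; the first bead whose
projected disc (radius = half the WCA minimum distance) covers the cell
centre decides its fate: head bead → covered, tail bead or nothing →
defect.  4-connected defect cells form defects; areas are reported in Å².
The defect-area distribution decays exponentially, $p(A) \propto
e^{-A/\pi_d}$; the size constant $\pi_d$ is the negative inverse slope of
a count-weighted log-linear fit, implemented as a Poisson regression on the
histogram counts over the window from $A_\mathrm{min}$ (default 15 Å²) to
the last bin resolved at $p_\mathrm{min}$ (default $10^{-4}$).  The
Poisson form matters: a least-squares fit on log-probabilities silently
drops empty tail bins and inflates the constant by ~12% at blocks of a
few thousand areas.  Errors are block standard errors over consecutive
blocks.  On surrogate trajectories the thresholds are applied at the
surrogate's own defect scale ($A_\mathrm{min} = 4$ Å²), since surrogate
defects are several-fold smaller than atomistic ones.

## Lipid sorting

Lipids are located by their head bead (consistent with the thickness
analysis), histogrammed in 50 bins along x (counts pooled frame-weighted
across frames and replicas), and summarized as zone-wise enrichment: the
count-weighted mean mole fraction in a zone divided by the initial
fraction, with boundary-straddling bins split by overlap length.  1 means
no sorting; the count-weighted mean enrichment over all zones is exactly 1
by construction.  Buffer bins are reported separately, not folded into
either zone.

## Umbrella sampling and WHAM

The amphipathic probe is two stiffly bonded parallel rows of beads —
a hydrophobic row that attracts tail beads and a purely repulsive polar
row — placed at the thin-zone centre on the upper leaflet.  Windows
restrain the probe's COM x with a harmonic spring (reference ladder: 111
windows at 0.2 nm spacing, $k_u = 10^3$ kJ mol$^{-1}$ nm$^{-2}$; scaled
runs use nine windows at 0.5 nm spacing with $k_u = 30$, i.e. a window
width of ~0.29 nm and ~1.7 sigma spacing, so adjacent histograms overlap
— sparser, stiffer ladders leave WHAM stitching noise larger than the
free-energy signal).  Windows
are initialized by direct placement plus per-window equilibration rather
than a continuous pull — functionally equivalent at these scales and much
simpler.  The standard self-consistent WHAM iteration (tolerance $10^{-7}$
kJ/mol on window free energies, 0.05 nm bins) yields $F(x)$, anchored at
its minimum.  The defect-sensing force is the OLS slope of $F$ against
distance from the thin-zone centre over the buffer zone, reported so that
positive = attraction toward the thin zone, and converted to pN via
$1\ \mathrm{kJ\,mol^{-1}\,nm^{-1}} = 1.660539$ pN (CODATA 2018 constants,
pinned).  `reparameterize_thickness()` maps $F(x)$ onto thickness through
the closed-form sigmoid inverse; whether a density term
$-k_BT \ln|dx/da|$ belongs in $F(a)$ depends on a derivation not available
here, so both modes exist behind `jacobian_correction` and the plain
transform is the default.

## Scaled-down study conditions

Simulation-based checks run on 10 × 4.8–5.4 nm² bilayers
($A_\mathrm{thin} = 2.5$, $A_\mathrm{buffer} = 2$ nm; 100–110 lipids per
leaflet), 16–30k steps of 25 fs with 0.3 ps$^{-1}$ friction (diffusion in
the surrogate bilayer is slow, ~$1.5 \times 10^{-4}$ nm²/ps; the low
friction speeds configurational sampling without affecting the sampled
ensemble).  Two calibrated areas are used:

* the **tensionless area** (0.475 nm²/lipid) for the field-response
  ladder at the reference $k \in \{0, 10, 20\}$, $D = 0.3$ nm;
* the **thickness-matched area** (0.50 nm²/lipid) for defect, sorting and
  probe runs with a clear squeeze ($k = 40$).  This implements the
  reference calibration criterion directly: the box area is chosen so
  that the *normal zone's* thickness under the field matches the
  tensionless membrane's, which is what the original protocol's
  surface-tension coupling achieves.  At that area the squeezed thin zone
  is genuinely dilute and defect-rich.

A consequence of the fixed-box ensemble deserves emphasis.  Without the
area reservoir, lateral lipid exchange between zones is kinetically
frozen at these scales (thin-zone occupancy is constant over the longest
runs), so composition differences between zones build up only through
slow boundary exchange.  The single-chain and polyunsaturated surrogates
enrich in the thin zone robustly; the PE and sterol surrogates, whose
depletion in the reference system rests on avoiding the dilute,
disordered zone, respond much more weakly here and their depletion is
resolved only marginally at desk scale.  These systems show the
paper-level phenomenology as signs and orderings; their magnitudes are
not comparable to MARTINI values and are not reported as such.

## Numerical choices and degenerate inputs

* Zone scaling and the squeeze force are continuous everywhere
  (float-exact at zone edges); positions wrap periodically in x and y,
  z is open.
* Builder lattices place exactly `floor(area / APL)` lipids per leaflet
  (rows differ by at most one site); species counts follow largest
  remainder, assigned by a seeded permutation per leaflet.  Build-time
  overlap is rejected below 0.3 nm, then relieved by displacement-capped
  steepest descent.
* Blow-ups (per-step displacement > 0.5 nm) and non-finite forces abort
  with the offending step/bead.
* WHAM tolerates but warns about windows sharing < 10 counts; a single
  unbiased window degenerates to the anchored log-histogram exactly.
* All randomness flows through explicit integer seeds (R's RNG seeds an
  internal xoshiro256+ stream for the thermostat), so every trajectory,
  build and fixture is bit-reproducible.

## Known limitations

* The surrogate's absolute thicknesses, tensions, defect areas and forces
  are not comparable to atomistic or MARTINI values; only their relative
  responses to the field are meaningful.
* Sorting at desk scale is kinetically limited: enrichment directions
  establish near zone boundaries well before global equilibrium, so
  magnitudes underestimate fully converged partitioning.
* The thinning field does no work bookkeeping: energy logs report the
  internal potential only.
* One leaflet pair, flat geometry, no curvature coupling, no explicit
  solvent, no electrostatics.
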