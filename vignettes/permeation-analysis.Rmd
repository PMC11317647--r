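---
title: "Quantifying ion permeation through channel pores with poreperm"
author: "poreperm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ion permeation through channel pores with poreperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreperm)
```

## Scope and model

`poreperm` turns molecular-dynamics trajectories of ion channels into the
quantitative observables used to characterize permeation: directional
permeation events and single-channel conductance, permeability ratios
between cation species, pore-radius profiles along the conduction axis,
selectivity-filter geometry distributions, ion hydration and knock-on
proximity statistics, 3D ion density maps, and potentials of mean force
(PMFs) reconstructed from umbrella-sampling windows by WHAM with bootstrap
errors.  The motivating system is a lysosomal two-pore cation channel
(TPC2-like: a dimeric channel whose selectivity filter is formed by
conserved asparagine pairs rather than the canonical DEKA motif), but
nothing in the package is specific to it: every analysis is parameterized
by a `PoreSpec` and selection expressions.

The package deliberately stops at analysis.  It does not run MD, evaluate
force fields, or handle trajectory production; inputs are topology +
coordinate files (PDB, GRO, DCD) or the package's own synthetic
generators.

### Unit conventions

One internal unit system is used everywhere: Angstrom, ns, charge in units
of *e*, voltage in mV, conductance in pS, energy in kcal/mol.  Inputs in
GROMACS units are converted at ingest (GRO coordinates nm -> Angstrom;
umbrella force constants kJ mol^-1 nm^-2 -> kcal mol^-1 A^-2, factor
`r signif(poreperm::permConstants$kJnm2_to_kcalA2, 4)`).  Mixing Angstrom/nm
and kJ/kcal is the classic source of silent factor errors in this kind of
pipeline; a single convention confines every conversion to the readers.

## The permeation event model

A `PoreSpec` defines the geometry all permeation analyses share: a unit
axis (default +z), a selection whose per-frame center anchors a cylinder of
radius 6 A (the conventional choice for a channel pore), the axial planes
of the selectivity filter (SF) and the cytosolic gate relative to that
center, and which side is luminal.  Because topologies parsed from
PDB/GRO files carry no masses, the anchor point is the center of
*geometry* of the selection; it is computed as a per-dimension circular
mean so that a selection straddling a periodic boundary still yields the
correct center.  This makes event counts invariant under rigid
translations and re-wrapping of the box, which the test suite asserts.

A permeation event is a full directional traversal: the ion leaves the
luminal bulk, transits the pore, and reaches the cytosolic bulk.
`detectPermeationEvents()` runs a per-ion finite-state machine over the
axial coordinate relative to the (possibly drifting) pore center:

* **Bulk hysteresis.**  Luminal bulk is beyond the SF plane plus a margin
  (default 2 A); cytosolic bulk beyond the gate plane minus the margin.
  Hysteresis is standard for crossing counters -- without it an ion
  sitting on a plane chatters between states.
* **Cylinder containment.**  In the default *strict* mode an ion must be
  inside the cylinder on every frame between the two bulk states; an ion
  that exits radially mid-pore restarts its state machine.  This is the
  strictest consistent reading of "only atoms found in the cylinder are
  counted".  A lenient mode (`strict = FALSE`) requires containment only
  on the final in-pore frame before emerging, for workflows that count an
  ion wherever it crosses the gate.  Both behaviors are tested; the
  choice is a flag because trajectory-derived counts differ only for ions
  that graze the cylinder wall.
* **Directionality.**  Reverse (cytosolic -> luminal) crossings are
  recorded with `direction = -1` but excluded from the event count used
  for conductance, which is defined directionally.
* A ion jumping from one bulk to the other with no intermediate frame
  (possible only at very coarse stride) emits nothing: it never
  demonstrated cylinder containment.

Conductance follows the charge-transport identity
`C = N_event * Q_ion / (t * V_tm)`; in package units
`C[pS] = N z * 1.602177e5 / (t[ns] V[mV])`.  Fractional `N` is accepted
because published event counts are means over repeats.  The permeability
ratio of two species is the ratio of their event rates under identical
conditions, conventionally printed as "x.x:1".

## Pore geometry

`radiusProfile()` re-implements the HOLE algorithm: at each axial level
the radius of the largest sphere, centered in that plane, that overlaps no
atom (`min_i |c - x_i| - vdw_i`, capped at 10 A), maximized over in-plane
center positions by seeded multi-start Nelder-Mead.  Two numerical choices
matter:

* **Center-following.**  Levels are processed outward from the level
  nearest the pore center, and each level's search disc (default radius
  2 A) is centered on the previous level's optimal sphere center.  A
  global in-plane search would escape through the pore mouth of any
  finite structure and report the vacuum outside -- the same reason HOLE
  anneals along the channel rather than searching globally.
* **van der Waals radii.**  Defaults C 1.70, N 1.55, O 1.52, S 1.80,
  P 1.80, H 1.20 A; hydrogens are included when the topology has them,
  because that is determinate and testable.  Unknown elements fall back
  to 1.70 A with a warning.

The synthetic oracle (`buildToyPore()`) places rings of atoms so the
on-axis inscribed radius is known in closed form.  Note a subtlety the
ground-truth record makes explicit: where the requested profile R(z)
varies, a sphere at level z can touch rings at neighbouring levels, so the
exact on-axis radius is `min_z' sqrt((R(z')+a)^2 + (z-z')^2) - a`, which
equals R(z) only where the profile is flat or gently varying.  The oracle
tests compare against this exact value, to 0.05 A.

`minPairDistance()` gives selectivity-filter separation time series
(minimum over heavy-atom pairs under the minimum-image convention --
gamma-carbon-only selections are expressed directly in the selection
language, e.g. `"resid 653 and name CG"`), and
`distanceDistribution()` builds the normalized 1D/2D densities used to
detect bimodal filter conformations.

## Hydration, contacts, knock-on

Coordination numbers count water oxygens strictly within 4.5 A of an ion,
the position of the first minimum of the bulk ion-water-oxygen RDF; the
boundary uses strict `<` because the boundary set has measure zero and a
deterministic convention beats an ambiguous one.  `rdf()` uses the
standard ideal-gas shell normalization; its first minimum is located after
the first maximum *comparable to the global peak* (>= half), because
near-empty small-r shells otherwise produce noise bumps mistaken for the
first shell, and is refined by quadratic interpolation.

Knock-on statistics (`nearestIonDistribution()`) follow the geometry of a
two-ion permeation mechanism: for each frame with an ion bound at the SF
(inside the SF band, default +/-2 A around the SF plane, and inside the
cylinder), the distance to the nearest same-species ion on the luminal
side is recorded; the distribution's mode and P(d < 7 A) summarize how
often a second ion is poised to assist.

## Density maps

`densityMap()` bins each tracked atom into exactly one voxel by
`floor((pos - origin)/spacing)`; counts are conserved exactly (asserted in
the tests) and out-of-bounds atoms are tallied separately.  The output is
number density (atoms A^-3) -- molarity conversion is left to the reader
since the normalization convention varies between tools.  Optional Kabsch
alignment before binning is off by default: the intended use case
positionally restrains the protein, and alignment would only blur a
restrained system.  OpenDX output round-trips through `readDX()` to 1e-6
relative and loads in VMD/PyMOL/Chimera.

## WHAM and bootstrap errors

`wham()` solves the standard self-consistency equations on a fixed grid
(bin 0.2 A by default, which resolves 1-A window spacing) from `f_i = 0`,
converging on the maximum change in window free energies (tolerance 1e-7
kcal/mol).  kBT uses the physical constant, 0.61603 kcal/mol at 310 K.
The PMF is shifted so its minimum is zero, matching how channel PMFs are
conventionally plotted; a bulk-reference zero is available.
Non-overlapping adjacent windows warn; a disconnected window chain is an
error naming the gap, since no amount of iteration can stitch it.

Bootstrap errors resample each window's samples with replacement
(window-wise, i.i.d. -- no autocorrelation treatment, matching the plain
"N bootstraps" convention; a block variant is future work), rerun WHAM
warm-started from the full-data solution, re-zero each replicate, and
report per-bin SDs.  With one replicate the SD is defined as zero.

## The synthetic world and what a green test establishes

The generators emulate exactly the features the analyses consume, nothing
more:

* `generateDriftTrajectory()`: overdamped Langevin ions (Euler-Maruyama,
  noise variance 2 D dt per axis) in a periodic box, with drift applied
  only inside the pore cylinder and directed luminal -> cytosolic --
  a cartoon of applied-field MD at 500-750 mV.  Optionally
  `planted_crossings` ions follow deterministic straight paths from the
  luminal bulk through the cylinder past the gate, so the exact crossing
  count is known by construction; with zero diffusion, detected events
  equal planted events exactly, for any planted count.  Positions are
  wrapped into the primary box before storage, forcing the analyses to
  handle wrapped input as real XTC-derived data would be.  Waters are
  lone oxygen atoms: no implemented definition ever consults a hydrogen.
* `sampleUmbrellaWindows()`: Metropolis samples from the exact biased
  Boltzmann density of an analytic free-energy surface, with the proposal
  step auto-tuned to 30-50% acceptance during burn-in.  The channel-scale
  oracle is a *bounded* double well -- two flat wells separated by a
  Gaussian barrier of 8 kcal/mol (width 3 A, the closed-filter barrier
  scale) -- because a quartic double well over a 57-A domain reaches
  thousands of kcal/mol at the edges and no umbrella chain could overlap
  there.  Windows use 1-A spacing over -35..+22 A with force constants
  2500 kJ mol^-1 nm^-2 near the barrier and 1000 elsewhere, mirroring
  practice.
* `buildToyPore()` and `buildHydrationFrame()` as described above.

A green suite therefore establishes algorithmic correctness against
closed-form and brute-force oracles at desk scale.  It does *not*
establish anything about real channel trajectories: the synthetic world
has no membrane, no electrostatics, no correlated ion motion and no
protein flexibility, so published trajectory-derived numbers (conductance
values, coordination minima, proximity probabilities, PMF barrier heights
from real windows) can only be reproduced by feeding the corresponding
deposited trajectory data through the same entry points.

## Numerical choices and degenerate inputs

* Orthorhombic boxes only; triclinic support is deferred.
* Event detection at coarse stride can miss transits entirely; stride is
  a first-class parameter everywhere and defaults to 1.
* `radiusProfile()` reports the cap (10 A), flagged, for levels with no
  atoms in capture range.
* Identical selections in `minPairDistance()` are rejected (the minimum
  would be trivially zero).
* `conductance()` refuses V = 0 (undefined) and t <= 0.
* WHAM with `max_iter` exceeded errors with the residual rather than
  returning a half-converged profile.
* All stochastic code paths (generators, multi-start searches, bootstrap)
  take explicit seeds and are exactly reproducible.

## Known limitations

* No MBAR estimator and no 2D PMFs.
* No autocorrelation-based effective sample sizes; bootstrap errors on
  strongly correlated window data will be optimistic.
* XTC cannot be read (compressed format with no reader available here);
  convert to GRO/PDB/DCD first.
* The pore axis is a straight line; curved centerline tracking is out of
  scope.
* Event-count-based conductance ignores local field inhomogeneity; it is
  the standard estimate, not an exact observable.
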