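---
title: "Methods: occupancy-based pore clogging and displacement currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy-based pore clogging and displacement currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreclog)
```

## Scope and model

`poreclog` post-processes all-atom MD trajectories of membrane nanopores
(the design case is α-Hemolysin in a lipid bilayer with 2 M KCl) to
quantify how an analyte inside the pore suppresses ionic conduction.  Two
observables are computed:

* the **current blockage** ΔI/I₀ from non-equilibrium trajectories, via
  the windowed displacement current
  I(t) = 1/(Δt·L_z) Σ q_i [z_i(t+Δt) − z_i(t)]; and
* the **pore clogging estimator** b = 1 − R̃₀/R̃ from equilibrium
  occupancy, where R̃ = Σ ρΔz/A_z is the quasi-1D resistance of the
  electrolyte-accessible channel.

The quasi-1D model assumes a continuum electrolyte of constant
resistivity ρ, a smoothly varying cross-section A(z), and neglects access
resistance.  None of these hold exactly at nanoscale, so b is a
*correlate* of ΔI/I₀, not a replacement; the package's validation checks
that correlation on synthetic geometries where both are known.

## The occupancy pipeline

1. **Rasterization.** Water and ion atoms are painted onto a regular
   grid; a cell counts as occupied when its *center* lies within the
   atom's Van der Waals radius.  The center test matches the common
   Volmap behaviour and is cheap; an any-overlap mode is available
   (`mode = "overlap"`) and is by construction a superset.  Atoms outside
   the grid are ignored — the grid is the analysis window, not the box.
2. **Averaging and normalization.** Per-frame binary maps are averaged
   and divided by the mean occupancy of a user-chosen *bulk region*.  The
   bulk region must sit in unperturbed electrolyte; the package deliberately
   does not auto-detect it, because a bad bulk (e.g. inside the analyte's
   excluded volume) silently rescales every area and can even flip the
   sign of b.  Both water+ion and water-only normalizations are possible
   through the atom selection; the default electrolyte selection is
   water + K + Cl.
3. **Through-channel filtering.** "Accessible when moving from one
   entrance towards the other" is formalized as monotone-z reachability
   with 6-connectivity: lateral (same-slice) steps are unrestricted,
   vertical steps must not reverse direction.  This removes exactly the
   reentrant pockets pointing at the opposite side while keeping lateral
   lobes; 26-connectivity is available for rougher maps.  The open
   threshold θ defaults to 0 (any strictly positive normalized
   occupancy), since no published cutoff exists; raising θ can only
   shrink masks (a tested invariant).  Seeds are the open cells of the
   entrance slice, optionally restricted to a disk around the pore axis
   so that bulk solvent outside the pore does not seed the sweep.
   Masks are computed per replica on that replica's averaged map, and b
   values are aggregated across replicas as independent measurements
   (mean ± SEM).
4. **Area, resistance, clogging.** A_z sums the filtered normalized map
   (fractional occupancies count fractionally, so sub-bulk layering near
   walls is represented).  A fully blocked slice gives R̃ = +∞ and
   b = 1.  b < 0 (clogged pore less resistive than the reference) is
   permitted but flagged as anomalous, because it usually indicates a
   mis-configured bulk or reference.  ρ defaults to 1; b is exactly
   ρ-invariant, so absolute resistivity only matters for absolute R.
   The truncated variant starts the z-sum a configurable 20 Å above the
   trans entrance, emulating a barrel-cut pore that removes the
   secondary (hydrophobic-ring) constriction from the signal.

## Displacement currents

Charges are taken from the atom metadata (a YAML table; PDB files carry
no charges, so the configuration is explicit and a missing entry is an
error, never a default).  Δz is minimum-image unwrapped by default —
without unwrapping, a single periodic crossing contributes a spurious
~L_z jump that dwarfs the physical signal at typical 40 ps windows.  L_z
is taken per window from the first frame of the pair, since NPT boxes
fluctuate.  The mean current discards an initial transient (the
relaxation of a pulled peptide, checked via the gyration-radius series)
and estimates its error by block averaging with 8 ns default blocks,
because successive windows are strongly autocorrelated; with fewer than
two blocks the plain SEM is used and flagged.  Species currents restrict
the sum to one species; the default "total" sums all selected
electrolyte atoms, and K/Cl decomposition is exact by linearity.

## The synthetic generator

Fixtures are parametric pores on the z axis: cylinders, hourglasses
(vestibule–constriction–vestibule profiles), and cylinders with a lateral
pocket cavity connected to the channel only through a thin neck at the
pocket top — the reentrant geometry the filter must remove.  Walls are
frozen spheres whose inner surface is tangent to the analytic radius
profile r(z), ring-spaced at 0.8 wall radii so the wall is leak-free;
electrolyte atoms are rasterized by the same code path as any real
trajectory.  Mobile particles are single beads (water 1.4 Å, K 1.5 Å,
Cl 1.8 Å — round synthetic values, not force-field radii) with two
placement modes:

* **random + Brownian**: uniform placement with a soft excluded-volume
  check, then steps drift·Δt + N(0, √(2DΔt)) with sticky rejection at the
  walls and periodic z.  Drift-only trajectories reproduce
  I = Σ q·v/L_z to machine precision; unbiased walks give zero mean
  current within statistical error.  Dynamics are ideal-gas (no
  particle–particle forces): the generator emulates *kinematics* for the
  current estimator, not liquid structure.
* **lattice**: a deterministic dense fill whose outermost ring per layer
  sits exactly at r(z) − r_particle, so the union of particle spheres
  reproduces the analytic channel surface.  The 0.5 Å default spacing
  keeps the sphere-union scalloping below 0.03 Å (sagitta
  r − √(r² − (s/2)²) for the 1.4 Å bead), making grid discretization the
  only error in the geometry pipeline.  This is what makes analytic
  closure tests sharp: A(z) = πr², annulus π(r² − r_b²) under a
  concentric bead chain.

Bead-chain obstructions act as solid rods (bead spacing ≤ bead radius).
Note a physical consequence used by the tests: in a 5 Å channel a 1.4 Å
solvent bead no longer fits once the rod exceeds ≈ 2.2 Å, so larger rods
are genuinely fully blocked (b = 1), not merely narrowed.

What the generator does *not* emulate: electrostatics, hydration
structure, peptide conformational flexibility, and NPT box fluctuation.
Passing the synthetic suite therefore validates the estimators'
arithmetic, the filter's topology and the pipeline's convergence — not
force-field-level realism.

## Numerical choices and degenerate inputs

* Coordinates are Å, times ps, charges e, currents nA
  (1 e/ps = 160.2176634 nA); z increases trans→cis; slice i covers
  [z_lo + (i−1)Δz, z_lo + iΔz); grid indices are 1-based.
* Rasterization of an empty selection is an all-zero map, not an error;
  non-finite coordinates are an error.
* An all-zero bulk region is a degenerate-normalization error (division
  is never silently skipped).
* An empty seed slice produces an all-false mask with a warning.
* Single-replica SEM is 0 and flagged; a single-atom gyration radius is
  the degenerate 0.
* The relaxation-time estimate is deliberately simple (first entry into
  a ±5% band around the tail mean, tail = last quarter); it answers "how
  much transient must be discarded", not "what is the correlation time".
* Histidine is classed POLAR by default (`positive_his = TRUE` reclasses
  it); Arg/Lys are POSITIVE, Asp/Glu NEGATIVE.  The class contrast uses
  Welch's t-test, which does not assume equal class variances.
* The apparent-volume and ASA columns of the shipped amino-acid table are
  compiled approximations from standard literature scales (the data file
  header documents this); the four Van der Waals volumes quoted in the
  README are exact table values.

## Problem sizes

The test suite and the acceptance script run synthetic systems sized for
a laptop-class single core: cylinders of 5–8 Å radius and 30–100 Å
length, grids up to 52×52×100 cells (0.5 Å), dense fills of ~16k
particles, Brownian runs of ≤ 251 frames, and 100 random ≤ 12³ grids for
the oracle comparison.  These sizes were chosen so every stage completes
in seconds while keeping discretization errors in the few-percent range;
the same code paths scale to real αHL maps (~100³ cells, thousands of
frames) linearly in atoms × frames.

## Known limitations

* XTC trajectories are not read; convert to DCD upstream.
* The monotone-z formalization of accessibility is this package's
  declared interpretation of directional filtering; other published
  pocket filters (probe-sphere profiling, persistence-based cavity
  analysis) answer related but different questions and are out of scope.
* Position-dependent resistivity ρ(z) is not implemented (the quasi-1D
  integral allows it; constant ρ is assumed throughout).
* Absolute currents require the driving field to be part of the upstream
  simulation; the package never applies fields, it only measures
  displacements.
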