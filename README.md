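# poreclog

Post-processing toolkit for molecular dynamics simulations of protein
nanopores used in single-molecule sensing, with α-Hemolysin (αHL) as the
motivating system.  When a peptide sits inside a nanopore it displaces
electrolyte and reduces the ionic current; the relative drop, the *current
blockage* ΔI/I₀ = (I₀ − I)/I₀, is the sensing signal.  `poreclog` measures
that blockage directly from trajectories and, more cheaply, predicts it
from equilibrium *pore clogging* — a quasi-1D conductance estimate built
from electrolyte occupancy maps.

## The model

**Occupancy map.** The simulation box is divided into cubic cells
(default 1 Å).  A cell is occupied in a frame if its center lies within a
Van der Waals radius of any water or ion atom.  Per-cell averages over
frames, normalized by a bulk region, give the map *M*.

**Through-channel filtering.** Electrolyte pockets near the constriction
do not carry trans-membrane current.  A cell belongs to the trans→cis
accessible pore iff an open path of face-adjacent cells with monotone
non-decreasing *z* connects the trans entrance slice to it (lateral moves
are free); cis→trans uses non-increasing *z*.  The filtered map *M̃* is
the intersection of both directions, which removes reentrant pockets while
keeping lateral lobes.

**Quasi-1D conductance.** The available cross-section per slice is
*A_z* = Σₓᵧ *M̃* ΔxΔy, and with constant electrolyte resistivity ρ the
pore resistance is *R̃* = Σᵢ ρΔz / *A_z,i* (access resistance neglected).
Pore clogging is

&nbsp;&nbsp;&nbsp;&nbsp;*b* = 1 − *R̃₀* / *R̃*,

with *R̃₀* the empty-pore value: *b* = 0 for an unobstructed pore, 1 at
full blockage.  A truncated variant starts the sum above the trans barrel
(default 20 Å), emulating a barrel-cut pore.

**Displacement current.** For each saved-frame window,
*I(t)* = 1/(Δt·L_z) Σᵢ qᵢ·[zᵢ(t+Δt) − zᵢ(t)] (minimum-image unwrapped,
reported in nA), with species decomposition (K⁺, Cl⁻), transient discard
and block-averaged errors.

A statistics layer relates *b* across homopeptides to amino-acid Van der
Waals volume, apparent volume, accessible surface area and
hydrophobicity class, and a synthetic-data module generates pore +
electrolyte fixtures (frozen wall spheres, Brownian or dense-lattice
electrolyte, concentric bead-chain obstructions) with analytic ground
truth for every stage.

## Worked example

Clogging of a synthetic 5 Å cylinder by a 2 Å bead chain threaded through
z = 10–40 Å:

```r
library(poreclog)

pore0 <- make_pore(pore_geometry("cylinder", radius = 5, length = 50))
fill  <- electrolyte_spec(n_water = Inf, placement = "lattice")
grid  <- grid_spec(origin = c(-13, -13, 0), dims = c(26, 26, 50))

st0   <- make_trajectory(pore0, fill, n_frames = 1)
map0  <- occupancy_map(st0$trajectory, grid = grid,
                       bulk_region = c(12, 15, 12, 15, 10, 40))
prof0 <- area_profile(accessible_channel(map0))
prof0
#> area_profile: 50 slices, z in [0.5, 49.5] A, dz = 1 A
#>   A: min 80.00, median 80.00, max 80.00 A^2

pore1 <- insert_obstruction(pore0, bead_radius = 2, z_range = c(10, 40))
st1   <- make_trajectory(pore1, fill, n_frames = 1)
map1  <- occupancy_map(st1$trajectory, grid = grid,
                       bulk_region = c(12, 15, 12, 15, 2, 8))
prof1 <- area_profile(accessible_channel(map1))

pore_clogging(prof1, prof0)
#> pore clogging: b = 0.0899  (R = 0.6868, R0 = 0.625)
```

The discretized area (80 Å² vs π·25 ≈ 78.5 Å²) and clogging (0.090 vs the
analytic annulus value 0.103) carry only the 1 Å grid-quantization error;
both converge under grid refinement.  The same fixtures exercise the
current module: twenty ±1e ions drifting at ±0.025 Å/ps through
L_z = 100 Å give I = 0.8011 nA, which `displacement_current()` reproduces
to machine precision.

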