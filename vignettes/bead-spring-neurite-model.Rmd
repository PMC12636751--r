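---
title: "A coarse-grained bead-spring model of neurite initiation mechanics"
author: "neuritesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained bead-spring model of neurite initiation mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritesim)
```

## The question the model addresses

A differentiating neuron must convert a round cell into one with long, thin
membrane projections (neurites).  Two mechanical quantities compete at the
cell surface: *cortical tension* — the adhesion of the plasma membrane to the
underlying actin cortex — and *membrane elasticity* — the membrane's own
resistance to shape change.  `neuritesim` implements a two-dimensional
coarse-grained bead-spring cell in which both quantities are explicit dials
(`U3` for the membrane–actin adhesion depth, `kappa00` for membrane bending
stiffness) and asks under which combinations growing actin filaments can
push the membrane into stable neurite-like protrusions.

The package's claim structure is deliberately qualitative: with the membrane
stiff (`kappa00 = 500`), low adhesion (`U3 = 3`) permits longer and more
persistent projections than high adhesion (`U3 = 30`); with the membrane
compliant (`kappa00 = 10`), the projection length is a *non-monotonic*
function of `U3`, maximal at intermediate adhesion.  Both claims are
recomputed from scratch by the test suite and by `scripts/acceptance.R`;
this vignette explains the model, the parameters, and the design decisions
behind them, and states nothing the code does not itself compute.

## Model geometry

A cell of `n_total = 700` beads (diameter `sigma = 1`, the length unit)
is assembled from:

* a **plasma membrane ring** of 240 beads (regular polygon, radius
  `240/(2*pi) ~ 38.2`, bond rest length = the polygon chord, so the built
  ring is unstressed unless `membrane_prestrain > 0`);
* a **nuclear envelope ring** of 110 beads (radius `~17.5`), built the same
  way;
* **14 radial actin filaments** of 25 beads each (24 shaft beads plus a
  terminal *head* bead), anchored by a spring to the nearest nuclear bead
  and ending with the head at `r_mem - 2^(1/6)*sigma`, i.e. exactly at the
  minimum of the membrane–actin adhesion well, so the nuclear envelope is
  mechanically connected to the membrane through the filaments from t = 0.

The partition 240 + 110 + 14×25 is a package choice; only the total n = 700
is fixed by the modeled system.  Earlier calibrations with 20 shorter
filaments showed a geometric artifact: with tips only ~12 σ apart on the
rim, unadhered filaments jam against each other laterally and push the
membrane collectively even at `U3 ~ 0`, erasing the low-adhesion regime.
Fourteen longer filaments leave room for an unattached tip to tilt and
glide off the membrane instead of pushing through it — which is precisely
the mechanical meaning of "no cortex–membrane attachment, no force
transmission".

## Energy terms

Four terms, each exposed as its own documented operation with energies and
analytic forces (`spring_energy_force()`, `bending_energy_force()`,
`attraction_energy_force()`, `excluded_volume_energy_force()`):

* **Bonds** (membrane, nuclear, filament, anchor): harmonic,
  `E = kappa/2 (r - r0)^2` with a single spring constant `kappa = 1000
  kT/sigma^2`.  The stiff value makes the membrane effectively inextensible,
  so protrusions must recruit contour length rather than stretch bonds, and
  keeps strong adhesion (`U3 = 30`) from stretching membrane bonds past the
  3× rupture guard (which a `kappa` of 100 did not).
* **Bending**: `E = kappa_b (1 - cos(theta - theta0))` at every consecutive
  bead triple of both rings and of each filament, with `theta0 = pi`
  everywhere (straight/flat preferred; for `theta0 = pi` the discrete form
  is orientation-independent).  `kappa00` is the membrane value — this is
  the package's reading of "membrane elastic constant": resistance to shape
  deformation, carried by curvature, not by stretch.  The nuclear ring
  defaults to the same value; filaments use `kappa_fil = 5 kT` — a
  deliberately floppy value at which a bare filament buckles under roughly
  0.1 kT/σ of tip load, so an unattached filament cannot push the membrane.
  That is the mechanical basis of the low-adhesion regime: force
  transmission from cytoskeleton to membrane requires the tip to adhere,
  and an adhered tip is held at both ends (nuclear anchor and membrane)
  and passes its terminal-bond growth directly to the membrane.  The
  microtubule flag `mt_fraction` multiplies the filament stiffness by 20
  for a chosen fraction of filaments and defaults to 0.
* **Membrane–actin adhesion** (cortical tension, `U3`): a WCA repulsive
  core of fixed strength `eps_rep = 1 kT` plus an attractive tail of depth
  `U3` — flat below the minimum at `2^(1/6) sigma`, Lennard-Jones-shaped
  out to `r_cut_attr = 2.5 sigma`, shifted to vanish continuously at the
  cutoff.  Splitting core from tail keeps excluded volume active at
  `U3 = 0` and makes the reference values 3.0 and 30.0 map directly onto well
  depth in kT.  By default only the filament *head* beads adhere
  (`attract_heads_only = TRUE`); with shaft beads adhering too the membrane
  wraps the sparse filament spokes into a star shape whose inward folds the
  radial-excess morphometric misreads as projections (see *Limitations*).
* **Excluded volume**: WCA repulsion between all other non-bonded pairs.
  Directly bonded pairs are excluded from non-bonded terms.

`total_energy()` returns the per-term breakdown; `total_forces()` the
per-bead force matrix.  Both can run either through the cell-list
accelerated pair enumeration or a brute-force O(n²) path, and the test
suite asserts their equality to 1e-10 as well as force = −∇E by central
differences.

## Dynamics

Beads follow overdamped (position-)Langevin dynamics integrated with
first-order Euler–Maruyama:

x(t+dt) = x(t) + F/γ·dt + √(2 kT dt/γ)·ξ,  ξ ~ N(0,1) per coordinate.

Cells at this scale are inertia-free, so the overdamped limit is the
simplest thermodynamically consistent choice; the integrator sits behind
`step_overdamped()` so it can be swapped.  Reduced units: `sigma = kT =
gamma = 1`; the time unit is the diffusion time of one bead across its own
diameter, and `D = kT/gamma = 1` (checked against the Einstein relation in
the tests).

**Timestep.** `dt = 1e-4`.  The stiffest modes set the ceiling: the zigzag
bending mode of a discrete ring has an effective per-coordinate stiffness
of roughly `16*kappa00/b^2` (`8000` at `kappa00 = 500`), and the adhesion
well curvature is `~57*U3` (`1710` at `U3 = 30`); `dt = 1e-4` keeps
`k*dt <= 0.8` for every term, and the energy-monotonicity test at `kT = 0`
plus the dt-halving test bound the integration error.  A run aborts with a
"numerical instability" error naming the step and bead if positions become
non-finite or a membrane bond stretches beyond 3× its rest length.

**Filament growth.** Polymerization is modeled as rest-length growth of the
terminal (head-adjacent) bond: independently per filament and per step,
with probability `growth_rate = 0.0035`, that bond's rest length grows by
`growth_increment = 0.05 sigma`, capped so a filament's total rest length
never exceeds `max_filament_length = 36 sigma`.  Bead count is therefore
conserved in every frame (the canonical n = 700 holds throughout).  Growth
speed ~`growth_rate*growth_increment/dt = 1.75 sigma` per time unit fills
the `+17 sigma` growth budget about a third of the way through the default
horizon, leaving time for the membrane to answer.

**Schedule.** Default `n_steps = 1.5e5` (`T = 15` time units),
`record_every = 5000` (31 frames).  These are the study conditions of the
shipped claims: long enough for unattached tips to glide off, for transient
low-adhesion tents to collapse, and — at stiff membranes — for gently
adhered tips to migrate along the membrane and merge their bumps, which is
what separates the low- from the high-adhesion regime there; short enough
that a default run completes in seconds on one CPU.  Recording sparsely
matters for the summary statistic: the headline quantity is the *maximum
over frames* of the projection length, and dense sampling of a fluctuating
outline rewards transient spikes rather than persistent projections.

**Seeding.** The dynamics loop owns a counter-seeded xoshiro256++ generator
derived from `params$seed`, so a trajectory is a pure function of its
parameters: same params + seed → bitwise-identical trajectories, and sweep
replicates are identical whether run one at a time or inside a sweep.  The
initial symmetry-breaking perturbation (`init_noise = 0.05 sigma` Gaussian
displacement) uses R's RNG under the same seed.

## Morphometrics

All outline measures work on the membrane beads in ring order (recovered by
walking the membrane bonds, so bead numbering is irrelevant) and are
invariant under rigid motions:

* `projection_length()`: max radial distance from the membrane centroid
  minus the *median* radial distance (the robust baseline; a single long
  neurite cannot inflate its own baseline), floored at zero.  This is the
  package's operationalization of "projection length" for simulated
  outlines — the source figures do not define one.
* `count_protrusions()`: maximal contiguous arcs with radial excess above a
  threshold, with circular wrap-around handled.
* `circularity()`: `4*pi*A/P^2` of the membrane polygon (shoelace area),
  `(pi/N)/tan(pi/N)` for a regular N-gon, decreasing with protrusions.
* `protrusion_stability()`: the fraction of late-window frames (default:
  final 25%) carrying at least one protrusion of at least threshold length.

The default detection threshold in `analyze_trajectory()` is half the
baseline radius (~19 σ for the default cell) — a conservative "unambiguous
neurite" scale.  The sweep functions default to an absolute threshold of
2 σ of radial excess, which detects neurite-scale protrusions while
ignoring thermal roughness of the outline (~0.5 σ); both are arguments,
not constants.

One subtlety is recorded here deliberately: for a circle with a single bead
displaced by d, the projection length is d only up to O(d/n), because the
displaced bead also shifts the mean centroid.  A coordinate-wise median
centre would fix that example but is not rotation-equivariant, which would
break rigid-motion invariance — the invariance was kept and the example is
tested at tolerance 2/n.

## Experiments and replication

`sweep_u3()` and `phase_diagram()` run seeded replicate batteries over
conditions.  Replicate seeds are `seed0 + (condition_index-1)*1e4 +
replicate`, collision-free below 1e4 replicates, so any replicate can be
reproduced in isolation.  Replicates that abort on the instability guard
are recorded as failed, warned about, and excluded from summaries (mean,
SD, SEM = SD/√n); a condition losing all replicates is an error.  Per-
replicate tidy tables and per-condition summaries are exportable
(`write_sweep()`), so any downstream statistics package can run the
formal tests; the package itself deliberately stops at descriptive
summaries.

The two shipped claims are encoded as acceptance tests with fixed master
seeds and n = 10 replicates per condition:

* `kappa00 = 500`, `U3 in {3, 30}`: mean max projection length at `U3 = 3`
  strictly exceeds that at `U3 = 30`, and mean stability is at least as
  high.  The shipped test re-runs this battery for three fixed master
  seeds (60 simulations, a practical test-suite runtime) and requires the
  ordering in at least two of the three; `scripts/acceptance.R` reports
  the underlying means for one seed.
* `kappa00 = 10`, `U3 in {1, 3, 10, 17.3, 30}` (log-spaced, containing 3.0
  and 30.0): the grid point maximizing mean max projection length is
  interior and exceeds both endpoints.

## What the generator emulates — and what it does not

The synthetic cell is the *model organism* here: a single adherent-free 2-D
cell with a fixed membrane reservoir, a rigid bead budget, and
polymerization represented by rest-length growth at 14 tips.  Passing tests
show that the implemented mechanics reproduce the claimed qualitative
dependence of protrusion on the two tension dials *within this model*.
They do not show anything about real neurons: there is no membrane area
exchange (exo/endocytosis), no actin turnover or branching, no myosin
contractility as a separate agent (cortical tension is collapsed into the
adhesion depth), no substrate, no 3-D membrane mechanics, and the
microtubule flag defaults to off.  The 2-D choice follows the planar
morphologies the model is meant to produce and keeps n = 700 meaningful as
a single closed membrane ring.

## Numerical choices and edge cases

* Neighbor lists: cell-list construction with a 0.3 σ Verlet skin, rebuilt
  when any bead has moved more than half the skin; attraction-capable pairs
  are listed out to `r_cut + skin`, all others only to the WCA contact
  distance + skin.  Equality with the O(n²) path is asserted to 1e-10.
* Degenerate geometry (coincident beads in a bond, angle, or pair) raises
  an error rather than producing NaN forces.
* The bending force is computed from cached `cos/sin(theta0)` and the
  signed vertex angle via cross/dot products — no `atan2`, no
  small-`sin(theta)` singularity.
* Angles `theta0` are validated to (0, 2π); at `theta0 = pi` (the only
  value the builder emits) the energy is orientation-independent.
* The self-intersection check in `circularity()` warns and still returns
  the shoelace value, as re-entrant outlines do occur transiently in
  strongly adhering regimes.
* Text trajectory format: versioned header + per-frame blocks with %.17g
  doubles — lossless round trip, byte-deterministic writes, digest-checked
  parameters, and a reader that rejects rather than repairs malformed
  files.  A structured text container was preferred over a binary one for
  portability and inspectability; extended-XYZ export (z padded to 0) is
  provided for visualization tools.

## Parameter summary

```{r params}
print(sim_params())
```

| Parameter | Default | Units | Why |
|---|---|---|---|
| `U3` | 3 | kT | adhesion depth; the shipped sweeps vary it 1–30 |
| `kappa00` | 10 | kT | membrane bending stiffness (compliant regime) |
| `kappa` | 1000 | kT/σ² | near-inextensible bonds; survives U3 = 30 adhesion |
| `kappa_fil` | 5 | kT | floppy filaments: thrust requires tip adhesion |
| `dt` | 1e-4 | τ | stability margin for the stiffest modes at κ00 = 500 |
| `n_steps` | 1.5e5 | — | T = 15 τ assay horizon |
| `growth_rate` | 0.0035 | /step | fills the growth budget mid-horizon |
| `max_filament_length` | 36 | σ | ~+17 σ growth budget per filament |
| `membrane_prestrain` | 0 | — | optional resting membrane tension |
| `attract_heads_only` | TRUE | — | adhesion acts at filament tips (see above) |

## Known limitations

* The U3 axis is calibrated, not derived: the mapping from adhesion depth
  to protrusion behavior depends on filament stiffness, growth speed, and
  the assay horizon, and the defaults were chosen (once) so that the
  qualitative orderings hold under the default schedule.  Other schedules
  need their own calibration.
* Above `U3 ~ 30` with all-actin adhesion the membrane can wrap the
  filament spokes; the median-baseline projection length then rises for
  reasons unrelated to neurite extension.  The heads-only default avoids
  this, but the all-actin option should be analyzed with circularity and
  renders alongside the scalar morphometrics.
* `mt_fraction > 0` multiplies filament bending stiffness by 20, which
  tightens the stable-timestep ceiling roughly in proportion; reduce `dt`
  accordingly.
* Growth is load-independent (no polymerization stall force); the cap on
  filament length is the only brake, which is one reason strong adhesion
  regimes can accumulate large internal stresses.
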