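---
title: "Predicting helix structures from density-map skeletons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting helix structures from density-map skeletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hxskel)
```

## The problem

Electron cryo-microscopy maps at 6-10 Å resolution do not resolve a
protein backbone, but the rod-like density of α-helices can be detected
and summarised as *skeletons*: polylines tracing each helix axis, in
Ångström coordinates, with no information about which part of the
sequence they correspond to or which way the chain runs through them.
Independently, secondary-structure prediction (SSP) on the sequence
yields approximate helix segments.

`hxskel` predicts ranked three-dimensional structures for the helical
part of the chain from these two inputs alone, without constructing
loops. The search space is the set of *topologies*: ordered assignments
of sequence helix segments to skeletons, each with an N→C direction.
With `K` skeletons and `N ≥ K` predicted segments there are

$$\frac{N!}{(N-K)!}\,2^K$$

topologies. The pipeline (a) enumerates this space, (b) removes
topologies whose implied loops or lengths are geometrically impossible,
(c) for each survivor samples rigid placements of ideal helices on the
skeleton axes by simulated annealing under a contact energy, and
(d) ranks the pooled structures by that energy, lower being better.

## Screening

Two screens prune the topology space before any structure is built.

**Length screen.** A skeleton of axis length $L$ is estimated to hold
`round(L / rise) + 1` residues with `rise = 1.3` Å per residue. A
skeleton and a segment are compatible when their residue counts differ
by at most 50% of the skeleton's count (boundary inclusive). The 1.3 Å
constant is an empirical stick-length-to-residue calibration: detected
sticks end where helix density tapers, so they are shorter than the
geometric helix rise of ~1.5 Å per residue would suggest. Both constants
appear in the package — 1.3 Å for length estimation
(`screening_params()`), ~1.5 Å as the measured rise of the constructed
ideal helix — and they are deliberately independent parameters.
The `+ 1` fence-post convention (a 2-residue helix spans one rise) is
ours and can be disabled (`endpoint_convention = FALSE`).

**Distance screen.** For sequence-consecutive segments assigned to two
skeletons, the gap `d` between the C-terminal axis end of the earlier
helix and the N-terminal axis end of the later one (ends chosen per the
assigned directions) must be spannable by the loop: a topology is
eliminated iff `d > 3.8 · (n_loop + 2·s_max)` for any pair, with
`n_loop` the number of residues strictly between the segments and
`s_max = 2` the maximum window shift. We measure `d` between *axis*
endpoints rather than constructed backbone atoms; this keeps the screen
independent of the rotational placement parameters and is conservative
by about one helix radius (~2.3 Å). The inequality is strict: a loop
exactly at the limit is retained.

## Backbone construction and placement

For each skeleton an ideal straight helix is built from internal
coordinates with torsions φ = −60°, ψ = −50°, ω = 180° and standard
trans-peptide bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å;
angles 111.2°, 116.2°, 121.7°; these covalent values are a conventional
choice, configurable via `helix_geometry()`). The helix is expressed in
a canonical frame — axis along +z, first Cα at azimuth zero — and then
rigidly mapped onto the least-squares line through the skeleton
polyline. A placement is parameterised per skeleton by

* `s`: an integer shift (±2 by default) of the assigned sequence window
  against the segment centre, modelling SSP boundary error;
* `θ`: rotation about the helix axis (the azimuth reference is the world
  +x axis projected perpendicular to the axis, fixed so seeds reproduce);
* `t`: translation along the axis, 0 by default (sampling it is
  optional, matching the common simplification for rod-like density).

The assigned window has the *skeleton's* estimated residue count,
centred at the segment centre plus `s` (for even windows the centre is
the left-of-centre residue); windows sticking out past the sequence are
slid back in, and a slide larger than `s_max` invalidates the placement.

A note on axis fitting: the principal axis of a finite helical point
cloud is biased by partial turns, so `helix_axis()` recovers the axis of
a Cα trace exactly (direction from chord second differences, position
from an in-plane circle fit); the straight-line fit `fit_axis_line()` is
used for skeleton polylines, which are near-straight by construction.

## Side chains

Side chains exist in the model only to give each residue a centroid for
the contact energy. The shipped rotamer set
(`inst/extdata/rotamers.tsv`) is deliberately coarse: idealised
side-chain geometry with 1-3 conformations per residue type, defined in
the local N/CA/C backbone frame. Attachment is greedy and deterministic:
residues in sequence order, each taking the rotamer with the fewest
heavy-atom clashes (< 2.8 Å) against atoms already placed, ties going to
library order. Inside the annealing loop the first rotamer is attached
rigidly without a clash search; since the energy depends only on
centroids, and rotamers of one residue differ little in centroid
position, ranking is insensitive to this approximation. Side-chain
conformations are not re-optimised during annealing.

## Contact energy

Structures are scored with a multi-well, pairwise, helix-only contact
energy over residue pairs on *different* helices (within-helix pairs are
constant across placements of the same window and are excluded):

* if any of the 16 backbone atom pairs of residues *i, j* is closer than
  `r_core = 3` Å the pair contributes `+10` (clash penalty);
* otherwise the side-chain centroid distance `d` contributes `−ε` for
  `4 ≤ d < 8` Å, `−ε/2` for `8 ≤ d < 10` Å, and nothing beyond;
* `ε` depends on the residue classes (hydrophobic: AVLIMFWC; charged:
  DEKRH; polar: the rest), with depths H–H 2.0, H–P 0.5, H–C 0.3,
  P–P 0.2, P–C 0.2, C–C 0.1.

All constants live in `energy_params()` and the `[energy]` section of
the YAML config, so a different depth table (for example a 20×20
statistical potential) can be dropped in without code changes. This
functional form is a parameterised effective potential: it preserves the
properties that matter for ranking helix packings (pairwise, distance-
binned, contact-based, hydrophobic-core favouring); absolute energy
values are not comparable to any published potential.

## Simulated annealing and ranking

Each valid topology receives `samples` independent annealing runs
(defaults: 500; the acceptance experiments below use 100). A run starts
from a uniform random valid shift and uniform θ, then performs Metropolis
moves — one skeleton at a time, perturbing `s` by ±1, θ by a Gaussian
step of 20°, or (if enabled) `t` by 0.5 Å — under a geometric cooling
schedule. The schedule defaults (`T0 = 2`, `α = 0.95`,
`steps_per_T = 30`, `T_min = 0.02`) were calibrated on the synthetic
bundles: a typical proposal changes the energy by 0.3-3 units, so
temperatures above ~2 are free diffusion and add nothing, while the
terminal temperature makes uphill acceptance negligible — the run ends
in a quench. Moves whose shifted window would leave the sequence are
rejected, as are shift moves that would make two helices' windows claim
the same residue (the same conflict principle applied when combining
regions, enforced monotonically within a topology).

Determinism is a contract: run *r* of topology *i* under master seed *q*
uses an RNG seeded by a fixed mix of (q, i, r) (splitmix64), so the
pool is bit-identical for any worker count; `workers > 1` only
distributes topologies over forked processes.

The pool is sorted ascending by energy (stable; ties by topology
enumeration order, then sample index), percentiles are reported as
`100·rank/pool_size` rounded to two decimals, and two independently
predicted local regions can be combined lazily: candidate pairs are the
Cartesian product ranked by summed energy (a k-smallest-sums walk, the
product is never materialised), dropping pairs whose regions claim a
common sequence residue. Summed energy is the minimal consistent
choice for comparing pairs built from independently scored halves.

## The synthetic bundle generator

`make_bundle()` produces desk-scale inputs with known ground truth: an
up-down bundle of ideal helices on a circle of axes ~10 Å apart,
consecutive helices antiparallel, connected by 3-8 residue loops, with
3 polar padding residues at each terminus. Sequence design follows a
coiled-coil logic: a residue is hydrophobic iff its side chain points
within 65° of the bundle core in the native placement (the heptad a/d
positions plus their natural wobble subtend roughly this sector),
hydrophobic letters drawn from LVIFM, the rest from polar/charged
pools. Helix lengths are drawn spread across 8-20
residues (evenly spaced targets with ±1 jitter, shuffled): real helical
proteins mix short and long helices, and the spread is what makes the
length screen informative — near-equal lengths leave the topology space
permutation-degenerate for any class-level energy. Skeleton sticks are
emitted at 1.3 Å per residue of their helix, consistent with the
calibration the length-estimation constant implies. Helix midpoints are
axially aligned by default (`stagger = 0`); non-zero stagger makes
bundles look more like real proteins, but under a purely pairwise
contact score it rewards compensating non-native window shifts, so it
is off for the recovery experiments. Optional per-point skeleton noise,
per-segment reported-boundary error, and dropping the shortest helix
(K < N) emulate the main imperfections of real detection and SSP.

What the generator does *not* emulate: curved or kinked helices,
β-strands, irregular (non-ideal) backbone torsions, density-map noise
artefacts, and sequence idiosyncrasy beyond the three-class
hydrophobicity pattern. Passing the recovery experiments therefore
shows that the pipeline recovers topology and registration when its
model assumptions hold, not that it reaches any particular accuracy on
real maps.

## Scale of the shipped experiments

The test suite runs the full pipeline on ten seeded three-helix bundles
at 100 annealing runs per valid topology
— pools of one to a few thousand structures per bundle — which keeps
the whole suite in the minutes range on a single core while still
exercising enumeration, screening, annealing, ranking and RMSD
end-to-end. The same experiment asks that the ground-truth topology
survive screening on all ten bundles and that its best structure rank
in the top 5% of the pool with a no-superposition backbone RMSD below
2 Å on at least eight.

## Numerical choices and degenerate inputs

* Topology enumeration order is fixed (lexicographic segment tuples,
  directions counting − before +, first skeleton most significant), so
  ties and seeds reproduce.
* Counts use double arithmetic, exact below 2^53 — far beyond any
  realistic topology space; a warning fires past that.
* RMSD defaults to the shared map frame (no superposition), because
  predicted and reference structures live in the same density-map
  coordinates; `superpose = TRUE` applies the optimal (SVD)
  superposition.
* Skeletons with fewer than 2 points, coincident consecutive points,
  non-helix segment types, overlapping segments and out-of-range indices
  are rejected loudly at parse time.
* A single-helix model has energy 0 by definition (no inter-helix
  pairs).
* `helix_axis()` needs ≥ 4 points and falls back to the straight-line
  fit below that, so 2-3 residue fragments still place, just without
  the partial-turn correction.

## Known limitations

Loops are never built, so models contain only helix residues and the
energy never sees loop strain beyond the distance screen. The
straight-helix model cannot follow curved density rods (the axis fit
straightens them). Direction discrimination is intrinsically weak for
near-periodic hydrophobic patterns: reversing an ideal helix mirrors
its stripe into a pattern that a free azimuth can almost re-fit, so
direction variants of the correct assignment often score within a few
energy units of it — consistent with the observation that correct
topologies rank near, not at, the top of energy-sorted pools.

Axial registration is likewise weakly determined. The square wells
tolerate axial offsets of several Ångström before a pair changes bins,
and at the bin edges the landscape is ragged: among the integer window
shifts (and, when enabled, the bounded axial translation) the
energy-minimising placement of even the correct topology can sit a
whole residue away from the native registration, while unshifted
placements of the same topology lie much closer to it. This is a
property of step-well contact scores, not of the sampler — it shows up
as a gap between the energy-best and the RMSD-best structures of the
correct topology, and it bounds the backbone accuracy obtainable by
energy ranking alone at roughly one residue of axial slack. Density-map cross-correlation or smooth distance-dependent
potentials would be the natural remedies; both are out of scope here.
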