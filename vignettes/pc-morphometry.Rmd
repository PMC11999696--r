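---
title: "Purkinje cell morphometry: measurement conventions, classifiers and clustering statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purkinje cell morphometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmorph)
```

This vignette documents the measurement model behind `pcmorph`: what each
quantity means, which conventions were open choices and why we fixed them
the way we did, what the synthetic-data generators do and do not emulate,
and the numerical details (tolerances, tie-breaks, degenerate inputs) a
careful user should know.

## The measurement model

### Reconstructions and coordinates

The unit of morphometry is an `arbor`: a rooted tree of 3-D nodes with
radii, read from standard 7-column SWC (`read_swc()`). Units are
micrometers throughout. Coordinates are treated as parasagittal-plane
dominant: `x` runs anterior–posterior along the Purkinje cell (PC) layer,
`y` is radial depth from soma toward the pia, `z` is mediolateral. This
matches how parasagittal cerebellar sections are imaged; an alternative
mapping can be declared on the `arbor` object. Soma nodes may form a ring
(multiple soma nodes are accepted if they are a contiguous subtree
containing the root); structure codes 1/2/3 map to soma/axon/dendrite and
anything else becomes `unspecified`. No shrinkage factor or z-correction
is applied by default; `read_swc(scale_z =)` is the hook for users who
need one.

### Branch segments and orders

`decompose_branches()` cuts the dendritic tree into maximal paths between
branch points and tips. Each dendritic edge belongs to the segment of its
child node, so segment lengths partition total dendritic length *exactly*
(this is asserted in the tests, not just approximately). Orders are
centrifugal: every trunk — a dendrite emerging from the soma — is order 1,
and children of a branch point get the parent's order plus one. Soma and
axon material never contribute length.

### Eccentricity

Branch eccentricity is the angle of a segment relative to the PC-layer
plane. Every branch is translated so its origin (the branch point or soma
it emerges from) sits at (0, 0); vertices with negative mean radial
displacement are mirrored over the horizontal axis and those with
negative mean parasagittal displacement over the vertical axis, so that
direction is discarded but the angle from the layer is kept. The slope is
the through-origin least-squares fit $b = \sum xy / \sum x^2$ and the
eccentricity $\arctan b$, clamped to $[0°, 90°]$, with purely vertical
segments assigned 90°.

Two conventions here were genuinely open and we fixed them as follows.
First, because the branch start is translated to the origin, a
through-origin fit is the natural regression; an ordinary
least-squares-with-intercept variant is available via
`branch_eccentricity(intercept = TRUE)` for sensitivity analysis. Second,
"projecting downward/leftward" is decided by the *mean* vertex
displacement, which is robust to local wiggle in traced branches, rather
than by the endpoint alone. Degenerate segments whose vertices all
coincide return `NA` and are excluded from aggregates.

### Extent, shape, and regions

Width is the parasagittal extent over dendrite nodes and height the
radial extent, measured on raw coordinates with no rotation or alignment
of the arbor (alignment would inject an analysis choice the data do not
support). The shape index is $+100\,(W/H - 1)$ when $W \ge H$ and
$-100\,(H/W - 1)$ otherwise, so positive values mean wider-than-tall.

Segments are assigned to proximal / intermediate / distal thirds of the
molecular-layer thickness by the radial position of their arc-length
midpoint. When the thickness is not recorded, the measured arbor height
is the proxy. Bins close on their upper edge (a midpoint exactly at one
third is proximal); midpoints above the nominal thickness are clamped to
distal with a warning rather than dropped.

### Caliber and the thin threshold

Segment mean diameter is the length-weighted mean of node diameters
(2 × radius). The thin-caliber threshold is
$\exp(\overline{\ln d} + s_{\ln d})$ over a pool of *segment mean*
diameters — segment means rather than node-wise diameters, because the
segment is the unit all other caliber statistics use. Pooling both
species' segments reproduces the published cross-species threshold scale
(≈1.3 µm); the threshold can also be passed directly. Zero or negative
diameters are excluded from the log statistics with a warning. The
primary dendrite diameter is the largest node diameter on order-1
segments within two soma diameters of the soma centroid.

### Sholl profiles

"Centrifugal" Sholl distance is the 3-D Euclidean radius from the soma
centroid (shells, not path distance); a path-distance variant is exposed
as `sholl_profile(mode = "path")` because both readings occur in the
field. Each edge is subdivided into pieces of at most 0.25 µm assigned to
the shell containing their midpoint. Length is therefore conserved
exactly by construction (every piece lands in some shell); the published
0.5% conservation bound is a free consequence. A branch is counted in
every shell its path intersects. The cumulative profile is monotone and
ends at 1.

## Spine taxonomy and statistics

Spines are classified by `classify_spine()`: two heads on a shared neck →
`branched`; a single head with ≥3 distinct puncta → `cluster`; otherwise
`thin` below 0.5 µm head diameter and `mushroom` at or above. The 0.5 µm
boundary is assigned to mushroom — the defining description ("less than
or greater than 500 nm") leaves the boundary open, so we close it on the
right and assert that choice in a test. Branched spines count once in
densities (one spine, two heads); per-head counts remain in the records
so synapse extrapolations can weight them.

Head volume defaults to a sphere, $(\pi/6)d^3$; measured volumes (as
reported for spine clusters) may be supplied directly. The
spine-to-surround volume fraction divides summed head volumes by the
annular cylinder between the dendrite surface (mean radius $r$) and the
spine reach ($r + p$, $p$ the mean protrusion distance):
$100\,\Sigma V / (\pi L((r+p)^2 - r^2))$. A branch with spines but zero
mean protrusion is a degenerate shell and errors rather than returning
infinity. The Rayleigh helper $R = 0.61\lambda/\mathrm{NA}$ gives the
resolution floor against which head diameters should be interpreted
(241.8 nm for 555 nm excitation at NA 1.4).

## Cell classifiers

`classify_morphology()` implements the three primary-dendrite classes.
Poly: more than one trunk, regardless of relative size. Split: a single
trunk that bifurcates within the bifurcation window *and* either
symmetrically or with the smaller daughter projecting beyond the
minor-branch threshold. Normative: everything else. The window is two
measured soma diameters in human (somata 25–35 µm) and a fixed 40 µm in
mouse; minor-branch thresholds are 200 µm (human) and 100 µm (mouse).
"Symmetric" is accepted as a supplied flag because it is a visual call in
practice; for automated pipelines a numeric daughter-diameter ratio
(default ≥ 0.75) can be passed instead and is documented as an extension,
not part of the core rule. The geometric reference point for the
minor-branch projection ("distance from the main dendritic compartment")
is not defined anywhere authoritative; we interpret it as parasagittal
distance from the larger daughter's subtree and expect callers to supply
the measured value.

`classify_orientation()` applies only to Split and Poly cells (calling it
on a Normative cell is an error, since those cells have one compartment
and no orientation). Horizontal requires a single dendrite ramifying
parallel with the layer for >300 µm (human; >150 µm mouse) or an opposing
pair at >150 µm each (>75 µm mouse), where "parallel" means <30° from
the layer plane at the run-length threshold, measured as the chord angle
of the soma-to-threshold-point vector.

`classify_foliar()` compares pial length to the granule-layer/white-matter
border length: longer pial surface → Gyrus, shorter → Sulcus, equal →
Bank. Because "equal" on traced outlines is qualitative, a relative
tolerance (default 5%) defines the Bank band and is configurable.

## Spatial clustering statistics

### Adjacency scores and runs

Along the anterior–posterior order of one slice, each cell starts at
score −1 (isolated). If an immediately adjacent cell lies within the
species threshold (1000 µm human, 200 µm mouse — roughly the scale at
which dendritic fields can overlap), the score becomes 0, and each
within-threshold adjacent cell with a matching class adds +1. The
complete match uses five classes (Normative, V-Split, H-Split, V-Poly,
H-Poly); `type_only` and `orientation_only` are the liberal variants. In
`orientation_only` mode Normative cells, which carry no orientation,
match only other Normative cells — the least assuming reading of an
undefined case.

Runs are maximal stretches in which *every* adjacent pair is within
threshold and matching; a sub-threshold gap terminates a run even between
matching cells. Run length is the summed consecutive Euclidean
inter-somatic distance.

### Permutation nulls

The null holds every cell's position and foliar label fixed and permutes
the (morphology, orientation) labels without replacement — a seeded
Fisher–Yates shuffle, so the label multiset is conserved exactly and the
same seed always reproduces the same permutation sequence (both
properties are asserted in tests). `within_foliar` mode permutes within
each foliar stratum instead, which removes any clustering attributable to
foliation. The clustering excess is the observed share of cells with
score ≥ 1 minus the shuffled mean of the same share, in percentage
points. The denominator is cells with score ≥ 0; whether isolated
(score −1) cells belong in the denominator is unspecified in the source
procedure, so the alternative is available behind
`include_isolated = TRUE`.

### Population and shell profiles

`population_match_profile()` tallies, for each cell, the class
composition of all cells within a radius (excluding the focal cell), and
averages compositions per focal class; the shuffled-mean composition is
subtracted. Per-class elevations are then averaged — *unweighted* across
the five classes, since a per-cell weighting would let the most common
class dominate exactly the comparison the statistic is meant to balance.
The matching summary is the mean diagonal elevation, the nonmatching
summary the mean off-diagonal. Because each cell's composition sums to 1
in both observed and shuffled data, the class-frequency-weighted
elevations sum to zero; this conservation identity is tested to numerical
tolerance.

`shell_match_profile()` restricts the tally to an annulus
$[kw, (k+1)w)$, ignoring the core of more local cells, which isolates
clustering at distance from the strong local signal. The human shell
width defaults to 500 µm and the mouse to 100 µm — 20% of the human
value, matching the species ratio of dendritic widths. Cells whose shell
is empty are excluded from that shell's average; cells near the slice
edge keep their one-sided tally rather than being dropped.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure the analysis
assumes, calibrated to the published cohort means stored in
`species_preset()`.

**Cell maps** (`simulate_cell_map()`): positions accumulate from positive
spacing draws (defaults 300 ± 100 µm human, 30 ± 10 µm mouse — inside the
adjacency threshold, so consecutive cells are usually adjacent, as in
real maps); the label of cell $i$ copies cell $i-1$ with probability
$\kappa$ and is otherwise drawn from the configured class frequencies.
First-order Markov copying was chosen as the clustering mechanism because
it is analytically tractable — the expected run length is
$1/(1 - p_\text{match})$ with
$p_\text{match} = \kappa + (1-\kappa)\sum_c f_c^2$ — and reproduces
published run-size phenomenology (means around 2.6–3.1 cells) at
$\kappa \approx 0.3$–$0.5$. $\kappa = 1$ is rejected as degenerate. The
default class frequencies (10% Normative, 45% Split, 45% Poly, split
between orientations) reflect a human posterior-region-like mixture;
they are a modeling choice, not a measured table. Foliar labels follow an
alternating gyrus/bank/sulcus segmentation by position.

**Arbors** (`simulate_arbor()`): the branch-segment count is drawn from
the cohort distribution (2750 ± 247 human, 707 ± 118 mouse) and the
topology built by bifurcating a uniformly random open tip until the drawn
count is reached; segment lengths are gamma draws whose mean is the
cohort total length divided by the cohort branch count, so the expected
total dendritic length equals the cohort target (63,645 µm human,
6,004 µm mouse) by construction. We deliberately do *not* drive growth by
a per-length bifurcation probability: near the branch counts required,
such a branching process sits close to criticality and its segment-count
distribution is far too heavy-tailed to calibrate a cohort mean. Node
steps have exact lengths and growth is steered (direction reflection,
never truncation) to stay below the molecular-layer height cap, so the
emitted geometry equals the bookkeeping totals exactly — the tests
compare `total_length()` on the emitted tree to the generator's ledger
with `tolerance = 1e-9`.

**Spiny branches** (`simulate_spiny_branch()`): per-type counts are
Poisson at the preset densities (human: 5.37 thin, 0.49 mushroom, 0.42
branched, 0.52 cluster per µm; mouse: 4.56/0.13/0.49 and *zero* clusters,
modeling their effective absence in mouse); attributes are truncated
normals consistent with the classification rules, and cluster head
diameter scales linearly with puncta count.

What the generators do **not** emulate: truncation of arbors at slice
boundaries, tracing errors, anisotropic optical blur, within-cell spatial
correlation of spine types, foliation-driven arbor deformation, and any
correlation between a cell's morphology class and its arbor geometry.
Passing recovery tests on synthetic data therefore demonstrates that the
*pipeline* measures what the generators encode — it does not validate the
biological conclusions on real tissue, for which the deposited
reconstructions remain the reference.

## Problem sizes and numerical choices

The test and acceptance workloads use 30 simulated human arbors for
cohort length recovery (5% band), 50 branches of 30 µm for density
recovery (3 SEM band), 200 maps of 500 cells for null calibration of the
clustering excess (3 SE band around zero), 100 maps of ≤30 cells for
exact brute-force equivalence of the clustering statistics, and 50-rep
averages over $\kappa \in \{0, 0.2, 0.4, 0.6, 0.8\}$ for monotonicity
(rank correlation must be exactly 1). These sizes keep each property
statistically sharp while completing in minutes on a single CPU, and are
stated here so users scaling them up know the calibration points.

Numerical details worth knowing: Sholl shell indices are
`ceiling(r / step)`, so a radius exactly on a shell boundary belongs to
the inner shell; eccentricity clamps tiny negative fitted slopes to 0°;
`arbor()` validation requires parents to be declared before children,
which structurally rules out cycles and yields a named error for orphans;
the permutation p-value in `pc_clustering()` uses the (+1)/(n+1)
correction; and all CSV/JSON writers emit plain text so results diff
cleanly under version control.

## Known limitations

- The clustering analysis is strictly 1-D along the layer; mediolateral
  structure is out of scope.
- Orientation and morphology classification consume *measured* features
  (`pc_features()`); the package does not extract those features from raw
  images or decide symmetry visually.
- Head diameters near the diffraction limit (≈242 nm for Cy3/NA 1.4)
  should be read as relative, not absolute; the package reports them as
  given.
- The arbor generator targets cohort-level length and branch-count
  distributions, not per-cell realism of higher-order statistics
  (eccentricity profiles, fractal branching symmetry).
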