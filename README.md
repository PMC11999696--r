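# pcmorph

Comparative morphometrics for cerebellar Purkinje cells (PCs). The package
quantifies single-neuron dendritic reconstructions, classifies dendritic
spines and whole cells by rule-based criteria, and tests whether PC
morphological subtypes cluster spatially along the Purkinje cell layer —
the analysis chain used to compare adult human and mouse PCs, where human
cells are roughly 11× longer (≈64,000 vs ≈6,000 µm of dendrite), denser in
spines (≈6.8 vs ≈5.1 per µm) and far more often multi-branched.

It is written for anatomists and quantitative neuroscientists who have
SWC-style reconstructions, per-branch spine annotations, or parasagittal
cell maps, and want cohort-comparable numbers plus permutation-based
clustering statistics without any image processing.

## What it computes

**Arbor metrics** (`read_swc()`, `arbor_summary()`, `decompose_branches()`,
`sholl_profile()`, `diameter_profile()`): total dendritic length, branch
segments with centrifugal order, terminal counts, arbor width/height and a
signed shape index (+100·(W/H − 1) for wide arbors, −100·(H/W − 1) for
tall), branch eccentricity from a through-origin fit after mirroring
(angle from the PC-layer plane in [0°, 90°]), log-normal thin-caliber
threshold exp(mean(ln d) + sd(ln d)) and thin-length fraction, and 1 µm
Sholl shells that conserve total length exactly.

**Spine metrics** (`classify_spine()`, `spine_densities()`,
`volume_fraction()`, `rayleigh_limit()`): the thin/mushroom/branched/
cluster taxonomy (0.5 µm head-diameter boundary; clusters are single heads
with ≥3 puncta), per-type densities, the spine-to-surround volume fraction
100·ΣV / (πL((r+p)² − r²)), the R = 0.61λ/NA confocal resolution limit,
and total-spine extrapolation length × density.

**Cell classifiers** (`classify_morphology()`, `classify_orientation()`,
`classify_foliar()`): Normative / Split / Poly primary-dendrite classes
(bifurcation within two soma distances, or 40 µm in mouse; 200/100 µm
minor-branch projection), Vertical / Horizontal orientation (parallel runs
>300/150 µm single or >150/75 µm opposing pairs at <30° from the layer),
and Gyrus / Bank / Sulcus foliar subregions from pial vs granule-layer
border lengths.

**Spatial clustering** (`pc_clustering()`, `adjacency_scores()`,
`cluster_runs()`, `population_match_profile()`, `shell_match_profile()`):
per-cell adjacency cluster scores in {−1, 0, 1, 2} (neighbors within
1000 µm human / 200 µm mouse; +1 per matching adjacent cell over the five
classes Normative, V-Split, H-Split, V-Poly, H-Poly), run statistics,
and observed-minus-shuffled match-rate elevations at increasing radii or
in core-excluding shells, all against seeded label-permutation nulls.

**Synthetic data** (`simulate_arbor()`, `simulate_cell_map()`,
`simulate_spiny_branch()`): seeded generators calibrated to the published
cohort means, with exact ground-truth bookkeeping, so the entire pipeline
is testable end to end without microscopy data. `run_pipeline()`
orchestrates simulate → measure → classify → cluster and writes CSVs plus
a JSON manifest.

## Worked example

```r
library(pcmorph)

# a calibrated synthetic human PC, measured by the arbor pipeline
sim <- simulate_arbor(arbor_sim_config("human", seed = 8))
arbor_summary(sim$arbor)
#   total_length n_branches n_terminal_branches max_width max_height shape_index
#          58477       2549                1275       339        236          44

# spine densities on a synthetic 30 um spiny branch (human preset)
br <- simulate_spiny_branch(spine_sim_config("human", seed = 8))
round(spine_densities(br$spines, br$length), 2)
#    total     thin mushroom branched  cluster
#     6.93     5.33     0.57     0.33     0.70

# is morphology spatially clustered along the layer?
map <- simulate_cell_map(map_sim_config(n_cells = 500,
                                        copy_probability = 0.4, seed = 8))$map
pc_clustering(map, n_shuffles = 20, seed = 8)
# Adjacency clustering (complete match, threshold 1000 um, 500 cells)
#   observed clustered rate: 74.6%
#   shuffled mean rate:      40.5% (20 shuffles)
#   excess over null:        +34.1 points (perm. p = 0.048)
```

The arbor summary is one simulated cell drawn from the human cohort
distribution (58,477 µm of dendrite over 2,549 branch segments, a wide
arbor with shape index +44). The spiny branch recovers a total density of
6.93 spines/µm from per-type Poisson draws. The clustering fit shows that
with label-copying strength κ = 0.4, 74.6% of cells match at least one
adjacent neighbor versus 40.5% expected under label permutation — a
+34 percentage-point excess, the package's core statistic.

## Vignette

`vignettes/pc-morphometry.Rmd` documents the measurement conventions, the
classifier thresholds, the clustering statistics and their permutation
nulls, the simulator calibration, and known limitations.
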