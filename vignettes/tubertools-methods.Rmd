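---
title: "Methods: CT tuber volumetry, growth kinetics and starch co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT tuber volumetry, growth kinetics and starch co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubertools)
```

`tubertools` implements an integrated analysis for potato tuber physiology:
non-destructive tuber volumetry from X-ray computed tomography (CT),
growth-velocity estimation from repeated scans, a microarray selection
pipeline that extracts transcription-factor (TF) candidates co-expressed
with starch biosynthetic genes, and efficiency-corrected qPCR
quantification. Because the original scans are not publicly deposited and
the array contrasts cannot be reconstructed exactly, every stage is paired
with a seeded synthetic-data generator with analytic ground truth; all
claims about the pipeline are made, and tested, against that ground truth.

## CT volumetry

A reconstructed volume is a 3D grid of voxels carrying 16-bit grey levels
proportional to X-ray attenuation, with isotropic spacing in mm
(`voxel_volume()`; the emulated scan protocol has 141 µm voxels, so
`phantom_spec()` defaults to `spacing_mm = 0.141`). Tuber material is
segmented by an inclusive grey-level window: a voxel is tuber iff
$T_\mathrm{low} \le g \le T_\mathrm{high}$, with defaults 2938 and 3963 —
the standard threshold pair for tubers against soil at 200 kV. The window
is inclusive on both sides because the field's "lower and upper threshold"
phrasing does not state strictness; inclusivity is the natural reading and
is what the tests pin down. Foreground voxels are grouped into
26-connected components (tubers are compact blobs; 6-connectivity is
available), and components below `min_voxels = 64` are dropped as speckle.
Residual mistakes — touching tubers, retained stones — are handled the way
the original interactive workflow handled them: explicit manual edits
(`mask_edit()`, `apply_mask_edits()`), never an automatic split.

Volume is estimated by whole-voxel counting:
$V = N \cdot (s/10)^3\ \mathrm{cm}^3$ for $N$ labelled voxels at spacing
$s$ mm. No partial-volume weighting is applied, exactly matching the
voxel-counting estimator being validated. `validate_volumes()` regresses
calculated on measured volumes and reports the Pearson correlation — the
validation design that gave r = 0.986 over seventeen real tubers, which
the synthetic campaign in `scripts/acceptance.R` mirrors (17 spheres,
0.5–50 cm³, blur 1 voxel, grey noise sd 50, 0.4 mm binning; that binning
keeps the smallest tuber above 12 voxels radius so discretization error
stays below the percent level).

### The phantom generator

`generate_phantom()` builds a scene of ellipsoidal tubers in soil. Ground
truth (labels and analytic volumes $\tfrac43\pi abc\,(s/10)^3$) is frozen
*before* degradation; the grey volume then receives (i) a piecewise-
constant field of the two population means, (ii) separable Gaussian
partial-volume blur (`blur_sigma`, voxels), and (iii) additive Gaussian
noise with the per-region sd. Membership is "voxel centre inside the
ellipsoid", the same convention as the counting estimator, evaluated in a
cross-multiplied form so lattice points lying exactly on the surface are
counted inclusively rather than lost to floating-point rounding.
Overlapping tubers are rejected (discrete organs; ambiguous truth), as are
tubers extending outside the grid.

The soil/tuber grey populations are a modelling choice — the real soil
distribution is not published. The defaults put the tuber mean at the
centre of the segmentation window (3450) and the soil mean at 2426, so
the lower threshold 2938 sits midway between the populations. With the
decision boundary at the population midpoint, partial-volume blur moves
roughly as many boundary voxels into the window as out of it, which is
the regime in which whole-voxel counting is approximately unbiased; the
residual curvature bias of a blurred convex surface is
$\Delta V/V \approx -3\sigma^2/r^2$ and visible in the tests as a small
negative error for small spheres.

`project_and_reconstruct()` provides reconstruction artifacts for
robustness testing: each horizontal slice is forward-projected into a
parallel-beam sinogram (linear splatting onto detector bins) and
reconstructed with Ram–Lak filtered back-projection. This is a desk-scale
stand-in: real scans use a cone beam and Feldkamp-type reconstruction,
which — together with beam hardening, scatter and geometry calibration —
is out of scope. The simulator's uniform-image and sphere round-trip
behaviour (interior mean within 2%, volume within 5%) is pinned by tests.

## Growth kinetics

`estimate_velocity()` fits volume (cm³) on time (days) per tuber by
ordinary least squares and reports the slope in cm³/day. OLS is the
default because it uses every scan and is well defined from three points
up; an endpoint difference-quotient mode (`method = "endpoint"`) is kept
because with sparse scan campaigns the two conventions can differ and the
original figure could have used either. No smoothing or outlier rejection
is applied: a bad scan should propagate visibly, not silently.

"Non-growing" has no numeric definition in the field ("virtually stopped
growing"), so the growing call is an explicit dual rule:
`velocity > 0.1 cm³/day` (absolute floor, roughly the volume resolution of
a day-scale scan interval) **or** `velocity > 0.01/day × mean volume`
(relative rule, 1% of the tuber per day). Both thresholds are arguments
and config fields; the OR combination means large tubers can qualify via
fractional growth even when the absolute rule dominates for small ones.

## The expression pipeline

### Normalization

`normalize_expression()` applies the classic three-step recipe: floor at 5
intensity units, divide each chip by its post-floor 50th percentile, then
divide each feature by its median across the entire dataset. After step 3
every feature's median is exactly 1, making profiles comparable across
experiments. "Entire dataset" is scoped to whatever matrix is passed in:
when the three experiments are analysed jointly the dataset is their
union, and the provenance element records the sample set used, so the
scoping is never implicit. Step 2 assumes most features are unchanged —
with the default synthetic design 15% of features are planted, which the
chip median tolerates; planting a majority of features would visibly
compress fold changes (this is a property of the recipe, not a bug).

### Differential selection

`select_differential()` implements volcano selection between two
conditions: orientation-free fold change
$\max(\bar a/\bar b,\ \bar b/\bar a)$ of normalized intensities, and a
two-sided t-test on log2 values. "More than two-fold" is implemented as
$FC \ge 2$ (inclusive; configurable). The variance assumption of the
original volcano tool is unknown; this package defaults to the classical
pooled-variance t-test rather than Welch's. The reason is concrete: at two
replicates per condition the Welch–Satterthwaite degrees of freedom
collapse toward 1 and the test has almost no power (simulated ~0.67 at a
4-fold effect, log2 noise 0.25, versus ~0.96 for the pooled test), which
would make two-replicate experiments useless — while for the balanced
designs used here the pooled test is exact under equal variances.
`var_equal = FALSE` restores Welch.

Benjamini–Hochberg correction is gated on the design, not on a hidden
switch: it is applied iff both contrasted conditions have at least four
replicates (`correct_min_replicates`), encoding the convention of
correcting the four-replicate growth-velocity experiment but not the
two-replicate time courses. For multi-condition experiments the contrast
pair must be given explicitly; an "extreme-pair" convenience mode
contrasts the conditions with the largest and smallest overall means, and
the chosen pair is recorded in the result's attributes.

`intersect_feature_sets()` keeps features differentially expressed under
*all* conditions (the Venn intersection) and reports every region
cardinality.

### Clustering and TF candidates

`cluster_profiles()` z-scores each feature profile across samples and runs
Euclidean K-means on the standardized rows — equivalent to clustering
under Pearson correlation distance $d = 1 - r$, since for z-scored
vectors $\|x - y\|^2 = 2(n-1)(1 - r)$. `k = 5` is the
cluster count of the emulated analysis. Determinism: the best of
`n_init = 25` restarts by within-cluster sum of squares under a seeded
RNG; `stats::kmeans` (Hartigan–Wong) does the inner work. The original
tool's exact algorithm is unknowable, so equivalence is claimed only at
the property level (planted-structure recovery, invariances), never
bit-level. `k` equal to the number of profiles returns the singleton
partition directly. Zero-variance profiles are refused by name — a flat
profile has no correlation to anything.

`select_clusters()` ranks clusters by how many marker features (known
starch biosynthetic genes, in the real analysis) they contain;
`extract_tf_candidates()` returns the TF-annotated features of those
clusters ranked by the Pearson correlation of their standardized profile
with the mean marker profile — the co-expression argument that a
regulator should track its targets. `summarize_function()` reports the
functional composition of any feature set (the real analysis found 37%
metabolism, 9% storage protein, 6% TFs in its three marker clusters).

### The expression generator

`generate_expression()` emulates the three-experiment design: a diurnal
leaf time course (4 time points × 2 replicates), a tuber-induction series
(3 stages × 2), and growing vs non-growing tubers (2 × 4). Five
co-expression clusters of 30 features are planted, each spanning the full
log2 effect (default 2, i.e. 4-fold) between the extreme conditions of
every experiment: three "up" shapes that carry marker genes, one
transient shape and one opposite-phase shape without markers — mirroring
a five-cluster outcome in which markers concentrate in three clusters.
Noise is multiplicative log-normal (log2 sd 0.25 by default, a typical
between-replicate spread for spotted-oligo arrays); background features
are flat. Six percent of each planted cluster is annotated
"transcription factor"; the co-regulated TF truth set is restricted to
marker-bearing clusters. The generator does **not** emulate dye bias,
spatial array artifacts, probe-level effects or missing values, so
passing tests demonstrate the selection logic, not robustness to platform
artifacts.

## qPCR

`pfaffl_ratio()` computes efficiency-corrected relative expression
$\mathrm{ratio} = E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with
$\Delta Ct = Ct(\mathrm{control}) - Ct(\mathrm{sample})$, so induced
genes give ratios above 1 (the orientation is stated in the output
columns). Technical replicates are aggregated to mean Ct first. At
$E_t = E_r = 2$ the formula reduces to $2^{-\Delta\Delta Ct}$.
Efficiencies are user inputs in $(1, 2]$; standard-curve estimation is
out of scope. Because conventions differ on qPCR error bars, both error
routes are reported: the technical-replicate sd of each $\Delta Ct$ and a
first-order (delta-method) sd of the ratio. `generate_qpcr()` inverts the
formula from chosen true ratios, so the zero-jitter round trip is exact
to floating precision.

## Reproducible runs

`run_config()` centralizes every stage parameter with the standard
defaults (2938/3963 window, floor 5, 50th percentile, 2-fold cutoff at
α = 0.05, k = 5, growth thresholds) and validates structure and ranges,
reporting violations by field path. `run_pipeline()` executes the enabled
stages in dependency order, writes plain TSV/JSON outputs plus a
`manifest.json` (config, config hash, package/R versions, per-file
content hashes), and is byte-reproducible for a given config and seed.
One user seed is fanned out to per-stage substreams so stages can be
rerun independently without disturbing each other's draws.

## Numerical choices and test scales

Inclusive window bounds; 26-connectivity; `min_voxels = 64`; voxel-centre
ellipsoid membership with a relative $10^{-9}$ boundary tolerance; blur
kernels row-renormalized at grid edges (mass is conserved to ~0.1%);
flat growth series are assigned $r^2 = 1$ (a flat fit is exact); p-values
of identical groups are set to 1. The test and acceptance problem sizes
are chosen to finish on one CPU in minutes: 17-tuber campaigns at 0.4 mm
binning, 1000-feature expression matrices, 20-seed Monte-Carlo estimates
for operating characteristics (50 for the null-FDR simulation, 100 for TF
recovery), and a quartile-positioned step in the three-shape clustering
fixture so the planted shapes are mutually distinguishable (a half-split
step is nearly collinear with the ramp, z-scored r ≈ 0.87). Monte-Carlo
summaries of Bernoulli outcomes at these sizes carry binomial noise of a
few percentage points; the tests state their bounds accordingly.

## Known limitations

Parallel-beam slice-wise reconstruction only; no grey-level calibration
to Hounsfield-like units; no automatic separation of touching tubers; no
nonlinear growth models; no raw array-file parsing, spike-ins, enrichment
statistics or ortholog mapping; no qPCR efficiency estimation. Counts
from the real study (1662 intersected features, 913 in three clusters)
are not reproduction targets: they depend on undeposited scans and
unstated contrast pairs, so the package mirrors each claim qualitatively
on synthetic ground truth instead.
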