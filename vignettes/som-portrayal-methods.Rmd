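---
title: "SOM portrayal of blood transcriptomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM portrayal of blood transcriptomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`somportraits` analyses bulk blood transcriptomes by self-organizing-map
(SOM) "portrayal". This vignette is the package's own account of the
science behind each stage: the models, their assumptions, the tunable
parameters, the synthetic cohort used to test everything, and the design
choices made where the method left genuine freedom.

## The portrayal model

Each gene is treated as a data point in sample space: its (quantile
normalized, gene-centred) expression profile over all samples. A batch SOM
with a `rows x cols` grid compresses the tens of thousands of gene profiles
into `rows * cols` **metagenes** — codebook vectors that tile the gene
cloud while preserving its topology. The per-sample slice of the codebook,
arranged on the grid, is the sample's **expression portrait**: a 2-D image
of its transcriptome state in which co-expressed genes occupy compact map
regions.

Preprocessing is deliberately minimal: quantile normalization forces every
sample onto the identical value distribution (delegated to
`limma::normalizeQuantiles`, rank-interpolated ties), and gene-wise
centralization subtracts each gene's mean over *all* samples, controls
included. Everything downstream therefore works on log-scale deviations
from the cohort-average transcriptome; a portrait value of +1 means the
metagene is one log unit above its cohort mean in that sample.

### SOM training choices

* **Batch algorithm, not online.** Batch training is deterministic given
  the initialization, which is the plane spanned by the first two principal
  directions of the gene cloud (the random seed is used only when that
  plane is degenerate). Reproducibility is a hard requirement: identical
  inputs and seeds must give byte-identical outputs.
* **Neighborhood.** Gaussian on grid Euclidean distance, with the radius
  decaying linearly from `max(grid)/2` to 0.5 over the epochs
  (default 30). The final radius of 0.5 leaves just enough smoothing to
  keep the map topological without blurring module borders.
* **Winner rule.** By default genes join their *nearest* codebook vector —
  the standard batch SOM. `som_train(..., winner = "heskes")` instead
  assigns each gene to the node minimizing its neighborhood-weighted
  distortion; under that rule (and only under it) every epoch at fixed
  radius is a coordinate descent of the batch-SOM energy, which is what
  the energy-monotonicity test asserts. The two rules coincide as the
  radius shrinks. The nearest rule remains the default because the Heskes
  assignment degenerates at the wide radii of the early epochs (a nearly
  flat neighborhood makes all genes pick one node, collapsing the map).
* **Distance.** Euclidean on centralized profiles. As the radius
  vanishes, batch training reduces exactly to Lloyd's k-means, and the
  test suite verifies that fixed points satisfy the k-means conditions.

## Spot modules

The **variance map** (per-metagene variance of the codebook across
samples) highlights regions of co-ordinated differential expression.
`segment_spots()` thresholds it at a variance percentile (default 90) and
takes connected components under the 8-neighborhood as **spot modules**;
a spot's member genes are those whose best-matching unit lies inside it.

Two refinements matter in practice:

* **U-map edge cuts (default on).** Independent co-expression modules
  frequently abut on the map; a plain connected-component pass fuses them.
  The package applies the "maximum distance between neighboring pixels"
  idea at the edge level: an adjacency edge between two supra-threshold
  pixels is cut when the Euclidean distance between their codebook vectors
  exceeds `umap_factor` (default 2) times the map-wide median
  neighboring-pixel distance. Cluster borders are exactly where that
  distance spikes, so the cut separates modules without fragmenting them.
* **Minimum spot size (default 5 genes).** Supra-threshold pixel regions
  that collect no or only a handful of stray genes are interpolation
  artifacts of the SOM sheet between true modules, not modules; they are
  discarded. They otherwise contaminate spot counting, because they track
  the profile of the adjacent real module.

A spot is **active** (over-expressed) in a sample when its mean portrait
value strictly exceeds the `q = 0.98` quantile of the portrait *outside
the spot* and is positive. The reference quantile excludes the spot's own
pixels: for a large spot the top 2% of the whole portrait *is* the spot,
and the literal within-portrait quantile would mask precisely the samples
that over-express it; for small spots the two references coincide.

## Gene-set scoring

* **Fisher spot enrichment** tests over-representation of a gene set in a
  spot's member genes with the one-sided exact test over the gene
  universe (`stats::fisher.test`); Benjamini–Hochberg adjusted values are
  reported alongside raw p, and the conventional annotation threshold for
  spot tables is raw `p < 1e-7`.
* **GSZ** is the per-sample gene-set Z score: the difference between the
  set-mean and the transcriptome-mean of the (centralized) sample, divided
  by `s_j * sqrt(1/|G| - 1/N)` where `s_j` is the sample's SD over all `N`
  genes. This is the exact Z score of a set mean under random sampling of
  `|G|` genes without replacement — a standardized mean difference with
  finite-population correction. No variance shrinkage is applied; with set
  sizes of tens of genes against a background of thousands, the sampling
  correction dominates any shrinkage term.
* **Named transcriptomic scores.** The severity score is the mean
  expression profile of a designated over-expression spot (chosen
  automatically as the spot with the largest case-minus-control mean
  difference when a control group is annotated); viral/IFN, erythrocyte,
  platelet and coagulation scores are GSZ profiles of the corresponding
  signature sets. Spot profiles use gene means rather than metagene means:
  the genes are the measured quantities, and metagene means would weight
  genes by the local node population.

## Class discovery

Samples are stratified on the pairwise Pearson correlation matrix of their
portraits. K-means on the rows of that matrix (multi-start; 50 random
starts, deterministic given the seed) seeds `K` classes — the default
`K = 6` matches the stratification the method was built to reproduce —
and a silhouette refinement then iterates: recompute class centroids as
mean portraits, score every sample as

```
S_i = r(i, own centroid) - max over other classes of r(i, their centroid)
```

and move every sample with `S_i < 0` to its best-matching class, until no
sample moves (cap 100 iterations; ties to the lowest class index; a class
emptied during refinement restarts on the worst-fitting sample). Moving a
sample to its most-correlated centroid is exactly the move that makes its
own score positive, so the refinement is a correlation-metric Lloyd
iteration; mean `S` is tracked per iteration and never decreases in
practice, which the property tests assert. Centroids are mean portraits,
not medoids: the mean is the least-squares representative and keeps the
refinement consistent with the K-means seeding.

Multi-start seeding replaced a furthest-first start after measurement:
furthest-first anchors centers on extreme outlier samples and on identical
inputs recovered the planted classes markedly worse (adjusted Rand index
0.65 vs 0.84).

**Bootstrap stability** resamples the samples with replacement, re-runs
the discovery, matches resampled to reference classes one-to-one by greedy
maximal centroid correlation, and reports the mean percentage of in-bag
draws that keep their reference label (default `B = 100`). Note that even
structureless data shows stability above the permutation floor, because a
fixed dataset's noise correlations are themselves reproducible under
resampling; stability is informative relative to that floor, not to 50%.

## The prognostic map

For each metagene, the supporting cases are the outcome-bearing samples
whose portrait value exceeds `sd_factor` (default 1) times the metagene's
across-sample SD — "exceeding the SD" is read one-sided, since
over-expression spots are the objects of interest. The map value is the
percentage of 28-day survivors among supporting cases, reported to 0.1;
metagenes supported by fewer than 10% of the outcome-bearing samples (or
with zero SD) are masked and serialized as `NA` (rendered white). Controls
carry no outcome and are excluded both from the SD estimate and from
support counts. Per-class survivor percentages come with one-sided Fisher
exact tests of the class-vs-rest table, oriented along the observed
direction.

## The synthetic cohort generator

`simulate_cap_cohort()` is first-class, tested code: it generates the
study conditions under which every recovery claim is measured. It plants
three latent axes per sample —

* `u`, severity, in [0, 1]: zero for controls; for patients drawn at day 1
  from a trimodal Beta mixture (low/middle/high strata with density gaps
  at the class cut points 0.375 and 0.625) and decaying multiplicatively
  over longitudinal days (`u(d) = u(1) * 0.8^(d-1)`). Patients with an
  active interferon response draw severity instead from a broad
  low-to-middle continuum (70%) or the high stratum (30%).
* `v`, interferon response: a bimodal on/off axis — a truncated lognormal
  whose scale depends on a Bernoulli "IFN-active" state with
  cohort-specific prevalence (A 0.45, B 0.15, planting the cohort
  asymmetry); it decays over days like `u`.
* `w`, blood disturbance (erythrocyte/platelet mRNA): a bimodal amplitude
  (disturbed with probability 1/3) times a Gaussian mid-severity envelope,
  planting the mid-severity peak of the erythrocyte score.

Twelve modules of co-expressed genes load on these axes: severity-up,
severity-down, mid-severity, IFN and BD modules; two accessory modules
that co-activate with severity but carry independent variation (the
growing heterogeneity of transcriptional programs in severe disease); and
five decoys driven by independent standard-normal factors. Expression is
`e_gj = mu_g + loading * latent_j + noise`, with baselines
`mu_g ~ N(8, 1)` mimicking log-intensity arrays, per-gene loading jitter
Uniform(0.8, 1.2) and residual SD 0.5. The 28-day outcome follows
`P(death) = plogis(-2.2 + 2.0 u + 1.5 u v)` on the day-1 latents: death
risk grows with severity, and interferon response multiplies the risk of
severe cases only, so the planted IFN-high/high-severity class has the
worst prognosis by construction.

Planted class labels are a deterministic function of `(u, v, w)` recorded
in the truth object: IFN classes when `v > 0.30` (split at `u = 0.625`),
else BD when `w > 0.35`, else low/middle/high severity at the cuts
0.375/0.625. The severity cuts sit at the antimodes of the trimodal
mixture; the `v`/`w` thresholds sit in the density gaps of their bimodal
axes. Under the alternative `u_distribution = "beta"` (a Beta(2, 2)
continuum) the severity cuts fall back to tertiles — that option
reproduces a fully continuous cohort, in which discrete class recovery is
not achievable by construction and the recovery tests do not apply.

Effect sizes are generator defaults chosen once, during calibration, so
that the planted structure is recoverable at the documented thresholds;
they are not tuned per test. What passing recovery tests shows — and does
not show — about real data: the generator emulates latent axes, module
structure, cohort asymmetry, longitudinal decay and outcome coupling, but
not array probe effects, batch structure, heavy-tailed noise, overlapping
module membership, or the fully continuous severity spectrum of real
cohorts. Recovery numbers on real data will be lower; the tests certify
the machinery, not clinical performance.

## Benchmark problem sizes

The recovery benchmark (`run_recovery_benchmark()`, also driven by
`scripts/acceptance.R`) uses 2,000 genes, 10 controls + 170 patient
samples, 12 planted modules of 16 genes and a 20 x 20 map, repeated over
10 generator seeds; class discovery runs on the patient samples with
`K = 6`. These sizes keep a full 10-seed sweep within tens of seconds
while preserving the structure of the full-scale analysis (a 50 x 50 map
over ~20,000 genes behaves identically but trains proportionally longer).

## Numerical conventions and degenerate inputs

* Grid coordinates are 0-based, row-major, in every serialized table.
* Variance uses the unbiased (n−1) estimator throughout.
* Quantile-normalization ties take interpolated rank means.
* GSZ of the whole-transcriptome set is defined as 0 (the 0/0 limit);
  zero-variance samples yield `NA`.
* A SOM grid larger than the gene count is permitted (empty metagenes are
  allowed; empty nodes keep their previous codebook during updates).
* `fisher_spot_enrichment` requires the set to intersect the universe and
  the spot to lie inside it; empty universes are errors.
* Bootstrap replicates with fewer than `K` distinct samples are skipped
  and logged, never silently imputed.

## Known limitations

* Spot labels are variance-ordered letters; they are stable for one
  trained map but not comparable across maps.
* The U-map edge-cut factor trades merging against fragmentation; 2 is
  calibrated for maps whose modules are mutually independent, and very
  strongly correlated modules (such as a severity module and its
  accessory programs) may still merge into one spot.
* The silhouette refinement optimizes a local criterion and inherits the
  K-means seeding's locality; it reassigns but never splits classes.
* Underexpression spots are not segmented; the prognostic map reads
  over-expression only.
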