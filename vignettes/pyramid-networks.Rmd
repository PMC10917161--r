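---
title: "Multi-scale (pyramid) functional brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale (pyramid) functional brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcpyramid)
```

## The problem

A resting-state functional network is only defined relative to a choice of
nodes, and that choice is a trade-off. Large anatomical parcels give stable,
comparable nodes across subjects but average away focal abnormalities;
voxel-sized nodes are sensitive to focal effects but noisy and anatomically
unstable. `fcpyramid` implements a *pyramid* answer: the same data are
analysed at five nested parcellation scales at once, from 84 gray-matter
parcels at the finest scale (Scale-1) down to 4 at the coarsest (Scale-5,
left/right telencephalon and diencephalon), and features from all scales are
combined.

The packaged hierarchy (`fcp_hierarchy()`) is a recombination tree: every
Scale-1 parcel has a unique ancestor at each coarser scale
(gyrus subdivisions → gyri → lobes → cortex/nuclei → telencephalon/
diencephalon), with node counts 84/58/16/6/4. The printed lookup table this
tree is built from lists the parcel names per scale but not the parentage;
the packaged table reconstructs parentage from standard anatomical
assignment (e.g. the opercular, orbital and triangular subdivisions of the
inferior frontal gyrus share the IFG ancestor; parahippocampal and
entorhinal cortex, cingulate, amygdala and hippocampus sit in the limbic
lobe; caudate, putamen and pallidum form the basal ganglia). Two quirks of
the printed table are handled deliberately: the coarsest scale prints
"Diencephalon_L" twice where left/right symmetry clearly intends a right
diencephalon (the packaged table uses `Diencephalon_R`), and the spellings
`BasslGang`/`CerebralNucli` are kept verbatim so the packaged table
round-trips the published one.

## Pipeline

For each subject the pipeline is:

1. **Node time courses** — the unweighted mean of member-voxel BOLD series
   per parcel at each scale (`extract_node_timecourses()`). Nested means
   compose: a coarse node's series is the voxel-count-weighted mean of its
   children's series, which the tests verify numerically.
2. **Connectivity** — Pearson correlation between all node pairs, diagonal
   set to zero (`pearson_connectivity()`), giving 84², 58², 16², 6², 4²
   symmetric matrices.
3. **Binarization** — proportional thresholding (`proportional_threshold()`):
   the top `round(P·N(N−1)/2)` node pairs by *signed* correlation become
   edges, default P = 0.5. Signed ranking (a strongly negative correlation
   is a weak connection, not a strong one) follows the Brain Connectivity
   Toolbox convention; an absolute-value mode exists behind `mode =
   "absolute"`. Rounding is half-up, so the 6-node scale (15 pairs) keeps 8
   edges at P = 0.5. Ties at the cutoff are broken by (row, column) order so
   results are reproducible; with continuous correlations ties are
   measure-zero.
4. **Graph metrics** — from-scratch binary-graph implementations
   (`clustering_coefficients()`, `global_clustering()`,
   `global_efficiency()`, `local_efficiency()`,
   `betweenness_centrality()`), validated exhaustively against brute-force
   oracles and igraph. Conventions: `C_i = 0` and `E_i = 0` for degree < 2
   (Brain Connectivity Toolbox); disconnected pairs contribute 0 to
   efficiency, so no connectivity precondition is imposed — thresholded
   coarse-scale graphs are routinely disconnected; betweenness is Brandes'
   algorithm and is reported normalized by `(N−1)(N−2)/2` by default so
   features are comparable across scales with different node counts (raw
   mode is available and used in the oracle tests). No global betweenness
   is defined or computed.
5. **ALFF** — per voxel, the sum of single-sided DFT amplitudes
   `2|X_k|/n` over bins whose frequency `k/(n·tr)` lies in 0.01–0.1 Hz,
   endpoints inclusive, DC excluded (`compute_alff()`); then z-scored
   across voxels with the sample (n−1) standard deviation
   (`zscore_map()`); then averaged within nodes (`node_average_alff()`).
   The `2|X_k|/n` convention makes a pure in-band sinusoid of amplitude A
   return ALFF = A exactly, which pins the otherwise arbitrary scaling and
   makes the amplitude-linearity tests exact. No detrending happens inside
   the ALFF step: the pipeline assumes drift was removed upstream, and the
   synthetic generator is drift-free by construction.
6. **Group statistics** — elementwise mean/difference/SD connectivity
   summaries on the *unthresholded* correlation matrices
   (`summarize_connectivity()`; differences like 0.2 are only meaningful
   before binarization), and per-node two-tailed two-sample t-tests
   (`nodewise_ttest()`). "Student's t-test" is read as the pooled-variance
   test — the default meaning of the name — with Welch available behind a
   flag. Benjamini–Hochberg FDR (`fdr_bh()`, written out as the step-up
   rule and cross-checked against `p.adjust`) is applied per
   (metric, scale) family, matching per-figure reporting conventions; a
   node with zero pooled variance yields t = 0, p = 1 with a warning rather
   than an error, because all-zero coarse-scale metrics are an expected
   regime, not a failure.
7. **Classification** — per-scale feature vectors (84/58/16/6/4 values) or
   their 168-dimensional concatenation (`assemble_features()`; scales
   finest→coarsest, atlas order within scale, subjects sorted by id so
   reports are invariant to row order), classified by a linear SVM (LIBSVM
   via e1071, C = 1) under stratified 10-fold cross-validation with
   features standardized by training-fold statistics only
   (`crossval_svm()`). Kernel and C are unstated in the source method
   (which cites LIBSVM only); the linear kernel with C = 1 is the
   conventional default for n ≈ 40 subjects with 84–168 features, and both
   are configurable and echoed in the report. Stratification avoids
   single-class training folds at these sample sizes; specificity,
   sensitivity and accuracy are computed from confusion counts pooled
   across folds (stated in the report) with the patient class positive.
   Degenerate all-constant feature columns (e.g. all-zero Scale-5
   clustering) pass through standardization untouched rather than being
   dropped silently.

`run_pipeline()` orchestrates the stages from a config list or YAML file,
writes every intermediate artifact as TSV/JSON and a manifest with
parameters, seed, package version and per-artifact md5 hashes; identical
config + seed gives bit-identical artifacts.

## The synthetic cohort generator

There is no public deposit of the clinical cohorts this methodology was
demonstrated on, so the package ships a generator (`cohort_design()`,
`generate_cohort()`) that produces post-preprocessing BOLD cohorts with
exactly the structure the pipeline assumes: TR = 2 s, 240 time points
(an 8-minute scan), band-limited power in 0.01–0.1 Hz, and modular
covariance aligned with the atlas tree.

**Generative model.** For every parcel at every scale one latent signal is
drawn by spectral synthesis: unit-amplitude cosines at every DFT bin
frequency inside the passband with independent uniform phases, scaled to
exactly unit time-average power. Spectral synthesis was chosen over ARMA
filtering because it is *exactly* band-limited, which makes the ALFF tests
sharp (a generated latent has band power fraction 1 by construction). A
voxel in finest parcel `p` is the coupling-weighted sum of the latents of
`p`'s ancestors at all scales plus white noise:

    x_v(t) = gain_p · Σ_s w_s · L_{anc_s(p)}(t) + ε_v(t),  ε ~ N(0, noise_sd²)

Two voxels therefore correlate through every latent their parcels share,
so correlation decays as the lowest common ancestor moves to coarser
scales — the hierarchical-modularity property the tests check at large n.
The implied within-parcel voxel correlation is `Σw²/(Σw² + noise_sd²)`,
which the Monte-Carlo test verifies against its analytic value.

**Defaults** (chosen once as plausible resting-state values, and then left
alone): mixing weights `w = (1, 0.6, 0.45, 0.35, 0.25)` from finest to
coarsest scale and `noise_sd = 0.5`, giving within-parcel voxel
correlation ≈ 0.87 (spatially smoothed neighboring voxels), within-gyrus
node correlation ≈ 0.37, within-lobe ≈ 0.19, cross-lobe ≈ 0.09 and
interhemispheric ≈ 0.03; group sizes 21 patients / 20 controls; 10 voxels
per parcel.

**Group effects.** In patients, designated effect parcels (default:
bilateral parahippocampal gyrus and hippocampus, the classic early-AD
territory, when the packaged atlas is used) have their ancestor couplings
(scales ≥ 2) multiplied by `1 − coupling_reduction`, with the pre-noise
signal sd renormalised so the band amplitude is unchanged — and the
pre-noise signal then multiplied by `1 − alff_reduction`. The
renormalisation makes the two effects orthogonal: a pure coupling
reduction changes inter-node correlation but not spectral amplitude, and a
pure amplitude reduction changes ALFF but (noise aside) not correlation.
Patients are always the reduced group; flipping the direction is a label
swap. Each subject draws from an independent RNG stream derived from the
design seed and the subject index, so cohorts are reproducible regardless
of generation order.

**What the generator does not emulate:** hemodynamic response shapes,
motion and physiological artifacts, scanner drift, spatial registration
error, and any realistic AD effect size — no usable effect-size data
exist in the source material, so `coupling_reduction`/`alff_reduction`
are free experimental dials, not pathology estimates. Passing tests
therefore demonstrate that the pipeline recovers effects *of the assumed
form*, not that it would detect clinical disease.

## Statistical design choices in the validation suite

* **Null calibration** is asserted on node-averaged z-scored ALFF — the
  downstream node statistic with a continuous, near-Gaussian sampling
  distribution. Node-wise rejections within one cohort share latent
  signals and are positively correlated, so the pooled binomial band over
  cohorts × nodes would be too narrow; the suite instead uses the
  Monte-Carlo error of the mean of per-cohort rejection fractions (200
  cohorts as the independent unit). The family-level check allows the
  analogous Monte-Carlo slack because for continuous independent nulls the
  chance that the BH step-up makes any rejection in a family is exactly
  the nominal level (the Simes identity), not strictly below it.
* **Effect recovery** is asserted on nodal strength (`node_strength()`,
  the off-diagonal row mean of the correlation matrix), because a coupling
  reduction acts directly on a node's correlations. Clustering
  coefficients at P = 50% density recover the same effect only weakly:
  halving a node's sibling correlations (≈ 0.37 → 0.19) typically leaves
  them above the dense-graph edge threshold, so the binary neighborhood
  changes little. The scale contrast — effects injected at 4 of 84 finest
  parcels are detected at Scale-1 in ≥ 95% of cohorts but wash out at
  Scales 4–5 — is the package's synthetic analogue of the qualitative
  finding that inter-group differences concentrate in smaller-scale
  networks.
* **Graph-metric oracles.** Exhaustive verification over *all* graphs on
  up to 7 nodes at 3–10 edges is ~2 million graphs; the suite instead
  enumerates every graph on 4 and 5 nodes with 3–10 edges (~1 000 graphs),
  samples 200 random 6–7-node graphs against the same brute-force oracles
  (triangle enumeration, Floyd–Warshall, path-count dynamic programming —
  deliberately sharing no code with the implementation), and checks 500
  random 10–20-node graphs against igraph. Problem sizes throughout the
  suite (200 null cohorts, 100 effect cohorts, 50 classifier repeats) were
  fixed at design time as the smallest replicates at which the asserted
  rates have usefully narrow Monte-Carlo error.

## Known limitations

* The packaged parentage is a reconstruction; a different anatomical
  assignment of a handful of structures (e.g. amygdala to the nuclei
  rather than the limbic lobe) would change coarse-scale node composition.
* Negative-correlation regimes are underspecified for proportional
  thresholding: with signed ranking, negative edges simply rank last and
  vanish whenever fewer than half the pairs are negative. Data where most
  correlations are negative would silently keep some; the absolute-value
  mode exists for that situation.
* Only binary, undirected, unweighted graph analysis is implemented — no
  partial correlation, dynamic connectivity, weighted metrics, modularity
  or small-worldness.
* The SVM stage does no hyperparameter search, feature selection or nested
  cross-validation.

## A worked example

```{r example, eval = FALSE}
library(fcpyramid)
h <- fcp_hierarchy()
design <- cohort_design(h, n_patients = 10, n_controls = 10,
                        voxels_per_parcel = 4,
                        coupling_reduction = 0.5, alff_reduction = 0.3,
                        seed = 42)
cohort <- generate_cohort(design)
conn <- cohort_connectivity(cohort)
graphs <- threshold_connectivity(conn, p = 0.5)
metrics <- dplyr::bind_rows(metric_table(graphs, h), cohort_alff(cohort))
tests <- nodewise_ttest(metrics)
glance(tests)
autoplot(tests, metric = "alff")
report <- crossval_svm(assemble_features(metrics, "alff", "all"),
                       k_folds = 5, seed = 42)
report
```

The same analysis runs end to end from the packaged configuration with
`run_pipeline(system.file("extdata", "demo_config.yaml",
package = "fcpyramid"))`.
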