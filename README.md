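# fcpyramid

Multi-scale ("pyramid") analysis of resting-state functional brain
networks in R.

A graph-theoretic functional network is only defined relative to a node
definition, and node size is a trade-off: large anatomical parcels are
stable across subjects but insensitive to focal effects; small parcels are
sensitive but noisy and anatomically variable. `fcpyramid` analyses the
same BOLD data at **five nested parcellation scales simultaneously** — a
packaged gray-matter hierarchy with 84 / 58 / 16 / 6 / 4 nodes from finest
(Scale-1) to coarsest (Scale-5) — and combines features across scales, so
that fine scales capture localized abnormalities while coarse scales
suppress noise and anatomical variability.

For each subject and scale the pipeline computes

* node time courses: the mean BOLD series over each parcel's voxels;
* functional connectivity `D_ij`: Pearson correlation between node time
  courses (84², 58², 16², 6², 4² symmetric matrices, zero diagonal);
* a binary graph: the top `round(P·N(N−1)/2)` strongest connections kept
  as edges (proportional threshold, default P = 50%);
* binary graph metrics, implemented from scratch and oracle-tested:
  clustering coefficient `C_i = 2t_i/(k_i(k_i−1))` and its mean `C`,
  global efficiency `E` (mean inverse shortest path length), local
  efficiency `E_i` (E on the neighborhood of i), and Brandes betweenness
  centrality `B_i`;
* ALFF: per-voxel sum of DFT amplitudes in 0.01–0.1 Hz, z-scored across
  the brain, averaged per node;

and at the group level

* mean / difference / SD connectivity summaries;
* node-wise two-tailed two-sample t-tests with Benjamini–Hochberg FDR
  correction per (metric, scale) family;
* per-scale (84-, 58-, 16-, 6-, 4-dimensional) and concatenated
  (168-dimensional) feature classification with a linear SVM under
  stratified 10-fold cross-validation, reporting specificity, sensitivity
  and accuracy from pooled confusion counts.

Because no public deposit of the original clinical cohorts exists, the
package also ships a **synthetic BOLD cohort generator**
(`cohort_design()` / `generate_cohort()`): exactly band-limited
(0.01–0.1 Hz) latent signals attached to every node of the atlas tree,
mixed down to voxels so that correlation decays with the scale of the
lowest common ancestor, with configurable "patient" effects (reduced
inter-node coupling and/or reduced band amplitude at designated parcels).
Every downstream stage is validated on these cohorts.

## A worked example

```r
library(fcpyramid)
h <- fcp_hierarchy()
#> <fcp_hierarchy> 5 scales; node counts: 84/58/16/6/4

design <- cohort_design(h, n_patients = 10, n_controls = 10,
                        voxels_per_parcel = 4,
                        coupling_reduction = 0.5, alff_reduction = 0.3,
                        seed = 42)
cohort  <- generate_cohort(design)
conn    <- cohort_connectivity(cohort)
graphs  <- threshold_connectivity(conn, p = 0.5)
metrics <- dplyr::bind_rows(metric_table(graphs, h), cohort_alff(cohort))
tests   <- nodewise_ttest(metrics)
glance(tests)
#> # A tibble: 20 × 6
#>    metric      scale n_nodes n_sig_uncorrected n_sig_fdr       min_p
#>  1 alff            1      84                 8         4 0.000000110
#>  2 alff            2      58                 6         3 0.000000358
#>  3 alff            3      16                 3         0 0.00483
#>  4 alff            4       6                 1         0 0.0345
#>  5 alff            5       4                 0         0 0.522
#>  6 betweenness     1      84                 8         0 0.0136
#>  ...
```

The injected effect (coupling and amplitude reduced at bilateral
parahippocampal gyrus and hippocampus in "patients") is picked up by many
nodes at the fine scales and washes out toward Scale-5 — the pyramid's
motivating pattern. ALFF features survive FDR at Scales 1–2 only.

```r
report <- crossval_svm(assemble_features(metrics, "alff", "all"),
                       k_folds = 5, seed = 42)
report
#> <fcp_cv_report> 5-fold CV (linear kernel, C=1, seed 42)
#>   sensitivity 100.0%  specificity 80.0%  accuracy 90.0%
```

`autoplot()` methods exist for test tables and connectivity summaries, and
`tidy()`/`glance()` for every result object. The whole pipeline also runs
from a config file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "fcpyramid"))
```

writing all intermediate artifacts plus a manifest (parameters, seed,
version, md5 per artifact) to the output directory; identical config and
seed give bit-identical artifacts.

## Documentation

The methods vignette (`vignettes/pyramid-networks.Rmd`) documents the
generative model and its defaults, every numerical convention (amplitude
scaling, rounding, tie-breaks, degree-<2 conventions, FDR families), the
statistical design of the validation suite, and known limitations.
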