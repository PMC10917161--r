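# Demo pipeline configuration: a small synthetic two-group cohort with an
# AD-like coupling/amplitude reduction at bilateral parahippocampal gyrus
# and hippocampus, run through every stage at all five scales.
seed: 42
stages: [simulate, connect, metrics, alff, stats, classify]
design:
  n_patients: 10
  n_controls: 10
  n_timepoints: 240
  tr_seconds: 2
  voxels_per_parcel: 4
  effect_nodes: [PHG_L, PHG_R, Hippo_L, Hippo_R]
  coupling_reduction: 0.5
  alff_reduction: 0.3
threshold_p: 0.5
band: [0.01, 0.1]
alpha: 0.05
k_folds: 5
svm:
  kernel: linear
  cost: 1
metrics: [clustering, alff]
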