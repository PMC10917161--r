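# programmatic fixtures: toy hierarchies and small cohorts

write_hierarchy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# 2-scale toy: finest parcels 1..3 named a,b,c; parents {1,2}->A, {3}->B
toy_hierarchy <- function() {
  load_hierarchy(write_hierarchy_tsv(data.frame(
    scale1_id = 1:3, scale1_name = c("a", "b", "c"),
    scale2_id = c(1L, 1L, 2L), scale2_name = c("A", "A", "B"))))
}

# 3-scale toy: 4 finest -> 2 mid -> 1 root
toy_hierarchy3 <- function() {
  load_hierarchy(write_hierarchy_tsv(data.frame(
    scale1_id = 1:4, scale1_name = c("a", "b", "c", "d"),
    scale2_id = c(1L, 1L, 2L, 2L), scale2_name = c("AB", "AB", "CD", "CD"),
    scale3_id = 1L, scale3_name = "root")))
}

single_parcel_hierarchy <- function() {
  load_hierarchy(write_hierarchy_tsv(data.frame(
    scale1_id = 1L, scale1_name = "only")))
}

small_cohort <- function(n_per_group = 5, voxels_per_parcel = 2, seed = 11,
                         ...) {
  generate_cohort(cohort_design(
    fcp_hierarchy(), n_patients = n_per_group, n_controls = n_per_group,
    voxels_per_parcel = voxels_per_parcel, seed = seed, ...))
}
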