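test_that("cohort generation is deterministic given the seed", {
  d <- cohort_design(fcp_hierarchy(), n_patients = 2, n_controls = 2,
                     voxels_per_parcel = 1, seed = 5)
  a <- generate_cohort(d)
  b <- generate_cohort(d)
  expect_identical(a$ts, b$ts)
  expect_identical(a$subject_id, b$subject_id)
  # different seed changes the data
  d2 <- cohort_design(fcp_hierarchy(), n_patients = 2, n_controls = 2,
                      voxels_per_parcel = 1, seed = 6)
  expect_false(identical(generate_cohort(d2)$ts, a$ts))
})

test_that("generated series are complete, non-degenerate and band-limited", {
  co <- small_cohort(n_per_group = 2, voxels_per_parcel = 2, seed = 3)
  for (ts in co$ts) {
    expect_false(anyNA(ts))
    expect_true(all(apply(ts, 2, stats::sd) > 0))
  }
  # pre-noise latent: all spectral power lies inside the band by construction
  withr::with_seed(1, {
    lat <- band_limited_signal(240, 2, c(0.01, 0.1), n_series = 5)
  })
  for (j in 1:5) {
    expect_gte(band_power_fraction(lat[, j], 2, c(0.01, 0.1)), 0.99)
    expect_equal(mean(lat[, j]^2), 1, tolerance = 1e-10)  # exact unit power
  }
})

test_that("band power fraction matches pure sinusoid placement", {
  t_sec <- (0:239) * 2
  expect_equal(band_power_fraction(sin(2 * pi * 0.05 * t_sec), 2,
                                   c(0.01, 0.1)), 1)
  expect_equal(band_power_fraction(sin(2 * pi * 0.2 * t_sec), 2,
                                   c(0.01, 0.1)), 0)
  expect_error(band_power_fraction(rep(1, 100), 2, c(0.01, 0.1)),
               "constant")
  expect_error(band_power_fraction(c(1, 2), 2, c(0.01, 0.1)), "4 time")
})

test_that("mixing weights reproduce the implied within-parcel correlation", {
  # two-scale toy tree; voxel = 1*parcel latent + 0.5*root latent + noise.
  # implied within-parcel correlation = (1 + 0.25) / (1 + 0.25 + sd^2);
  # sd^2 = 5/6 gives rho = 0.6 exactly.
  toy <- toy_hierarchy()
  d <- cohort_design(toy, n_patients = 1, n_controls = 1,
                     n_timepoints = 2000, voxels_per_parcel = 6,
                     module_coupling = c(1, 0.5), noise_sd = sqrt(5 / 6),
                     seed = 17)
  co <- generate_cohort(d)
  rho <- purrr::map_dbl(co$ts, function(ts) {
    labs <- attr(co, "labels")
    within <- c()
    for (p in unique(labs)) {
      cm <- stats::cor(ts[, labs == p])
      within <- c(within, cm[upper.tri(cm)])
    }
    mean(within)
  })
  expect_true(all(abs(rho - 0.6) < 0.05))
})

test_that("voxel correlation decays as the common ancestor coarsens", {
  toy <- toy_hierarchy3()    # {a,b}->AB, {c,d}->CD -> root
  d <- cohort_design(toy, n_patients = 1, n_controls = 1,
                     n_timepoints = 4000, voxels_per_parcel = 4,
                     module_coupling = c(1, 0.6, 0.3), noise_sd = 0.4,
                     seed = 23)
  co <- generate_cohort(d)
  labs <- attr(co, "labels")
  cm <- stats::cor(co$ts[[1]])
  lvl <- function(p, q) {   # mean correlation between voxels of parcels p, q
    mean(cm[labs == p, labs == q])
  }
  cm11 <- cm[labs == 1, labs == 1]
  same_parcel <- mean(cm11[upper.tri(cm11)])
  sibling <- lvl(1, 2)       # share AB and root
  cousin <- mean(c(lvl(1, 3), lvl(1, 4), lvl(2, 3), lvl(2, 4)))  # root only
  expect_gt(same_parcel, sibling)
  expect_gt(sibling, cousin)
  expect_gt(cousin, -0.05)   # still weakly positive through the root latent
})

test_that("null design makes the two groups statistically exchangeable", {
  # zero reductions: the generative law is identical for both groups, so a
  # label swap must leave group-difference statistics distributionally
  # unchanged; check mean strength difference is near zero across subjects
  co <- small_cohort(n_per_group = 10, voxels_per_parcel = 1, seed = 31)
  s <- purrr::map_dbl(co$ts, function(ts) mean(pearson_connectivity(ts)))
  expect_gt(stats::t.test(s[co$group == "patient"],
                          s[co$group == "control"])$p.value, 0.01)
})

test_that("design validation rejects impossible configurations", {
  h <- fcp_hierarchy()
  expect_error(cohort_design(h, band = c(0.01, 0.3)), "Nyquist")
  expect_error(cohort_design(h, band = c(0, 0.1)), "Nyquist")
  expect_error(cohort_design(h, coupling_reduction = 1.5), "0, 1")
  expect_error(cohort_design(h, n_patients = 0), "positive")
  expect_error(cohort_design(h, module_coupling = c(1, 1)), "per scale")
  expect_error(cohort_design(h, effect_nodes = 999L), "finest")
})

test_that("cohorts round-trip through TSV export", {
  co <- small_cohort(n_per_group = 2, voxels_per_parcel = 1, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort_tsv(co, dir)
  back <- read_cohort_tsv(dir, tr_seconds = 2)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(as.character(back$group), as.character(co$group))
  expect_equal(back$ts[[1]], co$ts[[1]], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(attr(back, "labels"), attr(co, "labels"))
})

test_that("cohorts round-trip through NIfTI export", {
  co <- small_cohort(n_per_group = 1, voxels_per_parcel = 1, seed = 13)
  dir <- withr::local_tempdir()
  write_cohort_nifti(co, dir)
  img <- RNifti::readNifti(file.path(dir, paste0(co$subject_id[1], ".nii.gz")))
  expect_equal(dim(img), c(84, 1, 1, 240))
  expect_equal(img[3, 1, 1, ], unname(co$ts[[1]][, 3]), tolerance = 1e-6)
  lab <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  expect_equal(as.vector(lab), attr(co, "labels"))
})
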