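#' Specify a synthetic BOLD cohort
#'
#' Describes a two-group resting-state cohort with the statistical structure
#' the downstream pipeline assumes: per-voxel signals are weighted sums of
#' band-limited latent signals attached to every parcel of the atlas tree at
#' every scale, so that the correlation between two voxels is governed by the
#' scale of their lowest common ancestor. A "patient" group effect enters as
#' a multiplicative reduction of the inter-node coupling and/or of the
#' low-frequency band amplitude at designated finest-scale parcels.
#'
#' @param hierarchy An `fcp_hierarchy` (default: the packaged five-scale
#'   gray-matter atlas).
#' @param n_patients,n_controls Group sizes (defaults 21 and 20).
#' @param n_timepoints Samples per subject (default 240, i.e. an 8-min scan
#'   at `tr_seconds = 2`).
#' @param tr_seconds Sampling interval in seconds (default 2).
#' @param voxels_per_parcel Voxels simulated per finest parcel; either a
#'   single count or a vector over finest parcels (default 10).
#' @param band Passband in Hz, `c(low, high)` (default `c(0.01, 0.1)`);
#'   must lie strictly inside (0, Nyquist).
#' @param module_coupling Mixing weight of the latent signal at each scale
#'   (finest first; length = number of scales). The weight at scale 1 is the
#'   parcel's own signal; weights at coarser scales induce between-parcel
#'   correlation that decays as the lowest common ancestor gets coarser.
#' @param effect_nodes Finest-scale parcels carrying the group effect, as ids
#'   or names (default: bilateral parahippocampal gyrus and hippocampus
#'   where those parcels exist in the hierarchy, otherwise none).
#' @param coupling_reduction In `[0, 1]`: patients' coupling weights to all
#'   ancestors (scales >= 2) at effect nodes are multiplied by
#'   `1 - coupling_reduction`, with the pre-noise signal sd renormalised so
#'   the band amplitude is unchanged (default 0: null design).
#' @param alff_reduction In `[0, 1]`: patients' pre-noise signal at effect
#'   nodes is multiplied by `1 - alff_reduction` (default 0).
#' @param noise_sd Sd of additive white voxel noise (default 0.5; the
#'   pre-noise signal has sd ~ 1.3 under the default couplings).
#' @param seed Integer seed; each subject draws from an independent stream
#'   derived from `(seed, subject index)`.
#' @return A `cohort_design` list, validated.
#' @export
cohort_design <- function(hierarchy = fcp_hierarchy(),
                          n_patients = 21, n_controls = 20,
                          n_timepoints = 240, tr_seconds = 2,
                          voxels_per_parcel = 10,
                          band = c(0.01, 0.1),
                          module_coupling = default_coupling(hierarchy),
                          effect_nodes = NULL,
                          coupling_reduction = 0, alff_reduction = 0,
                          noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(hierarchy, "fcp_hierarchy"))
  n_finest <- node_count(hierarchy, 1)
  if (length(voxels_per_parcel) == 1) {
    voxels_per_parcel <- rep(voxels_per_parcel, n_finest)
  }
  if (is.null(effect_nodes)) {
    # AD-like default where the packaged atlas is in use; otherwise none
    effect_nodes <- intersect(c("PHG_L", "PHG_R", "Hippo_L", "Hippo_R"),
                              hierarchy$parcels[[1]]$name)
  }
  if (is.character(effect_nodes)) {
    effect_nodes <- parcel_id(hierarchy, effect_nodes, scale = 1)
  }
  d <- structure(list(
    hierarchy = hierarchy, n_patients = n_patients, n_controls = n_controls,
    n_timepoints = n_timepoints, tr_seconds = tr_seconds,
    voxels_per_parcel = as.integer(voxels_per_parcel), band = band,
    module_coupling = module_coupling, effect_nodes = as.integer(effect_nodes),
    coupling_reduction = coupling_reduction, alff_reduction = alff_reduction,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "cohort_design")
  validate_design(d)
  d
}

# default mixing weights, finest scale first; truncated/padded for shallow
# hierarchies used in tests
default_coupling <- function(hierarchy) {
  w <- c(1, 0.6, 0.45, 0.35, 0.25)
  n <- hierarchy$n_scales
  if (n <= 5) w[seq_len(n)] else c(w, rep(0.2, n - 5))
}

validate_design <- function(d) {
  h <- d$hierarchy
  if (d$n_patients < 1 || d$n_controls < 1 || d$n_timepoints < 4 ||
      any(d$voxels_per_parcel < 1)) {
    stop("all counts in a cohort_design must be positive", call. = FALSE)
  }
  if (length(d$voxels_per_parcel) != node_count(h, 1)) {
    stop("voxels_per_parcel must have one entry per finest parcel",
         call. = FALSE)
  }
  nyquist <- 1 / (2 * d$tr_seconds)
  if (d$band[1] <= 0 || d$band[2] <= d$band[1] || d$band[2] >= nyquist) {
    stop("band must satisfy 0 < low < high < Nyquist = ", nyquist, " Hz",
         call. = FALSE)
  }
  if (length(d$module_coupling) != h$n_scales || any(d$module_coupling < 0) ||
      d$module_coupling[1] <= 0) {
    stop("module_coupling needs one nonnegative weight per scale, ",
         "with a positive weight at the finest scale", call. = FALSE)
  }
  if (d$coupling_reduction < 0 || d$coupling_reduction > 1 ||
      d$alff_reduction < 0 || d$alff_reduction > 1) {
    stop("coupling_reduction and alff_reduction must be in [0, 1]",
         call. = FALSE)
  }
  if (length(d$effect_nodes) &&
      !all(d$effect_nodes %in% h$parcels[[1]]$id)) {
    stop("effect_nodes must be finest-scale parcel ids", call. = FALSE)
  }
  invisible(d)
}

# DFT bin indices (1..floor(n/2)) whose frequency k/(n*tr) lies in band,
# endpoints inclusive
band_bins <- function(n, tr, band) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  k[f >= band[1] & f <= band[2]]
}

#' Band-limited random-phase signals
#'
#' Spectral synthesis: each series is a sum of unit-amplitude cosines at
#' every DFT bin frequency inside `band`, with independent uniform random
#' phases, scaled so the time-average variance is exactly 1. All power lies
#' inside the band by construction.
#'
#' @param n_timepoints Series length.
#' @param tr_seconds Sampling interval (s).
#' @param band Passband in Hz.
#' @param n_series Number of independent series.
#' @return A `n_timepoints x n_series` matrix.
#' @export
band_limited_signal <- function(n_timepoints, tr_seconds, band, n_series = 1) {
  bins <- band_bins(n_timepoints, tr_seconds, band)
  if (!length(bins)) {
    stop("no DFT bin frequencies fall inside the band; ",
         "lengthen the record or widen the band", call. = FALSE)
  }
  t_idx <- seq_len(n_timepoints) - 1
  ang <- outer(t_idx, bins) * (2 * pi / n_timepoints)
  phases <- matrix(stats::runif(length(bins) * n_series, 0, 2 * pi),
                   length(bins), n_series)
  x <- cos(ang) %*% cos(phases) - sin(ang) %*% sin(phases)
  x * sqrt(2 / length(bins))
}

# deterministic 31-bit stream seed from (seed, subject index)
subject_seed <- function(seed, idx) {
  (as.numeric(seed) * 2654435761 + as.numeric(idx) * 40503) %% 2147483629
}

#' Generate a synthetic cohort
#'
#' Draws every subject of the design from an independent, reproducible RNG
#' stream. For each subject, one band-limited latent signal is drawn per
#' parcel per scale; a voxel's pre-noise signal is the coupling-weighted sum
#' of the latents of its parcel's ancestors (all voxels of a parcel share
#' it), and white noise of sd `noise_sd` is added per voxel. In patients,
#' effect nodes have ancestor couplings multiplied by
#' `1 - coupling_reduction` (signal sd renormalised) and the pre-noise signal
#' multiplied by `1 - alff_reduction`.
#'
#' @param design A [cohort_design()].
#' @return An `fcp_cohort`: a tibble with columns `subject_id`, `group`
#'   (factor, `"patient"`/`"control"`) and `ts` (list of
#'   time-by-voxel matrices), with attributes `labels` (finest parcel id per
#'   voxel column), `tr_seconds` and `design`.
#' @export
generate_cohort <- function(design) {
  validate_design(design)
  h <- design$hierarchy
  n_scales <- h$n_scales
  finest <- h$parcels[[1]]$id
  n_finest <- length(finest)
  labels <- rep(finest, times = design$voxels_per_parcel)

  # latent index bookkeeping: one block of columns per scale
  offs <- as.integer(cumsum(c(0, node_counts(h))))
  lat_col <- function(s, ids) offs[s] + match(ids, h$parcels[[s]]$id)
  n_lat <- offs[n_scales + 1]

  # per-parcel ancestor latent columns (n_finest x n_scales)
  anc_cols <- vapply(seq_len(n_scales), function(s) {
    lat_col(s, h$ancestor[[s]][finest])
  }, integer(n_finest))

  w_base <- design$module_coupling
  sd_base <- sqrt(sum(w_base^2))
  is_effect <- finest %in% design$effect_nodes

  # per-parcel weight matrix for one group (n_finest x n_scales) and the
  # per-parcel post-mix scale factor
  group_weights <- function(patient) {
    w <- matrix(w_base, n_finest, n_scales, byrow = TRUE)
    gain <- rep(1, n_finest)
    if (patient && any(is_effect)) {
      if (n_scales > 1 && design$coupling_reduction > 0) {
        w[is_effect, -1] <- w[is_effect, -1] * (1 - design$coupling_reduction)
        gain[is_effect] <- sd_base / sqrt(rowSums(w[is_effect, , drop = FALSE]^2))
      }
      gain[is_effect] <- gain[is_effect] * (1 - design$alff_reduction)
    }
    list(w = w, gain = gain)
  }
  gw <- list(control = group_weights(FALSE), patient = group_weights(TRUE))

  n_subj <- design$n_patients + design$n_controls
  group <- rep(c("patient", "control"),
               c(design$n_patients, design$n_controls))
  subject_id <- ifelse(group == "patient",
                       sprintf("sub-P%02d", cumsum(group == "patient")),
                       sprintf("sub-C%02d", cumsum(group == "control")))

  ts_list <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    set.seed(subject_seed(design$seed, i))
    lat <- band_limited_signal(design$n_timepoints, design$tr_seconds,
                               design$band, n_lat)
    g <- gw[[group[i]]]
    node_sig <- matrix(0, design$n_timepoints, n_finest)
    for (s in seq_len(n_scales)) {
      node_sig <- node_sig +
        lat[, anc_cols[, s], drop = FALSE] *
          matrix(g$w[, s], design$n_timepoints, n_finest, byrow = TRUE)
    }
    node_sig <- node_sig *
      matrix(g$gain, design$n_timepoints, n_finest, byrow = TRUE)
    vox <- node_sig[, match(labels, finest), drop = FALSE] +
      design$noise_sd * matrix(stats::rnorm(design$n_timepoints * length(labels)),
                               design$n_timepoints)
    colnames(vox) <- paste0("v", seq_along(labels))
    ts_list[[i]] <- vox
  }

  out <- tibble::tibble(
    subject_id = subject_id,
    group = factor(group, levels = c("patient", "control")),
    ts = ts_list)
  attr(out, "labels") <- labels
  attr(out, "tr_seconds") <- design$tr_seconds
  attr(out, "design") <- design
  class(out) <- c("fcp_cohort", class(out))
  out
}

#' Fraction of spectral power inside a band
#'
#' Periodogram power at the positive-frequency bins, DC excluded; returns the
#' fraction falling at bin frequencies inside `band` (endpoints inclusive).
#'
#' @param x Numeric time series (length >= 4).
#' @param tr_seconds Sampling interval (s).
#' @param band Passband in Hz.
#' @return A fraction in `[0, 1]`.
#' @export
band_power_fraction <- function(x, tr_seconds, band) {
  n <- length(x)
  if (n < 4) stop("need at least 4 time points", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("constant series: band power fraction is undefined", call. = FALSE)
  }
  spec <- Mod(stats::fft(x))[2:(floor(n / 2) + 1)]^2
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr_seconds)
  sum(spec[f >= band[1] & f <= band[2]]) / sum(spec)
}

#' Write a cohort as per-subject TSV tables plus a manifest
#'
#' Each subject becomes `<subject_id>.tsv` (time by voxel, with a header of
#' voxel ids); `manifest.tsv` records subject id, group and file name;
#' `labels.tsv` records the finest-scale parcel id of every voxel column.
#'
#' @param cohort An `fcp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    readr::write_tsv(tibble::as_tibble(cohort$ts[[i]]),
                     file.path(dir, paste0(cohort$subject_id[i], ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(
    tibble::tibble(subject_id = cohort$subject_id,
                   group = as.character(cohort$group),
                   file = paste0(cohort$subject_id, ".tsv")),
    file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(voxel = colnames(cohort$ts[[1]]),
                   parcel_id = attr(cohort, "labels")),
    file.path(dir, "labels.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort_tsv()]
#'
#' @param dir Directory containing `manifest.tsv`, `labels.tsv` and the
#'   per-subject tables.
#' @param tr_seconds Sampling interval to attach (s).
#' @return An `fcp_cohort` (without a `design` attribute).
#' @export
read_cohort_tsv <- function(dir, tr_seconds = 2) {
  man <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  lab <- readr::read_tsv(file.path(dir, "labels.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  ts_list <- purrr::map(man$file, function(f) {
    as.matrix(readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                              progress = FALSE))
  })
  out <- tibble::tibble(
    subject_id = man$subject_id,
    group = factor(man$group, levels = c("patient", "control")),
    ts = ts_list)
  attr(out, "labels") <- as.integer(lab$parcel_id)
  attr(out, "tr_seconds") <- tr_seconds
  class(out) <- c("fcp_cohort", class(out))
  out
}

#' Write a cohort as NIfTI volumes
#'
#' Lays the voxels of each subject out along the x axis of a 4D image
#' (`n_voxels x 1 x 1 x n_timepoints`) and writes a matching 3D finest-scale
#' label volume, so that NIfTI-based tooling can round-trip the synthetic
#' data. Requires the RNifti package.
#'
#' @param cohort An `fcp_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- attr(cohort, "tr_seconds")
  labels <- attr(cohort, "labels")
  RNifti::writeNifti(array(as.integer(labels), c(length(labels), 1, 1)),
                     file.path(dir, "labels.nii.gz"))
  for (i in seq_len(nrow(cohort))) {
    x <- t(cohort$ts[[i]])                       # voxels x time
    img <- array(x, c(nrow(x), 1, 1, ncol(x)))
    img <- RNifti::asNifti(img, pixdim = c(1, 1, 1, tr))
    RNifti::writeNifti(img, file.path(dir, paste0(cohort$subject_id[i],
                                                  ".nii.gz")))
  }
  invisible(dir)
}
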