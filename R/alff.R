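#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per time series, the sum of single-sided DFT amplitudes over the bins
#' whose frequency `k/(n * tr)` lies inside `band` (endpoints inclusive, DC
#' excluded). Amplitude is `2 |X_k| / n`, so a pure in-band sinusoid of
#' amplitude A at a bin frequency yields ALFF = A exactly, and doubling the
#' amplitude doubles the ALFF.
#'
#' @param ts Time-by-unit numeric matrix (or a single series).
#' @param tr_seconds Sampling interval in seconds.
#' @param band Passband in Hz (default `c(0.01, 0.1)`); must lie inside
#'   (0, Nyquist).
#' @return Named numeric vector of nonnegative ALFF values, one per unit.
#' @export
compute_alff <- function(ts, tr_seconds, band = c(0.01, 0.1)) {
  if (is.vector(ts)) ts <- matrix(ts, ncol = 1)
  n <- nrow(ts)
  nyquist <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyquist) {
    stop("band must satisfy 0 < low < high < Nyquist = ", nyquist, " Hz",
         call. = FALSE)
  }
  bins <- band_bins(n, tr_seconds, band)
  if (!length(bins)) {
    stop("no DFT bin frequencies fall inside the band", call. = FALSE)
  }
  amp <- 2 * Mod(stats::mvfft(ts)[bins + 1, , drop = FALSE]) / n
  out <- colSums(amp)
  names(out) <- colnames(ts)
  out
}

#' z-score a map across units
#'
#' Centers and scales with the sample standard deviation (n - 1) across all
#' included units, giving a map with mean 0 and sd 1 — the "normalized
#' across the whole brain" convention.
#'
#' @param x Numeric vector (>= 2 units, nonzero dispersion).
#' @return z-scored vector.
#' @export
zscore_map <- function(x) {
  if (length(x) < 2) stop("need at least 2 units to z-score", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero dispersion: z-score undefined", call. = FALSE)
  (x - mean(x)) / s
}

#' Node-averaged ALFF
#'
#' Unweighted mean of per-voxel (z-scored) ALFF values within each parcel at
#' the requested scale.
#'
#' @param alff_map Per-voxel values (typically z-scored).
#' @param labels Finest-scale parcel id per voxel.
#' @param h An `fcp_hierarchy`.
#' @param scale Target scale.
#' @return Named numeric vector, one value per node in atlas order.
#' @export
node_average_alff <- function(alff_map, labels, h, scale = 1) {
  check_scale(h, scale)
  if (length(alff_map) != length(labels)) {
    stop("labels must have one entry per unit", call. = FALSE)
  }
  lab_s <- coarsen_labels(h, labels, scale)
  ids <- h$parcels[[scale]]$id
  empty <- setdiff(ids, lab_s)
  if (length(empty)) {
    stop("no voxels for node(s) ",
         paste(h$parcels[[scale]]$name[match(empty, ids)], collapse = ", "),
         " at scale ", scale, call. = FALSE)
  }
  grp <- factor(lab_s, levels = ids)
  out <- as.vector(tapply(alff_map, grp, mean))
  names(out) <- h$parcels[[scale]]$name
  out
}

#' Per-subject, per-scale node-averaged ALFF features for a cohort
#'
#' Computes voxel ALFF in `band`, z-scores across voxels within subject, and
#' averages within nodes at the requested scales.
#'
#' @param cohort An `fcp_cohort`.
#' @param h Hierarchy (default: from the cohort design).
#' @param scales Scales (default: all).
#' @param band Passband in Hz.
#' @return Tidy tibble: `subject_id`, `group`, `scale`, `node_id`,
#'   `node_name`, `metric` (`"alff"`), `value`.
#' @export
cohort_alff <- function(cohort, h = cohort_hierarchy(cohort),
                        scales = seq_len(h$n_scales), band = c(0.01, 0.1)) {
  labels <- attr(cohort, "labels")
  tr <- attr(cohort, "tr_seconds")
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    zmap <- zscore_map(compute_alff(cohort$ts[[i]], tr, band))
    purrr::map_dfr(as.integer(scales), function(s) {
      v <- node_average_alff(zmap, labels, h, s)
      tibble::tibble(subject_id = cohort$subject_id[i],
                     group = cohort$group[i], scale = s,
                     node_id = h$parcels[[s]]$id,
                     node_name = names(v), metric = "alff",
                     value = unname(v))
    })
  })
}
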