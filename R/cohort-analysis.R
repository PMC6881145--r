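#' Extract features for every cell and timepoint of a cohort
#'
#' @param cells list of cells from [generate_cohort()].
#' @param what features to compute: `"all"` or a subset of
#'   `c("rs", "rin", "sag", "spikes", "vm_variance")` (`"spikes"` covers all
#'   spike-based features and the per-amplitude counts). Features not
#'   requested are `NA`.
#' @return data frame, one row per cell x timepoint, with the scalar
#'   [extract_features()] fields as columns plus a `spike_counts` list
#'   column (mean count per amplitude).
#' @export
cohort_features <- function(cells, what = "all") {
  rows <- list()
  for (cell in cells) {
    for (tp in names(cell$blocks)) {
      f <- extract_features(cell$blocks[[tp]], timepoint = tp,
                            cell_id = cell$id, what = what)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell$id, condition = cell$condition, timepoint = tp,
        n_tbs_spikes = cell$n_tbs_spikes,
        rs = f$rs, rin = f$rin, sag_ratio = f$sag_ratio,
        ap_threshold = f$ap_threshold, ahp_min = f$ahp_min,
        latency_ms = f$latency_ms, burst_index = f$burst_index,
        vm_variance = f$vm_variance, firing_rate_max = f$firing_rate_max,
        vm_rest = f$vm_rest, spike_amplitude = f$spike_amplitude,
        spike_counts = I(list(f$spike_counts)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-cell changes between the pre block and a post timepoint
#'
#' Firing (mean spike count on the maximal step), input resistance and
#' first-spike latency are expressed as percent change; sag ratio, spike
#' threshold, AHP and Vm variance as absolute differences, matching how the
#' corresponding group statistics are conventionally reported.
#'
#' @param features data frame from [cohort_features()].
#' @param post post timepoint label (default `"20"`).
#' @return data frame, one row per cell.
#' @export
cohort_changes <- function(features, post = "20") {
  pre <- features[features$timepoint == "pre", ]
  pst <- features[features$timepoint == post, ]
  m <- match(pre$cell_id, pst$cell_id)
  pst <- pst[m, ]
  data.frame(
    cell_id = pre$cell_id, condition = pre$condition,
    n_tbs_spikes = pre$n_tbs_spikes,
    firing_pre = pre$firing_rate_max, firing_post = pst$firing_rate_max,
    change_firing = percent_change(pre$firing_rate_max, pst$firing_rate_max),
    rin_pre = pre$rin, rin_post = pst$rin,
    change_rin = percent_change(pre$rin, pst$rin),
    latency_pre = pre$latency_ms, latency_post = pst$latency_ms,
    change_latency = percent_change(pre$latency_ms, pst$latency_ms),
    sag_pre = pre$sag_ratio, sag_post = pst$sag_ratio,
    d_sag = pst$sag_ratio - pre$sag_ratio,
    d_threshold = pst$ap_threshold - pre$ap_threshold,
    d_ahp = pst$ahp_min - pre$ahp_min,
    d_vm_variance = pst$vm_variance - pre$vm_variance,
    stringsAsFactors = FALSE)
}

#' Normalized input-output curves for a cohort
#'
#' Builds each cell's per-timepoint IO curve from the per-amplitude mean
#' spike counts already held in a [cohort_features()] table and normalizes
#' every timepoint against that cell's pre curve.
#'
#' @param features data frame from [cohort_features()] (needs the
#'   `spike_counts` list column).
#' @return list of `normalized_io` objects (all cells, all timepoints).
#' @export
cohort_io_normalized <- function(features) {
  out <- list()
  for (cid in unique(features$cell_id)) {
    rows <- features[features$cell_id == cid, ]
    curves <- lapply(seq_len(nrow(rows)), function(i) {
      counts <- rows$spike_counts[[i]]
      structure(list(timepoint = rows$timepoint[i], cell_id = cid,
                     amplitudes = as.numeric(names(counts)),
                     mean_counts = as.numeric(counts)),
                class = "io_curve")
    })
    pre <- curves[[which(rows$timepoint == "pre")[1]]]
    out <- c(out, lapply(curves, normalize_io, pre = pre))
  }
  out
}

#' Full plasticity comparison between two simulated groups
#'
#' Runs the feature -> change -> statistics pipeline for a stimulated and a
#' comparison cohort: group statistics for firing, input resistance and
#' latency; the spike-count correlation within the stimulated group; and
#' the pooled IO-fit slope/intercept comparison pre vs post.
#'
#' @param cells_a stimulated cohort (list from [generate_cohort()]).
#' @param cells_b comparison cohort.
#' @param post post timepoint label.
#' @param labels group labels.
#' @param what feature subset passed to [cohort_features()].
#' @return list with `changes_a`, `changes_b`, `firing`, `rin`, `latency`
#'   ([group_stats()] outputs), `correlation`
#'   ([correlate_with_stimulation()] output) and `io_fit`
#'   ([compare_io_fits()] output for group A).
#' @export
analyze_cohorts <- function(cells_a, cells_b, post = "20",
                            labels = c("TBS", "control"), what = "all") {
  fa <- cohort_features(cells_a, what)
  fb <- cohort_features(cells_b, what)
  ca <- cohort_changes(fa, post)
  cb <- cohort_changes(fb, post)
  res <- list(changes_a = ca, changes_b = cb)
  res$firing <- group_stats(ca$firing_pre, ca$firing_post,
                            cb$firing_pre, cb$firing_post, labels)
  res$rin <- group_stats(ca$rin_pre, ca$rin_post,
                         cb$rin_pre, cb$rin_post, labels)
  res$latency <- group_stats(ca$latency_pre, ca$latency_post,
                             cb$latency_pre, cb$latency_post, labels)
  res$correlation <- tryCatch(
    correlate_with_stimulation(ca$n_tbs_spikes, ca$change_firing),
    error = function(e) NULL)
  res$io_fit <- compare_io_fits(cohort_io_normalized(fa), "pre", post)
  res
}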