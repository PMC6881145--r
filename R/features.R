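#' Detect action potentials by the dV/dt threshold criterion
#'
#' The spike threshold is the first sample in each rising phase where dV/dt
#' (central differences) reaches `dvdt_thresh`; the peak is the maximum of
#' the following rising segment. Candidate crossings that are not followed
#' by a rise of at least `min_rise` mV within `rise_window_ms` are rejected
#' as noise.
#'
#' @param sweep an [ie_sweep()] object.
#' @param dvdt_thresh threshold on dV/dt (V/s, equivalently mV/ms).
#' @param min_rise minimal voltage rise above the threshold point for a
#'   crossing to count as a spike (mV).
#' @param rise_window_ms window used both to verify the rise and to locate
#'   the peak (ms).
#' @return data frame with one row per spike: `idx_threshold`,
#'   `t_threshold`, `v_threshold`, `idx_peak`, `t_peak`, `v_peak`, ordered
#'   in time.
#' @export
detect_spikes <- function(sweep, dvdt_thresh = 10, min_rise = 20,
                          rise_window_ms = 5) {
  if (sweep$dt > 0.2) {
    warning("dt > 0.2 ms is too coarse to resolve dV/dt reliably", call. = FALSE)
  }
  detect_spikes_v(sweep$v, sweep$dt, dvdt_thresh, min_rise, rise_window_ms)
}

# vector version used internally (spontaneous traces have no step metadata);
# the scan itself is compiled (see src/detect.cpp)
detect_spikes_v <- function(v, dt, dvdt_thresh = 10, min_rise = 20,
                            rise_window_ms = 5) {
  w <- as.integer(round(rise_window_ms / dt))
  idx <- detect_crossings_cpp(v, dt, dvdt_thresh, min_rise, w)
  spike_df(idx[, 1], idx[, 2], v, dt)
}

# fast-path data.frame assembly (no type/name checking overhead)
spike_df <- function(thr_idx, peak_idx, v, dt) {
  structure(list(idx_threshold = thr_idx, t_threshold = (thr_idx - 1) * dt,
                 v_threshold = v[thr_idx], idx_peak = peak_idx,
                 t_peak = (peak_idx - 1) * dt, v_peak = v[peak_idx]),
            class = "data.frame",
            row.names = if (length(thr_idx)) seq_along(thr_idx) else integer(0))
}

# profiled least-squares fit of y = C + A * exp(-t / tau) over the window;
# SSE is minimized over tau with the linear coefficients solved exactly
fit_exp_window <- function(t, y, tau_range = c(2, 200)) {
  sse <- function(tau) {
    x <- exp(-t / tau)
    vx <- stats::var(x)
    if (vx < .Machine$double.eps) return(sum((y - mean(y))^2))
    a <- stats::cov(x, y) / vx
    r <- y - (mean(y) - a * mean(x)) - a * x
    sum(r^2)
  }
  tau <- stats::optimize(sse, tau_range)$minimum
  x <- exp(-t / tau)
  a <- stats::cov(x, y) / stats::var(x)
  C <- mean(y) - a * mean(x)
  list(C = C, A = a, tau = tau, v0 = C + a)
}

#' Estimate series resistance from hyperpolarizing steps
#'
#' Fits a single exponential to each sweep between `window[1]` and
#' `window[2]` ms after step onset, extrapolates back to onset to estimate
#' the instantaneous voltage drop, and regresses the drop against the
#' injected current; the slope is the series resistance.
#'
#' @param hyper_sweeps list of hyperpolarizing [ie_sweep()] objects spanning
#'   at least two distinct amplitudes.
#' @param window fit window after step onset (ms).
#' @param average_repeats average repeats at each amplitude before fitting
#'   (the default; the short fit window makes single-trace fits on noisy
#'   recordings unstable under extrapolation). `FALSE` fits each sweep.
#' @return series resistance (MOhm).
#' @export
estimate_series_resistance <- function(hyper_sweeps, window = c(5, 15),
                                       average_repeats = TRUE) {
  if (average_repeats) {
    amp_of <- vapply(hyper_sweeps, function(s) s$step_amp, numeric(1))
    hyper_sweeps <- lapply(split(hyper_sweeps, amp_of), function(grp) {
      avg <- grp[[1]]
      avg$v <- rowMeans(vapply(grp, function(s) s$v,
                               numeric(length(grp[[1]]$v))))
      avg
    })
  }
  drops <- amps <- numeric(0)
  for (s in hyper_sweeps) {
    t_rel <- sweep_times(s) - (s$step_onset - 1) * s$dt
    idx <- which(t_rel >= window[1] & t_rel <= window[2])
    fit <- tryCatch(fit_exp_window(t_rel[idx], s$v[idx]),
                    error = function(e) NULL)
    if (is.null(fit)) next # flagged sweep: fit failure
    drops <- c(drops, fit$v0 - sweep_baseline(s))
    amps <- c(amps, s$step_amp)
  }
  if (length(unique(amps)) < 2L) {
    stop("series-resistance estimate needs >= 2 distinct hyperpolarizing amplitudes",
         call. = FALSE)
  }
  slope <- stats::coef(stats::lm(drops ~ amps))[["amps"]] # mV / pA
  slope * 1000 # MOhm
}

# per-sweep minimum deflection (mV, negative) within `window_ms` of onset
min_deflection <- function(s, window_ms = 150) {
  i1 <- min(length(s$v), s$step_onset + as.integer(round(window_ms / s$dt)))
  min(s$v[s$step_onset:i1]) - sweep_baseline(s)
}

# aggregate per-sweep values: mean over repeats per amplitude, then median
# across amplitudes
mean_then_median <- function(values, amps) {
  stats::median(tapply(values, amps, mean))
}

#' Input resistance from hyperpolarizing steps
#'
#' Per sweep, the minimum voltage within the first 150 ms of the step minus
#' the pre-step baseline, divided by the step current. Repeats at the same
#' amplitude are averaged; the cell value is the median across amplitudes.
#'
#' @param hyper_sweeps list of hyperpolarizing [ie_sweep()] objects.
#' @param window_ms search window for the voltage minimum (ms).
#' @return input resistance (MOhm, positive).
#' @export
input_resistance <- function(hyper_sweeps, window_ms = 150) {
  hyper_sweeps <- Filter(function(s) s$step_amp < 0, hyper_sweeps)
  if (!length(hyper_sweeps)) {
    stop("input resistance requires hyperpolarizing sweeps", call. = FALSE)
  }
  rin <- vapply(hyper_sweeps,
                function(s) 1000 * min_deflection(s, window_ms) / s$step_amp,
                numeric(1))
  amps <- vapply(hyper_sweeps, function(s) s$step_amp, numeric(1))
  mean_then_median(rin, amps)
}

#' Sag ratio from hyperpolarizing steps
#'
#' Computed on baseline-subtracted deflections: the median deflection over
#' the final 50 ms of the step divided by the minimum deflection within the
#' first 150 ms. Repeats are averaged per amplitude and the cell value is
#' the median across amplitudes. A ratio below 1 indicates I_h-mediated sag.
#'
#' @inheritParams input_resistance
#' @param steady_ms length of the steady-state window at the end of the
#'   step (ms).
#' @return sag ratio (dimensionless).
#' @export
sag_ratio <- function(hyper_sweeps, window_ms = 150, steady_ms = 50) {
  hyper_sweeps <- Filter(function(s) s$step_amp < 0, hyper_sweeps)
  if (!length(hyper_sweeps)) {
    stop("sag ratio requires hyperpolarizing sweeps", call. = FALSE)
  }
  ratio <- vapply(hyper_sweeps, function(s) {
    dmin <- min_deflection(s, window_ms)
    if (dmin == 0) stop("undefined sag ratio: zero minimum deflection", call. = FALSE)
    i0 <- max(s$step_onset, s$step_offset - as.integer(round(steady_ms / s$dt)) + 1L)
    steady <- stats::median(s$v[i0:s$step_offset]) - sweep_baseline(s)
    steady / dmin
  }, numeric(1))
  amps <- vapply(hyper_sweeps, function(s) s$step_amp, numeric(1))
  mean_then_median(ratio, amps)
}

# detect spikes once per sweep, scanning only the step window (plus a small
# margin); indices are shifted back to full-sweep coordinates
spikes_per_sweep <- function(sweeps, margin_ms = 2, ...) {
  lapply(sweeps, function(s) {
    m <- as.integer(round(margin_ms / s$dt))
    i0 <- max(1L, s$step_onset - m)
    i1 <- min(length(s$v), s$step_offset + m)
    e <- detect_spikes_v(s$v[i0:i1], s$dt, ...)
    if (nrow(e) && i0 > 1L) {
      sh <- i0 - 1L
      e$idx_threshold <- e$idx_threshold + sh
      e$idx_peak <- e$idx_peak + sh
      e$t_threshold <- e$t_threshold + sh * s$dt
      e$t_peak <- e$t_peak + sh * s$dt
    }
    e
  })
}

#' Action-potential threshold feature
#'
#' Median over depolarizing sweeps of the first spike's threshold voltage
#' (the dV/dt criterion point).
#'
#' @param depol_sweeps list of depolarizing [ie_sweep()] objects.
#' @param events optional precomputed [detect_spikes()] output per sweep.
#' @return threshold (mV), or `NA` if no sweep contains a spike.
#' @export
ap_threshold_feature <- function(depol_sweeps, events = NULL) {
  events <- events %||% spikes_per_sweep(depol_sweeps)
  firsts <- vapply(events, function(e) {
    if (nrow(e)) e$v_threshold[1] else NA_real_
  }, numeric(1))
  if (all(is.na(firsts))) return(NA_real_)
  stats::median(firsts, na.rm = TRUE)
}

#' Afterhyperpolarization feature
#'
#' For each eligible spike, the minimum voltage within 50 ms after the
#' spike threshold; a spike is eligible only if neither the next spike's
#' threshold nor the end of the current step falls inside that window. The
#' feature is the mean over eligible spikes across all depolarizing sweeps.
#'
#' @inheritParams ap_threshold_feature
#' @param window_ms AHP search window after the threshold point (ms).
#' @return AHP minimum (mV), or `NA` if no spike is eligible.
#' @export
ahp_feature <- function(depol_sweeps, events = NULL, window_ms = 50) {
  events <- events %||% spikes_per_sweep(depol_sweeps)
  vals <- numeric(0)
  for (si in seq_along(depol_sweeps)) {
    s <- depol_sweeps[[si]]
    e <- events[[si]]
    if (!nrow(e)) next
    t_end <- (s$step_offset - 1) * s$dt
    w <- as.integer(round(window_ms / s$dt))
    for (k in seq_len(nrow(e))) {
      t_thr <- e$t_threshold[k]
      next_thr <- if (k < nrow(e)) e$t_threshold[k + 1] else Inf
      if (next_thr <= t_thr + window_ms) next
      if (t_end <= t_thr + window_ms) next
      i0 <- e$idx_threshold[k] + 1L
      i1 <- min(length(s$v), e$idx_threshold[k] + w)
      vals <- c(vals, min(s$v[i0:i1]))
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Latency to first spike on the maximal current steps
#'
#' Per sweep at the maximal depolarizing amplitude, the time from step onset
#' to the first spike threshold; averaged across repeats. Sweeps without
#' spikes are excluded.
#'
#' @inheritParams ap_threshold_feature
#' @return latency (ms), or `NA` if no maximal-step sweep spikes.
#' @export
first_spike_latency <- function(depol_sweeps, events = NULL) {
  if (!length(depol_sweeps)) return(NA_real_)
  events <- events %||% spikes_per_sweep(depol_sweeps)
  amps <- vapply(depol_sweeps, function(s) s$step_amp, numeric(1))
  keep <- amps == max(amps)
  lat <- mapply(function(s, e) {
    if (!nrow(e)) return(NA_real_)
    e$t_threshold[1] - (s$step_onset - 1) * s$dt
  }, depol_sweeps[keep], events[keep])
  if (all(is.na(lat))) return(NA_real_)
  mean(lat, na.rm = TRUE)
}

# fraction of spikes participating in an inter-spike interval < isi_ms
in_burst_fraction <- function(t_spikes, isi_ms) {
  n <- length(t_spikes)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(0)
  short <- diff(t_spikes) < isi_ms
  inb <- c(short, FALSE) | c(FALSE, short)
  sum(inb) / n
}

#' Burst index
#'
#' A spike is "in a burst" if it participates in any inter-spike interval
#' shorter than `isi_ms`. Per sweep, the fraction of in-burst spikes; per
#' amplitude, the mean over repeats (or, in `"pooled"` mode, pooled in-burst
#' spikes over pooled spikes). The cell value is the highest per-amplitude
#' value among amplitudes whose mean spike count is at least `min_spikes`.
#'
#' @inheritParams ap_threshold_feature
#' @param isi_ms burst-defining inter-spike interval (ms).
#' @param min_spikes minimal mean spike count for an amplitude to qualify.
#' @param mode `"per_sweep"` (default) averages per-sweep fractions;
#'   `"pooled"` pools spikes across repeats before taking the fraction.
#' @return burst index in \[0, 1\], or `NA` if no amplitude qualifies.
#' @export
burst_index <- function(depol_sweeps, events = NULL, isi_ms = 10,
                        min_spikes = 5, mode = c("per_sweep", "pooled")) {
  mode <- match.arg(mode)
  events <- events %||% spikes_per_sweep(depol_sweeps)
  amps <- vapply(depol_sweeps, function(s) s$step_amp, numeric(1))
  counts <- vapply(events, nrow, integer(1))
  out <- NA_real_
  for (a in unique(amps)) {
    sel <- amps == a
    if (mean(counts[sel]) < min_spikes) next
    if (mode == "per_sweep") {
      fr <- vapply(events[sel], function(e) in_burst_fraction(e$t_threshold, isi_ms),
                   numeric(1))
      val <- mean(fr, na.rm = TRUE)
    } else {
      inb <- tot <- 0
      for (e in events[sel]) {
        n <- nrow(e)
        if (!n) next
        tot <- tot + n
        inb <- inb + n * in_burst_fraction(e$t_threshold, isi_ms)
      }
      val <- if (tot > 0) inb / tot else NA_real_
    }
    if (is.na(out) || (!is.na(val) && val > out)) out <- val
  }
  out
}

#' Membrane-potential variance of spontaneous activity
#'
#' Variance computed in non-overlapping segments of `segment_s` seconds; the
#' returned value is the median across segments. Spikes, if present, are
#' excised by blanking `blank_ms` around each peak before segmenting.
#'
#' @param v voltage samples (mV) of a spontaneous stretch.
#' @param dt sampling interval (ms).
#' @param segment_s segment length (s).
#' @param blank_ms half-width of the spike blanking window (ms).
#' @return median segment variance (mV^2).
#' @export
vm_variance <- function(v, dt, segment_s = 5, blank_ms = 5) {
  seg_n <- as.integer(round(segment_s * 1000 / dt))
  if (length(v) < seg_n) {
    stop("trace shorter than one segment", call. = FALSE)
  }
  sp <- detect_spikes_v(v, dt)
  if (nrow(sp)) {
    w <- as.integer(round(blank_ms / dt))
    for (i in sp$idx_peak) {
      v[max(1L, i - w):min(length(v), i + w)] <- NA
    }
  }
  n_seg <- length(v) %/% seg_n
  vars <- vapply(seq_len(n_seg), function(k) {
    stats::var(v[((k - 1) * seg_n + 1):(k * seg_n)], na.rm = TRUE)
  }, numeric(1))
  stats::median(vars)
}

#' Quality-control check for a recorded cell
#'
#' A cell passes if its resting membrane potential is below -55 mV, its
#' series resistance below 100 MOhm, and its spike amplitude above 40 mV
#' (all strict inequalities). Missing values fail the corresponding
#' criterion.
#'
#' @param features a [cell_features()] object or any list with `vm_rest`,
#'   `rs` and `spike_amplitude`.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
qc_pass <- function(features) {
  reasons <- character(0)
  if (is.na(features$vm_rest) || features$vm_rest >= -55) {
    reasons <- c(reasons, "vm_rest")
  }
  if (is.na(features$rs) || features$rs >= 100) {
    reasons <- c(reasons, "rs")
  }
  if (is.na(features$spike_amplitude) || features$spike_amplitude <= 40) {
    reasons <- c(reasons, "spike_amplitude")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Extract all intrinsic-excitability features from a block of sweeps
#'
#' Composes the individual feature operations over one testing block
#' (hyperpolarizing and depolarizing sweeps plus an optional spontaneous
#' segment). Features whose sweep class is missing are returned as `NA` and
#' listed in the `missing` element.
#'
#' @param block list with `sweeps` (list of [ie_sweep()]) and optionally
#'   `spont` (list with `v`, `dt`).
#' @param timepoint optional label stored with the result.
#' @param cell_id optional label stored with the result.
#' @param what `"all"` or a subset of
#'   `c("rs", "rin", "sag", "spikes", "vm_variance")`; features not
#'   requested come back `NA`. Trimming the set skips their computation,
#'   which matters in large simulation sweeps.
#' @return an object of class `cell_features`: fields `rs`, `rin`,
#'   `sag_ratio`, `ap_threshold`, `ahp_min`, `latency_ms`, `burst_index`,
#'   `vm_variance`, `spike_counts` (named vector, mean count per amplitude),
#'   `firing_rate_max` (mean count on the maximal step), `vm_rest`,
#'   `spike_amplitude`.
#' @export
extract_features <- function(block, timepoint = NA_character_,
                             cell_id = NA_character_, what = "all") {
  want <- function(x) identical(what, "all") || x %in% what
  sweeps <- block$sweeps
  amps <- vapply(sweeps, function(s) s$step_amp, numeric(1))
  hyper <- sweeps[amps < 0]
  depol <- if (want("spikes")) sweeps[amps > 0] else list()
  missing <- character(0)

  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  if (length(hyper)) {
    rs <- if (want("rs")) safe(estimate_series_resistance(hyper)) else NA_real_
    rin <- if (want("rin")) safe(input_resistance(hyper)) else NA_real_
    sag <- if (want("sag")) safe(sag_ratio(hyper)) else NA_real_
  } else {
    rs <- rin <- sag <- NA_real_
    missing <- c(missing, "hyperpolarizing sweeps")
  }

  if (length(depol)) {
    events <- spikes_per_sweep(depol)
    thr <- ap_threshold_feature(depol, events)
    ahp <- ahp_feature(depol, events)
    lat <- first_spike_latency(depol, events)
    bi <- burst_index(depol, events)
    counts <- vapply(events, nrow, integer(1))
    damps <- vapply(depol, function(s) s$step_amp, numeric(1))
    spike_counts <- tapply(counts, damps, mean)
    firing_max <- unname(spike_counts[as.character(max(damps))])
    all_amp <- unlist(lapply(events, function(e) e$v_peak - e$v_threshold))
    spike_amp <- if (length(all_amp)) mean(all_amp) else NA_real_
  } else {
    thr <- ahp <- lat <- bi <- firing_max <- spike_amp <- NA_real_
    spike_counts <- numeric(0)
    missing <- c(missing, "depolarizing sweeps")
  }

  vm_rest <- mean(vapply(sweeps, sweep_baseline, numeric(1)))
  vmvar <- if (!want("vm_variance")) {
    NA_real_
  } else if (!is.null(block$spont)) {
    safe(vm_variance(block$spont$v, block$spont$dt))
  } else {
    missing <- c(missing, "spontaneous trace")
    NA_real_
  }

  structure(list(cell_id = cell_id, timepoint = timepoint,
                 rs = rs, rin = rin, sag_ratio = sag,
                 ap_threshold = thr, ahp_min = ahp, latency_ms = lat,
                 burst_index = bi, vm_variance = vmvar,
                 spike_counts = spike_counts, firing_rate_max = firing_max,
                 vm_rest = vm_rest, spike_amplitude = spike_amp,
                 missing = missing),
            class = "cell_features")
}

#' @export
print.cell_features <- function(x, ...) {
  cat(sprintf("<cell_features> %s / %s\n", x$cell_id, x$timepoint))
  cat(sprintf("  Rs=%.1f MOhm  Rin=%.1f MOhm  sag=%.3f  Vrest=%.1f mV\n",
              x$rs, x$rin, x$sag_ratio, x$vm_rest))
  cat(sprintf("  threshold=%.1f mV  AHP=%.1f mV  latency=%.1f ms  burst=%.2f\n",
              x$ap_threshold, x$ahp_min, x$latency_ms, x$burst_index))
  cat(sprintf("  Vm var=%.2f mV^2  max-step count=%.1f  spike amp=%.1f mV\n",
              x$vm_variance, x$firing_rate_max, x$spike_amplitude))
  invisible(x)
}
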