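#' Build an input-output curve from spike counts
#'
#' Mean spike count per depolarizing amplitude at one timepoint.
#'
#' @param counts numeric vector of spike counts, one per sweep.
#' @param amps step amplitude (pA) per sweep, parallel to `counts`.
#' @param timepoint label (e.g. `"pre"`, `"20"`).
#' @param cell_id optional cell label.
#' @return an object of class `io_curve` with `amplitudes` (increasing) and
#'   `mean_counts`.
#' @export
build_io_curve <- function(counts, amps, timepoint = "pre",
                           cell_id = NA_character_) {
  if (length(counts) != length(amps)) {
    stop("counts and amps must be parallel vectors", call. = FALSE)
  }
  m <- tapply(counts, amps, mean)
  a <- as.numeric(names(m))
  o <- order(a)
  structure(list(timepoint = timepoint, cell_id = cell_id,
                 amplitudes = a[o], mean_counts = as.numeric(m)[o]),
            class = "io_curve")
}

#' Normalize an input-output curve against the pre-stimulation curve
#'
#' Spike counts are mapped through `(X - minPre) / (maxPre - minPre)`,
#' where `minPre` and `maxPre` are the pre curve's mean counts at its
#' smallest and largest amplitude. The current axis is mapped linearly to
#' \[0, 1\] over the cell's amplitude range, correcting for per-cell
#' differences in the step amplitudes used.
#'
#' @param curve an `io_curve` to normalize.
#' @param pre the same cell's pre-stimulation `io_curve`.
#' @return an object of class `normalized_io` with `norm_current` and
#'   `norm_count`.
#' @export
normalize_io <- function(curve, pre) {
  min_pre <- pre$mean_counts[1]
  max_pre <- pre$mean_counts[length(pre$mean_counts)]
  if (max_pre == min_pre) {
    stop("degenerate pre curve: maxPre equals minPre", call. = FALSE)
  }
  rng <- range(curve$amplitudes)
  structure(list(timepoint = curve$timepoint, cell_id = curve$cell_id,
                 norm_current = (curve$amplitudes - rng[1]) / diff(rng),
                 norm_count = (curve$mean_counts - min_pre) / (max_pre - min_pre)),
            class = "normalized_io")
}

#' Compare pooled linear fits of normalized input-output curves
#'
#' Pools every cell's normalized points at each of two timepoints and fits
#' straight lines; equality of slopes is tested by the current-by-timepoint
#' interaction term of the full model, and equality of intercepts by the
#' timepoint term of the common-slope (additive) model.
#'
#' @param normalized list of `normalized_io` objects (both timepoints mixed).
#' @param timepoint_a,timepoint_b the two timepoint labels to compare.
#' @return list with `slope_p`, `intercept_p`, and the pooled fit
#'   coefficients per timepoint.
#' @export
compare_io_fits <- function(normalized, timepoint_a = "pre", timepoint_b = "20") {
  tps <- vapply(normalized, function(x) as.character(x$timepoint), character(1))
  sel <- normalized[tps %in% c(timepoint_a, timepoint_b)]
  if (length(unique(vapply(sel, function(x) as.character(x$timepoint),
                           character(1)))) < 2L) {
    stop("need normalized curves at both timepoints", call. = FALSE)
  }
  df <- do.call(rbind, lapply(sel, function(x) {
    data.frame(tp = factor(as.character(x$timepoint),
                           levels = c(timepoint_a, timepoint_b)),
               current = x$norm_current, count = x$norm_count)
  }))
  full <- stats::lm(count ~ current * tp, data = df)
  addi <- stats::lm(count ~ current + tp, data = df)
  cf <- summary(full)$coefficients
  ca <- summary(addi)$coefficients
  if (nrow(cf) < 4L) stop("singular design in pooled fit", call. = FALSE)
  fits <- lapply(split(df, df$tp), function(d) stats::coef(stats::lm(count ~ current, d)))
  list(slope_p = cf[4, 4], intercept_p = ca[3, 4], fits = fits)
}

#' Percent change from pre to post
#'
#' `100 * (post - pre) / pre`; undefined (`NA`) when `pre` is 0 or missing.
#'
#' @param pre,post numeric values (vectorized).
#' @return percent change.
#' @export
percent_change <- function(pre, post) {
  out <- 100 * (post - pre) / pre
  out[!is.na(pre) & pre == 0] <- NA_real_
  out
}

#' Within- and between-group plasticity statistics
#'
#' Paired t-tests of pre vs post within each group and a two-tailed
#' two-sample t-test between the groups' percent changes, with mean and SEM
#' reported per group.
#'
#' @param pre_a,post_a pre and post values per cell, group A.
#' @param pre_b,post_b pre and post values per cell, group B.
#' @param labels group labels of length 2.
#' @return list with per-group `n`, `mean_change`, `sem_change`, `paired_p`,
#'   and `between_p`.
#' @export
group_stats <- function(pre_a, post_a, pre_b, post_b,
                        labels = c("TBS", "control")) {
  one <- function(pre, post) {
    ok <- stats::complete.cases(pre, post)
    pre <- pre[ok]; post <- post[ok]
    if (length(pre) < 2L) stop("need n >= 2 per group", call. = FALSE)
    ch <- percent_change(pre, post)
    list(n = length(pre),
         mean_change = mean(ch),
         sem_change = stats::sd(ch) / sqrt(length(ch)),
         paired_p = stats::t.test(post, pre, paired = TRUE)$p.value,
         changes = ch)
  }
  a <- one(pre_a, post_a)
  b <- one(pre_b, post_b)
  between <- stats::t.test(a$changes, b$changes, var.equal = FALSE)$p.value
  out <- stats::setNames(list(a[c("n", "mean_change", "sem_change", "paired_p")],
                              b[c("n", "mean_change", "sem_change", "paired_p")]),
                         labels)
  out$between_p <- between
  out
}

#' Correlate plasticity magnitude with stimulation strength
#'
#' Ordinary least squares of the per-cell change against the number of
#' spikes evoked during TBS; returns the coefficient of determination and
#' the slope's p-value.
#'
#' @param tbs_spike_counts spikes evoked during TBS, per cell.
#' @param changes per-cell change values (e.g. percent change in firing).
#' @return list with `r_squared`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate_with_stimulation <- function(tbs_spike_counts, changes) {
  ok <- stats::complete.cases(tbs_spike_counts, changes)
  x <- tbs_spike_counts[ok]; y <- changes[ok]
  if (length(x) < 3L) stop("need n >= 3 paired values", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared, p = sm$coefficients[2, 4],
       slope = stats::coef(fit)[["x"]], intercept = stats::coef(fit)[["(Intercept)"]],
       n = length(x))
}

#' Filter cells by TBS spike count
#'
#' Keeps cells whose theta-burst stimulation evoked at least `min_spikes`
#' spikes (inclusive). Used for matched comparisons between conditions that
#' differ in entrainment strength.
#'
#' @param cells list of cells (as from [generate_cohort()]) or any list
#'   whose elements carry `n_tbs_spikes`.
#' @param min_spikes inclusion threshold (inclusive).
#' @return the surviving subset of `cells`.
#' @export
dtx_subset_filter <- function(cells, min_spikes = 250) {
  Filter(function(cell) cell$n_tbs_spikes >= min_spikes, cells)
}
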