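#' Segment a position trace into laps by running direction
#'
#' Laps are the segments between successive turnaround extrema of the
#' position trace; each is labelled `"up"` (increasing position) or
#' `"down"`, and numbered within its direction. Directions are analyzed
#' independently downstream.
#'
#' @param position data frame with columns `t_s` and `x_cm`.
#' @param track_length track length (cm); positions must lie within it.
#' @return data frame with `start`, `end` (s), `direction`, `lap`.
#' @export
segment_laps <- function(position, track_length) {
  t <- position$t_s
  x <- position$x_cm
  if (is.unsorted(t)) stop("position times must be non-decreasing", call. = FALSE)
  if (any(x < 0 | x > track_length)) {
    stop("positions outside [0, track_length]", call. = FALSE)
  }
  d <- sign(diff(x))
  moving <- which(d != 0)
  if (!length(moving)) stop("fewer than 2 turnarounds: animal stationary", call. = FALSE)
  dm <- d[moving]
  turn <- moving[which(diff(dm) != 0)] + 1L # sample index of each extremum
  bounds <- unique(c(1L, turn, length(x)))
  if (length(bounds) < 3L) {
    stop("fewer than 2 turnarounds in position trace", call. = FALSE)
  }
  segs <- data.frame(start = t[bounds[-length(bounds)]],
                     end = t[bounds[-1]],
                     direction = ifelse(x[bounds[-1]] >= x[bounds[-length(bounds)]],
                                        "up", "down"),
                     stringsAsFactors = FALSE)
  segs$lap <- stats::ave(seq_len(nrow(segs)), segs$direction, FUN = seq_along)
  segs
}

#' Compute per-lap and mean spatial rate maps
#'
#' Bins spikes and occupancy per lap for one running direction. Rates are
#' spikes divided by occupancy time; bins a lap never visited are `NA`.
#' The mean map is total spikes over total occupancy per bin.
#'
#' @param session a `place_session` (or any list with `spikes`, `position`,
#'   `laps`, `track_length`).
#' @param bin_cm spatial bin width (cm).
#' @param direction which running direction to analyze.
#' @return an object of class `rate_map`: `bin_edges`, matrices `counts`,
#'   `occupancy` (s) and `rate` (Hz) with one row per lap, `mean_rate`
#'   (Hz per bin), `lap_mid_t` (s), `span` (s).
#' @export
compute_rate_map <- function(session, bin_cm = 2, direction = "up") {
  if (bin_cm <= 0) stop("bin_cm must be positive", call. = FALSE)
  laps <- session$laps[session$laps$direction == direction, , drop = FALSE]
  if (!nrow(laps)) stop("no laps in requested direction", call. = FALSE)
  n_bins <- as.integer(ceiling(session$track_length / bin_cm))
  edges <- seq(0, by = bin_cm, length.out = n_bins + 1L)

  pos <- session$position
  dt_pos <- stats::median(diff(pos$t_s))
  pos_bin <- pmin(pmax(findInterval(pos$x_cm, edges, rightmost.closed = TRUE), 1L),
                  n_bins)
  pos_lap <- match_interval(pos$t_s, laps$start, laps$end)

  sp_t <- session$spikes
  sp_x <- stats::approx(pos$t_s, pos$x_cm, xout = sp_t, rule = 2)$y
  sp_bin <- pmin(pmax(findInterval(sp_x, edges, rightmost.closed = TRUE), 1L), n_bins)
  sp_lap <- match_interval(sp_t, laps$start, laps$end)

  nl <- nrow(laps)
  occupancy <- matrix(0, nl, n_bins)
  counts <- matrix(0, nl, n_bins)
  ok <- !is.na(pos_lap)
  if (any(ok)) {
    tb <- table(factor(pos_lap[ok], levels = seq_len(nl)),
                factor(pos_bin[ok], levels = seq_len(n_bins)))
    occupancy <- occupancy + as.matrix(tb) * dt_pos
  }
  ok <- !is.na(sp_lap)
  if (any(ok)) {
    tb <- table(factor(sp_lap[ok], levels = seq_len(nl)),
                factor(sp_bin[ok], levels = seq_len(n_bins)))
    counts <- counts + as.matrix(tb)
  }
  rate <- counts / occupancy
  rate[occupancy == 0] <- NA # undefined bin: never visited on that lap
  tot_occ <- colSums(occupancy)
  mean_rate <- colSums(counts) / tot_occ
  mean_rate[tot_occ == 0] <- NA

  structure(list(bin_edges = edges, counts = counts, occupancy = occupancy,
                 rate = rate, mean_rate = mean_rate,
                 lap_mid_t = (laps$start + laps$end) / 2,
                 span = c(min(session$laps$start), max(session$laps$end))),
            class = "rate_map")
}

# index of the interval [starts_i, ends_i] containing each x (NA if none)
match_interval <- function(x, starts, ends) {
  i <- findInterval(x, starts)
  i[i < 1L] <- NA
  i[!is.na(i) & x > ends[pmax(i, 1L)]] <- NA
  i
}

#' Detect the place field of a mean rate map
#'
#' The field is the largest contiguous run of bins at or above
#' `threshold_frac` of the peak rate that contains the peak bin (first bin
#' by position on ties of the peak).
#'
#' @param mean_rate mean rate per bin (Hz).
#' @param threshold_frac fraction of the peak rate defining the field.
#' @return integer vector of field bin indices with attribute `degenerate`
#'   set when the field spans the whole map; `NULL` for a flat zero map.
#' @export
detect_field <- function(mean_rate, threshold_frac = 0.2) {
  r <- mean_rate
  r[is.na(r)] <- 0
  peak <- which.max(r) # first bin on ties
  if (r[peak] <= 0) return(NULL)
  above <- r >= threshold_frac * r[peak]
  lo <- peak
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- peak
  while (hi < length(r) && above[hi + 1L]) hi <- hi + 1L
  field <- lo:hi
  attr(field, "degenerate") <- length(field) == length(r)
  field
}

#' Per-lap in-field and out-of-field firing rates
#'
#' For each lap, spikes inside (outside) the field bins divided by the time
#' spent inside (outside). Laps with zero out-of-field occupancy get `NA`
#' out-of-field rate.
#'
#' @param map a [compute_rate_map()] result.
#' @param field integer field-bin indices from [detect_field()].
#' @return data frame with `lap`, `in_rate`, `out_rate`, `in_spikes`,
#'   `out_spikes` (Hz and counts).
#' @export
infield_outfield_rates <- function(map, field) {
  if (is.null(field)) stop("field is undefined", call. = FALSE)
  nb <- ncol(map$counts)
  outb <- setdiff(seq_len(nb), field)
  in_sp <- rowSums(map$counts[, field, drop = FALSE])
  out_sp <- rowSums(map$counts[, outb, drop = FALSE])
  in_occ <- rowSums(map$occupancy[, field, drop = FALSE])
  out_occ <- rowSums(map$occupancy[, outb, drop = FALSE])
  data.frame(lap = seq_len(nrow(map$counts)),
             in_rate = ifelse(in_occ > 0, in_sp / in_occ, NA),
             out_rate = ifelse(out_occ > 0, out_sp / out_occ, NA),
             in_spikes = in_sp, out_spikes = out_sp)
}

#' Lap-to-lap stability of the rate map
#'
#' Mean of all pairwise Pearson correlations between the per-lap binned
#' rate vectors. Single-lap maps are dominated by Poisson noise at
#' behavioral firing rates, so each lap's vector is Gaussian-smoothed
#' (`smooth_bins` standard deviation, the field's usual convention for rate
#' maps) before correlating; set `smooth_bins = 0` for raw vectors. Pairs
#' involving a lap with zero rate variance are skipped and the pair count
#' adjusted.
#'
#' @param lap_rates matrix of per-lap rates (laps x bins), e.g.
#'   `map$rate`.
#' @param smooth_bins standard deviation of the Gaussian smoothing kernel,
#'   in bins.
#' @return mean pairwise correlation, or `NA` if no pair is valid.
#' @export
stability <- function(lap_rates, smooth_bins = 2) {
  nl <- nrow(lap_rates)
  if (nl < 2L) stop("stability needs >= 2 laps", call. = FALSE)
  m <- smooth_lap_maps(lap_rates, smooth_bins)
  use <- if (anyNA(m)) "pairwise.complete.obs" else "everything"
  cc <- suppressWarnings(stats::cor(t(m), use = use))
  vals <- cc[upper.tri(cc)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

# Gaussian smoothing of each lap's rate vector, as one matrix product with
# a row-normalized (edge-corrected) kernel matrix; NA bins are imputed with
# the lap mean first
smooth_lap_maps <- function(lap_rates, smooth_bins) {
  if (smooth_bins <= 0) return(lap_rates)
  nb <- ncol(lap_rates)
  if (anyNA(lap_rates)) {
    imput <- rowMeans(lap_rates, na.rm = TRUE)
    idx <- which(is.na(lap_rates), arr.ind = TRUE)
    lap_rates[idx] <- imput[idx[, 1]]
  }
  lap_rates %*% smoothing_matrix(nb, smooth_bins)
}

# memoized row-normalized Gaussian smoothing matrix
.smooth_cache <- new.env(parent = emptyenv())
smoothing_matrix <- function(nb, smooth_bins) {
  key <- paste(nb, smooth_bins)
  S <- .smooth_cache[[key]]
  if (is.null(S)) {
    S <- stats::dnorm(outer(seq_len(nb), seq_len(nb), `-`), sd = smooth_bins)
    S <- t(S / rowSums(S))
    .smooth_cache[[key]] <- S
  }
  S
}

#' Skaggs spatial information (bits per spike)
#'
#' `sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` with `p_i` the
#' occupancy fraction of bin i, `lambda_i` its rate, and `lambda` the
#' occupancy-weighted mean rate.
#'
#' @param mean_rate mean rate per bin (Hz).
#' @param occupancy total occupancy per bin (s).
#' @return bits per spike, or `NA` when the overall mean rate is zero.
#' @export
spatial_information <- function(mean_rate, occupancy) {
  ok <- !is.na(mean_rate) & occupancy > 0
  p <- occupancy[ok] / sum(occupancy[ok])
  lam_i <- mean_rate[ok]
  lam <- sum(p * lam_i)
  if (lam <= 0) return(NA_real_)
  pos <- lam_i > 0
  sum(p[pos] * (lam_i[pos] / lam) * log2(lam_i[pos] / lam))
}

#' Cell inclusion criterion
#'
#' A cell is included when both its stability and spatial information
#' exceed the threshold (strictly).
#'
#' @param stability_value mean pairwise lap correlation.
#' @param spatial_info bits per spike.
#' @param threshold inclusion cutoff applied to both.
#' @return logical.
#' @export
include_cell <- function(stability_value, spatial_info, threshold = 0.1) {
  isTRUE(stability_value > threshold) && isTRUE(spatial_info > threshold)
}

#' Session thirds of a per-lap rate series
#'
#' The session span is divided into three equal time intervals; each lap is
#' assigned by its midpoint time (a lap exactly on a boundary goes to the
#' earlier third) and the per-lap rates are averaged within each third.
#'
#' @param lap_rates per-lap rates (Hz).
#' @param lap_mid_t lap midpoint times (s).
#' @param span numeric length-2, session start and end times (s).
#' @return named numeric vector `start`, `middle`, `end` (empty third gives
#'   `NA`).
#' @export
session_thirds <- function(lap_rates, lap_mid_t, span) {
  edges <- span[1] + diff(span) * c(1, 2) / 3
  third <- ifelse(lap_mid_t <= edges[1], 1L, ifelse(lap_mid_t <= edges[2], 2L, 3L))
  out <- vapply(1:3, function(k) {
    v <- lap_rates[third == k]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  stats::setNames(out, c("start", "middle", "end"))
}

#' Lap-by-lap firing rate correlation
#'
#' Pearson correlation between lap index and per-lap rate across the
#' session.
#'
#' @param lap_rates per-lap rates (Hz).
#' @return Pearson r, or `NA` with fewer than 3 finite laps or zero rate
#'   variance.
#' @export
lap_rate_correlation <- function(lap_rates) {
  ok <- is.finite(lap_rates)
  if (sum(ok) < 3L) return(NA_real_)
  x <- seq_along(lap_rates)[ok]
  y <- lap_rates[ok]
  if (stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Summarize one place-cell session
#'
#' Runs the full per-cell pipeline for one running direction: rate map,
#' field detection, in/out-of-field per-lap rates, stability, spatial
#' information, session thirds and lap-rate correlations.
#'
#' @param session a `place_session`.
#' @param bin_cm spatial bin width (cm).
#' @param direction running direction to analyze.
#' @return an object of class `session_stats` (list of the quantities
#'   above), or `NULL` when no field can be defined.
#' @export
session_stats <- function(session, bin_cm = 2, direction = "up") {
  map <- compute_rate_map(session, bin_cm, direction)
  field <- detect_field(map$mean_rate)
  if (is.null(field)) return(NULL)
  rates_from_maps(map, field)
}

# shared back end: statistics from count/occupancy matrices
rates_from_maps <- function(map, field) {
  rates <- infield_outfield_rates(map, field)
  structure(list(
    field = field,
    in_rate = rates$in_rate, out_rate = rates$out_rate,
    thirds_in = session_thirds(rates$in_rate, map$lap_mid_t, map$span),
    thirds_out = session_thirds(rates$out_rate, map$lap_mid_t, map$span),
    lap_corr_in = lap_rate_correlation(rates$in_rate),
    lap_corr_out = lap_rate_correlation(rates$out_rate),
    stability = stability(map$rate),
    spatial_info = spatial_information(map$mean_rate, colSums(map$occupancy))),
    class = "session_stats")
}

#' Population tests of rate drift
#'
#' Compares per-cell session-third rates with a one-way repeated-measures
#' ANOVA (cell as the repeated factor; cells with a missing third are
#' dropped listwise), and tests the center of the per-cell lap-correlation
#' distribution against zero with a one-tailed t-test when a Shapiro-Wilk
#' test does not reject normality at alpha = 0.05, otherwise a sign test.
#' The test direction is fixed by the stated hypothesis (`alternative`),
#' not chosen from the data, so the null false-positive rate stays at the
#' nominal level.
#'
#' @param thirds matrix (cells x 3) of start/middle/end mean rates.
#' @param correlations per-cell lap-rate correlations.
#' @param alternative direction of the center test (`"less"`: the
#'   distribution center is below zero).
#' @return list with `anova_F`, `anova_p`, `n_anova`, `center_p`,
#'   `center_test` (`"t"` or `"sign"`), `n_center`, `thirds_mean`,
#'   `thirds_sem`.
#' @export
population_tests <- function(thirds, correlations,
                             alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  thirds <- as.matrix(thirds)
  keep <- stats::complete.cases(thirds)
  th <- thirds[keep, , drop = FALSE]
  if (nrow(th) < 3L) stop("need >= 3 cells with complete thirds", call. = FALSE)
  long <- data.frame(
    rate = as.vector(th),
    third = factor(rep(c("start", "middle", "end"), each = nrow(th)),
                   levels = c("start", "middle", "end")),
    cell = factor(rep(seq_len(nrow(th)), 3L)))
  fit <- stats::aov(rate ~ third + Error(cell), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  anova_F <- tab["third", "F value"]
  anova_p <- tab["third", "Pr(>F)"]

  cc <- correlations[is.finite(correlations)]
  if (length(cc) < 3L) stop("need >= 3 finite correlations", call. = FALSE)
  normal <- stats::shapiro.test(cc)$p.value > 0.05
  if (normal) {
    center_p <- stats::t.test(cc, mu = 0, alternative = alternative)$p.value
    center_test <- "t"
  } else {
    n_pos <- sum(cc > 0)
    n_tot <- sum(cc != 0)
    alt <- switch(alternative, less = "less", greater = "greater",
                  two.sided = "two.sided")
    center_p <- stats::binom.test(n_pos, n_tot, 0.5, alternative = alt)$p.value
    center_test <- "sign"
  }
  list(anova_F = anova_F, anova_p = anova_p, n_anova = nrow(th),
       center_p = center_p, center_test = center_test, n_center = length(cc),
       thirds_mean = colMeans(th),
       thirds_sem = apply(th, 2, stats::sd) / sqrt(nrow(th)))
}

#' Simulate a population of place cells and summarize each
#'
#' Draws one session per cell (field centre uniform along the interior of
#' the track, independent spike realizations) and computes
#' [session_stats()] for the analyzed direction. For speed the statistics
#' are computed from the generator-native per-(lap, bin) count matrices,
#' which the spike-time path re-derives exactly (same binning); set
#' `use_counts = FALSE` to force the full spike-time pipeline.
#'
#' @param n_cells number of cells.
#' @param p baseline [place_session_params()]; each cell gets its own seed
#'   and field centre.
#' @param seed master seed.
#' @param apply_inclusion drop cells failing [include_cell()].
#' @param use_counts use the generator-native count matrices (fast path).
#' @return list with `stats` (per-cell `session_stats`), `thirds_out`,
#'   `thirds_in` (matrices), `corr_out`, `corr_in` (vectors), `n_included`.
#' @export
simulate_place_population <- function(n_cells, p = place_session_params(),
                                      seed = 1L, apply_inclusion = TRUE,
                                      use_counts = TRUE) {
  res <- vector("list", n_cells)
  set.seed(derive_seed(seed, 0L))
  centers <- stats::runif(n_cells, p$field_width, p$track_length - p$field_width)
  lap_t <- p$track_length / p$speed
  for (i in seq_len(n_cells)) {
    pi_ <- p
    pi_$seed <- derive_seed(seed, i)
    pi_$field_center <- centers[i]
    ses <- simulate_place_session(pi_, with_spike_times = !use_counts)
    if (use_counts) {
      laps_up <- ses$laps[ses$laps$direction == "up", ]
      nl <- nrow(laps_up)
      occ <- matrix(rep(diff(ses$bin_edges) / p$speed, each = nl), nl)
      map <- list(counts = ses$counts$up, occupancy = occ,
                  rate = ses$counts$up / occ,
                  mean_rate = colSums(ses$counts$up) / colSums(occ),
                  lap_mid_t = (laps_up$start + laps_up$end) / 2,
                  span = c(0, 2 * nl * lap_t))
      field <- detect_field(map$mean_rate)
      res[[i]] <- if (is.null(field)) NULL else rates_from_maps(map, field)
    } else {
      res[[i]] <- session_stats(ses)
    }
  }
  keep <- !vapply(res, is.null, logical(1))
  if (apply_inclusion) {
    keep <- keep & vapply(res, function(s) {
      !is.null(s) && include_cell(s$stability, s$spatial_info)
    }, logical(1))
  }
  res <- res[keep]
  list(stats = res,
       thirds_out = do.call(rbind, lapply(res, `[[`, "thirds_out")),
       thirds_in = do.call(rbind, lapply(res, `[[`, "thirds_in")),
       corr_out = vapply(res, `[[`, numeric(1), "lap_corr_out"),
       corr_in = vapply(res, `[[`, numeric(1), "lap_corr_in"),
       n_included = length(res))
}
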