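#' Simulate a place-cell session on a virtual linear track
#'
#' The animal runs back and forth at constant speed; the cell fires as an
#' inhomogeneous Poisson process whose rate is an in-field Gaussian bump
#' plus an out-of-field baseline. Both components change multiplicatively
#' lap by lap: the baseline by `drift_per_lap` (emulating an excitability
#' drift) and the bump peak by `in_field_gain_per_lap` (emulating in-field
#' synaptic potentiation). The bump has standard deviation
#' `field_width / 3` and is truncated to zero outside
#' `field_center +/- field_width / 2` (where it still exceeds the
#' conventional 20%-of-peak field criterion), so with a zero baseline no
#' spikes occur outside the detected field.
#'
#' Spikes are generated on a spatial grid of `gen_bin_cm` bins: with
#' constant running speed the dwell time per bin is constant, the count per
#' (lap, bin) is Poisson with mean rate x dwell, and spike times are placed
#' uniformly within the bin's dwell interval. This is exactly an
#' inhomogeneous Poisson process with a piecewise-constant rate at
#' `gen_bin_cm` resolution.
#'
#' @param p a [place_session_params()] object.
#' @param gen_bin_cm spatial resolution of the generator (cm).
#' @param with_spike_times materialize individual spike times (needed for
#'   the CSV interchange format and the spike-binning pipeline). `FALSE`
#'   keeps only the per-(lap, bin) count matrices, which is faster for
#'   population Monte Carlo runs; the Poisson draws are identical either
#'   way.
#' @return an object of class `place_session`: `spikes` (times, s),
#'   `position` (data frame `t_s`, `x_cm`), `laps` (data frame `start`,
#'   `end`, `direction`, `lap`), `track_length`, and the generator-native
#'   per-(lap, bin) count matrices `counts` (per direction) with
#'   `bin_edges`.
#' @export
simulate_place_session <- function(p, gen_bin_cm = 2,
                                   with_spike_times = TRUE) {
  set.seed(p$seed)
  lap_t <- p$track_length / p$speed # seconds per traversal
  n_trav <- 2L * p$n_laps
  total <- n_trav * lap_t

  if (with_spike_times) {
    t_pos <- seq(0, total, by = 1 / p$pos_hz)
    phase <- (t_pos / lap_t) %% 2
    x_pos <- p$track_length * (1 - abs(1 - phase))
    position <- data.frame(t_s = t_pos, x_cm = x_pos)
  } else {
    # counts-only sessions skip the sampled position trace
    position <- data.frame(t_s = numeric(0), x_cm = numeric(0))
  }

  n_bins <- as.integer(ceiling(p$track_length / gen_bin_cm))
  edges <- seq(0, by = gen_bin_cm, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  dwell <- gen_bin_cm / p$speed

  sigma <- p$field_width / 3
  bump <- exp(-(centers - p$field_center)^2 / (2 * sigma^2))
  bump[abs(centers - p$field_center) > p$field_width / 2] <- 0

  lap_idx <- seq_len(p$n_laps)
  base_l <- p$base_rate_out * p$drift_per_lap^(lap_idx - 1)
  peak_l <- p$peak_rate_in * p$in_field_gain_per_lap^(lap_idx - 1)
  # rate[lap, bin] shared by the two directions of the same lap index
  rate <- outer(base_l, rep(1, n_bins)) + outer(peak_l, bump)

  # all Poisson counts are drawn first (traversal-major), so the count
  # matrices are identical whether or not spike times are materialized
  lap_of <- (seq_len(n_trav) + 1L) %/% 2L
  cnt_all <- matrix(stats::rpois(n_trav * n_bins,
                                 t(rate[lap_of, , drop = FALSE]) * dwell),
                    nrow = n_bins)
  up_cols <- seq(1L, n_trav, by = 2L)
  counts <- list(up = t(cnt_all[, up_cols, drop = FALSE]),
                 down = t(cnt_all[, -up_cols, drop = FALSE]))
  spikes <- numeric(0)
  if (with_spike_times) {
    for (k in seq_len(n_trav)) {
      cnt <- cnt_all[, k]
      hot <- which(cnt > 0L)
      if (!length(hot)) next
      # dwell interval of each spiking bin within this traversal
      off <- if (k %% 2L == 1L) (hot - 1L) * dwell else (n_bins - hot) * dwell
      spikes <- c(spikes, (k - 1L) * lap_t + rep(off, cnt[hot]) +
                    stats::runif(sum(cnt[hot]), 0, dwell))
    }
  }

  laps <- structure(list(
    start = (seq_len(n_trav) - 1) * lap_t,
    end = seq_len(n_trav) * lap_t,
    direction = rep(c("up", "down"), p$n_laps),
    lap = rep(seq_len(p$n_laps), each = 2L)),
    class = "data.frame", row.names = seq_len(n_trav))

  structure(list(spikes = sort(spikes),
                 position = position,
                 laps = laps, track_length = p$track_length,
                 counts = counts, bin_edges = edges, params = p),
            class = "place_session")
}

#' @export
print.place_session <- function(x, ...) {
  cat(sprintf("<place_session> %d spikes, %d laps/direction, %.0f cm track, %.0f s\n",
              length(x$spikes), max(x$laps$lap), x$track_length,
              max(x$laps$end)))
  invisible(x)
}
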