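#' Build the theta-burst command-current waveform
#'
#' Lays EPSC-like events (difference of exponentials) on a zero trace with
#' the TBS timing: `pulses_per_burst` pulses at `intra_burst_hz` per burst,
#' `bursts_per_series` bursts at `burst_hz`, `n_series` series separated by
#' `inter_series_s`. Overlapping event tails sum.
#'
#' @param proto a [stim_protocol()] object with a populated `tbs_spec`.
#' @param dt sampling interval (ms).
#' @param tail_ms trailing zero-padding after the last event (ms).
#' @return numeric vector of command current (pA).
#' @export
build_tbs_waveform <- function(proto, dt, tail_ms = 50) {
  if (dt <= 0) stop("invalid protocol: dt must be positive", call. = FALSE)
  s <- proto$tbs_spec
  n_events <- tbs_pulse_count(proto)
  onsets <- tbs_event_onsets(s)
  if (n_events == 0L || length(onsets) == 0L) {
    return(numeric(as.integer(round(tail_ms / dt))))
  }
  kern <- epsc_kernel(s$epsc_rise_ms, s$epsc_decay_ms, s$epsc_amp_pA, dt)
  n <- as.integer(round((max(onsets) + tail_ms) / dt)) + length(kern)
  out <- numeric(n)
  for (t0 in onsets) {
    i0 <- as.integer(round(t0 / dt)) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    out[idx] <- out[idx] + kern
  }
  out
}

# onset times (ms) of every EPSC event in the full protocol
tbs_event_onsets <- function(s) {
  if (s$n_series < 1 || s$pulses_per_burst < 1 || s$bursts_per_series < 1) {
    return(numeric(0))
  }
  pulse_dt <- 1000 / s$intra_burst_hz
  burst_dt <- 1000 / s$burst_hz
  series_dt <- s$inter_series_s * 1000
  as.vector(outer(
    (seq_len(s$pulses_per_burst) - 1) * pulse_dt,
    as.vector(outer((seq_len(s$bursts_per_series) - 1) * burst_dt,
                    (seq_len(s$n_series) - 1) * series_dt, `+`)),
    `+`))
}

# difference-of-exponentials EPSC, normalized so the peak equals `amp`
epsc_kernel <- function(rise_ms, decay_ms, amp, dt, span = 8) {
  t <- seq(0, span * decay_ms, by = dt)
  w <- exp(-t / decay_ms) - exp(-t / rise_ms)
  amp * w / max(w)
}

# bias current (pA) holding the cell at `v_hold` with gates at steady state
holding_current <- function(params, v_hold) {
  p <- params
  h <- sigmoid_inf(v_hold, p$h_vhalf, p$h_k)
  a <- sigmoid_inf(v_hold, p$Da_vhalf, p$Da_k)
  d <- sigmoid_inf(v_hold, p$Di_vhalf, p$Di_k)
  p$gL * (v_hold - p$EL) - p$gL * p$DeltaT * exp((v_hold - p$VT) / p$DeltaT) +
    p$gh_max * h * (v_hold - p$Eh) + p$gD_max * a * d * (v_hold - p$EK)
}

# run the integrator from the holding steady state
run_from_holding <- function(params, command, dt, v_hold, with_noise) {
  eif_simulate_cpp(command, unclass(params), dt,
                   v0 = v_hold,
                   h0 = sigmoid_inf(v_hold, params$h_vhalf, params$h_k),
                   a0 = sigmoid_inf(v_hold, params$Da_vhalf, params$Da_k),
                   d0 = sigmoid_inf(v_hold, params$Di_vhalf, params$Di_k),
                   I_hold = holding_current(params, v_hold),
                   with_noise = with_noise)
}

#' Simulate one current-step sweep
#'
#' Integrates the conductance model through a 100 ms pre-step baseline, the
#' current step, and a 50 ms post-step window, starting from the holding
#' steady state (the inter-sweep interval far exceeds the membrane time
#' constant, so sweeps are independent).
#'
#' @param params a [neuron_params()] object.
#' @param step_amp step amplitude (pA).
#' @param proto a [stim_protocol()] object (step duration and holding target).
#' @param dt integration and sampling interval (ms); 0.025 ms default.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @param baseline_ms,post_ms pre- and post-step padding (ms).
#' @return an [ie_sweep()] object.
#' @export
simulate_sweep <- function(params, step_amp, proto = stim_protocol(),
                           dt = 0.025, seed = NULL,
                           baseline_ms = 100, post_ms = 50) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (dt > 0.05) {
    warning("dt > 0.05 ms is coarse for the gate kinetics", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_pre <- as.integer(round(baseline_ms / dt))
  n_step <- as.integer(round(proto$step_duration / dt))
  n_post <- as.integer(round(post_ms / dt))
  command <- c(numeric(n_pre), rep(step_amp, n_step), numeric(n_post))
  sim <- run_from_holding(params, command, dt, proto$holding_target,
                          with_noise = params$noise_sd > 0)
  ie_sweep(dt, sim$v, command,
           step_onset = n_pre + 1L, step_offset = n_pre + n_step,
           step_amp = step_amp)
}

#' Simulate the theta-burst stimulation and count evoked spikes
#'
#' Each series is integrated independently (the 15 s inter-series interval
#' far exceeds every time constant in the model, so the membrane state is
#' relaxed to holding between series). Returns the per-series traces and the
#' total number of spikes evoked across the whole protocol.
#'
#' @inheritParams simulate_sweep
#' @param proto a [stim_protocol()] object with a populated `tbs_spec`.
#' @return list with `sweeps` (one `ie_sweep` per series, `step_amp` set to
#'   the EPSC peak amplitude) and `n_spikes`.
#' @export
simulate_tbs <- function(params, proto = stim_protocol(), dt = 0.025,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- proto$tbs_spec
  one <- proto
  one$tbs_spec$n_series <- 1
  sweeps <- vector("list", s$n_series)
  n_spikes <- 0L
  if (s$n_series >= 1) {
    for (k in seq_len(s$n_series)) {
      command <- c(numeric(as.integer(round(50 / dt))),
                   build_tbs_waveform(one, dt))
      sim <- run_from_holding(params, command, dt, proto$holding_target,
                              with_noise = params$noise_sd > 0)
      n_spikes <- n_spikes + length(sim$spike_idx)
      sweeps[[k]] <- ie_sweep(dt, sim$v, command,
                              step_onset = as.integer(round(50 / dt)) + 1L,
                              step_offset = length(command),
                              step_amp = s$epsc_amp_pA)
    }
  }
  list(sweeps = sweeps, n_spikes = n_spikes)
}

#' Calibrate the EPSC amplitude to entrain burst firing
#'
#' Finds the smallest amplitude on a geometric grid for which a single burst
#' (simulated without noise) evokes at least `min_frac` of its pulses as
#' spikes, then adds 20% headroom. Mirrors the experimental practice of
#' adjusting the waveform until the cell follows the burst at ~100 Hz.
#'
#' @inheritParams simulate_tbs
#' @param min_frac required fraction of pulses answered by spikes.
#' @return amplitude (pA).
#' @export
calibrate_epsc_amp <- function(params, proto = stim_protocol(), dt = 0.025,
                               min_frac = 0.9) {
  quiet <- params
  quiet$noise_sd <- 0
  one <- proto
  one$tbs_spec$n_series <- 1
  one$tbs_spec$bursts_per_series <- 1
  n_pulse <- one$tbs_spec$pulses_per_burst
  for (amp in c(600, 900, 1350, 2000, 3000, 4500, 6800)) {
    one$tbs_spec$epsc_amp_pA <- amp
    res <- simulate_tbs(quiet, one, dt)
    if (res$n_spikes >= min_frac * n_pulse) return(amp * 1.2)
  }
  6800 * 1.2
}

#' Simulate a spontaneous (holding) voltage segment
#'
#' Subthreshold membrane noise around the holding potential, generated as a
#' discrete Ornstein-Uhlenbeck process with the cell's effective membrane
#' time constant at holding. Used for the Vm-variance feature.
#'
#' @param params a [neuron_params()] object.
#' @param duration_s segment duration (s).
#' @param dt sampling interval (ms); spontaneous stretches are subthreshold,
#'   so a coarser dt than the sweep integrator is adequate.
#' @param holding holding potential (mV).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return list with `v` (mV), `dt` (ms).
#' @export
simulate_spontaneous <- function(params, duration_s = 15, dt = 0.5,
                                 holding = -60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * 1000 / dt))
  tau <- params$Cm / params$gL
  rho <- exp(-dt / tau)
  innov_sd <- params$noise_sd * sqrt(1 - rho^2)
  eps <- rnorm(n, sd = innov_sd)
  v <- holding + as.numeric(stats::filter(eps, rho, method = "recursive"))
  list(v = v, dt = dt)
}
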