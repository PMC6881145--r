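# Analytic and randomized sweep fixtures, built in code.

# pure RC response: deflection = amp * R * (1 - exp(-t/tau)) during the step
make_rc_sweep <- function(amp = -200, R_mohm = 60, tau_ms = 20, dt = 0.1,
                          baseline_mv = -60, step_ms = 300, pre_ms = 100,
                          post_ms = 50, noise_sd = 0) {
  n_pre <- round(pre_ms / dt)
  n_step <- round(step_ms / dt)
  n_post <- round(post_ms / dt)
  t_step <- (seq_len(n_step) - 1) * dt
  defl <- amp * (R_mohm / 1000) * (1 - exp(-t_step / tau_ms))
  v_end <- defl[n_step]
  v <- c(rep(0, n_pre), defl, v_end * exp(-(seq_len(n_post) - 1) * dt / tau_ms)) +
    baseline_mv
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  i <- c(rep(0, n_pre), rep(amp, n_step), rep(0, n_post))
  ie_sweep(dt, v, i, n_pre + 1, n_pre + n_step, amp)
}

# two-compartment trace: instantaneous pipette drop (fast exponential,
# tau_fast) plus membrane charging (tau_m); used to validate the series-
# resistance estimator against its construction value
make_rs_sweep <- function(amp, rs_mohm, rm_mohm, tau_fast = 0.5, tau_m = 20,
                          dt = 0.05, pre_ms = 100, step_ms = 300) {
  n_pre <- round(pre_ms / dt)
  n_step <- round(step_ms / dt)
  t_step <- (seq_len(n_step) - 1) * dt
  defl <- amp * (rs_mohm / 1000) * (1 - exp(-t_step / tau_fast)) +
    amp * (rm_mohm / 1000) * (1 - exp(-t_step / tau_m))
  v <- c(rep(0, n_pre), defl) - 60
  i <- c(rep(0, n_pre), rep(amp, n_step))
  ie_sweep(dt, v, i, n_pre + 1, n_pre + n_step, amp)
}

# stylized spike train: baseline with linear-rise / instant-fall spikes at
# known onset times; the dV/dt criterion crossing sample is analytically the
# first sample of each rise
make_spike_sweep <- function(spike_t_ms, dt = 0.05, total_ms = 500,
                             rise_ms = 1, peak_mv = 30, base_mv = -60,
                             step_window = c(100, 400), step_amp = 200) {
  n <- round(total_ms / dt)
  v <- rep(base_mv, n)
  for (t0 in spike_t_ms) {
    i0 <- round(t0 / dt) + 1
    ramp <- seq(base_mv, peak_mv, length.out = round(rise_ms / dt))
    idx <- i0:(i0 + length(ramp) - 1)
    v[idx] <- ramp
  }
  i <- numeric(n)
  on <- round(step_window[1] / dt) + 1
  off <- round(step_window[2] / dt)
  i[on:off] <- step_amp
  ie_sweep(dt, v, i, on, off, step_amp)
}

# randomized subthreshold sweep with smooth structure, for oracle-equivalence
# property tests
make_random_sweep <- function(dt = 0.25, pre_ms = 100, step_ms = 300,
                              post_ms = 50, amp = -250) {
  n_pre <- round(pre_ms / dt)
  n_step <- round(step_ms / dt)
  n_post <- round(post_ms / dt)
  n <- n_pre + n_step + n_post
  t <- (seq_len(n) - 1) * dt
  v <- -60 + cumsum(rnorm(n, 0, 0.3)) * 0.2 +
    3 * sin(2 * pi * t / runif(1, 40, 400)) +
    rnorm(n, 0, 0.4)
  defl <- numeric(n)
  defl[(n_pre + 1):(n_pre + n_step)] <- amp * 0.05 *
    (1 - exp(-(seq_len(n_step) - 1) * dt / 15))
  i <- numeric(n)
  i[(n_pre + 1):(n_pre + n_step)] <- amp
  ie_sweep(dt, v + defl, i, n_pre + 1, n_pre + n_step, amp)
}

# brute-force oracles: direct loops over raw samples, independent of the
# implementation's vectorized paths
oracle_min_deflection <- function(s, window_ms = 150) {
  base_lo <- s$step_onset - round(50 / s$dt)
  baseline <- mean(s$v[base_lo:(s$step_onset - 1)])
  lim <- min(length(s$v), s$step_onset + round(window_ms / s$dt))
  best <- Inf
  for (k in s$step_onset:lim) if (s$v[k] < best) best <- s$v[k]
  best - baseline
}

oracle_dvdt_crossings <- function(v, dt, thresh = 10, min_rise = 20,
                                  window_ms = 5) {
  n <- length(v)
  dvdt <- rep(NA_real_, n)
  for (k in 2:(n - 1)) dvdt[k] <- (v[k + 1] - v[k - 1]) / (2 * dt)
  out <- integer(0)
  last_peak <- 0
  k <- 2
  while (k <= n - 1) {
    if (!is.na(dvdt[k]) && dvdt[k] >= thresh &&
        (is.na(dvdt[k - 1]) || dvdt[k - 1] < thresh) && k > last_peak) {
      lim <- min(n, k + round(window_ms / dt))
      pk <- k
      for (j in k:lim) if (v[j] > v[pk]) pk <- j
      if (v[pk] - v[k] >= min_rise) {
        out <- c(out, k)
        last_peak <- pk
      }
    }
    k <- k + 1
  }
  out
}

# deterministic seeds for property loops
property_seeds <- function(n) 1000 + seq_len(n)
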