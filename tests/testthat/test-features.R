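test_that("spike detection matches the finite-difference oracle on stylized trains", {
  sw <- make_spike_sweep(c(150, 200, 300))
  e <- detect_spikes(sw)
  expect_equal(nrow(e), 3L)
  expect_true(all(diff(e$t_threshold) > 0))
  expect_equal(e$idx_threshold, oracle_dvdt_crossings(sw$v, sw$dt))
  expect_true(all(e$v_peak > e$v_threshold))
  expect_true(all(e$t_threshold <= e$t_peak))
})

test_that("spike detection on a constant trace is empty, close spikes stay distinct", {
  flat <- ie_sweep(0.1, rep(-60, 5000), c(rep(0, 1000), rep(100, 3000), rep(0, 1000)),
                   1001, 4000, 100)
  expect_equal(nrow(detect_spikes(flat)), 0L)
  two <- detect_spikes(make_spike_sweep(c(200, 205)))
  expect_equal(nrow(two), 2L)
})

test_that("spike detection equals the oracle on randomized noisy traces", {
  for (s in property_seeds(25)) {
    set.seed(s)
    n_sp <- sample(0:6, 1)
    t_sp <- sort(100 + runif(n_sp) * 280)
    if (length(t_sp) > 1) t_sp <- t_sp[c(TRUE, diff(t_sp) > 8)]
    sw <- make_spike_sweep(t_sp, dt = 0.1)
    sw$v <- sw$v + rnorm(length(sw$v), 0, 0.3)
    expect_equal(detect_spikes(sw)$idx_threshold,
                 oracle_dvdt_crossings(sw$v, sw$dt))
  }
})

test_that("series resistance is recovered from two-compartment traces", {
  for (rs in c(5, 20, 50)) {
    sweeps <- lapply(c(-300, -250, -200), make_rs_sweep,
                     rs_mohm = rs, rm_mohm = 50)
    expect_equal(estimate_series_resistance(sweeps), rs, tolerance = 0.05 * rs)
  }
})

test_that("series resistance is zero without an instantaneous drop and", {
  sweeps <- lapply(c(-300, -200), make_rc_sweep, R_mohm = 50, tau_ms = 20)
  expect_equal(estimate_series_resistance(sweeps), 0, tolerance = 1)
  # duplicated sweeps: same regression points, same answer
  dup <- c(sweeps, sweeps)
  expect_equal(estimate_series_resistance(dup),
               estimate_series_resistance(sweeps))
  expect_error(estimate_series_resistance(sweeps[1]), "amplitudes")
})

test_that("input resistance follows the minimum-deflection definition", {
  # arithmetic: -15 mV minimum on a -300 pA step is 50 MOhm
  sw <- make_rc_sweep(amp = -300, R_mohm = 50, tau_ms = 5)
  expect_equal(input_resistance(list(sw)), 50, tolerance = 0.01)
  # analytic RC limit within 1%
  rc <- lapply(c(-300, -250, -200), make_rc_sweep, R_mohm = 60, tau_ms = 20)
  expect_equal(input_resistance(rc), 60, tolerance = 0.6)
  expect_error(input_resistance(list()), "hyperpolarizing")
})

test_that("input resistance uses the minimum within 150 ms, not the steady state", {
  # sag-like trace: minimum -18 mV at 80 ms, steady -12 mV
  dt <- 0.1
  n_pre <- 1000
  t <- (0:3499) * dt
  defl <- -12 - 6 * exp(-((t - 80) / 40)^2)
  v <- c(rep(-60, n_pre), defl - 60 + 12, rep(-60, 500))
  # build so that deflection minimum is exactly -18: shift baseline to 0
  v <- c(rep(-60, n_pre), -60 + defl - max(defl), rep(-60, 500))
  i <- c(rep(0, n_pre), rep(-300, 3500), rep(0, 500))
  sw <- ie_sweep(dt, v, i, n_pre + 1, n_pre + 3500, -300)
  expect_equal(input_resistance(list(sw)),
               1000 * oracle_min_deflection(sw) / -300)
})

test_that("input resistance and sag ratio are invariant to voltage offsets", {
  for (s in property_seeds(20)) {
    set.seed(s)
    sw <- make_random_sweep()
    shifted <- sw
    shifted$v <- sw$v + runif(1, -20, 20)
    expect_equal(input_resistance(list(shifted)), input_resistance(list(sw)),
                 tolerance = 1e-9)
    expect_equal(sag_ratio(list(shifted)), sag_ratio(list(sw)),
                 tolerance = 1e-9)
  }
})

test_that("sag ratio arithmetic and limits", {
  # steady deflection -10 mV over minimum -15 mV is 2/3
  dt <- 0.1
  defl <- c(seq(0, -15, length.out = 200), rep(-15, 300),
            seq(-15, -10, length.out = 500), rep(-10, 2000))
  v <- c(rep(-60, 1000), defl - 60, rep(-60, 300))
  i <- c(rep(0, 1000), rep(-300, 3000), rep(0, 300))
  sw <- ie_sweep(dt, v, i, 1001, 4000, -300)
  expect_equal(sag_ratio(list(sw)), 2 / 3, tolerance = 1e-6)
  # no-sag RC trace: ratio 1
  rc <- lapply(c(-300, -200), make_rc_sweep, R_mohm = 60, tau_ms = 15)
  expect_equal(sag_ratio(rc), 1, tolerance = 0.01)
})

test_that("AP threshold is the median over first spikes", {
  sweeps <- lapply(c(150, 200, 250), function(t0) make_spike_sweep(c(t0, t0 + 50)))
  # stylized ramps all cross at the same baseline voltage
  expect_equal(ap_threshold_feature(sweeps),
               median(vapply(sweeps, function(s) detect_spikes(s)$v_threshold[1],
                             numeric(1))))
  none <- list(make_spike_sweep(numeric(0)))
  expect_true(is.na(ap_threshold_feature(none)))
})

test_that("AHP eligibility follows the 50 ms window rule", {
  dt <- 0.05
  # single spike at 150 ms, step ends at 400 ms: eligible
  sw1 <- make_spike_sweep(150, dt = dt)
  e1 <- detect_spikes(sw1)
  expect_false(is.na(ahp_feature(list(sw1), list(e1))))
  # two spikes 30 ms apart: first excluded (next spike inside window),
  # second judged against step end only
  sw2 <- make_spike_sweep(c(200, 230), dt = dt)
  e2 <- detect_spikes(sw2)
  expect_equal(ahp_feature(list(sw2), list(e2)),
               min(sw2$v[(e2$idx_threshold[2] + 1):(e2$idx_threshold[2] + round(50 / dt))]))
  # spike 20 ms before step end: excluded entirely
  sw3 <- make_spike_sweep(380, dt = dt)
  expect_true(is.na(ahp_feature(list(sw3))))
})

test_that("AHP value equals a brute-force window minimum", {
  for (s in property_seeds(10)) {
    set.seed(s)
    sw <- make_spike_sweep(sort(runif(3, 120, 330)), dt = 0.1)
    sw$v <- sw$v + rnorm(length(sw$v), 0, 0.2)
    ev <- detect_spikes(sw)
    got <- ahp_feature(list(sw), list(ev))
    w <- round(50 / sw$dt)
    t_end <- (sw$step_offset - 1) * sw$dt
    vals <- c()
    for (k in seq_len(nrow(ev))) {
      nxt <- if (k < nrow(ev)) ev$t_threshold[k + 1] else Inf
      if (nxt > ev$t_threshold[k] + 50 && t_end > ev$t_threshold[k] + 50) {
        vals <- c(vals, min(sw$v[(ev$idx_threshold[k] + 1):(ev$idx_threshold[k] + w)]))
      }
    }
    expect_equal(got, if (length(vals)) mean(vals) else NA_real_)
  }
})

test_that("first-spike latency averages repeats at the maximal amplitude", {
  s1 <- make_spike_sweep(120)  # onset at 100 ms -> latency 20 ms
  s2 <- make_spike_sweep(130)  # latency 30 ms
  expect_equal(first_spike_latency(list(s1, s2)), 25, tolerance = 0.01)
  # sweeps at lower amplitude are ignored
  low <- make_spike_sweep(110)
  low$step_amp <- 100
  expect_equal(first_spike_latency(list(s1, s2, low)), 25, tolerance = 0.01)
  expect_true(is.na(first_spike_latency(list(make_spike_sweep(numeric(0))))))
})

test_that("burst index counts spikes participating in short ISIs", {
  bi_of <- function(isis) {
    t_sp <- 120 + cumsum(c(0, isis))
    sw <- make_spike_sweep(t_sp, dt = 0.05, total_ms = 600,
                           step_window = c(100, 550))
    burst_index(list(sw), min_spikes = 1)
  }
  expect_equal(bi_of(rep(5, 6)), 1)
  expect_equal(bi_of(rep(50, 4)), 0)
  # ISIs {5, 50, 8, 60}: spikes 1,2 (5 ms) and 3,4 (8 ms) are in bursts -> 4/5
  expect_equal(bi_of(c(5, 50, 8, 60)), 0.8)
})

test_that("burst index respects the 5-spike amplitude qualifier and bounds", {
  sparse <- make_spike_sweep(c(150, 250), dt = 0.05)
  expect_true(is.na(burst_index(list(sparse)))) # mean count 2 < 5
  for (s in property_seeds(10)) {
    set.seed(s)
    t_sp <- sort(120 + runif(8) * 250)
    sw <- make_spike_sweep(t_sp[c(TRUE, diff(t_sp) > 4)], dt = 0.05)
    bi <- burst_index(list(sw), min_spikes = 1)
    expect_gte(bi, 0)
    expect_lte(bi, 1)
  }
})

test_that("Vm variance is the median of per-segment variances", {
  expect_equal(vm_variance(rep(-60, 30000), dt = 1), 0)
  # three 5-s segments with known sample variances
  set.seed(1)
  seg <- function(sdv) rnorm(5000, -60, sdv)
  v <- c(seg(0.3), seg(0.45), seg(0.95))
  expect_equal(vm_variance(v, dt = 1),
               median(c(var(v[1:5000]), var(v[5001:10000]), var(v[10001:15000]))))
  expect_error(vm_variance(rnorm(100), dt = 1), "shorter")
})

test_that("white-noise Vm variance is recovered", {
  set.seed(99)
  v <- rnorm(25000, -60, 0.5) # 25 s at 1 ms sampling
  expect_equal(vm_variance(v, dt = 1), 0.25, tolerance = 0.1 * 0.25)
})

test_that("QC applies the three criteria with strict inequalities", {
  feat <- function(vm, rs, amp) list(vm_rest = vm, rs = rs, spike_amplitude = amp)
  expect_true(qc_pass(feat(-62, 50, 55))$pass)
  r <- qc_pass(feat(-50, 50, 55))
  expect_false(r$pass)
  expect_equal(r$reasons, "vm_rest")
  expect_false(qc_pass(feat(-55, 50, 55))$pass) # boundary fails
  expect_false(qc_pass(feat(-62, 100, 55))$pass)
  expect_false(qc_pass(feat(-62, 50, 40))$pass)
  expect_setequal(qc_pass(feat(-50, 120, 30))$reasons,
                  c("vm_rest", "rs", "spike_amplitude"))
})

test_that("feature extraction is pure and degrades gracefully", {
  p <- neuron_params()
  set.seed(5)
  block <- ieplast:::simulate_block(p, stim_protocol(), 0.025)
  f1 <- extract_features(block)
  f2 <- extract_features(block)
  expect_identical(f1, f2)
  hyper_only <- list(sweeps = Filter(function(s) s$step_amp < 0, block$sweeps),
                     spont = block$spont)
  fh <- extract_features(hyper_only)
  expect_false(is.na(fh$rin))
  expect_true(is.na(fh$latency_ms))
  expect_true(is.na(fh$firing_rate_max))
  expect_true("depolarizing sweeps" %in% fh$missing)
})
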