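make_triangle_position <- function(n_periods = 10, lap_s = 10, hz = 50,
                                   track = 200) {
  t <- seq(0, 2 * n_periods * lap_s, by = 1 / hz)
  phase <- (t / lap_s) %% 2
  data.frame(t_s = t, x_cm = track * ifelse(phase <= 1, phase, 2 - phase))
}

test_that("lap segmentation finds turnarounds in both directions", {
  pos <- make_triangle_position(10)
  laps <- segment_laps(pos, 200)
  expect_equal(sum(laps$direction == "up"), 10)
  expect_equal(sum(laps$direction == "down"), 10)
  expect_true(all(diff(laps$start) > 0))
  # turnaround times agree with a brute-force extremum scan
  x <- pos$x_cm
  ext <- c()
  for (k in 2:(length(x) - 1)) {
    if ((x[k] - x[k - 1]) * (x[k + 1] - x[k]) < 0) ext <- c(ext, pos$t_s[k])
  }
  expect_equal(sort(unique(laps$end[-nrow(laps)])), ext, tolerance = 1e-9)
  expect_error(segment_laps(data.frame(t_s = 1:100, x_cm = rep(50, 100)), 200),
               "turnaround")
})

test_that("rate maps conserve spikes and occupancy", {
  p <- place_session_params(seed = 5, n_laps = 20)
  ses <- simulate_place_session(p)
  map <- compute_rate_map(ses, bin_cm = 2)
  # occupancy-weighted mean equals total spikes / total time (up direction)
  up <- ses$laps[ses$laps$direction == "up", ]
  in_up <- vapply(ses$spikes, function(t) {
    any(t >= up$start & t <= up$end)
  }, logical(1))
  expect_equal(sum(map$counts), sum(in_up))
  expect_equal(sum(map$counts) / sum(map$occupancy),
               sum(map$mean_rate * colSums(map$occupancy), na.rm = TRUE) /
                 sum(map$occupancy))
  # doubling bin width halves bin count, preserves spike mass
  map4 <- compute_rate_map(ses, bin_cm = 4)
  expect_equal(ncol(map4$counts), ncol(map$counts) / 2)
  expect_equal(sum(map4$counts), sum(map$counts))
})

test_that("a homogeneous cell yields a flat rate map at the set rate", {
  p <- place_session_params(peak_rate_in = 0, base_rate_out = 2,
                            drift_per_lap = 1, n_laps = 30, seed = 8)
  ses <- simulate_place_session(p)
  map <- compute_rate_map(ses)
  expect_equal(mean(map$mean_rate), 2, tolerance = 0.15)
  expect_true(all(abs(map$mean_rate - 2) < 2.5))
})

test_that("field detection takes the contiguous run around the peak", {
  bump <- exp(-((1:100) - 40)^2 / 50)
  field <- detect_field(bump)
  expect_true(40 %in% field)
  expect_true(all(diff(field) == 1))
  expect_true(all(bump[field] >= 0.2 * max(bump)))
  expect_false(attr(field, "degenerate"))
  # flat zero map: no field
  expect_null(detect_field(rep(0, 50)))
  # uniform map: whole track, flagged degenerate
  uni <- detect_field(rep(3, 50))
  expect_equal(length(uni), 50)
  expect_true(attr(uni, "degenerate"))
  # two equal bumps: the first peak bin wins
  two <- c(rep(0, 10), rep(5, 5), rep(0, 10), rep(5, 5), rep(0, 10))
  f2 <- detect_field(two)
  expect_equal(range(f2), c(11, 15))
})

test_that("in/out-of-field rates partition every lap's spikes", {
  p <- place_session_params(seed = 9, n_laps = 25)
  ses <- simulate_place_session(p)
  map <- compute_rate_map(ses)
  field <- detect_field(map$mean_rate)
  rates <- infield_outfield_rates(map, field)
  expect_equal(rates$in_spikes + rates$out_spikes,
               unname(rowSums(map$counts)))
  # zero baseline: no out-of-field spikes on any lap
  p0 <- place_session_params(base_rate_out = 0, seed = 10)
  ses0 <- simulate_place_session(p0)
  map0 <- compute_rate_map(ses0)
  f0 <- detect_field(map0$mean_rate)
  r0 <- infield_outfield_rates(map0, f0)
  expect_true(all(r0$out_spikes == 0))
})

test_that("out-of-field rate recovers the generative baseline", {
  p <- place_session_params(base_rate_out = 1.5, drift_per_lap = 1,
                            in_field_gain_per_lap = 1, n_laps = 30, seed = 11)
  rates <- sapply(1:15, function(k) {
    pk <- p; pk$seed <- 100 + k
    ses <- simulate_place_session(pk)
    map <- compute_rate_map(ses)
    mean(infield_outfield_rates(map, detect_field(map$mean_rate))$out_rate,
         na.rm = TRUE)
  })
  expect_equal(mean(rates), 1.5, tolerance = 0.1)
})

test_that("stability is the mean pairwise lap correlation", {
  lap <- c(0, 1, 3, 7, 3, 1, 0)
  same <- rbind(lap, lap, lap)
  expect_equal(stability(same), 1)
  set.seed(12)
  three <- matrix(rnorm(30), 3, 10)
  manual <- mean(c(cor(three[1, ], three[2, ]), cor(three[1, ], three[3, ]),
                   cor(three[2, ], three[3, ])))
  expect_equal(stability(three, smooth_bins = 0), manual)
  # zero-variance laps drop their pairs
  withz <- rbind(lap, rep(2, 7), lap * 2 + 1)
  expect_equal(stability(withz, smooth_bins = 0), 1) # lap1-lap3 pair only
  expect_error(stability(matrix(1, 1, 5)), "2 laps")
})

test_that("uncorrelated laps have near-zero mean stability", {
  set.seed(13)
  vals <- replicate(200, stability(matrix(rnorm(5 * 20), 5, 20)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("spatial information matches closed forms", {
  occ <- rep(1, 10)
  expect_equal(spatial_information(rep(2, 10), occ), 0)
  # all spikes in one of two equally occupied bins: 1 bit/spike
  expect_equal(spatial_information(c(4, 0), c(1, 1)), 1)
  # Gaussian bump against a direct numerical evaluation
  lam <- exp(-((1:50) - 25)^2 / 20) * 5
  p_i <- rep(1 / 50, 50)
  lbar <- sum(p_i * lam)
  manual <- sum((p_i * (lam / lbar) * log2(lam / lbar))[lam > 0])
  expect_equal(spatial_information(lam, rep(2, 50)), manual)
  expect_true(is.na(spatial_information(rep(0, 10), occ)))
})

test_that("inclusion requires both criteria strictly above threshold", {
  expect_true(include_cell(0.5, 0.5))
  expect_false(include_cell(0.1, 0.5))
  expect_false(include_cell(0.5, 0.05))
  expect_false(include_cell(NA, 0.5))
})

test_that("session thirds split by time with boundary laps going earlier", {
  rates <- rep(2, 9)
  mids <- seq(50, 850, by = 100)
  th <- session_thirds(rates, mids, span = c(0, 900))
  expect_equal(unname(th), c(2, 2, 2))
  # linear decay: strictly decreasing thirds
  dec <- session_thirds(seq(9, 1), mids, c(0, 900))
  expect_true(all(diff(dec) < 0))
  # a lap exactly on the span/3 boundary joins the earlier third
  th2 <- session_thirds(c(1, 10), c(300, 600), span = c(0, 900))
  expect_equal(unname(th2), c(1, 10, NA_real_))
})

test_that("lap-rate correlation follows its definition and null scale", {
  expect_equal(lap_rate_correlation(1:10), 1)
  expect_true(is.na(lap_rate_correlation(rep(3, 10))))
  expect_true(is.na(lap_rate_correlation(c(1, 2))))
  set.seed(14)
  n <- 12
  r <- replicate(1000, lap_rate_correlation(rnorm(n)))
  expect_lt(abs(mean(r)), 0.03)
  expect_equal(sd(r), 1 / sqrt(n - 1), tolerance = 0.1)
})

test_that("population tests agree with reference implementations", {
  set.seed(15)
  n <- 30
  thirds <- matrix(rnorm(n * 3, 2), n, 3)
  corrs <- rnorm(n, 0, 0.3)
  res <- population_tests(thirds, corrs, alternative = "less")
  # RM-ANOVA against aov run independently
  long <- data.frame(rate = as.vector(thirds),
                     third = factor(rep(1:3, each = n)),
                     cell = factor(rep(1:n, 3)))
  ref <- summary(aov(rate ~ third + Error(cell), long))
  tab <- ref[["Error: Within"]][[1]]
  expect_equal(res$anova_F, tab["third", "F value"])
  expect_equal(res$anova_p, tab["third", "Pr(>F)"])
  # center test: normal data here, so a one-tailed t-test
  expect_equal(res$center_test, "t")
  expect_equal(res$center_p, t.test(corrs, alternative = "less")$p.value)
  # clearly non-normal correlations fall back to the sign test
  skew <- c(rep(-0.9, 12), runif(18, -0.05, 0))
  res2 <- population_tests(thirds, skew, alternative = "less")
  expect_equal(res2$center_test, "sign")
  expect_equal(res2$center_p,
               binom.test(sum(skew > 0), sum(skew != 0), alternative = "less")$p.value)
})

test_that("flat populations give null-looking tests", {
  set.seed(16)
  thirds <- matrix(2 + rnorm(60 * 3, 0, 0.2), 60, 3)
  corrs <- rnorm(60, 0, 0.2)
  res <- population_tests(thirds, corrs, alternative = "two.sided")
  expect_gt(res$anova_p, 0.01)
  expect_gt(res$center_p, 0.01)
})

test_that("place sessions are reproducible and respect their geometry", {
  p <- place_session_params(seed = 17)
  a <- simulate_place_session(p)
  b <- simulate_place_session(p)
  expect_identical(a$spikes, b$spikes)
  expect_true(all(a$position$x_cm >= 0 & a$position$x_cm <= p$track_length))
  expect_equal(nrow(a$laps), 2 * p$n_laps)
  expect_true(all(a$spikes >= 0 & a$spikes <= max(a$laps$end)))
})

test_that("driftless sessions have near-zero out-of-field lap correlation", {
  p <- place_session_params(drift_per_lap = 1, in_field_gain_per_lap = 1)
  rs <- vapply(1:100, function(k) {
    pk <- p; pk$seed <- 300 + k
    s <- session_stats(simulate_place_session(pk))
    s$lap_corr_out
  }, numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.05)
})

test_that("a drifting population is detected by the session-thirds pipeline", {
  p <- place_session_params(drift_per_lap = 0.98, n_laps = 30)
  pop <- simulate_place_population(40, p, seed = 18)
  expect_gt(pop$n_included, 30)
  th <- colMeans(pop$thirds_out)
  expect_true(all(diff(th) < 0)) # strictly decreasing out-of-field thirds
  res <- population_tests(pop$thirds_out, pop$corr_out, alternative = "less")
  expect_lt(res$anova_p, 0.05)
  expect_lt(res$center_p, 0.05)
})

test_that("the count-matrix fast path equals the spike-time pipeline", {
  p <- place_session_params(seed = 19, n_laps = 15)
  fast <- simulate_place_population(3, p, seed = 19, use_counts = TRUE,
                                    apply_inclusion = FALSE)
  slow <- simulate_place_population(3, p, seed = 19, use_counts = FALSE,
                                    apply_inclusion = FALSE)
  for (k in seq_along(fast$stats)) {
    expect_equal(fast$stats[[k]]$stability, slow$stats[[k]]$stability,
                 tolerance = 0.05)
    expect_equal(fast$stats[[k]]$thirds_out, slow$stats[[k]]$thirds_out,
                 tolerance = 0.15)
  }
})
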