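test_that("IO curves average repeats per amplitude", {
  counts <- c(5, 6, 7, 10, 11, 12)
  amps <- c(100, 100, 100, 200, 200, 200)
  cur <- build_io_curve(counts, amps)
  expect_equal(cur$amplitudes, c(100, 200))
  expect_equal(cur$mean_counts, c(6, 11))
  # zero counts are retained, not dropped
  cur0 <- build_io_curve(c(0, 0, 4), c(100, 100, 200))
  expect_equal(cur0$mean_counts, c(0, 4))
  # matches a manual average on random data
  set.seed(3)
  x <- rpois(40, 6)
  a <- rep(c(50, 150, 250, 350), each = 10)
  expect_equal(build_io_curve(x, a)$mean_counts,
               as.numeric(tapply(x, a, mean)))
})

test_that("IO normalization follows the (X - minPre)/(maxPre - minPre) rule", {
  pre <- build_io_curve(c(1, 5, 9), c(100, 200, 300), "pre")
  norm <- normalize_io(pre, pre)
  expect_equal(norm$norm_count, c(0, 0.5, 1)) # endpoints map to 0 and 1
  expect_equal(norm$norm_current, c(0, 0.5, 1))
  post <- build_io_curve(c(0, 3, 7), c(100, 200, 300), "20")
  np <- normalize_io(post, pre)
  expect_equal(np$norm_count, (c(0, 3, 7) - 1) / 8)
  flat <- build_io_curve(c(4, 4, 4), c(100, 200, 300), "pre")
  expect_error(normalize_io(flat, flat), "degenerate")
})

test_that("IO normalization differences are invariant to a common count offset", {
  pre <- build_io_curve(c(2, 6, 10), c(100, 200, 300), "pre")
  post <- build_io_curve(c(1, 4, 8), c(100, 200, 300), "20")
  base <- normalize_io(post, pre)$norm_count - normalize_io(pre, pre)$norm_count
  pre2 <- build_io_curve(c(2, 6, 10) + 7, c(100, 200, 300), "pre")
  post2 <- build_io_curve(c(1, 4, 8) + 7, c(100, 200, 300), "20")
  shifted <- normalize_io(post2, pre2)$norm_count - normalize_io(pre2, pre2)$norm_count
  expect_equal(base, shifted)
})

test_that("pooled IO fit comparison separates shift from gain", {
  set.seed(11)
  make_pop <- function(transform, tp) {
    lapply(1:16, function(i) {
      x <- seq(0, 1, length.out = 4)
      y <- transform(x + rnorm(4, 0, 0.04))
      structure(list(timepoint = tp, cell_id = i, norm_current = x,
                     norm_count = y), class = "normalized_io")
    })
  }
  pre <- make_pop(identity, "pre")
  # identical data at both timepoints: both p near 1
  same <- c(pre, lapply(pre, function(z) { z$timepoint <- "20"; z }))
  fit <- compare_io_fits(same, "pre", "20")
  expect_gt(fit$slope_p, 0.9)
  expect_gt(fit$intercept_p, 0.9)
  # pure vertical shift: intercept p small, slope p large
  fit2 <- compare_io_fits(c(pre, make_pop(function(x) x - 0.3, "20")), "pre", "20")
  expect_lt(fit2$intercept_p, 0.01)
  expect_gt(fit2$slope_p, 0.05)
  # pure gain change: slope p small
  fit3 <- compare_io_fits(c(pre, make_pop(function(x) x * 0.5, "20")), "pre", "20")
  expect_lt(fit3$slope_p, 0.01)
})

test_that("percent change arithmetic", {
  expect_equal(percent_change(10, 7), -30)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(20, 41), 105)
  expect_true(is.na(percent_change(0, 3)))
  expect_equal(percent_change(c(10, 20), c(7, 41)), c(-30, 105))
})

test_that("group statistics match the reference implementation", {
  set.seed(21)
  pre_a <- rnorm(16, 10, 2); post_a <- pre_a * 0.7 + rnorm(16, 0, 1)
  pre_b <- rnorm(11, 10, 2); post_b <- pre_b + rnorm(11, 0, 1)
  g <- group_stats(pre_a, post_a, pre_b, post_b)
  expect_equal(g$TBS$paired_p, t.test(post_a, pre_a, paired = TRUE)$p.value)
  ch_a <- 100 * (post_a - pre_a) / pre_a
  ch_b <- 100 * (post_b - pre_b) / pre_b
  expect_equal(g$between_p, t.test(ch_a, ch_b)$p.value, tolerance = 1e-12)
  expect_equal(g$TBS$mean_change, mean(ch_a))
  expect_equal(g$TBS$sem_change, sd(ch_a) / 4)
  expect_equal(g$TBS$n, 16L)
  # identical groups: between-group p is 1
  gi <- group_stats(pre_a, post_a, pre_a, post_a)
  expect_gt(gi$between_p, 0.99)
  expect_error(group_stats(1, 2, pre_b, post_b), "n >= 2")
})

test_that("between-group test has power at a 1 SD shift", {
  # TBS-sized groups: a one-SD mean difference is detected most of the time
  set.seed(31)
  hits <- mean(replicate(400, {
    a <- rnorm(16, -1); b <- rnorm(11, 0)
    t.test(a, b)$p.value < 0.05
  }))
  # compare implementation power on the same design
  set.seed(31)
  hits2 <- mean(replicate(400, {
    pre_a <- rep(10, 16); post_a <- 10 + rnorm(16, -1) / 10
    pre_b <- rep(10, 11); post_b <- 10 + rnorm(11, 0) / 10
    group_stats(pre_a, post_a, pre_b, post_b)$between_p < 0.05
  }))
  expect_equal(hits, hits2)
  expect_gt(hits2, 0.55)
})

test_that("stimulation-strength correlation returns OLS R^2 and p", {
  x <- c(100, 150, 200, 250, 300)
  y <- -0.1 * x + 5
  r <- suppressWarnings(correlate_with_stimulation(x, y))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, -0.1)
  set.seed(41)
  xr <- rnorm(16); yr <- rnorm(16)
  rr <- correlate_with_stimulation(xr, yr)
  fit <- summary(lm(yr ~ xr))
  expect_equal(rr$r_squared, fit$r.squared)
  expect_equal(rr$p, fit$coefficients[2, 4])
  expect_error(correlate_with_stimulation(rep(1, 5), rnorm(5)), "variance")
})

test_that("independent predictors give the null R^2 scale", {
  set.seed(51)
  n <- 10
  r2 <- replicate(1000, correlate_with_stimulation(rnorm(n), rnorm(n))$r_squared)
  expect_equal(mean(r2), 1 / (n - 1), tolerance = 0.2 / (n - 1))
})

test_that("the spike-count subset filter is boundary-inclusive", {
  cells <- lapply(c(300, 249, 250), function(n) list(n_tbs_spikes = n))
  kept <- dtx_subset_filter(cells)
  expect_equal(vapply(kept, `[[`, numeric(1), "n_tbs_spikes"), c(300, 250))
  expect_length(dtx_subset_filter(list()), 0L)
})
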