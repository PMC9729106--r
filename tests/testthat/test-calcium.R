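test_that("deltaF/F equals the direct formula", {
  const <- delta_f_over_f(rep(100, 50), baseline_window = 1:10,
                          sampling_rate = 10)
  expect_equal(const$values, rep(0, 50))

  raw <- c(rep(100, 10), seq(100, 150, length.out = 10))
  d <- delta_f_over_f(raw, baseline_window = 1:10, sampling_rate = 2)
  expect_equal(max(d$values), 0.5)

  set.seed(7)
  r <- runif(200, 50, 200)
  d2 <- delta_f_over_f(r, baseline_window = 1:30, sampling_rate = 10)
  f0 <- mean(r[1:30])
  expect_equal(d2$values, (r - f0) / f0)

  expect_error(delta_f_over_f(c(-1, -1, 5), baseline_window = 1:2,
                              sampling_rate = 1), "baseline")
})

test_that("3x3 smoothing equals the sliding-window mean oracle", {
  expect_equal(smooth_3x3(matrix(5, 4, 4)), matrix(5, 4, 4))

  fr <- matrix(0, 7, 7); fr[4, 4] <- 9
  sm <- smooth_3x3(fr)
  expect_equal(sm[3:5, 3:5], matrix(1, 3, 3))

  set.seed(11)
  rf <- matrix(rnorm(9 * 12), 9, 12)
  expect_equal(smooth_3x3(rf), oracle_mean3x3(rf))

  stack <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  sm3 <- smooth_3x3(stack)
  expect_equal(sm3[, , 2], oracle_mean3x3(stack[, , 2]))

  expect_error(smooth_3x3(matrix(1, 2, 5)), "3 x 3")
})

test_that("rising phase runs from the first supra-baseline point to the peak", {
  v <- c(rep(0, 10), 0.02, 0.1, 0.3, 0.6, 0.9, 1.0, 0.8, 0.5)
  tr <- fluorescence_trace(v, 10)
  ev <- extract_rising_phase(tr, peak_index = 16, baseline = 0.01)
  expect_equal(ev$onset_index, 11)
  expect_equal(ev$rising_values, v[11:16])

  # oracle: forward scan for the first value > baseline before the peak
  onset_oracle <- min(which(v[1:16] > 0.01))
  expect_equal(ev$onset_index, onset_oracle)

  expect_error(extract_rising_phase(tr, peak_index = 3, baseline = 0.01),
               "above baseline")
  short <- fluorescence_trace(c(0, 0.5, 1, 0.2), 10)
  expect_error(extract_rising_phase(short, 3, baseline = 0.4), "shorter")
})

test_that("noiseless model data are recovered exactly and equivariantly", {
  fs <- 50
  x <- seq(0.56, 2.5, by = 1 / fs)
  y <- 1 - exp(-2 * (x - 0.5))
  tr <- fluorescence_trace(c(rep(0, 28), y), fs)
  ev <- extract_rising_phase(tr, length(tr$values), baseline = 0)
  est <- fit_exponential_rise(ev, normalize = "free_amplitude")
  expect_lt(abs(est$k - 2) / 2, 1e-6)
  expect_lt(abs(est$t0 - 0.5) / 0.5, 1e-6)

  # agreement with an independent grid search on the same segment
  g <- oracle_exp_grid(ev$rising_times_s, ev$rising_values / max(ev$rising_values),
                       k_range = c(0.5, 4), t0_range = c(0.3, 0.56))
  est_peak <- fit_exponential_rise(ev, normalize = "peak")
  expect_lt(abs(est_peak$t0 - g$t0), 0.02)
  expect_lt(abs(est_peak$k - g$k), 0.1)

  # translation equivariance: shifting the segment shifts t0 exactly
  delta <- 0.8
  tr2 <- fluorescence_trace(c(rep(0, 28 + delta * fs), y), fs)
  ev2 <- extract_rising_phase(tr2, length(tr2$values), baseline = 0)
  est2 <- fit_exponential_rise(ev2, normalize = "free_amplitude")
  expect_equal(est2$t0 - est$t0, delta, tolerance = 1e-6)
})

test_that("spike-time recovery is unbiased under noise (200 replicates)", {
  fs <- 50; k_true <- 2; t0_true <- 0.5; sigma <- 0.05
  x <- seq(0.56, 3.0, by = 1 / fs)
  mu <- 1 - exp(-k_true * (x - t0_true))
  set.seed(42)
  t0_hat <- replicate(200, {
    y <- mu + rnorm(length(x), 0, sigma)
    ev <- structure(list(rising_values = y, rising_times_s = x,
                         sampling_rate = fs), class = "calcium_event")
    fit_exponential_rise(ev, normalize = "free_amplitude")$t0
  })
  se <- sd(t0_hat) / sqrt(length(t0_hat))
  expect_lt(abs(mean(t0_hat) - t0_true), 2 * se + 1e-4)
})

test_that("ROI-pair delay tracks the planted conduction delay and block rate", {
  est_pair <- function(delay_ms, block_prob, seed = 3) {
    pair <- gen_axon_roi_pair(delay_ms = delay_ms, block_prob = block_prob,
                              fs = 20, noise_sd = 0.01, seed = seed)
    fits <- lapply(pair[c("proximal", "distal")], function(tr) {
      pk <- which.max(tr$values)
      fit_exponential_rise(extract_rising_phase(tr, pk, baseline = 0.03))
    })
    rise_time_delay(fits$proximal, fits$distal)
  }
  same <- gen_axon_roi_pair(0, 0, noise_sd = 0, seed = 1)
  pk <- which.max(same$proximal$values)
  f <- fit_exponential_rise(extract_rising_phase(same$proximal, pk,
                                                 baseline = 0.01))
  expect_equal(rise_time_delay(f, f), 0)

  expect_equal(1000 * est_pair(150, 0), 150, tolerance = 0.35)

  # the population delay estimate grows with the planted per-pulse block
  # probability (median over axons; single-axon estimates are heavy-tailed)
  dts <- vapply(c(0, 0.3, 0.6), function(bp)
    median(vapply(1:60, function(s) est_pair(0, bp, seed = s), numeric(1)),
           na.rm = TRUE),
    numeric(1))
  expect_true(all(diff(dts) > 0))

  failed <- structure(list(t0 = NA_real_, k = NA_real_, converged = FALSE),
                      class = "spike_time_estimate")
  expect_true(is.na(rise_time_delay(f, failed)))
})

test_that("Pearson ROI correlation equals the textbook formula", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_roi_correlation(a, a), 1)
  expect_equal(pearson_roi_correlation(a, -a), -1)
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_roi_correlation(x, y), manual)
  expect_warning(r0 <- pearson_roi_correlation(rep(1, 5), a), "zero-variance")
  expect_true(is.na(r0))
  expect_error(pearson_roi_correlation(1:4, 1:5), "equal length")
})

test_that("trial averaging is the pointwise mean and shrinks noise ~ 1/sqrt(3)", {
  mk <- function(v) fluorescence_trace(v, 10)
  same <- average_trials(list(mk(1:10), mk(1:10), mk(1:10)))
  expect_equal(same$values, as.numeric(1:10))
  ramps <- average_trials(list(mk(1:10), mk(2 * (1:10)), mk(3 * (1:10))))
  expect_equal(ramps$values, 2 * (1:10))
  set.seed(9)
  sds <- replicate(300, sd(average_trials(
    list(mk(rnorm(20)), mk(rnorm(20)), mk(rnorm(20))))$values))
  expect_equal(mean(sds), 1 / sqrt(3), tolerance = 0.05)
  expect_error(average_trials(list(mk(1:10), mk(1:9), mk(1:10))), "length")
})

test_that("activity filter keeps axons with >= 1 transient per minute, inclusive", {
  expect_false(filter_active_axons(0, 300))
  expect_true(filter_active_axons(5, 300))
  expect_true(filter_active_axons(5, 300.0))   # exactly 1/min
  expect_false(filter_active_axons(4, 300))
  expect_error(filter_active_axons(1, 0), "> 0")
})
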