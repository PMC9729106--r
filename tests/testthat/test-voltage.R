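test_that("soma-averaged trace equals the row-mean oracle", {
  km <- kymograph(matrix(7, 100, 16), soma_pixels = 5:12)
  expect_equal(kymograph_to_trace(km)$values, rep(7, 100))

  one <- kymograph(matrix(1:16, 1, 16), soma_pixels = 3:6)
  expect_equal(kymograph_to_trace(one)$values, mean(3:6))

  set.seed(2)
  img <- matrix(rnorm(200 * 32), 200, 32)
  km2 <- kymograph(img, soma_pixels = 10:20)
  expect_equal(kymograph_to_trace(km2)$values, rowMeans(img[, 10:20]))

  expect_error(kymograph(img, soma_pixels = 30:40), "pixel bounds")
})

test_that("dip detection finds planted antidromic APs and nothing on flat traces", {
  stim <- 40 + 100 * 0:9
  flat <- structure(list(values = rep(100, 1000), sampling_rate = 1000,
                         time_ms = 0:999), class = "voltage_response_trace")
  d0 <- detect_dips(flat, stim)
  expect_true(all(is.na(d0$dip_ms)))

  ks <- gen_voltage_kymograph(100, b_true = 50, k_true = 0.3, noise_sd = 1,
                              seed = 4)
  e <- ks[[1]]
  d <- detect_dips(kymograph_to_trace(e$kymo), e$stim_times_ms)
  expect_lte(sum(!is.na(d$dip_ms)), 10)
  expect_equal(sum(!is.na(d$dip_ms)), sum(e$success))
  # planted latency 8 ms recovered within the 1 kHz sampling tolerance
  expect_true(all(abs(d$latency_ms[!is.na(d$dip_ms)] - 8) <= 1))
})

test_that("AP latency is the dip-stimulus interval and failures stay NA", {
  expect_equal(ap_latency(40, 40), 0)
  expect_equal(ap_latency(40, 52), 12)
  expect_true(is.na(ap_latency(40, NA)))
  expect_error(ap_latency(40, 30), "precedes")
})

test_that("FFT power matches the direct DFT sum and scales quadratically", {
  fs <- 1000; t <- (0:999) / fs
  expect_equal(fft_power_at(rep(3, 1000), 10, fs), 0)

  s1 <- sin(2 * pi * 10 * t)
  p1 <- fft_power_at(s1, 10, fs, detrend = FALSE)
  p2 <- fft_power_at(2 * s1, 10, fs, detrend = FALSE)
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
  expect_equal(p1, oracle_dft_power(s1, fs, 10), tolerance = 1e-12)

  # off-frequency sinusoid leaks nothing into the 10 Hz bin (integer periods)
  s7 <- sin(2 * pi * 7 * t)
  expect_lt(fft_power_at(s7, 10, fs, detrend = FALSE), 1e-20)

  set.seed(8)
  r <- rnorm(512)
  expect_equal(fft_power_at(r, 10, fs, detrend = FALSE),
               oracle_dft_power(r, fs, 10), tolerance = 1e-12)

  expect_error(fft_power_at(rnorm(50), 10, 1000), "shorter")
})

test_that("logistic threshold fit recovers exact and bracketed thresholds", {
  x <- seq(10, 100, by = 10)
  y <- 1 / (1 + exp(-0.3 * (x - 50)))
  fit <- fit_logistic_threshold(x, y)
  expect_true(fit$converged)
  expect_equal(fit$b, 50, tolerance = 1e-4)
  expect_equal(fit$a, 1, tolerance = 1e-4)

  step <- fit_logistic_threshold(seq(10, 60, by = 10), c(0, 0, 0, 1, 1, 1))
  expect_true(step$b > 30 && step$b < 40)

  expect_error(fit_logistic_threshold(c(1, 2, 3), c(0, 1, 1)), "4 distinct")
  allhigh <- fit_logistic_threshold(x, rep(1, 10))
  expect_false(allhigh$converged)
})

test_that("threshold estimation is unbiased over noisy dose-response replicates", {
  x <- seq(10, 100, by = 10)
  mu <- 2 / (1 + exp(-0.25 * (x - 55)))
  set.seed(21)
  b_hat <- replicate(100, {
    fit_logistic_threshold(x, pmax(0, mu + rnorm(length(x), 0, 0.05)))$b
  })
  se <- sd(b_hat) / sqrt(length(b_hat))
  expect_lt(abs(mean(b_hat) - 55), 2 * se + 0.05)
})

test_that("full kymograph pipeline recovers the planted threshold", {
  x <- seq(10, 100, by = 10)
  b_err <- vapply(1:12, function(s) {
    ks <- gen_voltage_kymograph(x, b_true = 52, k_true = 0.35, seed = s)
    pw <- vapply(ks, function(e) fft_power_at(kymograph_to_trace(e$kymo)),
                 numeric(1))
    fit_logistic_threshold(x, pw)$b - 52
  }, numeric(1))
  expect_lt(median(abs(b_err)), 10)  # within one current step

  # an "AD-like" cell (higher planted threshold) ranks above a "WT-like" one
  fit_b <- function(b, seed) {
    ks <- gen_voltage_kymograph(x, b_true = b, k_true = 0.35, seed = seed)
    pw <- vapply(ks, function(e) fft_power_at(kymograph_to_trace(e$kymo)),
                 numeric(1))
    fit_logistic_threshold(x, pw)$b
  }
  ad <- vapply(1:5, function(s) fit_b(70, s), numeric(1))
  wt <- vapply(1:5, function(s) fit_b(35, s + 100), numeric(1))
  expect_true(all(ad > wt))
})
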