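# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, not by calling the code they check.

# exhaustive scan for upward threshold crossings, with refractory pruning
oracle_crossings <- function(v, time_ms, threshold = 10, refractory_ms = 2) {
  times <- c()
  last <- -Inf
  for (i in 2:length(v)) {
    if (v[i] > threshold && v[i - 1] <= threshold &&
        time_ms[i] - last >= refractory_ms) {
      times <- c(times, time_ms[i])
      last <- time_ms[i]
    }
  }
  times
}

# analytic steady-state profile of a sealed-end passive cable with constant
# current I0 (nA) injected at x = 0
oracle_passive_profile <- function(x_um, I0_nA, diameter_um, L_um, channels) {
  lam_cm <- sqrt((diameter_um * 1e-4) * (1 / channels$gLeak) /
                   (4 * channels$Ra))
  ra <- channels$Ra / (pi * (diameter_um * 1e-4)^2 / 4)  # Ohm/cm
  x <- x_um * 1e-4; L <- L_um * 1e-4
  (I0_nA * 1e-9) * ra * lam_cm *
    cosh((L - x) / lam_cm) / sinh(L / lam_cm) * 1000  # mV
}

# grid search minimiser for the saturating-exponential rise
oracle_exp_grid <- function(x, y, k_range, t0_range, n = 200) {
  ks <- seq(k_range[1], k_range[2], length.out = n)
  ts <- seq(t0_range[1], t0_range[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (k in ks) for (t0 in ts) {
    r <- sum((y - (1 - exp(-k * (x - t0))))^2)
    if (r < best[3]) best <- c(k, t0, r)
  }
  list(k = best[1], t0 = best[2], rss = best[3])
}

# direct DFT summation power at the bin nearest a target frequency
oracle_dft_power <- function(v, fs, f_target) {
  n <- length(v)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  bin <- half[which.min(abs(freqs[half] - f_target))]
  f <- freqs[bin]
  t <- (seq_len(n) - 1) / fs
  Mod(sum(v * exp(-2i * pi * f * t)))^2 / n^2
}

# all set partitions of 1..n (restricted growth strings)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(s, maxlab) {
    if (length(s) == n) { out[[length(out) + 1]] <<- s; return() }
    for (lab in seq_len(maxlab + 1)) rec(c(s, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# weighted Newman modularity of a labelling over adjacency matrix W
oracle_modularity <- function(W, labels) {
  m2 <- sum(W)
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (labels[i] == labels[j]) q <- q + W[i, j] - deg[i] * deg[j] / m2
  q / m2
}

oracle_max_modularity <- function(W) {
  parts <- oracle_partitions(nrow(W))
  max(vapply(parts, function(p) oracle_modularity(W, p), numeric(1)))
}

# binary entropy in bits
oracle_h2 <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# 9-pixel sliding mean with reflect padding, direct implementation
oracle_mean3x3 <- function(fr) {
  n <- nrow(fr); m <- ncol(fr)
  refl <- function(i, k) min(max(i, 1), k)
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    s <- 0
    for (di in -1:1) for (dj in -1:1)
      s <- s + fr[refl(i + di, n), refl(j + dj, m)]
    out[i, j] <- s / 9
  }
  out
}

# a small conducting test axon reused by several cable tests
test_axon <- function(bulb_area = 0, ...) {
  cable_morphology(axon_diameter = 0.3, bulb_surface_area = bulb_area,
                   neck_diameter = if (bulb_area > 0)
                     neck_diameter_for_area(bulb_area) else 1, ...)
}

# regenerative threshold for the 0.3 um test axon, computed once per run
gstar_03 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- find_regenerative_density(test_axon())$g_star
    val
  }
})
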