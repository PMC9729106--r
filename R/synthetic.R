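#' Difference-of-exponentials calcium indicator kernel
#'
#' `(exp(-t/decay) - exp(-t/rise))`, peak-normalised to 1. Defaults emulate
#' a GCaMP6f-like indicator (50 ms rise, 400 ms decay).
#'
#' @param fs sampling rate, Hz.
#' @param rise_s,decay_s time constants, s (`0 < rise < decay`).
#' @param span_s kernel length, s.
#' @return numeric kernel sampled at `fs`.
#' @export
calcium_kernel <- function(fs, rise_s = 0.05, decay_s = 0.4, span_s = 3) {
  if (rise_s <= 0 || decay_s <= 0 || rise_s >= decay_s)
    stop("need 0 < rise_s < decay_s", call. = FALSE)
  t <- seq(0, span_s, by = 1 / fs)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Synthetic GCaMP trace from known spike times
#'
#' Spike train convolved with the indicator kernel plus i.i.d. Gaussian
#' noise; the ground truth travels with the trace.
#'
#' @param spike_times_s spike times in seconds.
#' @param duration_s trace duration, s.
#' @param fs sampling rate, Hz (2, 10 or 20 are typical).
#' @param rise_s,decay_s kernel time constants.
#' @param amplitude deltaF/F per spike.
#' @param noise_sd Gaussian noise s.d.
#' @param seed RNG seed.
#' @param roi_id ROI label.
#' @return a [fluorescence_trace()] with attribute `"truth"` (spike times,
#'   kernel parameters, seed).
#' @export
gen_gcamp_trace <- function(spike_times_s, duration_s, fs = 20,
                            rise_s = 0.05, decay_s = 0.4, amplitude = 1,
                            noise_sd = 0, seed = 1L, roi_id = "roi") {
  n <- round(duration_s * fs)
  drive <- numeric(n)
  for (ts in spike_times_s) {
    i <- floor(ts * fs) + 1L
    if (i >= 1L && i <= n) drive[i] <- drive[i] + amplitude
  }
  k <- calcium_kernel(fs, rise_s, decay_s)
  sig <- convolve(drive, rev(k), type = "open")[seq_len(n)]
  noise <- if (noise_sd > 0)
    withr::with_seed(seed, rnorm(n, 0, noise_sd)) else numeric(n)
  out <- fluorescence_trace(sig + noise, fs, roi_id = roi_id, unit = "dff")
  attr(out, "truth") <- list(spike_times_s = spike_times_s, rise_s = rise_s,
                             decay_s = decay_s, amplitude = amplitude,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic ROI pair on the two sides of a spheroid
#'
#' Emulates a stimulated axonal calcium experiment: a 50 Hz train of pulses
#' for 500 ms drives the proximal ROI with every pulse, while each pulse
#' reaches the distal ROI independently with probability `1 - block_prob`,
#' shifted by `delay_ms`. The truth record carries the planted delay and the
#' per-pulse pass outcomes.
#'
#' @param delay_ms conduction delay planted on the distal side.
#' @param block_prob per-pulse conduction block probability in `[0, 1]`.
#' @param fs imaging rate, Hz.
#' @param stim_rate_hz,train_ms,stim_start_s stimulation train (defaults:
#'   50 Hz for 500 ms starting at 1 s).
#' @param duration_s trace length, s.
#' @param noise_sd Gaussian noise s.d. (independent between ROIs).
#' @param amplitude_per_pulse deltaF/F contributed by one conducted pulse.
#' @param seed RNG seed (drives pass outcomes and noise).
#' @return list: `proximal`, `distal` ([fluorescence_trace()]s), `truth`.
#' @export
gen_axon_roi_pair <- function(delay_ms = 0, block_prob = 0, fs = 20,
                              stim_rate_hz = 50, train_ms = 500,
                              stim_start_s = 1, duration_s = 5,
                              noise_sd = 0.02, amplitude_per_pulse = 0.05,
                              seed = 1L) {
  if (block_prob < 0 || block_prob > 1)
    stop("'block_prob' must be in [0, 1]", call. = FALSE)
  n_pulses <- floor(train_ms / 1000 * stim_rate_hz) + 1L
  pulse_t <- stim_start_s + (seq_len(n_pulses) - 1L) / stim_rate_hz
  passes <- withr::with_seed(seed, runif(n_pulses) >= block_prob)
  prox <- gen_gcamp_trace(pulse_t, duration_s, fs,
                          amplitude = amplitude_per_pulse,
                          noise_sd = noise_sd, seed = seed + 1L,
                          roi_id = "proximal")
  dist <- gen_gcamp_trace(pulse_t[passes] + delay_ms / 1000, duration_s, fs,
                          amplitude = amplitude_per_pulse,
                          noise_sd = noise_sd, seed = seed + 2L,
                          roi_id = "distal")
  for (tr in c("prox", "dist")) {
    x <- get(tr); x$stim_onset_s <- stim_start_s; assign(tr, x)
  }
  list(proximal = prox, distal = dist,
       truth = list(delay_ms = delay_ms, block_prob = block_prob,
                    pulse_times_s = pulse_t, passed = passes, seed = seed))
}

#' Synthetic voltage-imaging kymograph series across stimulation currents
#'
#' For each current, a 1 s kymograph at 1 kHz with 10 pulses at 10 Hz; each
#' pulse elicits an antidromic-AP dip on the soma pixels with probability
#' `1 / (1 + exp(-k * (I - b)))`. Background pixels carry only noise.
#'
#' @param currents stimulation currents, uA.
#' @param b_true,k_true planted logistic threshold and slope.
#' @param n_pixels,soma_pixels kymograph geometry.
#' @param line_rate_hz line rate (default 1000).
#' @param baseline,dip_depth,dip_sd_ms,latency_ms dip shape: Gaussian dip of
#'   the given depth centred `latency_ms` after the pulse.
#' @param noise_sd per-pixel Gaussian noise s.d.
#' @param stim_start_ms first pulse onset.
#' @param seed RNG seed.
#' @return list with one element per current: `kymo` ([kymograph()]),
#'   `stim_times_ms`, `success` (planted per-pulse outcomes); plus `truth`.
#' @export
gen_voltage_kymograph <- function(currents, b_true = 50, k_true = 0.3,
                                  n_pixels = 64, soma_pixels = 24:40,
                                  line_rate_hz = 1000, baseline = 100,
                                  dip_depth = 12, dip_sd_ms = 2,
                                  latency_ms = 8, noise_sd = 1,
                                  stim_start_ms = 40, seed = 1L) {
  n_lines <- line_rate_hz  # 1 s sweep
  tms <- (seq_len(n_lines) - 1L) * 1000 / line_rate_hz
  stim <- stim_start_ms + 100 * 0:9  # 10 Hz: 5 ms pulses, 95 ms gaps
  out <- withr::with_seed(seed, lapply(seq_along(currents), function(ci) {
    I <- currents[ci]
    p <- 1 / (1 + exp(-k_true * (I - b_true)))
    success <- runif(10) < p
    img <- matrix(baseline + rnorm(n_lines * n_pixels, 0, noise_sd),
                  n_lines, n_pixels)
    for (q in which(success)) {
      centre <- stim[q] + latency_ms
      dip <- dip_depth * exp(-(tms - centre)^2 / (2 * dip_sd_ms^2))
      img[, soma_pixels] <- img[, soma_pixels] - dip
    }
    list(current = I, kymo = kymograph(img, line_rate_hz, soma_pixels),
         stim_times_ms = stim, success = success)
  }))
  names(out) <- sprintf("I_%g", currents)
  attr(out, "truth") <- list(b = b_true, k = k_true, currents = currents,
                             latency_ms = latency_ms, seed = seed)
  out
}

#' Synthetic cortical population raster with planted structure
#'
#' Cells are placed uniformly in a square field. Activity mixes three
#' sources: (i) independent background spiking, (ii) a shared latent
#' Gaussian factor with a spatially decaying kernel (distance-dependent
#' correlation), and (iii) stereotyped ensemble events -- in a fraction
#' `pattern_rep` of bins the population state is replaced by the
#' reactivation of one spatially contiguous planted cluster, so those bins
#' repeat a small set of stereotyped population states. The `"ad"` scenario
#' raises firing rates (through frequent ensemble reactivation), near-pair
#' correlation and repetitiveness, and plants fewer, larger clusters than
#' `"wt"`.
#'
#' @param n_cells number of neurons.
#' @param duration_s session length, s (default 1800 = 30 min).
#' @param fs frame rate, Hz (default 25; bins are 1/fs).
#' @param scenario `"wt"`, `"ad"`, or `"custom"` (take the explicit
#'   parameters below).
#' @param field_um side of the square imaging field, um.
#' @param base_rate_hz background firing rate per cell.
#' @param corr_length_um spatial correlation length of the shared factor.
#' @param corr_strength weight of the shared factor (0--1).
#' @param n_clusters number of planted ensembles.
#' @param pattern_rep fraction of bins occupied by a stereotyped ensemble
#'   reactivation.
#' @param seed RNG seed.
#' @return list: `raster` ([spike_raster()]), `cells` ([cell_map()]),
#'   `truth` (planted memberships and parameters).
#' @export
gen_population_raster <- function(n_cells = 150, duration_s = 1800, fs = 25,
                                  scenario = c("wt", "ad", "custom"),
                                  field_um = 400, base_rate_hz = NULL,
                                  corr_length_um = NULL, corr_strength = NULL,
                                  n_clusters = NULL, pattern_rep = NULL,
                                  seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_cells < 2L) stop("need at least 2 cells", call. = FALSE)
  defaults <- switch(scenario,
    wt = list(rate = 0.4, clen = 40, cstr = 0.25, ncl = 6, rep = 0.05),
    ad = list(rate = 0.25, clen = 80, cstr = 0.15, ncl = 2, rep = 0.7),
    custom = list(rate = 1.5, clen = 50, cstr = 0.6, ncl = 2, rep = 0.1))
  base_rate_hz <- base_rate_hz %||% defaults$rate
  corr_length_um <- corr_length_um %||% defaults$clen
  corr_strength <- corr_strength %||% defaults$cstr
  n_clusters <- n_clusters %||% defaults$ncl
  pattern_rep <- pattern_rep %||% defaults$rep

  n_bins <- round(duration_s * fs)
  p_base <- min(0.95, base_rate_hz / fs)
  withr::with_seed(seed, {
    xs <- runif(n_cells, 0, field_um)
    ys <- runif(n_cells, 0, field_um)
    cm <- cell_map(xs, ys)
    # spatially contiguous ensembles: nearest of n_clusters seed cells
    seeds <- sample.int(n_cells, n_clusters)
    d2seed <- outer(seq_len(n_cells), seeds, function(i, j)
      sqrt((xs[i] - xs[j])^2 + (ys[i] - ys[j])^2))
    member <- apply(d2seed, 1L, which.min)

    counts <- matrix(0L, n_cells, n_bins)
    if (p_base > 0)
      counts <- matrix(rbinom(n_cells * n_bins, 1L, p_base), n_cells, n_bins)
    # shared spatial factor: per-bin Gaussian field sampled at the cells,
    # thresholded into extra firing probability
    if (corr_strength > 0) {
      K <- exp(-as.matrix(stats::dist(cbind(xs, ys)))^2 /
                 (2 * corr_length_um^2))
      ch <- chol(K + diag(1e-6, n_cells))
      z <- t(ch) %*% matrix(rnorm(n_cells * n_bins), n_cells, n_bins)
      # during shared excursions (z > 1.2) a cell fires with extra
      # probability corr_strength, giving distance-decaying correlation
      bump <- (z > 1.2) * 1L
      extra <- matrix(rbinom(n_cells * n_bins, 1L,
                             pmin(0.95, as.numeric(bump) * corr_strength)),
                      n_cells, n_bins)
      counts <- counts + extra
    }
    # stereotyped ensemble reactivations replace the population state of
    # their bins: one whole cluster fires, everything else is silent
    if (pattern_rep > 0 && n_clusters >= 1L) {
      rep_bins <- which(runif(n_bins) < pattern_rep)
      if (length(rep_bins)) {
        which_cl <- sample.int(n_clusters, length(rep_bins), replace = TRUE)
        counts[, rep_bins] <- 0L
        for (ci in seq_len(n_clusters)) {
          bs <- rep_bins[which_cl == ci]
          if (length(bs)) counts[member == ci, bs] <- 1L
        }
      }
    }
    counts[counts > 1L] <- 1L
    rownames(counts) <- cm$cell_id
    list(raster = spike_raster(counts, bin_s = 1 / fs), cells = cm,
         truth = list(scenario = scenario, membership = member,
                      base_rate_hz = base_rate_hz,
                      corr_length_um = corr_length_um,
                      corr_strength = corr_strength,
                      n_clusters = n_clusters, pattern_rep = pattern_rep,
                      seed = seed))
  })
}

#' Parameter grid for the conduction sweep
#'
#' Cartesian grid covering the swept ranges (axon diameter 0.1--0.9 um,
#' bulb area 0--7,100 um^2, channel density 0--1.1 x the regenerative
#' threshold) at a configurable resolution.
#'
#' @param n_diameter,n_area,n_density points per axis.
#' @param diameter_range,area_range,density_range axis ranges; densities are
#'   multiples of the per-diameter regenerative threshold.
#' @return data.frame with one row per grid point and the axis vectors as
#'   attributes.
#' @export
gen_sweep_grid <- function(n_diameter = 5, n_area = 5, n_density = 3,
                           diameter_range = c(0.1, 0.9),
                           area_range = c(0, 7100),
                           density_range = c(0, 1.1)) {
  if (n_diameter < 1 || n_area < 1 || n_density < 1)
    stop("grid axes must be non-empty", call. = FALSE)
  if (diff(diameter_range) < 0 || diff(area_range) < 0 ||
      diff(density_range) < 0)
    stop("ranges must be non-decreasing", call. = FALSE)
  ds <- seq(diameter_range[1], diameter_range[2], length.out = n_diameter)
  as_ <- seq(area_range[1], area_range[2], length.out = n_area)
  ss <- seq(density_range[1], density_range[2], length.out = n_density)
  g <- expand.grid(axon_diameter = ds, bulb_surface_area = as_,
                   density = ss, KEEP.OUT.ATTRS = FALSE)
  attr(g, "diameter_grid") <- ds
  attr(g, "area_grid") <- as_
  attr(g, "density_grid") <- ss
  g
}
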