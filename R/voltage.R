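#' Line-scan kymograph container
#'
#' A lines x pixels intensity matrix from 1 kHz line scanning across a
#' voltage-indicator-labelled soma. Indicator polarity is kept raw: the
#' fluorescence *decreases* on depolarisation, so an action potential shows
#' up as a dip.
#'
#' @param intensity matrix, rows = scan lines (time), columns = pixels.
#' @param line_rate_hz line rate (default 1000).
#' @param soma_pixels integer vector of columns covering the soma.
#' @return object of class `kymograph`.
#' @export
kymograph <- function(intensity, line_rate_hz = 1000, soma_pixels) {
  if (!is.matrix(intensity)) stop("'intensity' must be a matrix", call. = FALSE)
  if (line_rate_hz <= 0) stop("'line_rate_hz' must be > 0", call. = FALSE)
  soma_pixels <- as.integer(soma_pixels)
  if (!length(soma_pixels) || min(soma_pixels) < 1L ||
      max(soma_pixels) > ncol(intensity))
    stop("'soma_pixels' must be a non-empty range within the pixel bounds",
         call. = FALSE)
  structure(list(intensity = intensity, line_rate_hz = line_rate_hz,
                 soma_pixels = soma_pixels),
            class = "kymograph")
}

#' Soma-averaged voltage response trace
#'
#' Per scan line, the mean intensity over the soma pixels: the membrane
#' potential readout of the neuron at that time.
#'
#' @param kymo a [kymograph()].
#' @return list of class `voltage_response_trace`: `values` (one per line),
#'   `sampling_rate` (Hz), `time_ms`.
#' @export
kymograph_to_trace <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  v <- rowMeans(kymo$intensity[, kymo$soma_pixels, drop = FALSE])
  structure(list(values = v, sampling_rate = kymo$line_rate_hz,
                 time_ms = (seq_along(v) - 1L) * 1000 / kymo$line_rate_hz),
            class = "voltage_response_trace")
}

#' Detect stimulation-locked dips (antidromic APs)
#'
#' For each stimulation pulse, finds the trace minimum within
#' `[stim, stim + search_window_ms]` and reports it as an antidromic AP time
#' if the dip depth below the pre-stimulus baseline exceeds
#' `n_mad` robust standard deviations of that baseline. Missing dips are
#' conduction failures and are reported as `NA` -- they are data, not errors.
#'
#' @param trace a `voltage_response_trace` (or numeric vector with
#'   `sampling_rate_hz`).
#' @param stim_times_ms stimulation onsets, ms, within the trace span.
#' @param search_window_ms post-pulse window searched for the dip (default
#'   30 ms).
#' @param n_mad dip-significance threshold (default 3).
#' @param baseline_ms pre-stimulus span (before the first pulse) used for
#'   the baseline median/MAD.
#' @param sampling_rate_hz used when `trace` is a bare vector.
#' @return data.frame: `stim_ms`, `dip_ms` (`NA` = failure), `depth`,
#'   `latency_ms`.
#' @export
detect_dips <- function(trace, stim_times_ms, search_window_ms = 30,
                        n_mad = 3, baseline_ms = NULL,
                        sampling_rate_hz = NULL) {
  if (inherits(trace, "voltage_response_trace")) {
    v <- trace$values; fs <- trace$sampling_rate
  } else {
    v <- as.numeric(trace)
    fs <- sampling_rate_hz %||% stop("give 'sampling_rate_hz'", call. = FALSE)
  }
  tms <- (seq_along(v) - 1L) * 1000 / fs
  if (any(stim_times_ms < 0) || any(stim_times_ms > max(tms)))
    stop("'stim_times_ms' must lie within the trace span", call. = FALSE)
  if (is.null(baseline_ms)) baseline_ms <- min(stim_times_ms)
  base <- v[tms < baseline_ms]
  if (length(base) < 5L) base <- v  # degenerate: whole-trace baseline
  b_med <- median(base)
  b_mad <- mad(base)
  out <- data.frame(stim_ms = stim_times_ms, dip_ms = NA_real_,
                    depth = NA_real_, latency_ms = NA_real_)
  for (i in seq_along(stim_times_ms)) {
    win <- which(tms >= stim_times_ms[i] &
                   tms <= stim_times_ms[i] + search_window_ms)
    if (!length(win)) next
    j <- win[which.min(v[win])]
    depth <- b_med - v[j]
    if (b_mad > 0 && depth > n_mad * b_mad) {
      out$dip_ms[i] <- tms[j]
      out$depth[i] <- depth
      out$latency_ms[i] <- tms[j] - stim_times_ms[i]
    }
  }
  out
}

#' Latency from stimulation to antidromic AP
#'
#' @param stim_time_ms,dip_time_ms times in ms; the dip must not precede the
#'   stimulus.
#' @return latency in ms (>= 0); `NA` in, `NA` out (failures are excluded
#'   from latency statistics by the caller).
#' @export
ap_latency <- function(stim_time_ms, dip_time_ms) {
  lat <- dip_time_ms - stim_time_ms
  if (any(lat < 0, na.rm = TRUE))
    stop("dip precedes stimulus; check pairing", call. = FALSE)
  lat
}

#' Spectral power at a target frequency
#'
#' Discrete Fourier power of the (mean- and linear-trend-detrended) trace at
#' the bin nearest `target_freq_hz`, normalised as `|X_f|^2 / N^2` so values
#' are comparable across trace lengths. The 10 Hz bin of a 10 Hz-stimulated
#' sweep indexes how reliably APs followed the stimulation.
#'
#' @param trace `voltage_response_trace` or numeric vector.
#' @param target_freq_hz frequency of interest (default 10).
#' @param sampling_rate_hz needed for bare vectors.
#' @param detrend subtract mean and linear trend first (default `TRUE`;
#'   removes photobleaching drift).
#' @return power in squared trace units.
#' @export
fft_power_at <- function(trace, target_freq_hz = 10, sampling_rate_hz = NULL,
                         detrend = TRUE) {
  if (inherits(trace, "voltage_response_trace")) {
    v <- trace$values; fs <- trace$sampling_rate
  } else {
    v <- as.numeric(trace)
    fs <- sampling_rate_hz %||% stop("give 'sampling_rate_hz'", call. = FALSE)
  }
  n <- length(v)
  if (n / fs < 1 / target_freq_hz)
    stop("trace shorter than one period of the target frequency", call. = FALSE)
  if (detrend) {
    x <- seq_len(n)
    v <- stats::lm.fit(cbind(1, x), v)$residuals
  }
  freqs <- (seq_len(n) - 1L) * fs / n
  half <- seq_len(floor(n / 2) + 1L)
  bin <- half[which.min(abs(freqs[half] - target_freq_hz))]
  Mod(fft(v)[bin])^2 / n^2
}

#' Fit the logistic stimulation-threshold curve
#'
#' Least-squares fit of `Y = a / (1 + exp(-k * (x - b)))` to per-current
#' response powers. The stimulation threshold is `b`, the current at the
#' half-height of the logistic (`Y(b) = a/2`).
#'
#' @param currents stimulation currents, uA (>= 4 distinct values spanning
#'   low and high response).
#' @param powers response powers (e.g. [fft_power_at()] per current).
#' @return object of class `threshold_fit`: `a`, `k`, `b` (threshold, uA),
#'   `residual`, `converged`.
#' @export
fit_logistic_threshold <- function(currents, powers) {
  stopifnot(length(currents) == length(powers))
  if (length(unique(currents)) < 4L)
    stop("need at least 4 distinct currents", call. = FALSE)
  pmax_ <- max(powers)
  if (pmax_ <= 0 || min(powers) > 0.5 * pmax_)
    return(structure(list(a = NA_real_, k = NA_real_, b = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          reason = "responses do not span low and high"),
                     class = "threshold_fit"))
  x <- currents; y <- powers
  # start b midway between the last sub-half-height and first supra-half-height
  # currents (robust for step-like data)
  b0 <- (max(x[y <= pmax_ / 2]) + min(x[y > pmax_ / 2])) / 2
  span <- max(x) - min(x)
  # steep (near-step) dose-response curves need a steep starting slope, so
  # try a ladder of initial k and keep the best converged fit
  fit <- NULL; best_rss <- Inf
  for (k0 in c(4, 12, 40, 120) / span) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + exp(-k * (x - b))),
                        start = list(a = pmax_, k = k0, b = b0),
                        lower = c(a = 1e-12, k = 1e-6, b = min(x) - span),
                        upper = c(a = 10 * pmax_, k = 1e3, b = max(x) + span),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      rss <- sum(stats::resid(cand)^2)
      if (rss < best_rss) { fit <- cand; best_rss <- rss }
    }
  }
  if (is.null(fit))
    return(structure(list(a = NA_real_, k = NA_real_, b = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          reason = "no convergence"),
                     class = "threshold_fit"))
  cf <- coef(fit)
  structure(list(a = unname(cf["a"]), k = unname(cf["k"]), b = unname(cf["b"]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 converged = unname(cf["a"]) > 0 && unname(cf["k"]) > 0),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<threshold_fit> a = %.4g, k = %.4g, threshold b = %.3f uA\n",
                x$a, x$k, x$b))
  else cat("<threshold_fit> failed:", x$reason %||% "non-convergence", "\n")
  invisible(x)
}
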