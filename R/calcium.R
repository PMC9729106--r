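#' Fluorescence trace container
#'
#' @param values trace values (raw intensity or deltaF/F).
#' @param sampling_rate Hz (2 for GCaMP6s, 10--20 for GCaMP6f are typical).
#' @param roi_id optional ROI label.
#' @param stim_onset_s optional stimulation onset, seconds.
#' @param unit `"dff"` or `"raw"`.
#' @return object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, sampling_rate, roi_id = NA_character_,
                               stim_onset_s = NA_real_,
                               unit = c("dff", "raw")) {
  unit <- match.arg(unit)
  if (any(!is.finite(values))) stop("trace values must be finite", call. = FALSE)
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0", call. = FALSE)
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 roi_id = roi_id, stim_onset_s = stim_onset_s, unit = unit),
            class = "fluorescence_trace")
}

#' Time axis of a fluorescence trace (seconds)
#' @param trace a `fluorescence_trace`.
#' @return numeric vector of sample times starting at 0.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1L) / trace$sampling_rate
}

#' Normalize raw fluorescence to deltaF/F
#'
#' `(F - F0) / F0` with the baseline `F0` taken as the mean over the
#' pre-stimulation window.
#'
#' @param raw raw-intensity `fluorescence_trace` (or numeric vector).
#' @param baseline_window integer index range (e.g. `1:20`) of the
#'   pre-stimulation samples; defaults to all samples before `stim_onset_s`.
#' @param sampling_rate needed when `raw` is a bare vector.
#' @return `fluorescence_trace` in deltaF/F units.
#' @export
delta_f_over_f <- function(raw, baseline_window = NULL, sampling_rate = NULL) {
  if (inherits(raw, "fluorescence_trace")) {
    v <- raw$values; fs <- raw$sampling_rate
    if (is.null(baseline_window)) {
      if (is.na(raw$stim_onset_s))
        stop("give 'baseline_window' or a trace with stim_onset_s", call. = FALSE)
      baseline_window <- seq_len(max(1L, floor(raw$stim_onset_s * fs)))
    }
  } else {
    v <- as.numeric(raw)
    fs <- sampling_rate %||% stop("give 'sampling_rate' for bare vectors",
                                  call. = FALSE)
    if (is.null(baseline_window))
      stop("give 'baseline_window' for bare vectors", call. = FALSE)
  }
  if (!length(baseline_window)) stop("empty baseline window", call. = FALSE)
  f0 <- mean(v[baseline_window])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline mean: check ROI segmentation", call. = FALSE)
  out <- fluorescence_trace((v - f0) / f0, fs,
                            roi_id = if (inherits(raw, "fluorescence_trace"))
                              raw$roi_id else NA_character_,
                            stim_onset_s = if (inherits(raw, "fluorescence_trace"))
                              raw$stim_onset_s else NA_real_,
                            unit = "dff")
  attr(out, "F0") <- f0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial 3x3 mean smoothing of an image stack
#'
#' Per-frame 3 x 3 box (mean) filter. Edges are handled by reflect padding
#' (the border row/column is mirrored), so a constant frame is unchanged
#' everywhere including the border.
#'
#' @param stack a matrix (one frame) or 3-d array (rows x cols x frames).
#' @return same shape, smoothed.
#' @export
smooth_3x3 <- function(stack) {
  sm1 <- function(fr) {
    if (nrow(fr) < 3L || ncol(fr) < 3L)
      stop("frames must be at least 3 x 3", call. = FALSE)
    pad <- rbind(fr[1L, , drop = FALSE], fr, fr[nrow(fr), , drop = FALSE])
    pad <- cbind(pad[, 1L, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
    n <- nrow(fr); m <- ncol(fr)
    acc <- matrix(0, n, m)
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + pad[di + seq_len(n), dj + seq_len(m)]
    acc / 9
  }
  if (is.matrix(stack)) return(sm1(stack))
  if (length(dim(stack)) == 3L) {
    out <- stack
    for (k in seq_len(dim(stack)[3L])) out[, , k] <- sm1(stack[, , k])
    return(out)
  }
  stop("'stack' must be a matrix or a 3-d array", call. = FALSE)
}

#' Extract the rising phase of a calcium event
#'
#' Scans backward from the event peak for the first data point exceeding the
#' baseline; the rising phase is the segment from that point through the
#' peak.
#'
#' @param trace `fluorescence_trace` (deltaF/F).
#' @param peak_index index of the event peak.
#' @param baseline baseline deltaF/F level.
#' @param min_length minimum accepted segment length (samples).
#' @return object of class `calcium_event`: `peak_index`, `baseline`,
#'   `onset_index`, `rising_values`, `rising_times_s`.
#' @export
extract_rising_phase <- function(trace, peak_index, baseline = 0,
                                 min_length = 3L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  v <- trace$values
  if (peak_index < 1L || peak_index > length(v))
    stop("'peak_index' out of range", call. = FALSE)
  if (v[peak_index] <= baseline)
    stop("peak is not above baseline", call. = FALSE)
  onset <- peak_index
  while (onset > 1L && v[onset - 1L] > baseline) onset <- onset - 1L
  # 'onset' is now the first supra-baseline sample of the event
  if (peak_index - onset + 1L < min_length)
    stop(sprintf("rising segment shorter than %d samples", min_length),
         call. = FALSE)
  idx <- onset:peak_index
  structure(list(peak_index = peak_index, baseline = baseline,
                 onset_index = onset, rising_values = v[idx],
                 rising_times_s = (idx - 1L) / trace$sampling_rate,
                 sampling_rate = trace$sampling_rate),
            class = "calcium_event")
}

#' Fit the saturating-exponential rise and estimate the spike time
#'
#' Fits `Y = 1 - exp(-k * (x - t0))` to the rising phase by nonlinear least
#' squares. The spike-time estimate is the x-intercept `t0` (where the
#' fitted curve crosses zero). By default the segment is rescaled by its
#' peak value so the model plateau of 1 applies; alternatively a free
#' amplitude `Y = A * (1 - exp(-k * (x - t0)))` can be fitted.
#'
#' @param event a `calcium_event` from [extract_rising_phase()].
#' @param normalize `"peak"` (default; divide by the peak value) or
#'   `"free_amplitude"`.
#' @return object of class `spike_time_estimate`: `t0` (s), `k` (1/s),
#'   `amplitude`, `residual` (RMS), `converged`.
#' @export
fit_exponential_rise <- function(event, normalize = c("peak", "free_amplitude")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(event, "calcium_event"))
  x <- event$rising_times_s
  y <- event$rising_values
  if (length(x) < 3L) stop("need at least 3 rising-phase samples", call. = FALSE)
  if (normalize == "peak") y <- y / y[length(y)]
  dur <- max(x) - min(x)
  # t0 may drift past the onset sample under noise (clamping it there would
  # truncate the estimator distribution and bias it); the peak time is a hard
  # ceiling
  lower <- c(k = 1e-8, t0 = x[1L] - 10 * dur)
  upper <- c(k = 10 * event$sampling_rate, t0 = x[length(x)])
  # linearised start: log(1 - Y/A) = -k * x + k * t0
  a0 <- if (normalize == "peak") 1 else max(y) * 1.05
  sel <- which(y / a0 > 0 & y / a0 < 0.99)
  start <- list(k = 1 / max(dur, 1e-6), t0 = x[1L])
  if (length(sel) >= 2L) {
    cf0 <- stats::coef(stats::lm(log(1 - y[sel] / a0) ~ x[sel]))
    if (is.finite(cf0[2L]) && cf0[2L] < 0) {
      k0 <- min(max(-cf0[2L], lower["k"] * 2), upper["k"] / 2)
      t00 <- min(max(unname(cf0[1L]) / k0, lower["t0"]), upper["t0"])
      start <- list(k = k0, t0 = t00)
    }
  }
  fit <- tryCatch({
    if (normalize == "peak")
      minpack.lm::nlsLM(y ~ 1 - exp(-k * (x - t0)), start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ A * (1 - exp(-k * (x - t0))),
                        start = c(start, A = y[length(y)]),
                        lower = c(lower, A = 1e-8),
                        upper = c(upper, A = 100 * max(abs(y))),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(t0 = NA_real_, k = NA_real_, amplitude = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "spike_time_estimate"))
  }
  cf <- coef(fit)
  conv <- isTRUE(tryCatch(fit$convInfo$isConv, error = function(e) TRUE)) &&
    unname(cf["k"]) > 0
  structure(list(t0 = unname(cf["t0"]), k = unname(cf["k"]),
                 amplitude = if (normalize == "peak")
                   event$rising_values[length(event$rising_values)]
                 else unname(cf["A"]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 converged = conv),
            class = "spike_time_estimate")
}

#' Rise-time delay between two ROIs
#'
#' Difference of estimated spike times, distal minus proximal; the readout
#' compared across the two sides of an individual spheroid.
#'
#' @param est_proximal,est_distal `spike_time_estimate` objects.
#' @return delay in seconds; `NA` if either fit failed.
#' @export
rise_time_delay <- function(est_proximal, est_distal) {
  stopifnot(inherits(est_proximal, "spike_time_estimate"),
            inherits(est_distal, "spike_time_estimate"))
  if (!isTRUE(est_proximal$converged) || !isTRUE(est_distal$converged))
    return(NA_real_)
  est_distal$t0 - est_proximal$t0
}

#' Pearson correlation between two ROI traces
#'
#' @param trace_a,trace_b `fluorescence_trace`s or numeric vectors of equal
#'   length (>= 3).
#' @return correlation coefficient in `[-1, 1]`; `NA` with a warning when a
#'   trace has zero variance.
#' @export
pearson_roi_correlation <- function(trace_a, trace_b) {
  a <- if (inherits(trace_a, "fluorescence_trace")) trace_a$values else trace_a
  b <- if (inherits(trace_b, "fluorescence_trace")) trace_b$values else trace_b
  if (length(a) != length(b)) stop("traces must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance trace: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Average stimulus-aligned trials
#'
#' Pointwise mean of repeated trials (three consecutive trials per axon in
#' the standard protocol).
#'
#' @param traces list of `fluorescence_trace`s with equal length and rate.
#' @return averaged `fluorescence_trace`.
#' @export
average_trials <- function(traces) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "fluorescence_trace")))
  lens <- vapply(traces, function(t) length(t$values), integer(1))
  rates <- vapply(traces, function(t) t$sampling_rate, numeric(1))
  if (length(unique(lens)) != 1L) stop("trial lengths differ", call. = FALSE)
  if (length(unique(rates)) != 1L) stop("trial sampling rates differ", call. = FALSE)
  vals <- rowMeans(do.call(cbind, lapply(traces, `[[`, "values")))
  fluorescence_trace(vals, rates[1L], roi_id = traces[[1L]]$roi_id,
                     stim_onset_s = traces[[1L]]$stim_onset_s,
                     unit = traces[[1L]]$unit)
}

#' Activity filter: at least one spontaneous transient per minute
#'
#' @param n_events number of spontaneous calcium transients per axon.
#' @param duration_s session duration in seconds.
#' @return logical: keep (`TRUE`) iff the event rate is >= 1/min (boundary
#'   inclusive).
#' @export
filter_active_axons <- function(n_events, duration_s) {
  if (any(duration_s <= 0)) stop("'duration_s' must be > 0", call. = FALSE)
  n_events / (duration_s / 60) >= 1
}

#' Detect spontaneous calcium events
#'
#' Local maxima of deltaF/F exceeding `baseline + n_mad * MAD`, separated by
#' at least `min_separation_s`.
#'
#' @param trace deltaF/F `fluorescence_trace`.
#' @param n_mad threshold in robust standard deviations (default 3).
#' @param min_separation_s minimum peak separation, seconds.
#' @return integer vector of peak indices.
#' @export
detect_calcium_events <- function(trace, n_mad = 3, min_separation_s = 1) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  v <- trace$values
  thr <- median(v) + n_mad * mad(v)
  n <- length(v)
  if (n < 3L) return(integer(0))
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE) & v > thr
  idx <- which(is_peak)
  if (!length(idx)) return(integer(0))
  min_gap <- min_separation_s * trace$sampling_rate
  keep <- idx[1L]
  for (i in idx[-1L]) if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
  keep
}
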