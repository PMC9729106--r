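#' Current-injection protocol
#'
#' @param pulses a data.frame with columns `onset` (ms), `duration` (ms) and
#'   `amplitude` (nA); pulses must be sorted by onset, non-overlapping and
#'   contained in `[0, sim_duration]`.
#' @param sim_duration total simulated time in ms.
#' @param dt integration step in ms (implicit scheme; default 0.025 ms).
#' @param injection_site `"start"` (compartment 1) or `"end"`; current is
#'   injected at one axon end.
#' @param tail_ms extra integrated time beyond `sim_duration` so that the
#'   response to a pulse at the very end of the stimulation window is still
#'   captured (default 15 ms). Pulse onsets must lie in
#'   `[0, sim_duration]`; a final pulse may spill into the tail.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(pulses, sim_duration, dt = 0.025,
                              injection_site = c("start", "end"),
                              tail_ms = 15) {
  injection_site <- match.arg(injection_site)
  if (!is.data.frame(pulses) ||
      !all(c("onset", "duration", "amplitude") %in% names(pulses)))
    stop("'pulses' needs columns onset, duration, amplitude", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (sim_duration <= 0) stop("'sim_duration' must be > 0", call. = FALSE)
  if (tail_ms < 0) stop("'tail_ms' must be >= 0", call. = FALSE)
  if (nrow(pulses) > 0) {
    if (is.unsorted(pulses$onset, strictly = FALSE))
      stop("pulses must be sorted by onset", call. = FALSE)
    if (any(pulses$onset < 0) || any(pulses$onset > sim_duration) ||
        any(pulses$onset + pulses$duration > sim_duration + tail_ms))
      stop("pulses must lie within [0, sim_duration]", call. = FALSE)
    ends <- pulses$onset + pulses$duration
    if (nrow(pulses) > 1 && any(pulses$onset[-1] < ends[-nrow(pulses)]))
      stop("pulses must not overlap", call. = FALSE)
    if (any(pulses$duration <= 0)) stop("pulse durations must be > 0", call. = FALSE)
  }
  structure(list(pulses = pulses, sim_duration = sim_duration, dt = dt,
                 injection_site = injection_site, tail_ms = tail_ms),
            class = "stimulus_protocol")
}

#' Build a regular pulse train
#'
#' A train of `n_pulses` identical pulses at `rate_hz`, i.e. one pulse every
#' `1000 / rate_hz` ms, so the silent gap between consecutive pulses is
#' `1000 / rate_hz - pulse_ms` (18 ms for 2 ms pulses at 50 Hz, 95 ms for
#' 5 ms pulses at 10 Hz).
#'
#' @param rate_hz pulse rate in Hz.
#' @param pulse_ms single pulse duration in ms.
#' @param amplitude_nA pulse amplitude in nA.
#' @param start_ms onset of the first pulse in ms.
#' @param n_pulses number of pulses; alternatively give `train_ms` and every
#'   pulse with onset in `[start_ms, start_ms + train_ms]` (both ends
#'   inclusive) is kept, i.e. `floor(train_ms / period) + 1` pulses.
#' @param train_ms optional train span in ms (used when `n_pulses` is `NULL`).
#' @return a pulse data.frame suitable for [stimulus_protocol()], with the
#'   inter-pulse gap attached as attribute `"gap_ms"`.
#' @examples
#' train <- pulse_train(50, pulse_ms = 2, n_pulses = 25, start_ms = 0)
#' attr(train, "gap_ms")  # 18
#' @export
pulse_train <- function(rate_hz, pulse_ms, amplitude_nA = 2, start_ms = 100,
                        n_pulses = NULL, train_ms = NULL) {
  if (rate_hz <= 0 || pulse_ms <= 0) stop("rate and pulse width must be > 0", call. = FALSE)
  period <- 1000 / rate_hz
  if (pulse_ms >= period)
    stop("pulse width must be shorter than the inter-pulse period", call. = FALSE)
  if (is.null(n_pulses)) {
    if (is.null(train_ms)) stop("give 'n_pulses' or 'train_ms'", call. = FALSE)
    n_pulses <- floor(train_ms / period + 1e-9) + 1L
  }
  onsets <- start_ms + period * (seq_len(n_pulses) - 1L)
  out <- data.frame(onset = onsets, duration = pulse_ms,
                    amplitude = amplitude_nA)
  attr(out, "gap_ms") <- period - pulse_ms
  out
}

#' Single strong input pulse (0.2 ms, 2 nA by default)
#'
#' @param onset_ms pulse onset in ms.
#' @param duration_ms,amplitude_nA pulse shape.
#' @return one-row pulse data.frame.
#' @export
single_pulse <- function(onset_ms = 100, duration_ms = 0.2, amplitude_nA = 2) {
  data.frame(onset = onset_ms, duration = duration_ms, amplitude = amplitude_nA)
}
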