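#' Resting membrane potential for a given channel density scaling
#'
#' Solves the steady-state current balance
#' `s*gNa*m_inf^3*h_inf*(V-ENa) + s*gK*n_inf^4*(V-EK) + gLeak*(V-ELeak) = 0`
#' for V, where `s = density_scale`. With `density_scale = 0` this is exactly
#' `ELeak`.
#'
#' @param channels a [channel_params()].
#' @return resting potential in mV.
#' @export
resting_potential <- function(channels = channel_params()) {
  s <- channels$density_scale
  if (s == 0) return(channels$ELeak)
  f <- function(v) {
    g <- .hh_gate_steady(v)
    s * channels$gNa_max * g[["m"]]^3 * g[["h"]] * (v - channels$ENa) +
      s * channels$gK_max * g[["n"]]^4 * (v - channels$EK) +
      channels$gLeak * (v - channels$ELeak)
  }
  stats::uniroot(f, lower = -90, upper = -40, tol = 1e-10)$root
}

# per-compartment absolute quantities in solver units (uS, nF)
.compartment_electrics <- function(comps, channels) {
  area_cm2 <- comps$area_um2 * 1e-8
  s <- channels$density_scale
  # densities S/cm^2 * area cm^2 = S -> 1e6 uS; spheroid compartments carry
  # the same scaled densities as the axon (contract)
  list(
    gna = channels$gNa_max * s * area_cm2 * 1e6,
    gk  = channels$gK_max * s * area_cm2 * 1e6,
    gl  = channels$gLeak * area_cm2 * 1e6,
    cap = channels$Cm * area_cm2 * 1e3   # uF/cm^2 * cm^2 -> uF -> 1e3 nF
  )
}

# axial coupling conductance (uS) between each compartment and its parent;
# half-cylinder resistances in series; the iso-potential bulb contributes none
.axial_conductances <- function(comps, channels) {
  n <- length(comps$parent)
  half_res <- function(i) {             # Ohm
    if (comps$kind[i] == "bulb") return(0)
    L <- comps$length_um[i] * 1e-4 / 2  # cm
    a <- pi * (comps$diameter_um[i] * 1e-4)^2 / 4
    channels$Ra * L / a
  }
  g <- numeric(n)
  for (i in 2:n) {
    r <- half_res(i) + half_res(comps$parent[i])
    g[i] <- 1e6 / r                     # 1/Ohm -> S -> uS
  }
  g
}

#' Simulate a spheroid-bearing axon
#'
#' Integrates the Hodgkin-Huxley cable equation over the compartment tree
#' with an implicit (linearised backward Euler) scheme and Rush-Larsen gate
#' updates. The state is initialised at the resting potential consistent
#' with `density_scale`, so a zero-stimulus run stays at rest. Deterministic
#' for fixed inputs.
#'
#' @param morph a [cable_morphology()] or prebuilt [build_morphology()] result.
#' @param channels a [channel_params()].
#' @param stim a [stimulus_protocol()].
#' @param record `"probes"` (default; proximal and distal probe traces at
#'   every step) or `"all"` (all compartments, subsampled in time by
#'   `record_stride` steps).
#' @param record_stride time subsampling for `record = "all"`.
#' @param probe_frac axial positions (fractions of axon length) of the
#'   proximal and distal probes; the proximal probe sits just distal to the
#'   injection end, the distal probe at the far axon end.
#' @return an object of class `voltage_solution`: `time_ms` and `probes`
#'   (matrix, one column per probe) sampled every `dt`; `rest_mV`;
#'   `v_record`/`t_record` when `record = "all"`; `compartments`; and solver
#'   metadata. Simulation failure (non-finite voltages) raises an error with
#'   diagnostics.
#' @export
simulate_cable <- function(morph, channels = channel_params(), stim,
                           record = c("probes", "all"), record_stride = 4L,
                           probe_frac = c(0.05, 1)) {
  record <- match.arg(record)
  stopifnot(inherits(stim, "stimulus_protocol"))
  comps <- if (inherits(morph, "cable_compartments")) morph
           else build_morphology(morph, channels)
  el <- .compartment_electrics(comps, channels)
  g_ax <- .axial_conductances(comps, channels)
  rest <- resting_potential(channels)
  n_axon <- comps$n_axon

  inj <- if (stim$injection_site == "start") 1L else n_axon
  # proximal probe just distal to the injection site, distal at the far end
  p_idx <- pmin(pmax(round(probe_frac * n_axon), 1L), n_axon)
  if (stim$injection_site == "end") p_idx <- n_axon + 1L - p_idx
  n_steps <- ceiling((stim$sim_duration + stim$tail_ms) / stim$dt)

  res <- .cable_hh_run(
    parent = as.integer(ifelse(is.na(comps$parent), -1L, comps$parent - 1L)),
    g_axial = g_ax, gna = el$gna, gk = el$gk, gl = el$gl,
    ena = channels$ENa, ek = channels$EK, el = channels$ELeak,
    cap = el$cap, v_init = rest, dt = stim$dt, n_steps = n_steps,
    pulse_onset = as.numeric(stim$pulses$onset),
    pulse_dur = as.numeric(stim$pulses$duration),
    pulse_amp = as.numeric(stim$pulses$amplitude),
    inj_index = inj - 1L, probe_idx = as.integer(p_idx - 1L),
    record_all = identical(record, "all"),
    record_stride = as.integer(record_stride))
  if (isTRUE(res$diverged))
    stop(sprintf(paste0("cable solver diverged (non-finite voltage); dt = %g ms, ",
                        "%d compartments, density_scale = %g"),
                 stim$dt, length(comps$parent), channels$density_scale),
         call. = FALSE)
  out <- list(time_ms = seq(0, by = stim$dt, length.out = n_steps + 1L),
              probes = res$probes, probe_idx = p_idx,
              probe_names = c("proximal", "distal"), rest_mV = rest,
              v_record = if (record == "all") res$v_record,
              t_record = if (record == "all") res$t_record,
              v_final = res$v_final, compartments = comps,
              channels = channels, stim = stim,
              solver = list(dt = stim$dt, method = "backward_euler_rush_larsen",
                            n_steps = n_steps, diverged = FALSE))
  class(out) <- "voltage_solution"
  out
}

#' @export
print.voltage_solution <- function(x, ...) {
  cat(sprintf("<voltage_solution> %d compartments, %.4g ms at dt = %g ms, rest %.2f mV\n",
              length(x$compartments$parent), max(x$time_ms), x$solver$dt,
              x$rest_mV))
  invisible(x)
}

#' Detect action potentials by threshold crossing
#'
#' Times of upward crossings of `threshold` (voltages exceeding 10 mV by
#' default) separated by at least `refractory_ms`.
#'
#' @param v membrane-potential trace in mV.
#' @param time_ms matching time vector (or scalar dt; the grid is then
#'   `0, dt, ...`).
#' @param threshold detection threshold in mV.
#' @param refractory_ms minimum separation between detected APs (default
#'   2 ms: wider than a spike, well under a 50 ms inter-pulse interval).
#' @return numeric vector of AP times in ms (empty for sub-threshold traces).
#' @export
detect_aps <- function(v, time_ms, threshold = 10, refractory_ms = 2) {
  if (any(!is.finite(v))) stop("'v' must be finite", call. = FALSE)
  if (length(time_ms) == 1L) time_ms <- (seq_along(v) - 1L) * time_ms
  stopifnot(length(time_ms) == length(v))
  up <- which(v[-1L] > threshold & v[-length(v)] <= threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- time_ms[up]
  keep <- times[1L]
  for (tt in times[-1L]) if (tt - keep[length(keep)] >= refractory_ms)
    keep <- c(keep, tt)
  keep
}

#' Minimal channel density supporting regenerative propagation
#'
#' Bisects on `density_scale` for the smallest scaling at which a single
#' strong input pulse produces an output AP at the distal probe of a
#' spheroid-free axon. The conventional sweep upper bound is `1.1 * g_star`.
#'
#' @param morph spheroid-free [cable_morphology()] (bulb area must be 0).
#' @param channels base [channel_params()]; its `density_scale` is ignored.
#' @param stim single-AP [stimulus_protocol()]; default 0.2 ms / 2 nA pulse
#'   at 10 ms in a 60 ms window.
#' @param lower,upper initial bracket for the search; if the upper bound
#'   does not propagate it is doubled up to `max_scale`.
#' @param max_scale give up ("non-regenerative") beyond this scaling.
#' @param tol bisection tolerance on the density scale.
#' @return list with `g_star`, `converged`, `n_iter`; `g_star = NA` with
#'   `converged = FALSE` if no propagation occurs even at `max_scale`.
#' @export
find_regenerative_density <- function(morph, channels = channel_params(),
                                      stim = NULL, lower = 0, upper = 1,
                                      max_scale = 8, tol = 1e-3) {
  stopifnot(inherits(morph, "cable_morphology"))
  if (morph$bulb_surface_area != 0)
    stop("the regenerative threshold is defined on the spheroid-free axon",
         call. = FALSE)
  if (is.null(stim))
    stim <- stimulus_protocol(single_pulse(onset_ms = 10), sim_duration = 60)
  fires <- function(s) {
    ch <- utils::modifyList(channels, list(density_scale = s,
                                           spheroid_density_scale = s))
    class(ch) <- "channel_params"
    sol <- simulate_cable(morph, ch, stim)
    length(detect_aps(sol$probes[, 2L], sol$time_ms)) >= 1L
  }
  while (!fires(upper)) {
    if (upper >= max_scale)
      return(list(g_star = NA_real_, converged = FALSE, n_iter = 0L))
    lower <- upper
    upper <- min(2 * upper, max_scale)
  }
  n_iter <- 0L
  while (upper - lower > tol) {
    mid <- (upper + lower) / 2
    if (fires(mid)) upper <- mid else lower <- mid
    n_iter <- n_iter + 1L
  }
  list(g_star = upper, converged = TRUE, n_iter = n_iter)
}
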