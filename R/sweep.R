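#' Default neck diameter for a given bulb area
#'
#' The neck ("stick") diameter co-varies with the bulb: it is interpolated
#' linearly in the bulb's equivalent spherical diameter between
#' `neck_d_range[1]` at area 0 and `neck_d_range[2]` at `area_max`
#' (defaults 0.3--8.3 um over 0--7,100 um^2, the swept ranges).
#'
#' @param area_um2 bulb surface area(s), um^2.
#' @param area_max area mapped to the largest neck diameter.
#' @param neck_d_range neck diameter range in um.
#' @return neck diameter(s) in um.
#' @export
neck_diameter_for_area <- function(area_um2, area_max = 7100,
                                   neck_d_range = c(0.3, 8.3)) {
  esd <- equivalent_spherical_diameter(area_um2)
  esd_max <- equivalent_spherical_diameter(area_max)
  pmax(neck_d_range[1],
       neck_d_range[1] + diff(neck_d_range) * esd / esd_max)
}

# pair each output AP to the nearest preceding input AP within one
# inter-pulse interval; unmatched inputs are blocked
.match_aps <- function(input_times, output_times, max_delay) {
  delays <- rep(NA_real_, length(input_times))
  used <- rep(FALSE, length(output_times))
  for (i in seq_along(input_times)) {
    cand <- which(!used & output_times >= input_times[i] &
                    output_times < input_times[i] + max_delay)
    if (length(cand)) {
      j <- cand[1L]
      delays[i] <- output_times[j] - input_times[i]
      used[j] <- TRUE
    }
  }
  delays
}

#' Conduction outcome of a single simulated experiment
#'
#' Counts input APs at the proximal probe and output APs at the distal probe
#' ("the other side of the spheroid"), pairs them to per-AP conduction
#' delays, and echoes the configuration.
#'
#' @param sol a `voltage_solution` from [simulate_cable()].
#' @param threshold,refractory_ms passed to [detect_aps()].
#' @param max_delay_ms matching window for input/output pairing; default one
#'   inter-pulse interval (or the remaining simulated time for a single pulse).
#' @return a list of class `conduction_outcome`: `n_input_aps`,
#'   `n_output_aps`, `per_ap_delay` (ms, `NA` for blocked APs),
#'   `median_delay`, `input_times`, `output_times`.
#' @export
conduction_outcome <- function(sol, threshold = 10, refractory_ms = 2,
                               max_delay_ms = NULL) {
  stopifnot(inherits(sol, "voltage_solution"))
  inp <- detect_aps(sol$probes[, 1L], sol$time_ms, threshold, refractory_ms)
  out <- detect_aps(sol$probes[, 2L], sol$time_ms, threshold, refractory_ms)
  if (is.null(max_delay_ms)) {
    max_delay_ms <- if (length(inp) >= 2L) min(diff(inp))
                    else max(sol$time_ms) - if (length(inp)) inp[1L] else 0
  }
  delays <- .match_aps(inp, out, max_delay_ms)
  structure(list(n_input_aps = length(inp), n_output_aps = length(out),
                 per_ap_delay = delays,
                 median_delay = if (any(!is.na(delays)))
                   stats::median(delays, na.rm = TRUE) else NA_real_,
                 input_times = inp, output_times = out,
                 stim = sol$stim, morphology = sol$compartments$morphology,
                 channels = sol$channels),
            class = "conduction_outcome")
}

#' Classify a conduction outcome against its no-spheroid reference
#'
#' `normal`: all input APs conducted and the median delay is within
#' `delay_tolerance` of the reference delay; `delayed`: all conducted but
#' slower; `blocked`: no output APs; `partial_block`: some but not all.
#'
#' @param outcome,reference `conduction_outcome` objects; the reference must
#'   come from the matching spheroid-free run (same protocol) and conduct
#'   every input AP.
#' @param delay_tolerance ms; default 0.25 ms, about three times the
#'   time-step convergence error of reference delays.
#' @return one of `"normal"`, `"delayed"`, `"blocked"`, `"partial_block"`.
#' @export
classify_conduction <- function(outcome, reference, delay_tolerance = 0.25) {
  stopifnot(inherits(outcome, "conduction_outcome"),
            inherits(reference, "conduction_outcome"))
  if (reference$n_output_aps != reference$n_input_aps)
    stop("reference outcome must conduct every input AP", call. = FALSE)
  same_protocol <- isTRUE(all.equal(outcome$stim$pulses, reference$stim$pulses)) &&
    outcome$stim$sim_duration == reference$stim$sim_duration
  if (!same_protocol)
    stop("outcome and reference were run under different protocols", call. = FALSE)
  if (outcome$n_output_aps == 0L) return("blocked")
  if (outcome$n_output_aps < outcome$n_input_aps) return("partial_block")
  if (abs(outcome$median_delay - reference$median_delay) <= delay_tolerance)
    "normal" else "delayed"
}

#' Sweep conduction outcomes over morphology and channel-density grids
#'
#' One simulation per (axon diameter, bulb area, density scale) grid point.
#' Rows with `bulb_surface_area = 0` are the per-diameter/density reference
#' used for regime classification. Individual solver failures are recorded
#' in the `error` column and the sweep continues. Deterministic.
#'
#' @param diameter_grid axon diameters, um.
#' @param area_grid bulb surface areas, um^2 (include 0 for references).
#' @param density_grid `density_scale` values. Either absolute scalings, or
#'   fractions of the per-diameter regenerative threshold when
#'   `density_relative = TRUE` (the conventional sweep runs 0 to 1.1 x
#'   g_star).
#' @param protocol `"single"` (one 0.2 ms / 2 nA pulse at 100 ms) or
#'   `"train_20Hz"` (20 Hz train of such pulses from 100 ms to the end of
#'   the window).
#' @param sim_duration_ms simulation window (default 10,000 ms).
#' @param channels base [channel_params()].
#' @param density_relative interpret `density_grid` as multiples of the
#'   per-diameter regenerative threshold `g_star`.
#' @param neck_diameter `NULL` to couple the neck to the bulb size via
#'   [neck_diameter_for_area()], or a fixed value in um.
#' @param delay_tolerance passed to [classify_conduction()].
#' @param dt integration step, ms.
#' @param ... further arguments to [cable_morphology()].
#' @return data.frame with one row per grid point: morphology and density
#'   echo, `n_input_aps`, `n_output_aps`, `median_delay_ms`, `regime`,
#'   `error`.
#' @export
run_conduction_sweep <- function(diameter_grid, area_grid, density_grid,
                                 protocol = c("single", "train_20Hz"),
                                 sim_duration_ms = 10000,
                                 channels = channel_params(),
                                 density_relative = TRUE,
                                 neck_diameter = NULL,
                                 delay_tolerance = 0.25, dt = 0.025, ...) {
  protocol <- match.arg(protocol)
  if (!length(diameter_grid) || !length(area_grid) || !length(density_grid))
    stop("grids must be non-empty", call. = FALSE)
  if (!any(area_grid == 0))
    area_grid <- c(0, area_grid)  # references are required for classification
  area_grid <- sort(unique(area_grid))
  pulses <- switch(protocol,
    single = single_pulse(onset_ms = 100),
    train_20Hz = pulse_train(20, pulse_ms = 0.2, amplitude_nA = 2,
                             start_ms = 100, train_ms = sim_duration_ms - 100))
  stim <- stimulus_protocol(pulses, sim_duration_ms, dt = dt)

  grid <- expand.grid(axon_diameter = diameter_grid,
                      bulb_surface_area = area_grid,
                      density = density_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$axon_diameter, grid$density, grid$bulb_surface_area), ]
  rownames(grid) <- NULL

  gstar <- NULL
  if (density_relative) {
    gstar <- vapply(diameter_grid, function(d) {
      find_regenerative_density(cable_morphology(axon_diameter = d, ...),
                                channels)$g_star
    }, numeric(1))
    names(gstar) <- as.character(diameter_grid)
  }

  n <- nrow(grid)
  res <- data.frame(grid,
                    neck_diameter = NA_real_, density_scale = NA_real_,
                    n_input_aps = NA_integer_, n_output_aps = NA_integer_,
                    median_delay_ms = NA_real_, regime = NA_character_,
                    error = NA_character_, stringsAsFactors = FALSE)
  ref_cache <- list()
  for (i in seq_len(n)) {
    d <- grid$axon_diameter[i]; A <- grid$bulb_surface_area[i]
    dens <- grid$density[i]
    scale <- if (density_relative) dens * gstar[[as.character(d)]] else dens
    nk <- if (!is.null(neck_diameter)) neck_diameter
          else if (A > 0) neck_diameter_for_area(A) else 1
    res$neck_diameter[i] <- if (A > 0) nk else NA_real_
    res$density_scale[i] <- scale
    key <- paste(d, dens)
    outc <- tryCatch({
      ch <- modifyList(channels, list(density_scale = scale,
                                      spheroid_density_scale = scale))
      class(ch) <- "channel_params"
      m <- cable_morphology(axon_diameter = d, bulb_surface_area = A,
                            neck_diameter = nk, ...)
      conduction_outcome(simulate_cable(m, ch, stim))
    }, error = function(e) e)
    if (inherits(outc, "error")) {
      res$error[i] <- conditionMessage(outc)
      next
    }
    res$n_input_aps[i] <- outc$n_input_aps
    res$n_output_aps[i] <- outc$n_output_aps
    res$median_delay_ms[i] <- outc$median_delay
    if (A == 0) {
      ref_cache[[key]] <- outc
      res$regime[i] <- if (outc$n_output_aps == outc$n_input_aps &&
                           outc$n_input_aps > 0L) "normal" else "blocked"
    } else if (!is.null(ref_cache[[key]]) &&
               ref_cache[[key]]$n_output_aps == ref_cache[[key]]$n_input_aps &&
               ref_cache[[key]]$n_input_aps > 0L) {
      res$regime[i] <- classify_conduction(outc, ref_cache[[key]],
                                           delay_tolerance)
    }
  }
  res
}

#' Read a sweep configuration from YAML
#'
#' Expected top-level keys: `diameter_grid`, `area_grid`, `density_grid`,
#' `protocol`, `sim_duration_ms`, optional `channels` (fields of
#' [channel_params()]) and `morphology` (extra [cable_morphology()] fields).
#'
#' @param path YAML file path.
#' @return list of arguments for [run_conduction_sweep()].
#' @export
read_sweep_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("diameter_grid", "area_grid", "density_grid"))
    if (is.null(cfg[[k]])) stop(sprintf("config misses '%s'", k), call. = FALSE)
  args <- list(diameter_grid = as.numeric(cfg$diameter_grid),
               area_grid = as.numeric(cfg$area_grid),
               density_grid = as.numeric(cfg$density_grid))
  if (!is.null(cfg$protocol)) args$protocol <- cfg$protocol
  if (!is.null(cfg$sim_duration_ms)) args$sim_duration_ms <- cfg$sim_duration_ms
  if (!is.null(cfg$channels)) args$channels <- do.call(channel_params, cfg$channels)
  args
}
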