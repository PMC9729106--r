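#' Axon-plus-spheroid ("cylinder and stick") morphology
#'
#' Describes a straight unmyelinated axon with, optionally, a spheroid
#' attached through a short neck ("stick") ending in a bulb head whose
#' membrane surface area is the controlled variable. The bulb is modelled
#' as a single iso-potential compartment parameterised directly by area,
#' because its electrical role -- a capacitive/conductive current sink --
#' depends on membrane area, not on shape.
#'
#' @param axon_length axon length in micrometres.
#' @param axon_diameter axon diameter in micrometres.
#' @param neck_length neck ("stick") length in micrometres.
#' @param neck_diameter neck diameter in micrometres.
#' @param bulb_surface_area bulb membrane surface area in square
#'   micrometres; `0` means no spheroid (pure axon).
#' @param attach_fraction position of the neck along the axon as a fraction
#'   of its length, strictly between 0 and 1.
#' @param n_segments_axon,n_segments_neck number of compartments; defaults
#'   (`NULL`) target ~3 um axon segments and 3 neck segments.
#' @param max_seg_lambda_frac maximum allowed segment length as a fraction
#'   of the passive length constant (checked in [build_morphology()]).
#' @return an object of class `cable_morphology`.
#' @seealso [build_morphology()], [equivalent_spherical_diameter()]
#' @export
cable_morphology <- function(axon_length = 566, axon_diameter = 0.3,
                             neck_length = 5, neck_diameter = 1,
                             bulb_surface_area = 0, attach_fraction = 0.5,
                             n_segments_axon = NULL, n_segments_neck = NULL,
                             max_seg_lambda_frac = 0.1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  for (nm in c("axon_length", "axon_diameter", "neck_length", "neck_diameter",
               "bulb_surface_area")) {
    v <- num1(get(nm), nm)
    if (v < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (axon_length <= 0 || axon_diameter <= 0)
    stop("axon length and diameter must be > 0", call. = FALSE)
  attach_fraction <- num1(attach_fraction, "attach_fraction")
  if (attach_fraction <= 0 || attach_fraction >= 1)
    stop("'attach_fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (bulb_surface_area > 0 && (neck_length <= 0 || neck_diameter <= 0))
    stop("a spheroid needs a neck with positive length and diameter",
         call. = FALSE)
  if (is.null(n_segments_axon)) n_segments_axon <- max(9L, ceiling(axon_length / 3))
  if (is.null(n_segments_neck)) n_segments_neck <- 3L
  n_segments_axon <- as.integer(num1(n_segments_axon, "n_segments_axon"))
  n_segments_neck <- as.integer(num1(n_segments_neck, "n_segments_neck"))
  if (n_segments_axon < 3L) stop("'n_segments_axon' must be >= 3", call. = FALSE)
  if (n_segments_neck < 1L) stop("'n_segments_neck' must be >= 1", call. = FALSE)
  structure(list(axon_length = axon_length, axon_diameter = axon_diameter,
                 neck_length = neck_length, neck_diameter = neck_diameter,
                 bulb_surface_area = bulb_surface_area,
                 attach_fraction = attach_fraction,
                 n_segments_axon = n_segments_axon,
                 n_segments_neck = n_segments_neck,
                 max_seg_lambda_frac = max_seg_lambda_frac),
            class = "cable_morphology")
}

#' @export
print.cable_morphology <- function(x, ...) {
  cat(sprintf("<cable_morphology> axon %g um x %g um (%d seg)\n",
              x$axon_length, x$axon_diameter, x$n_segments_axon))
  if (x$bulb_surface_area > 0) {
    cat(sprintf("  spheroid: bulb %g um^2 (eq. sphere d = %.2f um), neck %g x %g um at %g\n",
                x$bulb_surface_area,
                equivalent_spherical_diameter(x$bulb_surface_area),
                x$neck_length, x$neck_diameter, x$attach_fraction))
  } else cat("  no spheroid\n")
  invisible(x)
}

#' Hodgkin-Huxley channel parameters
#'
#' Conductance densities and reversal potentials for the active cable.
#' `density_scale` multiplies the sodium and potassium densities together;
#' spheroid compartments always carry the same (scaled) densities as the
#' axon, so `spheroid_density_scale` must equal `density_scale`.
#'
#' @param gNa_max,gK_max,gLeak maximum conductance densities in S/cm^2.
#' @param ENa,EK,ELeak reversal potentials in mV. The default leak reversal
#'   (-64.4 mV) keeps the resting potential near -65 mV and stable across
#'   the swept `density_scale` range.
#' @param Cm specific membrane capacitance in uF/cm^2.
#' @param Ra axial resistivity in Ohm cm.
#' @param density_scale unitless multiplier on `(gNa_max, gK_max)`.
#' @param spheroid_density_scale must equal `density_scale` (contract).
#' @return an object of class `channel_params`.
#' @export
channel_params <- function(gNa_max = 0.12, gK_max = 0.036, gLeak = 0.0003,
                           ENa = 50, EK = -77, ELeak = -64.4,
                           Cm = 1, Ra = 100, density_scale = 1,
                           spheroid_density_scale = density_scale) {
  if (any(c(gNa_max, gK_max, gLeak) < 0)) stop("conductances must be >= 0", call. = FALSE)
  if (density_scale < 0) stop("'density_scale' must be >= 0", call. = FALSE)
  if (!isTRUE(all.equal(spheroid_density_scale, density_scale)))
    stop("spheroid compartments must carry the same channel densities as the axon",
         call. = FALSE)
  if (Cm <= 0 || Ra <= 0) stop("'Cm' and 'Ra' must be > 0", call. = FALSE)
  structure(list(gNa_max = gNa_max, gK_max = gK_max, gLeak = gLeak,
                 ENa = ENa, EK = EK, ELeak = ELeak, Cm = Cm, Ra = Ra,
                 density_scale = density_scale,
                 spheroid_density_scale = density_scale),
            class = "channel_params")
}

#' Passive length constant of the axon
#'
#' lambda = sqrt(d * R_m / (4 * R_a)) with R_m = 1/gLeak.
#'
#' @param diameter_um axon diameter in micrometres.
#' @param channels a [channel_params()] object.
#' @return length constant in micrometres.
#' @export
passive_length_constant <- function(diameter_um, channels = channel_params()) {
  d_cm <- diameter_um * 1e-4
  rm <- 1 / channels$gLeak              # Ohm cm^2
  1e4 * sqrt(d_cm * rm / (4 * channels$Ra))
}

#' Discretise a morphology into a compartment tree
#'
#' Builds the compartment chain: a linear axon with, when
#' `bulb_surface_area > 0`, a side branch (the neck) at `attach_fraction`
#' terminating in a single iso-potential bulb compartment whose membrane
#' area equals `bulb_surface_area`. Compartments are connected through
#' half-cylinder axial resistances; the bulb contributes no axial
#' resistance of its own (iso-potential).
#'
#' @param morph a [cable_morphology()].
#' @param channels a [channel_params()]; needed for the segment-length
#'   check against the passive length constant and for axial resistances.
#' @return a list of class `cable_compartments` with parallel vectors
#'   `parent` (1-based, `NA` at the root), `length_um`, `diameter_um`
#'   (`NA` for the bulb), `area_um2`, `x_um` (axial position of axon
#'   compartment centres; `NA` off-axon), `kind`
#'   (`"axon"`/`"neck"`/`"bulb"`), plus probe bookkeeping.
#' @export
build_morphology <- function(morph, channels = channel_params()) {
  stopifnot(inherits(morph, "cable_morphology"))
  na <- morph$n_segments_axon
  seg_len <- morph$axon_length / na
  lambda <- passive_length_constant(morph$axon_diameter, channels)
  if (seg_len > morph$max_seg_lambda_frac * lambda)
    stop(sprintf(paste0("axon segment length %.2f um exceeds %g x the passive ",
                        "length constant (%.1f um); increase n_segments_axon"),
                 seg_len, morph$max_seg_lambda_frac, lambda), call. = FALSE)

  kind <- rep("axon", na)
  parent <- c(NA_integer_, seq_len(na - 1L))
  length_um <- rep(seg_len, na)
  diameter_um <- rep(morph$axon_diameter, na)
  x_um <- (seq_len(na) - 0.5) * seg_len
  attach_idx <- NA_integer_

  if (morph$bulb_surface_area > 0) {
    # compartment whose centre is nearest the attachment point
    attach_idx <- which.min(abs(x_um - morph$attach_fraction * morph$axon_length))
    nn <- morph$n_segments_neck
    neck_seg <- morph$neck_length / nn
    kind <- c(kind, rep("neck", nn), "bulb")
    parent <- c(parent, attach_idx, if (nn > 1L) na + seq_len(nn - 1L), na + nn)
    length_um <- c(length_um, rep(neck_seg, nn), NA_real_)
    diameter_um <- c(diameter_um, rep(morph$neck_diameter, nn), NA_real_)
    x_um <- c(x_um, rep(NA_real_, nn + 1L))
  }

  area_um2 <- ifelse(kind == "bulb", morph$bulb_surface_area,
                     pi * diameter_um * length_um)
  structure(list(parent = parent, kind = kind, length_um = length_um,
                 diameter_um = diameter_um, area_um2 = area_um2, x_um = x_um,
                 n_axon = na, attach_idx = attach_idx, morphology = morph),
            class = "cable_compartments")
}

#' Equivalent spherical diameter of a membrane area
#'
#' The diameter `d` of the sphere whose surface area `pi * d^2` equals the
#' given area: `d = sqrt(area / pi)`. This is the convention implemented
#' throughout the package for reporting bulb sizes.
#'
#' @param area_um2 membrane surface area in square micrometres (>= 0).
#' @return diameter in micrometres.
#' @export
equivalent_spherical_diameter <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 < 0))
    stop("'area_um2' must be finite and >= 0", call. = FALSE)
  sqrt(area_um2 / pi)
}
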