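# Extracellular field of an epiretinal disk electrode: analytic disk
# potential in a semi-infinite ohmic medium, transfer-resistance scaling,
# depth-dependent tissue inhomogeneity, and the biphasic pulse waveform.

#' Disk electrode specification
#'
#' @param radius electrode radius a, um
#' @param x,y,z electrode center, um; z is the axial height above the
#'   somatic plane (default 40, the epiretinal study condition)
#' @param rs transfer resistance, MOhm; defaults to the surface-area scaled
#'   value from the 10 um calibration (see [transfer_resistance()])
#' @return object of class `electrode_spec`
#' @export
electrode_spec <- function(radius, x = 0, y = 0, z = 40, rs = NULL) {
  if (radius <= 0) stop("electrode radius must be positive")
  rs <- rs %||% transfer_resistance(radius)
  if (rs <= 0) stop("transfer resistance must be positive")
  structure(list(a = radius, x = x, y = y, z = z, rs = rs),
            class = "electrode_spec")
}

#' Transfer resistance by surface-area scaling
#'
#' The calibrated transfer resistance is 0.725 (MOhm) for a 10 um radius
#' platinum disk 40 um above the cell; other electrode sizes scale by
#' surface area: Rs(a) = Rs0 * (a0/a)^2.
#'
#' @param a electrode radius, um
#' @param a0,rs0 calibration reference (10 um, 0.725)
#' @return transfer resistance (same units as `rs0`)
#' @export
transfer_resistance <- function(a, a0 = 10, rs0 = 0.725) {
  if (any(a <= 0)) stop("electrode radius must be positive")
  rs0 * (a0 / a)^2
}

#' Potential of a current-carrying disk electrode
#'
#' Analytic potential of an equipotential disk on the boundary of a
#' semi-infinite isotropic ohmic medium (the Newman/Wiley-Webster solution):
#' \deqn{V = (2/\pi) I R_s \arcsin\!\frac{2a}{\sqrt{(r-a)^2+z^2} +
#'   \sqrt{(r+a)^2+z^2}}}
#' normalized so that V = I Rs on the disk surface.  With I in uA and Rs in
#' MOhm the product is volts; the returned value is in mV.
#'
#' @param I applied current, uA (cathodic currents are negative)
#' @param electrode `electrode_spec`
#' @param points numeric xyz or an N x 3 matrix of points, um
#' @return potential(s), mV
#' @export
disk_potential <- function(I, electrode, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- sqrt((points[, 1] - electrode$x)^2 + (points[, 2] - electrode$y)^2)
  z <- abs(points[, 3] - electrode$z)
  a <- electrode$a
  arg <- 2 * a / (sqrt((r - a)^2 + z^2) + sqrt((r + a)^2 + z^2))
  1000 * (2 / pi) * I * electrode$rs * asin(pmin(arg, 1))
}

#' Depth-dependent tissue inhomogeneity profile
#'
#' The somatic layer can have up to twice the resistivity of the dendritic
#' and axonal layers.  The transfer resistance is scaled by an
#' axial-distance-dependent coefficient C(z): C(0) = 1 at the somatic layer
#' (so the peak resistivity corresponds to the calibrated Rs), and C falls
#' smoothly and symmetrically to R_distant/R_peak far from the layer.
#' Implemented as a Gaussian bump,
#' C(z) = 1/ratio + (1 - 1/ratio) exp(-(z/width)^2).
#'
#' @param ratio R_peak / R_distant >= 1 (1 = homogeneous tissue)
#' @param width somatic-layer scale, um
#' @return object of class `inhomogeneity_profile`
#' @export
inhomogeneity_profile <- function(ratio = 1, width = 20) {
  if (ratio < 1) stop("resistivity ratio must be >= 1")
  if (width <= 0) stop("width must be positive")
  structure(list(ratio = ratio, width = width),
            class = "inhomogeneity_profile")
}

#' @rdname inhomogeneity_profile
#' @param z retinal depth coordinate(s), um (0 = center of the somatic layer)
#' @param profile `inhomogeneity_profile`
#' @return dimensionless scaling coefficient(s)
#' @export
inhomogeneity_coeff <- function(z, profile = inhomogeneity_profile()) {
  stopifnot(inherits(profile, "inhomogeneity_profile"))
  1 / profile$ratio +
    (1 - 1 / profile$ratio) * exp(-(z / profile$width)^2)
}

#' Charge-balanced biphasic pulse
#'
#' Cathodic-first, charge-balanced rectangular pulse: -I for one phase
#' duration, then +I for one phase duration, no inter-phase gap.  The study
#' condition is 0.1 ms per phase.
#'
#' @param amplitude pulse current magnitude I, uA
#' @param phase_ms phase duration, ms
#' @param onset_ms pulse onset, ms
#' @return object of class `pulse_spec`
#' @export
pulse_spec <- function(amplitude, phase_ms = 0.1, onset_ms = 1) {
  if (phase_ms <= 0) stop("phase duration must be positive")
  structure(list(amplitude = amplitude, phase_ms = phase_ms,
                 onset_ms = onset_ms), class = "pulse_spec")
}

#' Instantaneous pulse current
#' @param pulse `pulse_spec`
#' @param t time(s), ms
#' @return signed current, uA
#' @export
pulse_current <- function(pulse, t) {
  I <- pulse$amplitude
  on <- pulse$onset_ms
  ph <- pulse$phase_ms
  ifelse(t >= on & t < on + ph, -I,
         ifelse(t >= on + ph & t < on + 2 * ph, I, 0))
}

# unit-current spatial factor (mV per uA of electrode current), including
# the depth-dependent inhomogeneity coefficient evaluated at each point's
# own retinal depth
ve_unit_factor <- function(points, electrode, profile = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  v <- disk_potential(1, electrode, points)
  if (!is.null(profile)) v <- v * inhomogeneity_coeff(points[, 3], profile)
  v
}

#' Extracellular potential at the compartments of a placed cell
#'
#' Composes the disk potential, the pulse waveform and the inhomogeneity
#' coefficient: Ve_i(t) = V_disk(I(t), midpoint_i) * C(z_i).
#'
#' @param seg segmented cell (or an N x 3 matrix of points)
#' @param electrode `electrode_spec`
#' @param pulse `pulse_spec`
#' @param t time(s), ms (scalar or vector)
#' @param profile optional `inhomogeneity_profile`
#' @param offset planar (x, y) offset of the cell, um
#' @return matrix of potentials, mV (length(t) rows x N compartments)
#' @export
field_at_compartments <- function(seg, electrode, pulse, t, profile = NULL,
                                  offset = c(0, 0)) {
  pts <- if (inherits(seg, "rgc_segmented"))
    compartment_midpoints(seg, offset) else seg
  unit <- ve_unit_factor(pts, electrode, profile)
  outer(pulse_current(pulse, t), unit)
}
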