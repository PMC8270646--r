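# Physics conversions: Bragg spacing from the scattering angle, the
# configured rotational displacement, and the rotational diffusion
# coefficient D_R = Gamma * Phi_theta^2 / 4 (picometer^2 per second),
# where Gamma is the median accepted ACF decay constant and Phi_theta the
# picometer-scale rotational displacement per resolvable angular step.

#' Bragg lattice spacing from the scattering angle
#'
#' `d = wavelength / (2 * sin(two_theta / 2))`, angles in degrees.
#'
#' @param two_theta Scattering angle 2-theta in degrees, in (0, 180].
#' @param wavelength Wavelength in Angstrom (> 0).
#' @return d-spacing in Angstrom.
#' @export
bragg_d <- function(two_theta, wavelength) {
  if (any(!is.finite(two_theta)) || any(two_theta <= 0) || any(two_theta > 180))
    stop_parameter("two_theta must be in (0, 180] degrees")
  if (!is_scalar_num(wavelength) || wavelength <= 0)
    stop_parameter("wavelength must be > 0")
  wavelength / (2 * sin(two_theta * pi / 360))
}

#' Rotational displacement from the configuration
#'
#' The rotational displacement `phi_theta` (picometres) is a required
#' configuration input: it derives from the experiment's angular resolution
#' and is not recomputed here. In diagnostic mode a rough pixel-subtense
#' estimate `d * (pixel_pitch * bin / distance)` is also reported, clearly
#' labeled non-normative — it is a sanity log line, not a substitute.
#'
#' @param config List containing `phi_theta` (pm).
#' @param diagnostic Also compute the pixel-subtense estimate?
#' @param geometry,d_space,bin_size Inputs for the diagnostic estimate
#'   ([detector_geometry()], Angstrom, bin).
#' @return `phi_theta` in pm; with `diagnostic = TRUE`, a list
#'   `(phi_theta, pixel_subtense_estimate_pm)`.
#' @export
rotational_displacement <- function(config, diagnostic = FALSE,
                                    geometry = NULL, d_space = NULL,
                                    bin_size = 1L) {
  if (is.null(config$phi_theta))
    stop_config("configuration is missing required field 'phi_theta'")
  phi <- config$phi_theta
  if (!is_scalar_num(phi) || phi <= 0)
    stop_config("'phi_theta' must be a positive number (pm)")
  if (!diagnostic) return(phi)
  est <- NA_real_
  if (!is.null(geometry) && !is.null(d_space)) {
    # d [A -> pm] times the angle subtended by one (binned) pixel
    est <- (d_space * 100) *
      (geometry$pixel_pitch / 1000 * bin_size / geometry$distance)
  }
  list(phi_theta = phi, pixel_subtense_estimate_pm = est)
}

#' Rotational diffusion coefficient from the median decay constant
#'
#' `D_R = gamma * phi_theta^2 / 4`.
#'
#' @param gamma Median ACF decay constant (s^-1, > 0).
#' @param phi_theta Rotational displacement (pm, > 0).
#' @return D_R in pm^2/s.
#' @export
rotational_diffusion_coefficient <- function(gamma, phi_theta) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop_parameter("gamma must be > 0")
  if (any(!is.finite(phi_theta)) || any(phi_theta <= 0))
    stop_parameter("phi_theta must be > 0")
  gamma * phi_theta^2 / 4
}

#' Assemble a dynamics result
#'
#' @param two_theta Ring scattering angle (degrees).
#' @param wavelength Wavelength (Angstrom).
#' @param gamma_summary Median accepted decay constant (s^-1).
#' @param phi_theta Rotational displacement (pm).
#' @param motion_class `"rotational-diffusion"`, `"d-space-fluctuation"`
#'   or `"both"`.
#' @return A `dynamics_result` list with `two_theta`, `d_space`,
#'   `phi_theta`, `gamma_summary`, `d_r`, `motion_class`.
#' @export
dynamics_result <- function(two_theta, wavelength, gamma_summary, phi_theta,
                            motion_class = c("rotational-diffusion",
                                             "d-space-fluctuation", "both")) {
  motion_class <- match.arg(motion_class)
  structure(list(
    two_theta = two_theta,
    d_space = bragg_d(two_theta, wavelength),
    phi_theta = phi_theta,
    gamma_summary = gamma_summary,
    d_r = rotational_diffusion_coefficient(gamma_summary, phi_theta),
    motion_class = motion_class
  ), class = "dynamics_result")
}
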