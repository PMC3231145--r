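#' Spectral filter specification
#'
#' A narrow-band interference filter in front of the detector, characterised
#' by its pass-band FWHM, peak transmission, and the bandwidth of the
#' fluorescence emission line (or transmitted band) it selects from.
#'
#' @param fwhm filter pass-band FWHM, nm (> 0).
#' @param transmission peak transmission efficiency in [0, 1].
#' @param emission_bandwidth bandwidth of the emission spectrum, nm (> 0).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(fwhm, transmission, emission_bandwidth) {
  .check_scalar(fwhm, "fwhm", min = 0, allow_min = FALSE)
  .check_scalar(transmission, "transmission", min = 0, max = 1)
  .check_scalar(emission_bandwidth, "emission_bandwidth", min = 0,
                allow_min = FALSE)
  structure(list(fwhm = fwhm, transmission = transmission,
                 emission_bandwidth = emission_bandwidth),
            class = "filter_spec")
}

#' Fraction of in-band photons passed by the filter
#'
#' `min(1, FWHM / emission_bandwidth) * transmission`: the band ratio is
#' capped at 1 when the filter pass band covers the whole emission line.
#'
#' @param f a [filter_spec()].
#' @return fraction in [0, 1].
#' @export
filter_transmission_factor <- function(f) {
  stopifnot(inherits(f, "filter_spec"))
  min(1, f$fwhm / f$emission_bandwidth) * f$transmission
}

#' Detector specification
#'
#' Geometry, photon-to-electron conversion and electronic limits of the
#' detector. Either a `responsivity` (A/W at unit gain) or the
#' `quantum_efficiency`/`gain` pair can drive the output-voltage
#' computation; `transimpedance` (V/A) converts the photocurrent to the
#' voltage scale on which `noise_floor` and `saturation` are expressed.
#'
#' @param name detector label.
#' @param active_area active area, cm^2 (> 0).
#' @param quantum_efficiency QE in (0, 1].
#' @param gain internal electron gain G (>= 1; 1e5-1e6 for a SiPM).
#' @param responsivity A/W at gain 1, or `NULL`.
#' @param transimpedance V/A, or `NULL` (then output stays in electrons/s).
#' @param noise_floor output noise floor, volts.
#' @param saturation maximum output, volts; must exceed `noise_floor`.
#' @return an object of class `detector_spec`.
#' @export
detector_spec <- function(name = "detector", active_area, quantum_efficiency,
                          gain = 1, responsivity = NULL,
                          transimpedance = NULL, noise_floor, saturation) {
  .check_scalar(active_area, "active_area", min = 0, allow_min = FALSE)
  .check_scalar(quantum_efficiency, "quantum_efficiency", min = 0, max = 1,
                allow_min = FALSE)
  .check_scalar(gain, "gain", min = 1)
  if (!is.null(responsivity))
    .check_scalar(responsivity, "responsivity", min = 0, allow_min = FALSE)
  if (!is.null(transimpedance))
    .check_scalar(transimpedance, "transimpedance", min = 0, allow_min = FALSE)
  .check_scalar(noise_floor, "noise_floor", min = 0, allow_min = FALSE)
  .check_scalar(saturation, "saturation", min = 0, allow_min = FALSE)
  if (noise_floor >= saturation)
    stopf("noise_floor (%g V) must be below saturation (%g V)",
          noise_floor, saturation)
  structure(list(name = name, active_area = active_area,
                 quantum_efficiency = quantum_efficiency, gain = gain,
                 responsivity = responsivity, transimpedance = transimpedance,
                 noise_floor = noise_floor, saturation = saturation),
            class = "detector_spec")
}

#' Analog post-amplifier specification
#'
#' @param amplification dimensionless gain (>= 1).
#' @return an object of class `amplifier_spec`.
#' @export
amplifier_spec <- function(amplification = 1) {
  .check_scalar(amplification, "amplification", min = 1)
  structure(list(amplification = amplification), class = "amplifier_spec")
}

#' Fraction of photons in the detection plane that hit the active area
#'
#' `min(1, active / exposed)`.
#'
#' @param active_area detector active area, cm^2.
#' @param exposed_area irradiated area in the detection plane, cm^2 (> 0).
#' @return fraction in [0, 1].
#' @export
detector_area_fraction <- function(active_area, exposed_area) {
  .check_scalar(active_area, "active_area", min = 0)
  .check_scalar(exposed_area, "exposed_area", min = 0, allow_min = FALSE)
  min(1, active_area / exposed_area)
}

#' Electron rate out of the detector
#'
#' `E_D = P_D * QE * G`. In pulse-counting operation this is the count
#' rate before discrimination; in analog operation it is the photocurrent
#' divided by the electron charge.
#'
#' @param p_d photon rate at the detector, photons/s.
#' @param det a [detector_spec()].
#' @return electrons/s.
#' @export
electron_rate <- function(p_d, det) {
  .check_scalar(p_d, "p_d", min = 0)
  stopifnot(inherits(det, "detector_spec"))
  p_d * det$quantum_efficiency * det$gain
}

#' Analog output voltage of the detection chain
#'
#' Two equivalent routes. The responsivity route converts the photon rate
#' back to incident watts through the 5.03e15 constant, applies the
#' responsivity at unit gain, the gain, the transimpedance and the
#' amplification. The electron route multiplies the electron rate by the
#' electron charge (giving amps), then transimpedance and amplification.
#' The responsivity route is preferred when a responsivity is specified.
#' Output is clipped at the detector saturation unless `clip = FALSE`
#' (root finding on the unclipped curve needs the raw value).
#'
#' @param p_d photon rate at the detector, photons/s.
#' @param wavelength photon wavelength, nm.
#' @param det a [detector_spec()].
#' @param amp an [amplifier_spec()].
#' @param clip clip the output at `det$saturation`.
#' @param exact use the exact 1/(h c) constant in the responsivity route.
#' @return output voltage, V.
#' @export
output_signal <- function(p_d, wavelength, det, amp = amplifier_spec(),
                          clip = TRUE, exact = FALSE) {
  .check_scalar(p_d, "p_d", min = 0)
  .check_scalar(wavelength, "wavelength", min = 0, allow_min = FALSE)
  stopifnot(inherits(det, "detector_spec"), inherits(amp, "amplifier_spec"))
  ti <- det$transimpedance
  if (!is.null(det$responsivity)) {
    watts <- p_d / (photons_per_watt_nm(exact) * wavelength)
    amps <- watts * det$responsivity * det$gain
    if (is.null(ti)) ti <- 1
  } else if (!is.null(ti)) {
    amps <- electron_rate(p_d, det) * .ELECTRON_CHARGE
  } else {
    stopf("detector '%s' has neither a responsivity nor a transimpedance; cannot form a voltage",
          det$name)
  }
  v <- amps * ti * amp$amplification
  if (isTRUE(clip)) min(v, det$saturation) else v
}
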