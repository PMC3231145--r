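#' photonbudget: absolute photon budgets for microfluidic optical analysis
#'
#' Traces photon and electron rates through the optical train of a
#' microfluidic fluorescence or absorption analyser -- source, coupling
#' optics, sample, spectral filter, detector, amplifier -- and derives
#' absolute calibration curves, minimum detection limits and dynamic ranges.
#'
#' @keywords internal
"_PACKAGE"

# Photons per second emitted by 1 W at 1 nm. The rounded engineering constant
# is the package default; the exact value is 1e-9/(h*c).
.PHOTONS_PER_W_NM <- 5.03e15
.PHOTONS_PER_W_NM_EXACT <- 1e-9 / (6.62607015e-34 * 2.99792458e8)

.LUMENS_PER_WATT_PEAK <- 683      # photometric peak at 555 nm
.AVOGADRO <- 6.022e23
.ELECTRON_CHARGE <- 1.602e-19     # coulombs

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar <- function(x, name, min = -Inf, max = Inf,
                          allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok)
    stopf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
          if (allow_min) "[" else "(", min, max, if (allow_max) "]" else ")")
  invisible(x)
}

#' Photon-rate conversion constant
#'
#' Photons per second per (watt x nanometre). The default is the rounded
#' engineering value 5.03e15; `exact = TRUE` returns 1e-9/(h c), which differs
#' by about 0.08%.
#'
#' @param exact use the exact physical constant instead of the rounded one.
#' @return photons s^-1 W^-1 nm^-1.
#' @export
photons_per_watt_nm <- function(exact = FALSE) {
  if (isTRUE(exact)) .PHOTONS_PER_W_NM_EXACT else .PHOTONS_PER_W_NM
}

#' Convert luminous flux to radiant power
#'
#' Photometric LED ratings (lumens) are converted to watts through the 683
#' lm/W photometric peak and the wavelength-dependent luminous efficacy,
#' treated as the dimensionless luminosity-function value V(lambda) in (0, 1].
#'
#' @param lumens luminous flux, lm (>= 0).
#' @param luminous_efficacy dimensionless fraction in (0, 1].
#' @return radiant power in watts.
#' @examples
#' lumens_to_watts(683, 1)   # 1 W
#' @export
lumens_to_watts <- function(lumens, luminous_efficacy) {
  .check_scalar(lumens, "lumens", min = 0)
  .check_scalar(luminous_efficacy, "luminous_efficacy", min = 0, max = 1,
                allow_min = FALSE)
  lumens / (.LUMENS_PER_WATT_PEAK * luminous_efficacy)
}

#' Photon emission rate of a monochromatic source
#'
#' `rate = 5.03e15 * power(W) * wavelength(nm)`, the standard radiometric
#' conversion (the constant is a rounding of 1/(h c) in these units; see
#' [photons_per_watt_nm()]).
#'
#' @param power radiant power, W (>= 0).
#' @param wavelength wavelength, nm (> 0).
#' @param exact use the exact 1/(h c) constant.
#' @return photon rate, photons/s.
#' @examples
#' watts_to_photon_rate(2e-3, 470)
#' @export
watts_to_photon_rate <- function(power, wavelength, exact = FALSE) {
  .check_scalar(power, "power", min = 0)
  .check_scalar(wavelength, "wavelength", min = 0, allow_min = FALSE)
  photons_per_watt_nm(exact) * power * wavelength
}

#' Solid angle of an emission cone
#'
#' Converts a full conical beam angle 2*theta (as quoted on LED datasheets)
#' to the subtended solid angle `2*pi*(1 - cos(theta))` in steradians.
#'
#' @param full_angle full emission angle in degrees, in (0, 360].
#' @return solid angle in steradians, in (0, 4*pi].
#' @examples
#' cone_to_solid_angle(360)  # 4*pi, full sphere
#' cone_to_solid_angle(10)   # narrow LED
#' @export
cone_to_solid_angle <- function(full_angle) {
  .check_scalar(full_angle, "full_angle", min = 0, max = 360,
                allow_min = FALSE)
  2 * pi * (1 - cos(full_angle / 2 * pi / 180))
}

#' Light source specification
#'
#' Describes an LED or laser source by its radiant power (or photometric
#' lumens plus luminous efficacy), nominal wavelength, full conical emission
#' angle and emitting area. Exactly one of `power` and `lumens` must be given.
#'
#' @param name label for reports.
#' @param power radiant power, W. Mutually exclusive with `lumens`.
#' @param lumens luminous flux, lm. Requires `luminous_efficacy`.
#' @param luminous_efficacy V(lambda) fraction in (0, 1].
#' @param wavelength nominal wavelength, nm.
#' @param full_emission_angle full cone angle 2*theta, degrees in (0, 360].
#' @param emitting_area emitting area A_S, cm^2 (> 0).
#' @return an object of class `source_spec`.
#' @examples
#' led <- source_spec("blue LED", power = 5e-3, wavelength = 470,
#'                    full_emission_angle = 10, emitting_area = 0.04)
#' source_photon_rate(led)
#' @export
source_spec <- function(name = "source", power = NULL, lumens = NULL,
                        luminous_efficacy = NULL, wavelength,
                        full_emission_angle, emitting_area) {
  if (is.null(power) == is.null(lumens))
    stopf("exactly one of `power` and `lumens` must be given for source '%s'",
          name)
  if (!is.null(lumens) && is.null(luminous_efficacy))
    stopf("`luminous_efficacy` is required when the source is rated in lumens")
  if (!is.null(power)) .check_scalar(power, "power", min = 0)
  if (!is.null(lumens)) {
    .check_scalar(lumens, "lumens", min = 0)
    .check_scalar(luminous_efficacy, "luminous_efficacy", min = 0, max = 1,
                  allow_min = FALSE)
  }
  .check_scalar(wavelength, "wavelength", min = 0, allow_min = FALSE)
  .check_scalar(full_emission_angle, "full_emission_angle", min = 0, max = 360,
                allow_min = FALSE)
  .check_scalar(emitting_area, "emitting_area", min = 0, allow_min = FALSE)
  structure(list(name = name, power = power, lumens = lumens,
                 luminous_efficacy = luminous_efficacy,
                 wavelength = wavelength,
                 full_emission_angle = full_emission_angle,
                 emitting_area = emitting_area),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  rating <- if (!is.null(x$power)) sprintf("%g W", x$power)
            else sprintf("%g lm (efficacy %g)", x$lumens, x$luminous_efficacy)
  cat(sprintf("<source_spec> %s: %s at %g nm, %g deg full angle, %g cm^2\n",
              x$name, rating, x$wavelength, x$full_emission_angle,
              x$emitting_area))
  invisible(x)
}

#' Solid angle of a source's emission cone
#'
#' @param src a [source_spec()].
#' @return steradians.
#' @export
source_solid_angle <- function(src) {
  stopifnot(inherits(src, "source_spec"))
  cone_to_solid_angle(src$full_emission_angle)
}

#' Total photon emission rate of a source
#'
#' Applies the lumens-to-watts conversion when the source is rated
#' photometrically, then the watts-to-photon-rate conversion.
#'
#' @param src a [source_spec()].
#' @param exact use the exact 1/(h c) constant.
#' @return photon rate, photons/s.
#' @export
source_photon_rate <- function(src, exact = FALSE) {
  stopifnot(inherits(src, "source_spec"))
  p <- if (!is.null(src$power)) src$power
       else lumens_to_watts(src$lumens, src$luminous_efficacy)
  watts_to_photon_rate(p, src$wavelength, exact = exact)
}

#' Number of molecules in a volume at a given concentration
#'
#' `N = C * V * 6.022e23`. A 100 micrometre cube holds 1 nL = 1e-9 L.
#'
#' @param concentration molarity, mol/L (>= 0).
#' @param volume volume in litres (> 0).
#' @return molecule count (not rounded).
#' @examples
#' molecule_count(1e-6, 1e-9)  # 1 uM in 1 nL: 6.022e8 molecules
#' @export
molecule_count <- function(concentration, volume) {
  .check_scalar(concentration, "concentration", min = 0)
  .check_scalar(volume, "volume", min = 0, allow_min = FALSE)
  concentration * volume * .AVOGADRO
}
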