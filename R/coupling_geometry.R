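#' Lens specification
#'
#' @param radius lens radius, cm (> 0).
#' @param focal_length focal length F, cm (> 0).
#' @return an object of class `lens_spec`.
#' @export
lens_spec <- function(radius, focal_length) {
  .check_scalar(radius, "radius", min = 0, allow_min = FALSE)
  .check_scalar(focal_length, "focal_length", min = 0, allow_min = FALSE)
  structure(list(radius = radius, focal_length = focal_length),
            class = "lens_spec")
}

#' Optical fiber specification
#'
#' @param core_radius fiber core radius, cm (> 0).
#' @param numerical_aperture NA = n*sin(theta_F), dimensionless, 0 < NA <= n.
#' @param refractive_index refractive index n of the medium the fiber
#'   accepts from (1 air, 1.33 water, 1.36 ethanol).
#' @param transmission single-scalar fiber transmission efficiency in (0, 1].
#' @return an object of class `fiber_spec`.
#' @export
fiber_spec <- function(core_radius, numerical_aperture,
                       refractive_index = 1, transmission = 1) {
  .check_scalar(core_radius, "core_radius", min = 0, allow_min = FALSE)
  .check_scalar(refractive_index, "refractive_index", min = 1)
  .check_scalar(numerical_aperture, "numerical_aperture", min = 0,
                max = refractive_index, allow_min = FALSE)
  .check_scalar(transmission, "transmission", min = 0, max = 1,
                allow_min = FALSE)
  structure(list(core_radius = core_radius,
                 numerical_aperture = numerical_aperture,
                 refractive_index = refractive_index,
                 transmission = transmission),
            class = "fiber_spec")
}

#' Fraction of source photons intercepted by the first lens
#'
#' Flat-disk form `pi R^2 / (Omega_S x1^2)`, capped at 1: when the lens
#' subtends more than the emission cone every photon hits it. The exact
#' spherical-cap form `2*pi*(1 - cos(atan(R/x1)))/Omega_S` is available for
#' validating the approximation at large angles.
#'
#' @param omega_s source emission solid angle, sr.
#' @param lens a [lens_spec()].
#' @param x1 source-to-lens distance, cm (> 0).
#' @param exact_cap use the spherical-cap form instead of the flat disk.
#' @return fraction in [0, 1].
#' @export
source_to_lens_fraction <- function(omega_s, lens, x1, exact_cap = FALSE) {
  .check_scalar(omega_s, "omega_s", min = 0, max = 4 * pi)
  stopifnot(inherits(lens, "lens_spec"))
  .check_scalar(x1, "x1", min = 0, allow_min = FALSE)
  if (omega_s == 0) return(0)
  omega_lens <- if (isTRUE(exact_cap)) {
    2 * pi * (1 - cos(atan(lens$radius / x1)))
  } else {
    pi * lens$radius^2 / x1^2
  }
  min(1, omega_lens / omega_s)
}

#' Thin-lens conjugate image distance
#'
#' Solves `1/F = 1/x1 + 1/x2` for the image distance x2.
#'
#' @param focal_length focal length F, cm.
#' @param x1 object distance, cm; must exceed F for a real image.
#' @return image distance x2, cm.
#' @export
conjugate_distance <- function(focal_length, x1) {
  .check_scalar(focal_length, "focal_length", min = 0, allow_min = FALSE)
  .check_scalar(x1, "x1", min = 0, allow_min = FALSE)
  if (x1 <= focal_length)
    stopf("no real image: object distance x1 = %g must exceed the focal length %g",
          x1, focal_length)
  1 / (1 / focal_length - 1 / x1)
}

#' Area of the imaged source spot at the sample plane
#'
#' With transverse magnification m = x2/x1, the physically consistent area
#' scaling is m^2 (`magnification = "area"`, the default). The alternative
#' `"linear"` mode scales the area by m itself; both modes coincide at
#' symmetric 2F-2F imaging, where the spot equals the source size.
#'
#' @param area_source source emitting area A_S, cm^2.
#' @param x1 object distance, cm.
#' @param x2 image distance, cm.
#' @param magnification `"area"` (m^2 scaling) or `"linear"` (m scaling).
#' @return spot area A_C at the sample plane, cm^2.
#' @export
image_spot <- function(area_source, x1, x2,
                       magnification = c("area", "linear")) {
  .check_scalar(area_source, "area_source", min = 0, allow_min = FALSE)
  .check_scalar(x1, "x1", min = 0, allow_min = FALSE)
  .check_scalar(x2, "x2", min = 0, allow_min = FALSE)
  magnification <- match.arg(magnification)
  m <- x2 / x1
  area_source * if (magnification == "area") m^2 else m
}

#' Area of a circle clipped to a centred strip
#'
#' Area of `{x^2 + y^2 <= r^2} \cap {|x| <= half_width}`, by circular
#' segments. Used for the spot/view/channel overlap fractions.
#'
#' @param r circle radius, cm.
#' @param half_width strip half-width, cm.
#' @return area, cm^2.
#' @export
circle_strip_area <- function(r, half_width) {
  .check_scalar(r, "r", min = 0)
  .check_scalar(half_width, "half_width", min = 0)
  if (r == 0) return(0)
  h <- min(half_width, r)
  2 * (h * sqrt(r^2 - h^2) + r^2 * asin(h / r))
}

#' Overlap fractions of focal spot, detector view and channel
#'
#' The focal spot and the detector-view region are concentric circles
#' centred on the channel axis (the system is assumed aligned). For a
#' microchannel (a strip of width `channel_width`), `f_into_channel` is the
#' fraction of spot photons that land on analyte fluid, and `f_viewed` is
#' the fraction of the illuminated fluid area that the detector sees. For a
#' thin film the fluid fills the plane, so `f_into_channel = 1` and
#' `f_viewed` is the concentric circle-circle overlap ratio.
#'
#' @param spot_radius focal-spot radius, cm.
#' @param view_radius detector-view radius, cm; `Inf` means the detector
#'   views the whole illuminated region.
#' @param channel_width channel width, cm (ignored for thin films).
#' @param sample_kind `"microchannel"` or `"thin_film"`.
#' @return list with `f_into_channel` and `f_viewed`, both in [0, 1].
#' @export
overlap_fractions <- function(spot_radius, view_radius = Inf, channel_width,
                              sample_kind = c("microchannel", "thin_film")) {
  sample_kind <- match.arg(sample_kind)
  .check_scalar(spot_radius, "spot_radius", min = 0, allow_min = FALSE)
  if (!(is.numeric(view_radius) && length(view_radius) == 1L &&
        (is.infinite(view_radius) || view_radius > 0)))
    stopf("`view_radius` must be a positive number or Inf")
  if (sample_kind == "thin_film") {
    f_viewed <- if (is.infinite(view_radius)) 1
                else min(1, view_radius^2 / spot_radius^2)
    return(list(f_into_channel = 1, f_viewed = f_viewed))
  }
  .check_scalar(channel_width, "channel_width", min = 0, allow_min = FALSE)
  h <- channel_width / 2
  a_spot <- pi * spot_radius^2
  a_in <- circle_strip_area(spot_radius, h)
  f_into <- min(1, a_in / a_spot)
  f_viewed <- if (is.infinite(view_radius)) 1 else {
    r_min <- min(spot_radius, view_radius)
    min(1, circle_strip_area(r_min, h) / a_in)
  }
  list(f_into_channel = f_into, f_viewed = f_viewed)
}

#' Fraction of isotropic sample emission collected by the second lens
#'
#' The fluorescing sample radiates into 4*pi sr; a lens of radius R at
#' distance x3 intercepts `R^2 / (4 x3^2)`, capped at 0.5 because a single
#' lens on one side cannot collect more than a hemisphere.
#'
#' @param lens a [lens_spec()].
#' @param x3 sample-to-lens distance, cm (> 0).
#' @return fraction in [0, 0.5].
#' @export
sample_to_lens_fraction <- function(lens, x3) {
  stopifnot(inherits(lens, "lens_spec"))
  .check_scalar(x3, "x3", min = 0, allow_min = FALSE)
  min(0.5, lens$radius^2 / (4 * x3^2))
}

#' Fiber acceptance half-angle
#'
#' `theta_F = asin(NA / n)` in degrees.
#'
#' @param fiber a [fiber_spec()].
#' @return half acceptance angle, degrees.
#' @export
fiber_half_angle <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_spec"))
  asin(fiber$numerical_aperture / fiber$refractive_index) * 180 / pi
}

#' Fiber acceptance solid angle
#'
#' @param fiber a [fiber_spec()].
#' @return acceptance solid angle Omega_F, sr.
#' @export
fiber_acceptance_solid_angle <- function(fiber) {
  cone_to_solid_angle(2 * fiber_half_angle(fiber))
}

#' Photon rate coupled from an extended source into a fiber
#'
#' Two-step coupling: the fraction of the source area within the fiber's
#' acceptance cone, `min(1, Omega_F d^2 / A_S)`, times the fraction of the
#' photons from that area that land on the core, `pi R_F^2 / (Omega_S d^2)`.
#' The product is additionally capped so the coupled rate never exceeds the
#' emitted rate. While the acceptance footprint under-fills the source,
#' increasing d does not change the result (the d^2 factors cancel).
#'
#' @param p_s source photon rate, photons/s.
#' @param src a [source_spec()] (supplies A_S and Omega_S).
#' @param fiber a [fiber_spec()].
#' @param d source-to-fiber distance, cm (> 0).
#' @param apply_transmission multiply by the fiber's transmission scalar.
#' @return photon rate entering the fiber, photons/s.
#' @export
source_to_fiber_rate <- function(p_s, src, fiber, d,
                                 apply_transmission = TRUE) {
  .check_scalar(p_s, "p_s", min = 0)
  stopifnot(inherits(src, "source_spec"), inherits(fiber, "fiber_spec"))
  .check_scalar(d, "d", min = 0, allow_min = FALSE)
  omega_f <- fiber_acceptance_solid_angle(fiber)
  omega_s <- source_solid_angle(src)
  area_factor <- min(1, omega_f * d^2 / src$emitting_area)
  core_factor <- pi * fiber$core_radius^2 / (omega_s * d^2)
  f <- min(1, area_factor * core_factor)
  p_s * f * if (isTRUE(apply_transmission)) fiber$transmission else 1
}

#' Fraction of isotropic emission captured by a fiber end face
#'
#' At distance d from an isotropic point-like emitter the fiber core
#' intercepts `min(pi R_F^2, Omega_F d^2) / (4 pi d^2)`: the line-of-sight
#' solid angle of the core, limited by the acceptance cone. As d -> 0 the
#' fraction tends to the acceptance bound Omega_F / (4 pi).
#'
#' @param fiber a [fiber_spec()].
#' @param d emitter-to-fiber distance, cm (>= 0).
#' @return fraction in [0, Omega_F/(4 pi)].
#' @export
fiber_capture_fraction <- function(fiber, d) {
  stopifnot(inherits(fiber, "fiber_spec"))
  .check_scalar(d, "d", min = 0)
  omega_f <- fiber_acceptance_solid_angle(fiber)
  if (d^2 * omega_f <= pi * fiber$core_radius^2) return(omega_f / (4 * pi))
  pi * fiber$core_radius^2 / (4 * pi * d^2)
}

#' Direct source-to-aperture fraction without intermediate optics
#'
#' The receiving aperture (detector active area or sample region) takes the
#' place of the lens in the flat-disk interception formula. For a conical
#' emitter the fraction is `min(1, A / (Omega_S d^2))`; for an isotropic
#' emitter (a fluorescing sample) it is `min(0.5, A / (4 pi d^2))`, capped
#' at the one-sided hemisphere bound.
#'
#' @param active_area receiving aperture area, cm^2 (>= 0).
#' @param d separation, cm (> 0).
#' @param emission `"cone"` (requires `omega_s`) or `"isotropic"`.
#' @param omega_s emission solid angle for the cone case, sr.
#' @return fraction in [0, 1].
#' @export
no_optics_fraction <- function(active_area, d,
                               emission = c("cone", "isotropic"),
                               omega_s = NULL) {
  emission <- match.arg(emission)
  .check_scalar(active_area, "active_area", min = 0)
  .check_scalar(d, "d", min = 0, allow_min = FALSE)
  if (emission == "cone") {
    if (is.null(omega_s)) stopf("`omega_s` is required for cone emission")
    .check_scalar(omega_s, "omega_s", min = 0, max = 4 * pi, allow_min = FALSE)
    min(1, active_area / (omega_s * d^2))
  } else {
    min(0.5, active_area / (4 * pi * d^2))
  }
}
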