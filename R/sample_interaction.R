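#' Analyte photophysics
#'
#' Molar absorption coefficient and fluorescence quantum yield. The Beer-
#' Lambert attenuation used throughout is base-e, `exp(-eps * C * l)`;
#' datasheet coefficients quoted on the conventional decadic (base-10) scale
#' can be supplied with `epsilon_base = "10"` and are converted by ln(10)
#' on construction.
#'
#' @param name analyte label.
#' @param epsilon molar absorption coefficient, L mol^-1 cm^-1 (>= 0).
#' @param quantum_yield fluorescence quantum yield in [0, 1].
#' @param epsilon_base `"e"` (natural, the default) or `"10"` (decadic,
#'   converted to natural on storage).
#' @return an object of class `analyte_spec`; `$epsilon` is always natural.
#' @export
analyte_spec <- function(name = "analyte", epsilon, quantum_yield,
                         epsilon_base = c("e", "10")) {
  epsilon_base <- match.arg(epsilon_base)
  .check_scalar(epsilon, "epsilon", min = 0)
  .check_scalar(quantum_yield, "quantum_yield", min = 0, max = 1)
  if (epsilon_base == "10") epsilon <- epsilon * log(10)
  structure(list(name = name, epsilon = epsilon,
                 quantum_yield = quantum_yield),
            class = "analyte_spec")
}

#' Sample geometry and contents
#'
#' Either a microchannel (width x depth cross-section, a given length) or a
#' thin film (thickness, lateral extent). The optical path length through
#' the analyte depends on the illumination axis and is chosen by the
#' calibration engine: channel depth or film thickness for normal
#' illumination, channel width for cross-channel fiber illumination, channel
#' length for coaxial illumination.
#'
#' @param kind `"microchannel"` or `"thin_film"`.
#' @param width,depth,length microchannel dimensions, cm.
#' @param thickness,extent thin-film thickness (cm) and lateral extent
#'   (cm^2).
#' @param analyte an [analyte_spec()].
#' @return an object of class `sample_spec`.
#' @export
sample_spec <- function(kind = c("microchannel", "thin_film"),
                        width = NULL, depth = NULL, length = NULL,
                        thickness = NULL, extent = NULL, analyte) {
  kind <- match.arg(kind)
  stopifnot(inherits(analyte, "analyte_spec"))
  if (kind == "microchannel") {
    for (nm in c("width", "depth", "length")) {
      v <- get(nm)
      if (is.null(v)) stopf("microchannel samples require `%s`", nm)
      .check_scalar(v, nm, min = 0, allow_min = FALSE)
    }
  } else {
    for (nm in c("thickness", "extent")) {
      v <- get(nm)
      if (is.null(v)) stopf("thin-film samples require `%s`", nm)
      .check_scalar(v, nm, min = 0, allow_min = FALSE)
    }
  }
  structure(list(kind = kind, width = width, depth = depth, length = length,
                 thickness = thickness, extent = extent, analyte = analyte),
            class = "sample_spec")
}

#' Photons transmitted through the analyte (Beer-Lambert)
#'
#' `P_T = P_c * exp(-eps * C * l)`; strictly decreasing in concentration.
#'
#' @param p_c photon rate striking the fluid, photons/s.
#' @param analyte an [analyte_spec()].
#' @param concentration molarity, mol/L.
#' @param path optical path length l, cm.
#' @return transmitted photon rate, photons/s.
#' @export
transmitted_photons <- function(p_c, analyte, concentration, path) {
  .check_scalar(p_c, "p_c", min = 0)
  stopifnot(inherits(analyte, "analyte_spec"))
  .check_scalar(concentration, "concentration", min = 0)
  .check_scalar(path, "path", min = 0)
  p_c * exp(-analyte$epsilon * concentration * path)
}

#' Photons absorbed in the analyte
#'
#' Exact form `P_c (1 - exp(-eps C l))`, or the optically-thin first-order
#' form `P_c * eps * C * l` (valid for eps*C*l << 1; always an
#' overestimate of the exact value).
#'
#' @inheritParams transmitted_photons
#' @param mode `"exact"` or `"thin"`.
#' @return absorbed photon rate, photons/s.
#' @export
absorbed_photons <- function(p_c, analyte, concentration, path,
                             mode = c("exact", "thin")) {
  mode <- match.arg(mode)
  .check_scalar(p_c, "p_c", min = 0)
  stopifnot(inherits(analyte, "analyte_spec"))
  .check_scalar(concentration, "concentration", min = 0)
  .check_scalar(path, "path", min = 0)
  tau <- analyte$epsilon * concentration * path
  p_c * if (mode == "exact") -expm1(-tau) else tau
}

#' Fluorescence emission rate
#'
#' `P_Sa = P_abs * QY`.
#'
#' @param p_abs absorbed photon rate, photons/s.
#' @param qy quantum yield in [0, 1].
#' @return emitted fluorescence photon rate, photons/s.
#' @export
fluorescence_rate <- function(p_abs, qy) {
  .check_scalar(p_abs, "p_abs", min = 0)
  .check_scalar(qy, "qy", min = 0, max = 1)
  p_abs * qy
}

#' Coaxial fiber-in-channel response
#'
#' Excitation light launched along the channel axis decays as
#' `p(x) = p0 * exp(-eps C x)`. Each slice dx absorbs
#' `p(x) * eps * C * dx`, emits isotropically with yield QY, and the
#' collection fiber at the far end (separated from the channel exit by
#' `gap`) captures the line-of-sight fraction
#' `min(pi R_F^2, Omega_F d^2) / (4 pi d^2)` with `d = (L - x) + gap`
#' (see [fiber_capture_fraction()]). The captured fluorescence is a
#' composite-Simpson sum over `n_slices` slices uniform in the absorbed fraction
#' `s = 1 - exp(-eps C x)` (so the nodes concentrate automatically where
#' the light is actually absorbed, and the rule stays accurate even when
#' the absorption depth is far smaller than the channel); the transmitted
#' beam is `p0 * exp(-eps C L)`. At high concentration the excitation is
#' consumed near the entrance, far from the collection fiber, so the
#' captured rate first flattens and then declines past `eps*C*L` of a few:
#' coaxial coupling is non-linear at high C and geometrically inefficient.
#'
#' @param p0 photon rate entering the channel, photons/s.
#' @param sample a microchannel [sample_spec()].
#' @param concentration molarity, mol/L.
#' @param collect_fiber the collection [fiber_spec()] (indexed to the
#'   channel medium, e.g. n = 1.33 for water).
#' @param gap channel-exit-to-fiber distance, cm (>= 0).
#' @param n_slices number of integration slices (>= 100).
#' @return list with `fluor_captured` and `transmitted`, photons/s.
#' @export
coaxial_channel_response <- function(p0, sample, concentration,
                                     collect_fiber, gap = 0.02,
                                     n_slices = 1000) {
  .check_scalar(p0, "p0", min = 0)
  stopifnot(inherits(sample, "sample_spec"), inherits(collect_fiber, "fiber_spec"))
  if (sample$kind != "microchannel")
    stopf("coaxial response requires a microchannel sample")
  .check_scalar(concentration, "concentration", min = 0)
  .check_scalar(gap, "gap", min = 0)
  if (!is.numeric(n_slices) || n_slices < 100)
    stopf("`n_slices` must be at least 100 for a resolved integral")
  L <- sample$length
  eps <- sample$analyte$epsilon
  qy <- sample$analyte$quantum_yield
  omega_f <- fiber_acceptance_solid_angle(collect_fiber)
  rf2 <- pi * collect_fiber$core_radius^2
  tau <- eps * concentration * L
  if (tau == 0) {
    fluor <- 0
  } else {
    # integrate d(fluor) = p0 * qy * cap(x) ds over the absorbed fraction
    # s = 1 - exp(-eps C x), s in [0, 1 - exp(-tau)]
    n <- as.integer(n_slices) + as.integer(n_slices) %% 2L  # Simpson: even
    s_top <- -expm1(-tau)
    s <- seq(0, s_top, length.out = n + 1)
    x <- pmin(-log1p(-s) / (eps * concentration), L)
    x[n + 1] <- L
    d <- (L - x) + gap
    cap <- ifelse(d^2 * omega_f <= rf2, omega_f / (4 * pi),
                  rf2 / (4 * pi * d^2))
    h <- s_top / n
    w <- rep(c(2, 4), length.out = n + 1)
    w[1] <- 1; w[n + 1] <- 1
    fluor <- p0 * qy * h / 3 * sum(w * cap) * collect_fiber$transmission
  }
  list(fluor_captured = fluor,
       transmitted = p0 * exp(-eps * concentration * L))
}

#' Fluid volume of a sample
#'
#' @param sample a [sample_spec()].
#' @return volume in litres (1 cm^3 = 1e-3 L).
#' @export
sample_volume <- function(sample) {
  stopifnot(inherits(sample, "sample_spec"))
  cm3 <- if (sample$kind == "microchannel")
    sample$width * sample$depth * sample$length
  else sample$thickness * sample$extent
  cm3 * 1e-3
}
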