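`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coupling-stage descriptors
#'
#' Describe how one side of the sample is optically coupled. `coupling_lens`
#' takes the object/image distances (`x1`, `x2`, for the excitation side;
#' `x2 = NULL` is filled in from the thin-lens conjugate relation) or the
#' sample-to-lens distance `x3` (collection side). `coupling_fiber` takes
#' the stand-off `distance` (source-to-fiber D on the excitation side,
#' channel-to-fiber gap on the collection side). `coupling_none` takes the
#' bare stand-off between source/detector and the sample.
#'
#' @param lens a [lens_spec()].
#' @param fiber a [fiber_spec()].
#' @param x1,x2,x3 lens distances, cm.
#' @param distance stand-off, cm.
#' @param view_radius radius of the sample region seen by the collection
#'   side, cm (`Inf`: sees the whole illuminated region).
#' @return an object of class `coupling`.
#' @name coupling
NULL

#' @rdname coupling
#' @export
coupling_lens <- function(lens, x1 = NULL, x2 = NULL, x3 = NULL,
                          view_radius = Inf) {
  stopifnot(inherits(lens, "lens_spec"))
  structure(list(kind = "lens", lens = lens, x1 = x1, x2 = x2, x3 = x3,
                 view_radius = view_radius), class = "coupling")
}

#' @rdname coupling
#' @export
coupling_fiber <- function(fiber, distance, view_radius = Inf) {
  stopifnot(inherits(fiber, "fiber_spec"))
  .check_scalar(distance, "distance", min = 0, allow_min = FALSE)
  structure(list(kind = "fiber", fiber = fiber, distance = distance,
                 view_radius = view_radius), class = "coupling")
}

#' @rdname coupling
#' @export
coupling_none <- function(distance, view_radius = Inf) {
  .check_scalar(distance, "distance", min = 0, allow_min = FALSE)
  structure(list(kind = "none", distance = distance,
                 view_radius = view_radius), class = "coupling")
}

#' Assemble a complete optical train
#'
#' Binds source, excitation coupling, sample, collection coupling, filter,
#' detector and amplifier into one validated system. Mixed optics (lens on
#' one side, fiber or nothing on the other) are allowed for the
#' `"perpendicular"` geometry; `"cross"` and `"coaxial"` geometries require
#' fiber coupling on both sides and a microchannel sample.
#'
#' @param source a [source_spec()].
#' @param excitation,collection [coupling][coupling_lens] descriptors.
#' @param sample a [sample_spec()].
#' @param filter a [filter_spec()].
#' @param detector a [detector_spec()].
#' @param amplifier an [amplifier_spec()].
#' @param mode `"fluorescence"` or `"absorption"`.
#' @param geometry `"perpendicular"`, `"cross"` (fiber across the channel)
#'   or `"coaxial"` (fibers along the channel axis).
#' @param emission_wavelength fluorescence emission wavelength, nm
#'   (defaults to the source wavelength; set it to the Stokes-shifted line
#'   centre for real fluorophores).
#' @param exposed_area irradiated area in the detection plane, cm^2, for
#'   the detector-area fraction; `NULL` means the detector catches the
#'   whole collected beam.
#' @param name label used in sweep tables.
#' @param options list of numerical switches: `magnification` ("area" or
#'   "linear" spot scaling, see [image_spot()]), `exact_constant` (use
#'   1/(h c) instead of 5.03e15), `exact_cap` (spherical-cap lens
#'   interception), `n_slices` (coaxial integration resolution).
#' @return an object of class `optical_train`.
#' @export
optical_train <- function(source, excitation, sample, collection, filter,
                          detector, amplifier = amplifier_spec(),
                          mode = c("fluorescence", "absorption"),
                          geometry = c("perpendicular", "cross", "coaxial"),
                          emission_wavelength = NULL, exposed_area = NULL,
                          name = "system", options = list()) {
  mode <- match.arg(mode)
  geometry <- match.arg(geometry)
  opts <- list(magnification = "area", exact_constant = FALSE,
               exact_cap = FALSE, n_slices = 1000)
  bad <- setdiff(names(options), names(opts))
  if (length(bad)) stopf("unknown options: %s", paste(bad, collapse = ", "))
  opts[names(options)] <- options
  train <- structure(
    list(source = source, excitation = excitation, sample = sample,
         collection = collection, filter = filter, detector = detector,
         amplifier = amplifier, mode = mode, geometry = geometry,
         emission_wavelength = emission_wavelength %||% source$wavelength,
         exposed_area = exposed_area, name = name, options = opts),
    class = "optical_train")
  validate_train(train)
  train
}

#' Validate an optical train
#'
#' Collects every violated constraint and raises a single configuration
#' error listing all of them; returns the train invisibly when valid.
#'
#' @param train an [optical_train()].
#' @return the train, invisibly.
#' @export
validate_train <- function(train) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(inherits(train$source, "source_spec"), "source must be a source_spec")
  chk(inherits(train$sample, "sample_spec"), "sample must be a sample_spec")
  chk(inherits(train$filter, "filter_spec"), "filter must be a filter_spec")
  chk(inherits(train$detector, "detector_spec"),
      "detector must be a detector_spec")
  chk(inherits(train$excitation, "coupling") &&
      inherits(train$collection, "coupling"),
      "excitation and collection must be coupling descriptors")
  if (length(v)) stopf("invalid optical train:\n- %s", paste(v, collapse = "\n- "))
  ex <- train$excitation; co <- train$collection
  if (train$geometry %in% c("cross", "coaxial")) {
    chk(ex$kind == "fiber" && co$kind == "fiber",
        sprintf("%s geometry requires fiber coupling on both sides",
                train$geometry))
    chk(train$sample$kind == "microchannel",
        sprintf("%s geometry requires a microchannel sample", train$geometry))
  } else {
    chk(ex$kind != "fiber",
        "fiber excitation of a perpendicular system is the cross geometry; set geometry = 'cross'")
    if (ex$kind == "lens") {
      chk(!is.null(ex$x1), "lens excitation requires x1")
      if (!is.null(ex$x1)) {
        f1 <- ex$lens$focal_length
        chk(ex$x1 > f1, sprintf("x1 = %g must exceed the focal length %g for a real image",
                                ex$x1 %||% NA_real_, f1))
        x2 <- ex$x2
        if (!is.null(x2)) {
          chk(abs(1 / f1 - 1 / ex$x1 - 1 / x2) < 1e-9 * (1 / f1),
              "x1 and x2 do not satisfy the thin-lens conjugate relation")
        }
      }
    }
    if (co$kind == "lens") chk(!is.null(co$x3), "lens collection requires x3")
  }
  if (length(v)) stopf("invalid optical train:\n- %s", paste(v, collapse = "\n- "))
  invisible(train)
}

#' @export
print.optical_train <- function(x, ...) {
  cat(sprintf("<optical_train> %s: %s / %s geometry\n", x$name, x$mode,
              x$geometry))
  cat(sprintf("  source: %s | excitation: %s | sample: %s | collection: %s | detector: %s\n",
              x$source$name, x$excitation$kind, x$sample$kind,
              x$collection$kind, x$detector$name))
  invisible(x)
}

# Geometry factors that do not depend on concentration: photon rate
# delivered into the analyte fluid per source photon, spot/view radii,
# optical path length and the interrogated (illuminated-and-viewed) area.
.train_geometry <- function(train) {
  src <- train$source; ex <- train$excitation; sam <- train$sample
  co <- train$collection; opts <- train$options
  omega_s <- source_solid_angle(src)
  out <- list(omega_s = omega_s)
  view_r <- co$view_radius %||% Inf
  if (train$geometry == "perpendicular") {
    if (ex$kind == "lens") {
      x2 <- ex$x2 %||% conjugate_distance(ex$lens$focal_length, ex$x1)
      f_stage <- source_to_lens_fraction(omega_s, ex$lens, ex$x1,
                                         exact_cap = opts$exact_cap)
      a_spot <- image_spot(src$emitting_area, ex$x1, x2,
                           magnification = opts$magnification)
    } else {                         # no optics: near field + cone footprint
      f_stage <- 1
      a_spot <- src$emitting_area + omega_s * ex$distance^2
    }
    spot_r <- sqrt(a_spot / pi)
    if (sam$kind == "microchannel") {
      ov <- overlap_fractions(spot_r, view_r, sam$width, "microchannel")
      a_int <- circle_strip_area(min(spot_r, view_r), sam$width / 2)
      path <- sam$depth
    } else {
      ov <- overlap_fractions(spot_r, view_r, sample_kind = "thin_film")
      ov$f_into_channel <- min(1, sam$extent / a_spot)
      a_int <- min(pi * min(spot_r, view_r)^2, sam$extent)
      path <- sam$thickness
    }
    out$f_excitation <- f_stage * ov$f_into_channel
    out$f_viewed <- ov$f_viewed
    out$spot_radius <- spot_r
    out$path <- path
    out$interrogated_volume_L <- a_int * path * 1e-3
  } else if (train$geometry == "cross") {
    rf <- ex$fiber$core_radius
    ov <- overlap_fractions(rf, Inf, sam$depth, "microchannel")
    out$f_beam_into_channel <- ov$f_into_channel
    out$f_viewed <- 1
    out$path <- sam$width
    a_beam <- circle_strip_area(rf, sam$depth / 2)
    out$interrogated_volume_L <- a_beam * sam$width * 1e-3
  } else {                           # coaxial
    out$f_viewed <- 1
    out$path <- sam$length
    out$interrogated_volume_L <- sample_volume(sam)
  }
  out
}

#' Detector output at one concentration, with the per-stage photon budget
#'
#' Concatenates the stage equations appropriate to the train's geometry and
#' couplings: source strength, excitation coupling, Beer-Lambert
#' absorption (exact exponential) and fluorescence yield, collection
#' coupling, spectral filter, detector area, photon-to-voltage conversion
#' and amplification. The returned trace carries the photon rate after
#' every stage so any point of a calibration curve can be audited by hand.
#'
#' @param train an [optical_train()].
#' @param concentration analyte molarity, mol/L (>= 0).
#' @param clip clip the output voltage at the detector saturation.
#' @return list with `volts` and a named numeric `trace`.
#' @export
signal_at_concentration <- function(train, concentration, clip = TRUE) {
  validate_train(train)
  .check_scalar(concentration, "concentration", min = 0)
  geo <- .train_geometry(train)
  src <- train$source; sam <- train$sample; co <- train$collection
  opts <- train$options
  p_s <- source_photon_rate(src, exact = opts$exact_constant)
  trace <- c(source = p_s)
  if (train$geometry == "perpendicular") {
    p_c <- p_s * geo$f_excitation
  } else {
    p_f <- source_to_fiber_rate(p_s, src, train$excitation$fiber,
                                train$excitation$distance)
    trace <- c(trace, into_fiber = p_f)
    p_c <- if (train$geometry == "cross") p_f * geo$f_beam_into_channel
           else p_f                    # coaxial: launched along the channel
  }
  trace <- c(trace, into_sample = p_c)
  if (train$geometry == "coaxial") {
    res <- coaxial_channel_response(p_c, sam, concentration, co$fiber,
                                    gap = co$distance,
                                    n_slices = opts$n_slices)
    trace <- c(trace, transmitted = res$transmitted)
    p_coll <- if (train$mode == "fluorescence") res$fluor_captured
              else res$transmitted * co$fiber$transmission
    trace <- c(trace, after_collection = p_coll)
  } else {
    p_t <- transmitted_photons(p_c, sam$analyte, concentration, geo$path)
    p_abs <- p_c - p_t
    trace <- c(trace, transmitted = p_t, absorbed = p_abs)
    if (train$mode == "fluorescence") {
      p_em <- fluorescence_rate(p_abs, sam$analyte$quantum_yield)
      trace <- c(trace, emitted = p_em)
      g <- switch(co$kind,
        lens = sample_to_lens_fraction(co$lens, co$x3),
        none = no_optics_fraction(train$detector$active_area, co$distance,
                                  "isotropic"),
        fiber = fiber_capture_fraction(co$fiber, co$distance) *
                co$fiber$transmission)
      p_coll <- p_em * geo$f_viewed * g
    } else {
      g <- switch(co$kind,
        lens = 1,                      # co-linear beam refocused on detector
        none = {                       # diverging beam footprint at detector
          a_beam <- pi * geo$spot_radius^2 + geo$omega_s * co$distance^2
          min(1, train$detector$active_area / a_beam)
        },
        fiber = co$fiber$transmission)
      p_coll <- p_t * g
    }
    trace <- c(trace, after_collection = p_coll)
  }
  p_filt <- p_coll * filter_transmission_factor(train$filter)
  f_area <- if (is.null(train$exposed_area)) 1
            else detector_area_fraction(train$detector$active_area,
                                        train$exposed_area)
  p_d <- p_filt * f_area
  trace <- c(trace, after_filter = p_filt, at_detector = p_d)
  lambda <- if (train$mode == "fluorescence") train$emission_wavelength
            else src$wavelength
  v <- output_signal(p_d, lambda, train$detector, train$amplifier,
                     clip = clip, exact = opts$exact_constant)
  trace <- c(trace, electrons = electron_rate(p_d, train$detector),
             output_V = v)
  list(volts = v, trace = trace)
}

#' Volume of sample both illuminated and viewed
#'
#' The molecule counts on calibration curves refer to this interrogated
#' volume: the geometric intersection of the illuminated region, the
#' detector-view region and the fluid.
#'
#' @param train an [optical_train()].
#' @return volume in litres.
#' @export
interrogated_volume <- function(train) {
  validate_train(train)
  .train_geometry(train)$interrogated_volume_L
}

#' Compute a calibration curve
#'
#' Sweeps a concentration grid and records, per point, the molecule count
#' in the interrogated volume, the key stage photon rates and the output
#' voltage.
#'
#' @param train an [optical_train()].
#' @param c_min,c_max grid endpoints, mol/L (`c_min < c_max`).
#' @param n_points number of grid points (>= 2).
#' @param spacing `"log"` or `"linear"`.
#' @param clip clip outputs at the detector saturation.
#' @return a data frame of class `calibration_curve` with attributes
#'   `train` and `interrogated_volume_L`.
#' @export
calibration_curve <- function(train, c_min = 1e-12, c_max = 1e-3,
                              n_points = 91, spacing = c("log", "linear"),
                              clip = TRUE) {
  validate_train(train)
  spacing <- match.arg(spacing)
  .check_scalar(c_min, "c_min", min = 0, allow_min = (spacing == "linear"))
  .check_scalar(c_max, "c_max", min = 0, allow_min = FALSE)
  if (!(c_min < c_max)) stopf("c_min must be below c_max")
  if (!is.numeric(n_points) || n_points < 2) stopf("n_points must be >= 2")
  conc <- if (spacing == "log")
    10^seq(log10(c_min), log10(c_max), length.out = n_points)
  else seq(c_min, c_max, length.out = n_points)
  conc[1] <- c_min; conc[length(conc)] <- c_max   # exact endpoints
  vol <- interrogated_volume(train)
  rows <- lapply(conc, function(cc) {
    s <- signal_at_concentration(train, cc, clip = clip)
    tr <- s$trace
    data.frame(concentration_M = cc,
               molecule_count = molecule_count(cc, vol),
               p_source = tr[["source"]],
               p_into_sample = tr[["into_sample"]],
               p_at_detector = tr[["at_detector"]],
               output_V = s$volts)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_curve", "data.frame")
  attr(out, "train") <- train
  attr(out, "interrogated_volume_L") <- vol
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  train <- attr(x, "train")
  keep <- x$output_V > 0 & x$concentration_M > 0
  graphics::plot(x$concentration_M[keep], x$output_V[keep], log = "xy",
                 type = "b", pch = 16, cex = 0.6,
                 xlab = "concentration (mol/L)",
                 ylab = "detector output (V)",
                 main = train$name, ...)
  graphics::abline(h = c(train$detector$noise_floor,
                         train$detector$saturation), lty = 2, col = "grey40")
  invisible(x)
}

# Monotone level crossing, bisected on log10(concentration).
.solve_level <- function(train, level, lower = 1e-15, upper = 10,
                         tol = 1e-6) {
  f <- function(cc) signal_at_concentration(train, cc, clip = FALSE)$volts - level
  f_lo <- f(lower); f_hi <- f(upper)
  if (f_lo == 0) return(lower)
  if (f_hi == 0) return(upper)
  if (sign(f_lo) == sign(f_hi)) {
    return(structure(NA_real_, f_lower = f_lo + level, f_upper = f_hi + level))
  }
  lo <- log10(lower); hi <- log10(upper)
  s_lo <- sign(f_lo)
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(10^mid)
    if (fm == 0) return(10^mid)
    if (sign(fm) == s_lo) lo <- mid else hi <- mid
    if ((10^hi - 10^lo) <= tol * 10^lo) break
  }
  10^((lo + hi) / 2)
}

#' Minimum detection limit
#'
#' The concentration at which the (unclipped) calibration curve crosses the
#' detector noise floor, solved by bisection on a geometric concentration
#' bracket to a relative tolerance of 1e-6. In the optically thin regime
#' the result equals `noise_floor / slope` of the linear calibration curve.
#'
#' @param train an [optical_train()].
#' @param noise_floor threshold voltage; defaults to the detector's.
#' @param lower,upper concentration bracket, mol/L.
#' @return MDL in mol/L, or `NA` (with attributes `f_lower`, `f_upper`
#'   giving the bracket-end voltages) when the floor is not crossed inside
#'   the bracket.
#' @export
find_mdl <- function(train, noise_floor = NULL, lower = 1e-15, upper = 10) {
  validate_train(train)
  noise_floor <- noise_floor %||% train$detector$noise_floor
  .check_scalar(noise_floor, "noise_floor", min = 0, allow_min = FALSE)
  .solve_level(train, noise_floor, lower = lower, upper = upper)
}

#' Dynamic range
#'
#' Ratio of the highest assayable concentration (where the unclipped
#' calibration curve reaches the detector saturation) to the MDL. With the
#' exact Beer-Lambert exponential the curve flattens at high concentration,
#' so the factor can exceed the electronic ratio saturation/noise. When the
#' optical asymptote stays below saturation the range is open-ended
#' upwards and `Inf` is returned, with the asymptotic voltage attached.
#'
#' @param train an [optical_train()].
#' @param noise_floor,saturation threshold voltages; default to the
#'   detector's.
#' @param lower,upper concentration bracket, mol/L.
#' @return dynamic-range factor with attributes `mdl_M` and `c_max_M`.
#' @export
dynamic_range <- function(train, noise_floor = NULL, saturation = NULL,
                          lower = 1e-15, upper = 10) {
  validate_train(train)
  noise_floor <- noise_floor %||% train$detector$noise_floor
  saturation <- saturation %||% train$detector$saturation
  mdl <- find_mdl(train, noise_floor, lower = lower, upper = upper)
  if (is.na(mdl)) stopf("noise floor not crossed in [%g, %g] M", lower, upper)
  if (noise_floor == saturation)
    return(structure(1, mdl_M = mdl, c_max_M = mdl))
  c_max <- .solve_level(train, saturation, lower = lower, upper = upper)
  if (is.na(c_max)) {
    asym <- signal_at_concentration(train, upper, clip = FALSE)$volts
    return(structure(Inf, mdl_M = mdl, c_max_M = NA_real_,
                     asymptote_V = asym))
  }
  structure(c_max / mdl, mdl_M = mdl, c_max_M = c_max)
}

# Nested parameter access by dotted path, e.g. "source.power",
# "collection.x3", "sample.analyte.quantum_yield".
.param_get <- function(train, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- train
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stopf("parameter path '%s' not found at '%s'", path, k)
    node <- node[[k]]
  }
  if (!is.numeric(node) || length(node) != 1L)
    stopf("parameter path '%s' is not a single numeric value", path)
  node
}

.param_set <- function(train, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys,
                 accumulate = FALSE, init = quote(train))
  eval(call("<-", expr, value))
  train
}

#' Parameter sensitivity of the output signal
#'
#' Central finite difference of the (unclipped) output voltage with respect
#' to any numeric parameter of the train, addressed by a dotted path such
#' as `"source.power"`, `"collection.x3"` or
#' `"sample.analyte.quantum_yield"`. The normalised form
#' `(dS/dp) * (p/S)` is the log-log slope: 1 for purely multiplicative
#' parameters, -2 for inverse-square distances.
#'
#' @param train an [optical_train()].
#' @param parameter_path dotted path to a numeric parameter.
#' @param concentration molarity at which to evaluate, mol/L.
#' @param rel_step relative finite-difference step.
#' @param normalized return the dimensionless normalised sensitivity.
#' @return the (normalised) partial derivative.
#' @export
sensitivity <- function(train, parameter_path, concentration,
                        rel_step = 1e-4, normalized = TRUE) {
  validate_train(train)
  p0 <- .param_get(train, parameter_path)
  if (p0 == 0) stopf("cannot take a relative step from a zero parameter")
  h <- rel_step * abs(p0)
  s_plus <- signal_at_concentration(
    .param_set(train, parameter_path, p0 + h), concentration, clip = FALSE)$volts
  s_minus <- signal_at_concentration(
    .param_set(train, parameter_path, p0 - h), concentration, clip = FALSE)$volts
  deriv <- (s_plus - s_minus) / (2 * h)
  if (!normalized) return(deriv)
  s0 <- signal_at_concentration(train, concentration, clip = FALSE)$volts
  if (s0 == 0) stopf("signal is zero at this concentration; normalised sensitivity undefined")
  deriv * p0 / s0
}

#' Performance summary of one train
#'
#' MDL, highest assayable concentration, dynamic range and the
#' low-concentration calibration slope (instrument responsivity).
#'
#' @param train an [optical_train()].
#' @param c_ref reference concentration for the slope, mol/L (thin regime).
#' @return one-row data frame.
#' @export
performance_summary <- function(train, c_ref = 1e-10) {
  validate_train(train)
  slope <- signal_at_concentration(train, c_ref, clip = FALSE)$volts / c_ref
  dr <- tryCatch(dynamic_range(train), error = function(e) {
    structure(NA_real_, mdl_M = find_mdl(train), c_max_M = NA_real_)
  })
  data.frame(name = train$name, geometry = train$geometry,
             sample = train$sample$kind, source = train$source$name,
             detector = train$detector$name,
             mdl_M = as.numeric(attr(dr, "mdl_M")),
             c_max_M = as.numeric(attr(dr, "c_max_M")),
             dynamic_range = as.numeric(dr),
             slope_V_per_M = slope,
             stringsAsFactors = FALSE)
}

#' Performance table over a set of optical trains
#'
#' Applies [performance_summary()] to each train; a failing train yields a
#' row of `NA`s with the error message, not a fatal error.
#'
#' @param trains list of [optical_train()] objects.
#' @param c_ref reference concentration for slopes, mol/L.
#' @return data frame, one row per train, with an `error` column.
#' @export
design_sweep <- function(trains, c_ref = 1e-10) {
  if (!length(trains)) stopf("at least one train is required")
  rows <- lapply(trains, function(tr) {
    res <- tryCatch(cbind(performance_summary(tr, c_ref = c_ref),
                          error = NA_character_, stringsAsFactors = FALSE),
                    error = function(e)
                      data.frame(name = tr$name %||% "?",
                                 geometry = NA, sample = NA, source = NA,
                                 detector = NA, mdl_M = NA_real_,
                                 c_max_M = NA_real_, dynamic_range = NA_real_,
                                 slope_V_per_M = NA_real_,
                                 error = conditionMessage(e),
                                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
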