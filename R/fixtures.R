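# Representative example systems. Component values are synthetic,
# datasheet-plausible numbers for the class of parts involved (LED dies,
# 1.5 cm lenses, 100 um fibers, a SiPM and an amplified photodiode); they
# are not tied to any particular commercial part. The geometry follows a
# bench layout: imaging lenses at their 2F-2F conjugates, bare source and
# detector at a 1 cm stand-off when no optics are used, collection fibers
# separated from the channel end by a 500 um substrate wall.

#' Representative component library
#'
#' The synthetic component set used by [example_train()] and
#' [generate_fixtures()]: three LED sources (10 and 150 degree blue, 120
#' degree UV), a 1.5 cm focal-length lens, a 100 um core NA 0.22 fiber, a
#' 100 um square microchannel and a 100 um thin film, a fluorescein-like
#' analyte, a band-pass filter, a SiPM (1 mV noise floor, 500 mV
#' saturation) and an amplified photodiode (1 mV, 5 V).
#'
#' @return named list of spec objects and geometry constants.
#' @export
example_components <- function() {
  analyte <- analyte_spec("fluorescein-like", epsilon = 8e4,
                          quantum_yield = 0.9)
  list(
    sources = list(
      led_blue_10 = source_spec("10 deg blue LED", power = 5e-3,
                                wavelength = 470, full_emission_angle = 10,
                                emitting_area = 0.04),
      led_blue_150 = source_spec("150 deg blue LED", power = 5e-3,
                                 wavelength = 470, full_emission_angle = 150,
                                 emitting_area = 0.04),
      led_uv_120 = source_spec("120 deg UV LED", power = 5e-3,
                               wavelength = 365, full_emission_angle = 120,
                               emitting_area = 0.04)),
    lens = lens_spec(radius = 0.75, focal_length = 1.5),
    fiber_air = fiber_spec(core_radius = 0.005, numerical_aperture = 0.22,
                           refractive_index = 1, transmission = 0.9),
    fiber_water = fiber_spec(core_radius = 0.005, numerical_aperture = 0.22,
                             refractive_index = 1.33, transmission = 0.9),
    channel = sample_spec("microchannel", width = 0.01, depth = 0.01,
                          length = 1, analyte = analyte),
    channel_coaxial = sample_spec("microchannel", width = 0.01, depth = 0.01,
                                  length = 0.1, analyte = analyte),
    film = sample_spec("thin_film", thickness = 0.01, extent = 1,
                       analyte = analyte),
    filter = filter_spec(fwhm = 25, transmission = 0.9,
                         emission_bandwidth = 50),
    detectors = list(
      sipm = detector_spec("SiPM", active_area = 0.09,
                           quantum_efficiency = 0.2, gain = 1e6,
                           transimpedance = 50, noise_floor = 1e-3,
                           saturation = 0.5),
      ampd = detector_spec("AmPD", active_area = 0.05,
                           quantum_efficiency = 0.65, gain = 1,
                           responsivity = 0.25, transimpedance = 5e7,
                           noise_floor = 1e-3, saturation = 5)),
    geometry = list(x1 = 3, x3 = 1.5, standoff = 1, fiber_d = 0.1,
                    fiber_gap = 0.05),
    emission_wavelength = 520)
}

#' Build one representative optical train
#'
#' @param optics `"lens"`, `"none"`, `"cross"` (fiber across the channel)
#'   or `"coaxial"` (fiber along the channel).
#' @param sample `"microchannel"` or `"thin_film"` (fiber optics imply a
#'   microchannel).
#' @param source `"led_blue_10"`, `"led_blue_150"` or `"led_uv_120"`.
#' @param detector `"sipm"` or `"ampd"`.
#' @param components component library, by default [example_components()].
#' @return an [optical_train()] in fluorescence mode.
#' @export
example_train <- function(optics = c("lens", "none", "cross", "coaxial"),
                          sample = c("microchannel", "thin_film"),
                          source = c("led_blue_10", "led_blue_150",
                                     "led_uv_120"),
                          detector = c("sipm", "ampd"),
                          components = example_components()) {
  optics <- match.arg(optics)
  sample <- match.arg(sample)
  source <- match.arg(source)
  detector <- match.arg(detector)
  cm <- components
  g <- cm$geometry
  if (optics %in% c("cross", "coaxial")) {
    sam <- if (optics == "coaxial") cm$channel_coaxial else cm$channel
    ex <- coupling_fiber(cm$fiber_air, distance = g$fiber_d)
    co <- coupling_fiber(cm$fiber_water, distance = g$fiber_gap)
    geometry <- optics
  } else {
    sam <- if (sample == "microchannel") cm$channel else cm$film
    ex <- if (optics == "lens") coupling_lens(cm$lens, x1 = g$x1)
          else coupling_none(g$standoff)
    co <- if (optics == "lens") coupling_lens(cm$lens, x3 = g$x3)
          else coupling_none(g$standoff)
    geometry <- "perpendicular"
  }
  nm <- paste(optics,
              if (optics == "coaxial") "microchannel_1000um"
              else if (optics == "cross") "microchannel" else sample,
              source, detector, sep = "_")
  optical_train(source = cm$sources[[source]], excitation = ex, sample = sam,
                collection = co, filter = cm$filter,
                detector = cm$detectors[[detector]],
                mode = "fluorescence", geometry = geometry,
                emission_wavelength = cm$emission_wavelength, name = nm)
}

#' The full 36-system example grid
#'
#' Three optics/sample pairs per coupling family (lens and no-optics each
#' with microchannel and thin film; fiber with cross and coaxial channel)
#' times three sources times two detectors.
#'
#' @param components component library.
#' @return named list of 36 [optical_train()] objects.
#' @export
example_system_grid <- function(components = example_components()) {
  combos <- list(
    list("lens", "microchannel"), list("lens", "thin_film"),
    list("none", "microchannel"), list("none", "thin_film"),
    list("cross", "microchannel"), list("coaxial", "microchannel"))
  trains <- list()
  for (cb in combos)
    for (src in c("led_blue_10", "led_blue_150", "led_uv_120"))
      for (det in c("sipm", "ampd")) {
        tr <- example_train(cb[[1]], cb[[2]], src, det,
                            components = components)
        trains[[tr$name]] <- tr
      }
  trains
}

.coupling_to_config <- function(cp, side) {
  out <- list(coupling = cp$kind)
  if (cp$kind == "lens") {
    out$lens <- list(radius_cm = cp$lens$radius,
                     focal_length_cm = cp$lens$focal_length)
    if (!is.null(cp$x1)) out$x1_cm <- cp$x1
    if (!is.null(cp$x2)) out$x2_cm <- cp$x2
    if (!is.null(cp$x3)) out$x3_cm <- cp$x3
  } else if (cp$kind == "fiber") {
    out$fiber <- list(core_radius_cm = cp$fiber$core_radius,
                      numerical_aperture = cp$fiber$numerical_aperture,
                      refractive_index = cp$fiber$refractive_index,
                      transmission = cp$fiber$transmission)
    out$distance_cm <- cp$distance
  } else {
    out$distance_cm <- cp$distance
  }
  if (!is.null(cp$view_radius) && is.finite(cp$view_radius))
    out$view_radius_cm <- cp$view_radius
  out
}

#' Serialise an optical train to the configuration schema
#'
#' @param train an [optical_train()].
#' @param sweep optional sweep block (list with `c_min_M`, `c_max_M`, ...).
#' @return plain list in the `system_config` schema.
#' @export
train_to_config <- function(train, sweep = NULL) {
  src <- train$source
  sb <- list(name = src$name)
  if (!is.null(src$power)) sb$power_W <- src$power
  if (!is.null(src$lumens)) {
    sb$lumens <- src$lumens
    sb$luminous_efficacy <- src$luminous_efficacy
  }
  sb$wavelength_nm <- src$wavelength
  sb$full_emission_angle_deg <- src$full_emission_angle
  sb$emitting_area_cm2 <- src$emitting_area
  sam <- train$sample
  smp <- list(kind = sam$kind)
  if (sam$kind == "microchannel") {
    smp$width_cm <- sam$width; smp$depth_cm <- sam$depth
    smp$length_cm <- sam$length
  } else {
    smp$thickness_cm <- sam$thickness; smp$extent_cm2 <- sam$extent
  }
  smp$analyte <- list(name = sam$analyte$name,
                      epsilon_L_per_mol_cm = sam$analyte$epsilon,
                      quantum_yield = sam$analyte$quantum_yield)
  det <- train$detector
  db <- list(name = det$name, active_area_cm2 = det$active_area,
             quantum_efficiency = det$quantum_efficiency, gain = det$gain)
  if (!is.null(det$responsivity)) db$responsivity_A_per_W <- det$responsivity
  if (!is.null(det$transimpedance))
    db$transimpedance_V_per_A <- det$transimpedance
  db$noise_floor_V <- det$noise_floor
  db$saturation_V <- det$saturation
  cfg <- list(schema_version = .SCHEMA_VERSION, name = train$name,
              mode = train$mode, geometry = train$geometry,
              source = sb,
              emission_wavelength_nm = train$emission_wavelength,
              excitation = .coupling_to_config(train$excitation, "excitation"),
              sample = smp,
              collection = .coupling_to_config(train$collection, "collection"),
              filter = list(fwhm_nm = train$filter$fwhm,
                            transmission = train$filter$transmission,
                            emission_bandwidth_nm =
                              train$filter$emission_bandwidth),
              detector = db,
              amplifier = list(amplification =
                                 train$amplifier$amplification))
  if (!is.null(train$exposed_area)) cfg$exposed_area_cm2 <- train$exposed_area
  if (!is.null(sweep)) cfg$sweep <- sweep
  cfg
}

#' Write the 36 example system configurations to disk
#'
#' One YAML file per system in the example grid, each with a default
#' 1e-12 to 1e-3 mol/L, 10 points/decade log sweep. Every file validates
#' with [load_config()].
#'
#' @param out_dir writable directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trains <- example_system_grid()
  sweep <- list(c_min_M = 1e-12, c_max_M = 1e-3, points_per_decade = 10,
                spacing = "log")
  paths <- vapply(trains, function(tr) {
    p <- file.path(out_dir, paste0(tr$name, ".yaml"))
    save_config(train_to_config(tr, sweep = sweep), p)
    p
  }, character(1))
  invisible(unname(paths))
}
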