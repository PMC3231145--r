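# Declarative YAML system configuration: parsing, validation, fixtures,
# CSV/JSON export. Units in config files are fixed and spelled out in the
# key names (cm, nm, cm^2, mol/L, V, A/W); there is no unit parsing.

.SCHEMA_VERSION <- 1

.TOP_KEYS <- c("schema_version", "name", "mode", "geometry", "source",
               "emission_wavelength_nm", "excitation", "sample",
               "collection", "filter", "detector", "amplifier",
               "exposed_area_cm2", "sweep", "options")
.BLOCK_KEYS <- list(
  source = c("name", "power_W", "lumens", "luminous_efficacy",
             "wavelength_nm", "full_emission_angle_deg",
             "emitting_area_cm2"),
  excitation = c("coupling", "lens", "fiber", "x1_cm", "x2_cm",
                 "distance_cm", "view_radius_cm"),
  collection = c("coupling", "lens", "fiber", "x3_cm", "distance_cm",
                 "view_radius_cm"),
  lens = c("radius_cm", "focal_length_cm"),
  fiber = c("core_radius_cm", "numerical_aperture", "refractive_index",
            "transmission"),
  sample = c("kind", "width_cm", "depth_cm", "length_cm", "thickness_cm",
             "extent_cm2", "analyte"),
  analyte = c("name", "epsilon_L_per_mol_cm", "quantum_yield",
              "epsilon_base"),
  filter = c("fwhm_nm", "transmission", "emission_bandwidth_nm"),
  detector = c("name", "active_area_cm2", "quantum_efficiency", "gain",
               "responsivity_A_per_W", "transimpedance_V_per_A",
               "noise_floor_V", "saturation_V"),
  amplifier = c("amplification"),
  sweep = c("c_min_M", "c_max_M", "n_points", "points_per_decade",
            "spacing"),
  options = c("magnification", "exact_constant", "exact_cap", "n_slices"))

.check_keys <- function(block, allowed, where, violations) {
  if (is.null(block)) return(violations)
  if (!is.list(block))
    return(c(violations, sprintf("'%s' must be a mapping", where)))
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    violations <- c(violations, sprintf("unknown key(s) in '%s': %s", where,
                                        paste(bad, collapse = ", ")))
  violations
}

#' Validate a system configuration
#'
#' Structural validation (unknown keys are rejected, required blocks must
#' be present) followed by construction of every component spec, so every
#' physical-constraint violation declared by the spec constructors is
#' caught. All violations are aggregated into a single error.
#'
#' @param config a named list as returned by [load_config()].
#' @return the config, invisibly, with class `system_config`.
#' @export
validate_config <- function(config) {
  v <- character()
  v <- .check_keys(config, .TOP_KEYS, "top level", v)
  for (blk in c("source", "sample", "filter", "detector", "excitation",
                "collection"))
    if (is.null(config[[blk]]))
      v <- c(v, sprintf("required block '%s' is missing", blk))
  for (blk in intersect(names(.BLOCK_KEYS), names(config)))
    v <- .check_keys(config[[blk]], .BLOCK_KEYS[[blk]], blk, v)
  for (side in c("excitation", "collection")) {
    v <- .check_keys(config[[side]]$lens, .BLOCK_KEYS$lens,
                     paste0(side, ".lens"), v)
    v <- .check_keys(config[[side]]$fiber, .BLOCK_KEYS$fiber,
                     paste0(side, ".fiber"), v)
  }
  v <- .check_keys(config$sample$analyte, .BLOCK_KEYS$analyte,
                   "sample.analyte", v)
  sv <- config$schema_version
  if (!is.null(sv) && sv != .SCHEMA_VERSION)
    v <- c(v, sprintf("unsupported schema_version %s (expected %d)",
                      sv, .SCHEMA_VERSION))
  if (!length(v)) {
    tryCatch(.build_train(config),
             error = function(e) v <<- c(v, conditionMessage(e)))
  }
  if (length(v))
    stopf("invalid system configuration:\n- %s", paste(v, collapse = "\n- "))
  class(config) <- c("system_config", "list")
  invisible(config)
}

#' Load and validate a system configuration file
#'
#' @param path YAML file describing one optical train plus sweep settings.
#' @return validated config of class `system_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Save a system configuration
#'
#' Writes YAML that [load_config()] reads back identically.
#'
#' @param config a `system_config` (or plain list in the same schema).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

.build_coupling <- function(blk, side) {
  kind <- blk$coupling %||% "none"
  view <- blk$view_radius_cm %||% Inf
  switch(kind,
    lens = {
      if (is.null(blk$lens)) stopf("%s: lens coupling needs a lens block", side)
      lens <- lens_spec(blk$lens$radius_cm, blk$lens$focal_length_cm)
      coupling_lens(lens, x1 = blk$x1_cm, x2 = blk$x2_cm, x3 = blk$x3_cm,
                    view_radius = view)
    },
    fiber = {
      if (is.null(blk$fiber)) stopf("%s: fiber coupling needs a fiber block", side)
      fb <- blk$fiber
      coupling_fiber(fiber_spec(fb$core_radius_cm, fb$numerical_aperture,
                                fb$refractive_index %||% 1,
                                fb$transmission %||% 1),
                     distance = blk$distance_cm, view_radius = view)
    },
    none = coupling_none(blk$distance_cm, view_radius = view),
    stopf("%s: unknown coupling kind '%s'", side, kind))
}

.build_train <- function(config) {
  sb <- config$source
  src <- source_spec(name = sb$name %||% "source", power = sb$power_W,
                     lumens = sb$lumens,
                     luminous_efficacy = sb$luminous_efficacy,
                     wavelength = sb$wavelength_nm,
                     full_emission_angle = sb$full_emission_angle_deg,
                     emitting_area = sb$emitting_area_cm2)
  ab <- config$sample$analyte
  if (is.null(ab)) stopf("sample block needs an analyte block")
  analyte <- analyte_spec(name = ab$name %||% "analyte",
                          epsilon = ab$epsilon_L_per_mol_cm,
                          quantum_yield = ab$quantum_yield,
                          epsilon_base = ab$epsilon_base %||% "e")
  smp <- config$sample
  sample <- sample_spec(kind = smp$kind, width = smp$width_cm,
                        depth = smp$depth_cm, length = smp$length_cm,
                        thickness = smp$thickness_cm,
                        extent = smp$extent_cm2, analyte = analyte)
  fb <- config$filter
  filt <- filter_spec(fb$fwhm_nm, fb$transmission, fb$emission_bandwidth_nm)
  db <- config$detector
  det <- detector_spec(name = db$name %||% "detector",
                       active_area = db$active_area_cm2,
                       quantum_efficiency = db$quantum_efficiency,
                       gain = db$gain %||% 1,
                       responsivity = db$responsivity_A_per_W,
                       transimpedance = db$transimpedance_V_per_A,
                       noise_floor = db$noise_floor_V,
                       saturation = db$saturation_V)
  amp <- amplifier_spec(config$amplifier$amplification %||% 1)
  optical_train(source = src,
                excitation = .build_coupling(config$excitation, "excitation"),
                sample = sample,
                collection = .build_coupling(config$collection, "collection"),
                filter = filt, detector = det, amplifier = amp,
                mode = config$mode %||% "fluorescence",
                geometry = config$geometry %||% "perpendicular",
                emission_wavelength = config$emission_wavelength_nm,
                exposed_area = config$exposed_area_cm2,
                name = config$name %||% "system",
                options = config$options %||% list())
}

#' Build the optical train described by a configuration
#'
#' @param config a validated `system_config`.
#' @return an [optical_train()].
#' @export
as_optical_train <- function(config) {
  .build_train(config)
}

#' Concentration grid described by a config's sweep block
#'
#' @param config a `system_config`.
#' @return list with `c_min`, `c_max`, `n_points`, `spacing`.
#' @export
sweep_settings <- function(config) {
  sw <- config$sweep %||% list()
  c_min <- sw$c_min_M %||% 1e-12
  c_max <- sw$c_max_M %||% 1e-3
  n <- sw$n_points %||%
    (round((log10(c_max) - log10(c_min)) * (sw$points_per_decade %||% 10)) + 1)
  list(c_min = c_min, c_max = c_max, n_points = n,
       spacing = sw$spacing %||% "log")
}

# 32-bit FNV-1a over the text serialisation; stable identifier for logs and
# export headers.
.fnv1a <- function(txt) {
  mul32 <- function(a, b) {
    lo <- a %% 65536; hi <- a %/% 65536
    ((lo * b) %% 4294967296 + ((hi * b) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in as.integer(charToRaw(txt))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Stable hash of a system configuration
#'
#' @param config a `system_config` or plain list.
#' @return 8-hex-digit FNV-1a hash of the YAML serialisation.
#' @export
config_hash <- function(config) {
  .fnv1a(yaml::as.yaml(unclass(config), precision = 15))
}

#' Export a calibration curve
#'
#' Deterministic text output: numbers are rounded to 6 significant digits,
#' so re-exporting the same curve yields identical bytes. The CSV variant
#' carries `#`-prefixed header lines with the tool version and, when the
#' curve was computed from a config, its hash.
#'
#' @param curve a [calibration_curve()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param config optional `system_config` the curve came from (for the
#'   hash header).
#' @return `path`, invisibly.
#' @export
export_curve <- function(curve, path, format = c("csv", "json"),
                         config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(curve))
  df <- as.data.frame(lapply(curve, function(col)
    if (is.numeric(col)) signif(col, 6) else col))
  ver <- as.character(utils::packageVersion("photonbudget"))
  if (format == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(sprintf("# photonbudget %s", ver), con)
    if (!is.null(config))
      writeLines(sprintf("# config_hash %s", config_hash(config)), con)
    utils::write.csv(format(df, digits = 6, trim = TRUE, scientific = NA),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(tool = sprintf("photonbudget %s", ver),
                              config_hash = if (!is.null(config))
                                config_hash(config) else NULL,
                              curve = df),
                         path, digits = NA, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}
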