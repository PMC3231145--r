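#' Monte-Carlo sampler configuration
#'
#' Describes an extended emitter (uniform over a disk of given area,
#' directions uniform over the spherical cap of the emission cone -- the
#' exact solid-angle measure, not uniform in polar angle) and a receiving
#' target. Targets:
#' \describe{
#'   \item{disk}{a coaxial disk of radius `radius` at distance `distance`
#'     (a lens or detector aperture).}
#'   \item{strip}{an infinite strip of half-width `half_width` at distance
#'     `distance` (a microchannel in the sample plane).}
#'   \item{fiber}{a coaxial disk of radius `radius` at distance `distance`
#'     that additionally accepts only directions within `half_angle`
#'     degrees of the axis (a fiber core with its acceptance cone).}
#' }
#'
#' @param n_samples number of photons (>= 1e4 for any assertion).
#' @param seed integer RNG seed (always explicit).
#' @param emitter list with `area` (cm^2; 0 for a point source) and
#'   `full_angle` (degrees).
#' @param target list with `kind` ("disk", "strip" or "fiber") and the
#'   fields above.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 1e6, seed, emitter, target) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stopf("`n_samples` must be a positive count")
  .check_scalar(seed, "seed")
  if (is.null(emitter$full_angle))
    stopf("emitter needs a `full_angle` in degrees")
  .check_scalar(emitter$full_angle, "emitter$full_angle", min = 0, max = 360,
                allow_min = FALSE)
  .check_scalar(emitter$area %||% 0, "emitter$area", min = 0)
  if (is.null(target$kind) ||
      !target$kind %in% c("disk", "strip", "fiber"))
    stopf("target$kind must be 'disk', 'strip' or 'fiber'")
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 emitter = emitter, target = target),
            class = "sampler_config")
}

#' Brute-force geometric coupling fraction
#'
#' Samples photon origins uniformly over the emitting disk and directions
#' uniformly over the emission spherical cap, propagates each ray to the
#' target plane, and returns the unbiased hit fraction with its binomial
#' standard error. Bit-identical for a fixed seed; the global RNG state is
#' restored on exit. This is the independent check for the algebraic
#' flat-disk coupling factors, and quantifies their approximation error at
#' large emission angles.
#'
#' @param cfg a [sampler_config()].
#' @return list with `fraction`, `se` and `n`.
#' @examples
#' cfg <- sampler_config(1e5, seed = 1,
#'                       emitter = list(area = 0, full_angle = 60),
#'                       target = list(kind = "disk", radius = 0.75,
#'                                     distance = 10))
#' estimate_fraction(cfg)
#' @export
estimate_fraction <- function(cfg) {
  stopifnot(inherits(cfg, "sampler_config"))
  tgt <- cfg$target
  d <- tgt$distance
  if (is.null(d) || !is.finite(d) || d <= 0)
    stopf("degenerate geometry: target needs a positive `distance`")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  n <- cfg$n_samples
  # positions uniform on the emitting disk
  r_src <- sqrt((cfg$emitter$area %||% 0) / pi)
  rr <- r_src * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  x0 <- rr * cos(phi); y0 <- rr * sin(phi)
  # directions uniform over the spherical cap: cos(theta) uniform
  cos_max <- cos(cfg$emitter$full_angle / 2 * pi / 180)
  ct <- stats::runif(n, cos_max, 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  psi <- stats::runif(n, 0, 2 * pi)
  dx <- st * cos(psi); dy <- st * sin(psi)   # dz = ct
  # propagate to the plane z = d (rays with ct <= 0 never reach it)
  fwd <- ct > 0
  t <- ifelse(fwd, d / ct, NA_real_)
  xh <- x0 + t * dx; yh <- y0 + t * dy
  hit <- switch(tgt$kind,
    disk = fwd & (xh^2 + yh^2 <= tgt$radius^2),
    strip = fwd & (abs(xh) <= tgt$half_width),
    fiber = {
      cos_acc <- cos(tgt$half_angle * pi / 180)
      fwd & (xh^2 + yh^2 <= tgt$radius^2) & (ct >= cos_acc)
    })
  hit[is.na(hit)] <- FALSE
  p <- mean(hit)
  list(fraction = p, se = sqrt(p * (1 - p) / n), n = n)
}
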