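# Independent numeric oracles used across the suite.

# 2-D quadrature for the area of a circle clipped to a centred strip.
quad_circle_strip <- function(r, half_width) {
  h <- min(half_width, r)
  stats::integrate(function(x) 2 * sqrt(pmax(0, r^2 - x^2)), -h, h,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Planck-relation photon rate (exact physical constants).
photon_rate_hc <- function(power_w, wavelength_nm) {
  h <- 6.62607015e-34; c <- 2.99792458e8
  power_w * (wavelength_nm * 1e-9) / (h * c)
}

# A deliberately near-linear high-throughput train: lens-coupled thin film
# with a boosted source so detector saturation is reached while eps*C*l is
# still far below 1.
linear_film_train <- function(detector = "sipm", power = 0.05) {
  cm <- example_components()
  cm$sources$led_blue_10$power <- power
  example_train("lens", "thin_film", "led_blue_10", detector,
                components = cm)
}
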