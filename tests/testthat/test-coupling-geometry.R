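test_that("source-to-lens fraction follows the capped flat-disk form", {
  lens <- lens_spec(0.75, 1.5)
  # 10 degree LED close to a large lens: every photon is intercepted
  expect_equal(source_to_lens_fraction(cone_to_solid_angle(10), lens, 2), 1)
  # 60 degree full angle at 10 cm
  om <- cone_to_solid_angle(60)
  expect_equal(source_to_lens_fraction(om, lens, 10),
               pi * 0.75^2 / (om * 100), tolerance = 1e-12)
  expect_lt(source_to_lens_fraction(om, lens_spec(1e-9, 1.5), 10), 1e-12)
  expect_error(source_to_lens_fraction(om, lens, 0), "x1")
  # exact spherical-cap form never exceeds the flat-disk approximation
  for (x1 in c(1, 2, 5, 20)) {
    expect_lte(source_to_lens_fraction(om, lens, x1, exact_cap = TRUE),
               source_to_lens_fraction(om, lens, x1) + 1e-12)
  }
})

test_that("thin-lens conjugates solve 1/F = 1/x1 + 1/x2 to machine precision", {
  expect_equal(conjugate_distance(1.5, 3), 3)
  expect_equal(conjugate_distance(1.5, 4.5), 2.25)
  expect_error(conjugate_distance(1.5, 1.5), "real image")
  expect_error(conjugate_distance(1.5, 1.0), "real image")
  for (x1 in seq(1.6, 30, length.out = 25)) {
    x2 <- conjugate_distance(1.5, x1)
    expect_equal(1 / 1.5 - 1 / x1 - 1 / x2, 0, tolerance = 1e-15)
  }
})

test_that("imaged spot area scales by the chosen magnification convention", {
  expect_equal(image_spot(0.04, 3, 3), 0.04)               # 2F-2F imaging
  expect_equal(image_spot(0.04, 3, 3, "linear"), 0.04)
  expect_equal(image_spot(0.04, 4.5, 2.25), 0.01)          # (1/2)^2
  expect_equal(image_spot(0.04, 4.5, 2.25, "linear"), 0.02)
})

test_that("circle-strip overlap area matches quadrature", {
  set.seed(42)
  for (i in 1:20) {
    r <- runif(1, 0.01, 2)
    h <- runif(1, 0.001, 2.5)
    expect_equal(circle_strip_area(r, h), quad_circle_strip(r, h),
                 tolerance = 1e-9)
  }
  expect_equal(circle_strip_area(1, 1), pi)      # tangent: full circle
  expect_equal(circle_strip_area(1, 5), pi)      # strip wider than circle
  expect_equal(circle_strip_area(0, 1), 0)
})

test_that("spot/view/channel overlap fractions cover the nine size regimes", {
  w <- 0.01
  # spot inside the channel strip (including the tangent case)
  expect_equal(overlap_fractions(0.002, Inf, w)$f_into_channel, 1)
  expect_equal(overlap_fractions(w / 2, Inf, w)$f_into_channel, 1)
  # spot much wider than the channel: against the quadrature oracle
  r <- 5 * w / 2
  ov <- overlap_fractions(r, Inf, w)
  expect_equal(ov$f_into_channel, quad_circle_strip(r, w / 2) / (pi * r^2),
               tolerance = 1e-6)
  # detector view narrower than the illuminated stripe
  ov2 <- overlap_fractions(r, 0.015, w)
  expect_equal(ov2$f_viewed,
               quad_circle_strip(0.015, w / 2) / quad_circle_strip(r, w / 2),
               tolerance = 1e-6)
  # thin film: everything is fluid; view/spot circle-circle ratio
  f <- overlap_fractions(0.1, 0.05, sample_kind = "thin_film")
  expect_equal(f$f_into_channel, 1)
  expect_equal(f$f_viewed, 0.25)
  expect_equal(overlap_fractions(0.1, Inf, sample_kind = "thin_film")$f_viewed, 1)
  # every combination of sizes stays inside [0, 1]
  for (spot in c(0.001, 0.005, 0.02)) for (view in c(0.001, 0.005, 0.02, Inf)) {
    ov <- overlap_fractions(spot, view, w)
    expect_true(ov$f_into_channel >= 0 && ov$f_into_channel <= 1)
    expect_true(ov$f_viewed >= 0 && ov$f_viewed <= 1)
  }
})

test_that("collection by the second lens is inverse-square with a hemisphere cap", {
  expect_equal(sample_to_lens_fraction(lens_spec(0.75, 1.5), 1.5), 0.0625)
  expect_equal(sample_to_lens_fraction(lens_spec(10, 1.5), 1), 0.5)
  expect_lt(sample_to_lens_fraction(lens_spec(0.75, 1.5), 1e4), 1e-8)
  expect_error(sample_to_lens_fraction(lens_spec(0.75, 1.5), 0), "x3")
})

test_that("fiber acceptance follows NA = n sin(theta)", {
  expect_equal(fiber_half_angle(fiber_spec(0.005, 1, 1)), 90)
  expect_equal(fiber_half_angle(fiber_spec(0.005, 0.22, 1)),
               asin(0.22) * 180 / pi)
  expect_equal(fiber_half_angle(fiber_spec(0.005, 0.22, 1.33)),
               asin(0.22 / 1.33) * 180 / pi)
  expect_error(fiber_spec(0.005, 1.1, 1), "numerical_aperture")
  f <- fiber_spec(0.005, 0.22, 1)
  expect_equal(fiber_acceptance_solid_angle(f),
               2 * pi * (1 - cos(asin(0.22))))
})

test_that("source-to-fiber coupling saturates its viewed-area factor and caps at unity", {
  src <- source_spec(power = 1, wavelength = 470, full_emission_angle = 60,
                     emitting_area = 1e-4)
  fib <- fiber_spec(0.005, 0.22, 1, transmission = 1)
  om_f <- fiber_acceptance_solid_angle(fib)
  om_s <- source_solid_angle(src)
  # far enough that Omega_F d^2 >= A_S: the area factor is exactly 1
  d_far <- sqrt(src$emitting_area / om_f) * 2
  expect_equal(source_to_fiber_rate(1e12, src, fib, d_far),
               1e12 * pi * 0.005^2 / (om_s * d_far^2))
  # vanishing core collects nothing
  expect_lt(source_to_fiber_rate(1e12, src,
                                 fiber_spec(1e-9, 0.22, 1), 0.1), 1e-3)
  # never more photons out than in
  tight <- source_spec(power = 1, wavelength = 470, full_emission_angle = 1,
                       emitting_area = 1e-8)
  expect_lte(source_to_fiber_rate(1e12, tight, fiber_spec(1, 0.9, 1), 0.01),
             1e12)
  # while the acceptance footprint under-fills the source, d cancels out
  src2 <- source_spec(power = 1, wavelength = 470, full_emission_angle = 60,
                      emitting_area = 0.04)
  d1 <- 0.05; d2 <- 0.1   # both under-filled: Omega_F d^2 < A_S
  expect_lt(om_f * d2^2, src2$emitting_area)
  expect_equal(source_to_fiber_rate(1e12, src2, fib, d1),
               source_to_fiber_rate(1e12, src2, fib, d2))
})

test_that("fiber capture of isotropic emission is acceptance-limited near the face", {
  fib <- fiber_spec(0.005, 0.22, 1.33)
  om_f <- fiber_acceptance_solid_angle(fib)
  expect_equal(fiber_capture_fraction(fib, 0), om_f / (4 * pi))
  expect_equal(fiber_capture_fraction(fib, 1e-4), om_f / (4 * pi))
  d <- 0.1  # far field: bare line-of-sight solid angle
  expect_equal(fiber_capture_fraction(fib, d),
               pi * fib$core_radius^2 / (4 * pi * d^2))
  # continuous at the crossover distance
  d_c <- sqrt(pi * fib$core_radius^2 / om_f)
  expect_equal(fiber_capture_fraction(fib, d_c * (1 - 1e-9)),
               fiber_capture_fraction(fib, d_c * (1 + 1e-9)),
               tolerance = 1e-6)
})

test_that("bare-aperture coupling caps at unity (cone) and a hemisphere (isotropic)", {
  expect_equal(no_optics_fraction(0, 0.5, "isotropic"), 0)
  expect_equal(no_optics_fraction(1, 0.5, "isotropic"), 1 / (4 * pi * 0.25))
  expect_equal(no_optics_fraction(100, 0.1, "isotropic"), 0.5)
  om <- cone_to_solid_angle(10)
  expect_equal(no_optics_fraction(om * 4, 2, "cone", omega_s = om), 1)
  expect_equal(no_optics_fraction(1e-4, 2, "cone", omega_s = om),
               1e-4 / (om * 4))
  expect_error(no_optics_fraction(1, 2, "cone"), "omega_s")
})
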