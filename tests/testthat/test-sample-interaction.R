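fl <- analyte_spec("dye", epsilon = 8e4, quantum_yield = 0.79)

test_that("Beer-Lambert transmission and absorption are exact complements", {
  expect_equal(transmitted_photons(1e12, fl, 0, 0.01), 1e12)
  expect_equal(transmitted_photons(1e12, fl, 10, 10), 0)
  expect_equal(transmitted_photons(1e12, fl, 1e-6, 0.01),
               1e12 * exp(-8e-4))
  expect_equal(absorbed_photons(1e12, fl, 0, 0.01), 0)
  expect_equal(absorbed_photons(1e12, fl, 0, 0.01, "thin"), 0)
  expect_equal(absorbed_photons(1e12, fl, 1e-6, 0.01),
               1e12 * (1 - exp(-8e-4)))
  expect_equal(absorbed_photons(1e12, fl, 1e-6, 0.01, "thin"), 8e8)
  # saturation limit: optically thick sample absorbs essentially everything
  thick <- analyte_spec("x", 1, 1)
  expect_equal(absorbed_photons(1, thick, 10, 1) / 1, 1 - exp(-10))
  # conservation to machine precision across ten decades of concentration
  for (conc in 10^seq(-12, -2, by = 1)) {
    pt <- transmitted_photons(1e12, fl, conc, 0.01)
    pa <- absorbed_photons(1e12, fl, conc, 0.01)
    expect_equal(pt + pa, 1e12, tolerance = 1e-15)
  }
})

test_that("thin-regime absorption overestimates the exact form by at most tau/2", {
  for (tau in c(1e-6, 1e-4, 1e-2, 0.1)) {
    conc <- tau / (8e4 * 0.01)
    exact <- absorbed_photons(1, fl, conc, 0.01)
    thin <- absorbed_photons(1, fl, conc, 0.01, "thin")
    expect_gte(thin, exact)
    expect_lte((thin - exact) / thin, tau / 2 + 1e-12)
  }
})

test_that("fluorescence yield scales absorption and never exceeds it", {
  expect_equal(fluorescence_rate(8e8, 0), 0)
  expect_equal(fluorescence_rate(8e8, 1), 8e8)
  expect_equal(fluorescence_rate(8e8, 0.79), 6.32e8)
  expect_error(fluorescence_rate(8e8, 1.2), "qy")
})

test_that("decadic absorption coefficients are converted by ln(10)", {
  nat <- analyte_spec("a", 1000, 0.9)
  dec <- analyte_spec("a", 1000, 0.9, epsilon_base = "10")
  expect_equal(dec$epsilon, 1000 * log(10))
  expect_equal(transmitted_photons(1, dec, 1e-4, 1),
               10^(-1000 * 1e-4 * 1))
  expect_equal(nat$epsilon, 1000)
})

test_that("sample specs require the dimensions of their kind", {
  expect_error(sample_spec("microchannel", width = 0.01, depth = 0.01,
                           analyte = fl), "length")
  expect_error(sample_spec("thin_film", thickness = 0.01, analyte = fl),
               "extent")
  ch <- sample_spec("microchannel", width = 0.01, depth = 0.01, length = 1,
                    analyte = fl)
  expect_equal(sample_volume(ch), 0.01 * 0.01 * 1 * 1e-3)
  fm <- sample_spec("thin_film", thickness = 0.01, extent = 1, analyte = fl)
  expect_equal(sample_volume(fm), 1e-5)
})

coax_sample <- sample_spec("microchannel", width = 0.01, depth = 0.01,
                           length = 0.1,
                           analyte = analyte_spec("dye", 8e4, 0.9))
coll <- fiber_spec(0.005, 0.22, 1.33, transmission = 1)

test_that("coaxial channel response is a converged quadrature with physical limits", {
  # no analyte: no fluorescence, full transmission
  r0 <- coaxial_channel_response(1e12, coax_sample, 0, coll, gap = 0.05)
  expect_equal(r0$fluor_captured, 0)
  expect_equal(r0$transmitted, 1e12)
  # refining the grid changes nothing at the 1e-6 level (concentrations
  # whose absorption depth 1/(eps C) is resolved by 1000 slices)
  for (conc in c(1e-8, 1e-6, 1e-4)) {
    a <- coaxial_channel_response(1e12, coax_sample, conc, coll,
                                  gap = 0.05, n_slices = 1000)
    b <- coaxial_channel_response(1e12, coax_sample, conc, coll,
                                  gap = 0.05, n_slices = 2000)
    expect_equal(a$fluor_captured, b$fluor_captured, tolerance = 1e-6)
    expect_equal(a$transmitted, b$transmitted)
  }
  # capture can never beat total absorption into the best-case solid angle
  om_f <- fiber_acceptance_solid_angle(coll)
  for (conc in c(1e-9, 1e-6, 1e-3, 1)) {
    r <- coaxial_channel_response(1e12, coax_sample, conc, coll, gap = 0.05)
    expect_lt(r$fluor_captured, 1e12 * 0.9 * om_f / (4 * pi))
  }
  # below an absorbance of order one the captured fluorescence grows with
  # concentration while transmission falls; past that the absorption
  # migrates toward the channel entrance, away from the collection fiber,
  # and the captured rate turns over (the non-linear coaxial regime)
  concs <- 10^seq(-10, -4, by = 0.5)
  res <- lapply(concs, function(cc)
    coaxial_channel_response(1e12, coax_sample, cc, coll, gap = 0.05))
  fluor <- vapply(res, `[[`, numeric(1), "fluor_captured")
  trans <- vapply(res, `[[`, numeric(1), "transmitted")
  expect_true(all(diff(fluor) > 0))
  expect_true(all(diff(trans) < 0))
  peak <- coaxial_channel_response(1e12, coax_sample, 3e-4, coll,
                                   gap = 0.05)$fluor_captured
  deep <- coaxial_channel_response(1e12, coax_sample, 1e-1, coll,
                                   gap = 0.05)$fluor_captured
  expect_lt(deep, peak)
  expect_error(coaxial_channel_response(1e12, coax_sample, 1e-6, coll,
                                        gap = 0.05, n_slices = 10),
               "n_slices")
})
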