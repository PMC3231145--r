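tr_lens <- example_train("lens", "microchannel", "led_blue_10", "sipm")
tr_film <- example_train("lens", "thin_film", "led_blue_10", "sipm")
tr_coax <- example_train("coaxial", "microchannel", "led_blue_10", "sipm")

test_that("blank samples give zero fluorescence and maximal transmission", {
  expect_equal(signal_at_concentration(tr_lens, 0)$volts, 0)
  abs_train <- example_train("lens", "microchannel", "led_blue_10", "sipm")
  abs_train$mode <- "absorption"
  v0 <- signal_at_concentration(abs_train, 0, clip = FALSE)$volts
  expect_gt(v0, 0)
  for (conc in c(1e-6, 1e-4, 1e-2))
    expect_lt(signal_at_concentration(abs_train, conc, clip = FALSE)$volts, v0)
})

test_that("the optically thin signal is linear in concentration and source power", {
  for (tr in list(tr_lens, tr_film, tr_coax)) {
    s1 <- signal_at_concentration(tr, 1e-10, clip = FALSE)$volts
    s2 <- signal_at_concentration(tr, 2e-10, clip = FALSE)$volts
    expect_equal(s2 / s1, 2, tolerance = 1e-3)
  }
  boosted <- example_components()
  boosted$sources$led_blue_10$power <- 2 * boosted$sources$led_blue_10$power
  tr2 <- example_train("lens", "microchannel", "led_blue_10", "sipm",
                       components = boosted)
  expect_equal(signal_at_concentration(tr2, 1e-9, clip = FALSE)$volts /
               signal_at_concentration(tr_lens, 1e-9, clip = FALSE)$volts, 2,
               tolerance = 1e-9)
})

test_that("fluorescence output rises and absorption output falls with concentration", {
  concs <- 10^seq(-11, -2, by = 0.5)
  v <- vapply(concs, function(cc)
    signal_at_concentration(tr_lens, cc, clip = FALSE)$volts, numeric(1))
  expect_true(all(diff(v) > 0))
  # coaxial: monotone below an along-channel absorbance of order one
  concs_coax <- 10^seq(-11, -4, by = 0.5)
  v <- vapply(concs_coax, function(cc)
    signal_at_concentration(tr_coax, cc, clip = FALSE)$volts, numeric(1))
  expect_true(all(diff(v) > 0))
  ab <- tr_lens; ab$mode <- "absorption"
  v <- vapply(concs, function(cc)
    signal_at_concentration(ab, cc, clip = FALSE)$volts, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("the stage trace only shrinks across passive stages", {
  for (tr in list(tr_lens, tr_film,
                  example_train("none", "thin_film", "led_uv_120", "ampd"),
                  example_train("cross", "microchannel", "led_blue_150",
                                "sipm"))) {
    t <- signal_at_concentration(tr, 1e-7)$trace
    expect_lte(t[["into_sample"]], t[["source"]])
    expect_lte(t[["absorbed"]], t[["into_sample"]])
    expect_lte(t[["emitted"]], t[["absorbed"]])
    expect_lte(t[["after_collection"]], t[["emitted"]])
    expect_lte(t[["after_filter"]], t[["after_collection"]])
    expect_lte(t[["at_detector"]], t[["after_filter"]])
    expect_true(all(t >= 0))
  }
})

test_that("calibration curves hit their grid endpoints and scale with the source", {
  cc <- calibration_curve(tr_lens, 1e-12, 1e-3, n_points = 19)
  expect_identical(cc$concentration_M[1], 1e-12)
  expect_identical(cc$concentration_M[nrow(cc)], 1e-3)
  expect_true(all(diff(cc$concentration_M) > 0))
  expect_equal(ncol(cc), 6)
  dark <- example_components()
  dark$sources$led_blue_10$power <- 0
  tr0 <- example_train("lens", "microchannel", "led_blue_10", "sipm",
                       components = dark)
  cc0 <- calibration_curve(tr0, 1e-12, 1e-3, n_points = 5)
  expect_true(all(cc0$output_V == 0))
  lin <- calibration_curve(tr_lens, 1e-9, 1e-8, n_points = 10,
                           spacing = "linear")
  expect_equal(diff(lin$concentration_M),
               rep(1e-9, 9), tolerance = 1e-9)
})

test_that("log-log slope of the thin-regime calibration curve is unity", {
  for (tr in list(tr_lens, tr_film)) {
    cc <- calibration_curve(tr, 1e-12, 1e-9, n_points = 25, clip = FALSE)
    fit <- stats::lm(log10(output_V) ~ log10(concentration_M), data = cc)
    expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 1e-3)
  }
})

test_that("molecule counts use the interrogated (illuminated and viewed) volume", {
  vol_lens <- interrogated_volume(tr_lens)
  # illuminated stripe of the channel, not the whole channel volume
  expect_lt(vol_lens, sample_volume(tr_lens$sample))
  cc <- calibration_curve(tr_lens, 1e-9, 1e-8, n_points = 3)
  expect_equal(cc$molecule_count,
               cc$concentration_M * vol_lens * 6.022e23)
  # coaxial interrogates the whole channel
  expect_equal(interrogated_volume(tr_coax), sample_volume(tr_coax$sample))
})

test_that("bisection MDL matches the closed form and responds to noise and power", {
  tr <- linear_film_train()
  mdl <- find_mdl(tr)
  slope <- signal_at_concentration(tr, 1e-12, clip = FALSE)$volts / 1e-12
  expect_equal(mdl, tr$detector$noise_floor / slope, tolerance = 1e-3)
  expect_equal(find_mdl(tr, noise_floor = tr$detector$noise_floor / 2),
               mdl / 2, tolerance = 1e-3)
  # more source power, lower detection limit (strictly monotone sweep)
  mdls <- vapply(c(0.01, 0.05, 0.25), function(p)
    find_mdl(linear_film_train(power = p)), numeric(1))
  expect_true(all(diff(mdls) < 0))
})

test_that("an unreachable noise floor is reported, not invented", {
  faint <- example_components()
  faint$sources$led_blue_10$power <- 1e-15
  tr <- example_train("coaxial", "microchannel", "led_blue_10", "sipm",
                      components = faint)
  expect_true(is.na(find_mdl(tr)))
  expect_error(dynamic_range(tr), "not crossed")
})

test_that("dynamic range is the electronic ratio for a linear train and larger with curvature", {
  lin <- linear_film_train()            # saturates while optically thin
  dr <- dynamic_range(lin)
  expect_equal(as.numeric(dr), lin$detector$saturation /
                 lin$detector$noise_floor, tolerance = 1e-3)
  expect_equal(as.numeric(dynamic_range(lin,
                                        noise_floor = 0.1, saturation = 0.1)), 1)
  # exact exponential: the curve flattens, the range stretches
  dr_lens <- dynamic_range(tr_lens)
  expect_gt(as.numeric(dr_lens),
            tr_lens$detector$saturation / tr_lens$detector$noise_floor)
  expect_equal(as.numeric(dr_lens),
               attr(dr_lens, "c_max_M") / attr(dr_lens, "mdl_M"))
  # coaxial capture plateaus below saturation: open-ended range upwards,
  # reported with the optical asymptote
  dr_coax <- dynamic_range(tr_coax)
  expect_identical(as.numeric(dr_coax), Inf)
  expect_lt(attr(dr_coax, "asymptote_V"), tr_coax$detector$saturation)
})

test_that("normalised sensitivities recover the known exponents", {
  expect_equal(sensitivity(tr_lens, "source.power", 1e-8), 1,
               tolerance = 1e-6)
  expect_equal(sensitivity(tr_lens, "sample.analyte.quantum_yield", 1e-8), 1,
               tolerance = 1e-6)
  expect_equal(sensitivity(tr_lens, "collection.x3", 1e-8), -2,
               tolerance = 1e-5)
  expect_equal(sensitivity(tr_lens, "amplifier.amplification", 1e-8), 1,
               tolerance = 1e-6)
  expect_error(sensitivity(tr_lens, "no.such.knob", 1e-8), "not found")
})

test_that("design sweeps agree with direct solves and survive broken rows", {
  one <- design_sweep(list(tr_lens))
  expect_equal(one$mdl_M, find_mdl(tr_lens), tolerance = 1e-6)
  broken <- tr_lens
  broken$detector <- "not a detector"
  tab <- design_sweep(list(tr_lens, broken))
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$mdl_M[1]))
  expect_true(is.na(tab$mdl_M[2]))
  expect_match(tab$error[2], "detector")
})

test_that("inconsistent trains fail validation with the violated constraint named", {
  cm <- example_components()
  expect_error(
    optical_train(cm$sources$led_blue_10,
                  coupling_fiber(cm$fiber_air, 0.1), cm$film,
                  coupling_fiber(cm$fiber_water, 0.05), cm$filter,
                  cm$detectors$sipm, geometry = "coaxial"),
    "microchannel")
  expect_error(
    optical_train(cm$sources$led_blue_10,
                  coupling_lens(cm$lens, x1 = 1.0), cm$channel,
                  coupling_lens(cm$lens, x3 = 1.5), cm$filter,
                  cm$detectors$sipm),
    "focal length")
  expect_error(
    optical_train(cm$sources$led_blue_10,
                  coupling_lens(cm$lens), cm$channel,
                  coupling_lens(cm$lens, x3 = 1.5), cm$filter,
                  cm$detectors$sipm),
    "x1")
})
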