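# Instrument models: skin-safe power, fiber modes, detector limits,
# illumination strategies and flux calibration.

test_that("ANSI-limited power matches the reference hardware values", {
  expect_equal(signif(ansi_limited_power(850, 3.5), 2), 38)
  expect_equal(ansi_limited_power(1064, 3.5), 96.2, tolerance = 1e-3)
  # area scaling
  expect_equal(ansi_limited_power(850, 7) / ansi_limited_power(850, 3.5), 4)
  expect_error(ansi_limited_power(650), "unsupported band")
  expect_error(ansi_limited_power(1500), "unsupported band")
})

test_that("LP-mode counting matches the reference fibers", {
  expect_equal(count_guided_modes(fiber_preset("fmf_smf28"), 850), 12)
  expect_equal(count_guided_modes(fiber_preset("fmf_smf28"), 1064), 6)
  expect_equal(count_guided_modes(fiber_preset("smf_780hp"), 850), 2)
  # any fiber below the first cutoff guides exactly one spatial mode
  for (d in c(3, 4, 5)) {
    f <- fiber_model("test", d, 0.12)
    V <- pi * d * 0.12 / 0.85
    if (V < 2.405) expect_equal(count_guided_modes(f, 850), 2)
  }
})

test_that("bundle mode estimate matches V^2/2 arithmetic and scalings", {
  bundle <- fiber_preset("bundle_scos")
  n850 <- bundle_mode_count(bundle, 850)
  expect_equal(n850, 1.48e7, tolerance = 0.01)
  # linear in fiber count
  half <- fiber_model("half", 50, 0.66, n_fibers = 1000)
  expect_equal(bundle_mode_count(half, 850) * 2, n850)
  # V ~ 1/lambda
  expect_equal(bundle_mode_count(bundle, 1064) / n850, (850 / 1064)^2,
               tolerance = 1e-12)
})

test_that("minimum speckle-to-pixel ratio follows the mode budget", {
  n_modes <- bundle_mode_count(fiber_preset("bundle_scos"), 850)
  expect_equal(min_speckle_to_pixel(2.5e6, n_modes), 0.41, tolerance = 0.01)
  expect_equal(min_speckle_to_pixel(1e6, 1e6), 1)
  expect_equal(min_speckle_to_pixel(4e6, 1e6) / min_speckle_to_pixel(1e6, 1e6), 2)
})

test_that("saturation limits come from the hold-off reciprocal", {
  expect_equal(signif(saturation_limit(22e-9), 2), 4.5e7)
  expect_equal(signif(saturation_limit(33e-9), 2), 3.0e7)
  expect_equal(saturation_limit(11e-9), 2 * saturation_limit(22e-9))
  expect_identical(saturation_limit(0), Inf)
})

test_that("detector presets carry the reference hardware parameters", {
  spad <- detector_preset("dcs_850_sispad", dark_count_rate = 1500)
  expect_equal(spad$quantum_efficiency, 0.55)
  expect_equal(spad$dark_count_rate, 1500)
  expect_equal(spad$hold_off, 22e-9)
  snspd <- detector_preset("dcs_1064_snspd")
  expect_equal(snspd$quantum_efficiency, 0.90)
  expect_equal(snspd$dark_count_rate, 0)
  expect_equal(snspd$hold_off, 33e-9)
  cmos <- detector_preset("scos_850_cmos")
  expect_equal(cmos$quantum_efficiency, 0.20)
  expect_equal(cmos$read_noise, 2.5)
  expect_equal(cmos$max_frame_rate, 150)
  expect_equal(cmos$n_pixels, 2.5e6)
  # critical exposure implied by the frame-rate ceiling
  expect_equal(1 / cmos$max_frame_rate, 6.67e-3, tolerance = 1e-3)
})

test_that("illumination plans implement the four delivery strategies", {
  l850 <- laser_preset("laser_850")
  l1064 <- laser_preset("laser_1064")
  expect_equal(l850$max_output_power_mw / l850$ansi_power_mw, 7.9, tolerance = 0.01)
  expect_equal(l1064$max_output_power_mw / l1064$ansi_power_mw, 10)

  cw <- illumination_plan("cw_single", l850, "dcs")
  expect_equal(cw$instantaneous_power, 38)
  expect_equal(cw$duty_cycle, 1)

  multi <- illumination_plan("cw_multi", l1064, "dcs")
  expect_equal(multi$n_sources, 10L)
  expect_equal(multi$instantaneous_power, 100)

  # the 850 nm laser supports up to 8 sub-ANSI spots via the override
  multi8 <- illumination_plan("cw_multi", l850, "dcs", n_sources = 8)
  expect_equal(multi8$n_sources, 8L)
  expect_lte(multi8$instantaneous_power, 38)

  pulsed_dcs <- illumination_plan("pulsed_frame_limited", l850, "dcs")
  expect_equal(pulsed_dcs$duty_cycle, 38 / 300, tolerance = 1e-12)
  expect_equal(pulsed_dcs$instantaneous_power, 300)
  expect_equal(pulsed_dcs$instantaneous_power * pulsed_dcs$duty_cycle, 38)

  # continuous-illumination limit of the power-limited pulsed plan
  pp <- illumination_plan("pulsed_power_limited", l850, "scos",
                          t_exp = 1 / 150, camera_max_fps = 150)
  expect_equal(pp$duty_cycle, 1, tolerance = 1e-12)
  expect_equal(pp$instantaneous_power, 38, tolerance = 1e-12)

  pf <- illumination_plan("pulsed_frame_limited", l850, "scos",
                          t_exp = 1e-3, camera_max_fps = 150)
  expect_equal(pf$instantaneous_power, 300)
  expect_equal(pf$effective_frame_rate, 38 / (300 * 1e-3), tolerance = 1e-12)

  expect_error(illumination_plan("pulsed_power_limited", l850, "scos"),
               "t_exp")
  # every plan satisfies the average-power constraint by construction
  for (st in c("cw_single", "cw_multi", "pulsed_frame_limited")) {
    p <- illumination_plan(st, l850, "scos", t_exp = 2e-3, camera_max_fps = 150)
    expect_lte(p$instantaneous_power * p$duty_cycle, l850$ansi_power_mw + 1e-9)
  }
})

test_that("photon flux per mode is anchored to the calibration and scales with power", {
  run <- homogeneous_run()
  l850 <- laser_preset("laser_850")
  calib <- flux_calibration(850)
  cw <- illumination_plan("cw_single", l850, "dcs")
  expect_equal(photon_flux_per_mode(25, run$reflectance, calib, cw), 10e3)
  pulsed <- illumination_plan("pulsed_frame_limited", l850, "dcs")
  expect_equal(photon_flux_per_mode(25, run$reflectance, calib, pulsed),
               10e3 * 300 / 38)
  # throughput penalty is a plain multiplier
  expect_equal(photon_flux_per_mode(25, run$reflectance, calib, cw,
                                    per_mode_throughput_factor = 1 / 9),
               10e3 / 9)
  # non-increasing in separation for a diffuse reflectance curve
  flux <- vapply(c(10, 15, 25, 40), function(s) {
    photon_flux_per_mode(s, run$reflectance, calib, cw)
  }, numeric(1))
  expect_true(all(diff(flux) < 0))
  expect_error(photon_flux_per_mode(60, run$reflectance, calib, cw),
               "outside")
  # 1064 calibration preset
  expect_equal(flux_calibration(1064)$cps_per_mode_at_reference, 67.1e3)
})
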