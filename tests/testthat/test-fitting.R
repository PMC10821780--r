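# Blood flow index inversion for both modalities.

test_that("decay-rate estimation is exact on the generating model", {
  tau <- tau_grid_multitau(tau_max = 5e-3, include_zero = TRUE)
  g2 <- correlation_curve(tau, 1 + 0.5 * exp(-1e4 * tau), "intensity_g2",
                          beta = 0.5)
  expect_equal(estimate_decay_rate(g2, 0.5), 1e4, tolerance = 1e-3)
  # beta profiled out when not supplied
  expect_equal(estimate_decay_rate(g2, beta = NULL), 1e4, tolerance = 1e-3)
  flat <- correlation_curve(tau, rep(1.001, length(tau)), "intensity_g2",
                            beta = 0.5)
  expect_error(estimate_decay_rate(flat, 0.5), "no visible decay")
})

test_that("decay-rate estimation is unbiased under additive noise", {
  tau <- tau_grid_multitau(tau_max = 5e-3, include_zero = TRUE)
  clean <- 1 + 0.5 * exp(-1e4 * tau)
  set.seed(77)
  gammas <- vapply(1:100, function(i) {
    noisy <- clean + rnorm(length(tau), sd = 0.01)
    estimate_decay_rate(correlation_curve(tau, noisy, "intensity_g2",
                                          beta = 0.5), 0.5)
  }, numeric(1))
  expect_lt(abs(mean(gammas) / 1e4 - 1), 0.02)
})

test_that("the g2 decay rate is near-linear in the flow index", {
  geom <- semi_infinite_geometry(25, fitting_optical_properties(850), 850)
  tau <- tau_grid_multitau(tau_max = 1e-2, include_zero = TRUE)
  g_of <- function(bfi) {
    g2 <- siegert_g2(semi_infinite_g1(geom, bfi, tau), 0.5)
    estimate_decay_rate(g2, 0.5)
  }
  expect_equal(g_of(1.2e-8) / g_of(6e-9), 2, tolerance = 0.10)
})

test_that("fit-range cutoff follows the decay amplitude definition", {
  tau <- tau_grid_multitau(tau_max = 5e-3, include_zero = TRUE)
  g2 <- correlation_curve(tau, 1 + 0.5 * exp(-1e4 * tau), "intensity_g2",
                          beta = 0.5)
  expect_equal(fit_range_cutoff(g2, 1), max(tau))
  t_half <- fit_range_cutoff(g2, 0.5)
  # nearest grid point at or past ln(2)/Gamma
  expect_gte(t_half, log(2) / 1e4)
  expect_lt(t_half, log(2) / 1e4 * 1.3)
  fr <- seq(0.1, 1, by = 0.1)
  cuts <- vapply(fr, function(f) fit_range_cutoff(g2, f), numeric(1))
  expect_true(all(diff(cuts) >= 0))
  expect_error(fit_range_cutoff(g2, 0), "fraction")
})

test_that("forward-inverse identity holds for DCS fits", {
  settings <- fit_settings(fitting_optical_properties(850), 850, beta = 0.5)
  tau <- tau_grid_multitau(tau_max = 5e-2, include_zero = TRUE)
  for (sds in c(5, 15, 25, 40)) {
    geom <- semi_infinite_geometry(sds, settings$optics, 850)
    for (bfi in c(1e-9, 1e-8, 1e-7, 1e-6)) {
      g2 <- siegert_g2(semi_infinite_g1(geom, bfi, tau), 0.5)
      fit <- fit_bfi_from_g2(g2, settings, geom)
      expect_true(fit$converged)
      expect_equal(fit$bfi, bfi, tolerance = 1e-3)
    }
  }
})

test_that("noisy-ensemble DCS fits are unbiased at high count rates", {
  settings <- fit_settings(fitting_optical_properties(850), 850, beta = 0.5)
  geom <- semi_infinite_geometry(20, settings$optics, 850)
  tau <- tau_grid_multitau(tau_max = 1e-2, include_zero = TRUE)
  g2 <- siegert_g2(semi_infinite_g1(geom, 6e-8, tau), 0.5)
  gamma <- estimate_decay_rate(g2, 0.5)
  sigma <- dcs_noise_sigma(dcs_noise_params(1e-6, 0.1, 0.5, gamma, 1), tau)
  reals <- gaussian_noise_realizations(g2, sigma, 100, seed = 9)
  fits <- apply(reals, 2, function(y) {
    fit_bfi_from_g2(correlation_curve(tau, y, "intensity_g2", beta = 0.5),
                    settings, geom)$bfi
  })
  expect_lt(abs(mean(fits) / 6e-8 - 1), 0.02)
})

test_that("MC-generated curves are inverted close to the ground truth", {
  run <- homogeneous_run()
  tau <- tau_grid_multitau(tau_max = 1e-2, include_zero = TRUE)
  det <- which(run$histories$detectors$sds_mm == 25)
  g1 <- g1_from_histories(run$histories, list(tissue = scalp_optics()),
                          flow_state(c(tissue = 1e-8)), tau, det)
  settings <- fit_settings(scalp_optics(), 850, beta = 0.5)
  fit <- fit_bfi_from_g2(siegert_g2(g1, 0.5), settings, sds_mm = 25)
  expect_equal(fit$bfi, 1e-8, tolerance = 0.05)
})

test_that("forward-inverse identity holds for SCOS contrast fits", {
  settings <- fit_settings(fitting_optical_properties(850), 850, beta = 0.25)
  for (sds in c(5, 25, 40)) {
    geom <- semi_infinite_geometry(sds, settings$optics, 850)
    for (bfi in c(1e-9, 1e-7)) for (te in c(1e-5, 1e-3, 2e-2)) {
      kf2 <- speckle_contrast_from_g1(
        function(u) semi_infinite_g1_values_for_test(geom, bfi, u), 0.25, te)
      fit <- fit_bfi_from_contrast(data.frame(t_exp = te, kf2 = kf2),
                                   settings, geom)
      expect_true(fit$converged)
      expect_equal(fit$bfi, bfi, tolerance = 1e-3)
    }
  }
})

test_that("the contrast forward map is strictly decreasing in flow", {
  geom <- semi_infinite_geometry(25, fitting_optical_properties(850), 850)
  kf2s <- vapply(10^seq(-9, -6, by = 0.5), function(bfi) {
    speckle_contrast_from_g1(
      function(u) semi_infinite_g1_values_for_test(geom, bfi, u), 0.25, 1e-3)
  }, numeric(1))
  expect_true(all(diff(kf2s) < 0))
})

test_that("contrast perturbations move the fitted flow the opposite way", {
  settings <- fit_settings(fitting_optical_properties(850), 850, beta = 0.25)
  geom <- semi_infinite_geometry(25, settings$optics, 850)
  kf2 <- speckle_contrast_from_g1(
    function(u) semi_infinite_g1_values_for_test(geom, 6e-8, u), 0.25, 1e-3)
  up <- fit_bfi_from_contrast(data.frame(t_exp = 1e-3, kf2 = kf2 * 1.05),
                              settings, geom)
  down <- fit_bfi_from_contrast(data.frame(t_exp = 1e-3, kf2 = kf2 * 0.95),
                                settings, geom)
  expect_lt(up$bfi, 6e-8)
  expect_gt(down$bfi, 6e-8)
  expect_error(
    fit_bfi_from_contrast(data.frame(t_exp = 1e-3, kf2 = 0.3), settings, geom),
    "out of range"
  )
})

test_that("ensemble CoV of contrast fits matches first-order error propagation", {
  settings <- fit_settings(fitting_optical_properties(850), 850, beta = 0.25)
  geom <- semi_infinite_geometry(25, settings$optics, 850)
  bfi0 <- 6e-8; te <- 1e-3
  model <- function(bfi) {
    speckle_contrast_from_g1(
      function(u) semi_infinite_g1_values_for_test(geom, bfi, u), 0.25, te)
  }
  kf2 <- model(bfi0)
  sigma <- 0.02 * kf2
  set.seed(61)
  fits <- vapply(1:100, function(i) {
    obs <- kf2 + rnorm(1, sd = sigma)
    fit_bfi_from_contrast(data.frame(t_exp = te, kf2 = obs), settings, geom)$bfi
  }, numeric(1))
  cov_emp <- sd(fits) / mean(fits)
  deriv <- (model(bfi0 * 1.01) - model(bfi0 * 0.99)) / (0.02 * bfi0)
  cov_pred <- sigma / abs(deriv) / bfi0
  expect_equal(cov_emp, cov_pred, tolerance = 0.25)
})
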