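# Analytic forward models: effective reflection coefficient, semi-infinite
# field autocorrelation, Siegert relation, exposure-integrated contrast, and
# the history-based autocorrelation.

test_that("effective reflection coefficient matches the polynomial and is monotone", {
  expect_equal(effective_reflection_coefficient(1.0), 0.0016, tolerance = 1e-12)
  expect_equal(effective_reflection_coefficient(1.4), 0.5295, tolerance = 2e-4)
  n <- seq(1, 1.6, by = 0.01)
  expect_true(all(diff(effective_reflection_coefficient(n)) > 0))
  expect_error(effective_reflection_coefficient(0.9), "refractive index")
})

test_that("semi-infinite geometry satisfies its invariants", {
  geom <- semi_infinite_geometry(25, optical_properties(0.15, 8.5, 1.4), 850)
  expect_gte(geom$r1, geom$rho)
  expect_gt(geom$r_b, geom$r1)
  expect_gt(geom$R_eff, 0)
  expect_lt(geom$R_eff, 1)
  expect_equal(geom$r1, sqrt(geom$rho^2 + geom$l_star^2))
  expect_equal(geom$r_b, sqrt(geom$rho^2 + (geom$l_star + 2 * geom$z_b)^2))
})

test_that("semi-infinite g1 reproduces an independent high-precision evaluation", {
  # frozen values from an arbitrary-precision (50-digit) transcription of the
  # semi-infinite correlation diffusion solution at rho = 2.5 cm,
  # mu_a = 0.15 /cm, mu_s' = 8.5 /cm, n = 1.4, 850 nm, BFi = 6e-8 cm^2/s
  geom <- semi_infinite_geometry(25, optical_properties(0.15, 8.5, 1.4), 850)
  got <- semi_infinite_g1(geom, 6e-8, c(0, 1e-6, 1e-5, 1e-4))
  expect_identical(got$values[1], 1)          # exact at zero delay
  expect_equal(got$values[2], 0.86217419401904540, tolerance = 1e-10)
  expect_equal(got$values[3], 0.26455767298902091, tolerance = 1e-10)
  expect_equal(got$values[4], 0.00022914712420608092, tolerance = 1e-8)
})

test_that("semi-infinite g1 limits and validation behave", {
  geom <- semi_infinite_geometry(25, optical_properties(0.15, 8.5, 1.4), 850)
  # large BFi at fixed tau drives g1 to zero
  expect_lt(semi_infinite_g1(geom, 1e-3, 1e-4)$values, 1e-12)
  # monotone decreasing in tau for positive flow
  tau <- tau_grid_multitau(include_zero = TRUE, tau_max = 1e-3)
  vals <- semi_infinite_g1(geom, 6e-8, tau)$values
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(semi_infinite_g1(geom, NaN, tau), "bfi")
  expect_error(semi_infinite_g1(geom, 6e-8, c(-1e-6, 1e-6)), "tau")
})

test_that("Siegert relation maps field to intensity correlation", {
  tau <- c(0, 1e-5, 1e-4)
  g1 <- correlation_curve(tau, c(1, 0.5, 0), "field_g1")
  g2 <- siegert_g2(g1, 0.5)
  expect_equal(g2$values, c(1.5, 1.125, 1))
  expect_true(all(g2$values >= 1 & g2$values <= 1.5))
  # single-exponential field decay gives g2 - 1 = beta exp(-2 Gamma tau)
  tau <- seq(0, 5e-4, length.out = 60)
  gam <- 8e3
  g2e <- siegert_g2(correlation_curve(tau, exp(-gam * tau), "field_g1"), 0.4)
  expect_equal(g2e$values, 1 + 0.4 * exp(-2 * gam * tau), tolerance = 1e-12)
  expect_error(siegert_g2(correlation_curve(tau, exp(-gam * tau), "field_g1"), 1.2),
               "beta")
  expect_error(siegert_g2(g2e, 0.5), "field g1")
})

test_that("exposure-integrated contrast matches the single-exponential closed form", {
  gam <- 1e4
  for (x in 10^seq(-3, 3, by = 1)) {
    t_exp <- x / gam
    kf2 <- speckle_contrast_from_g1(function(u) exp(-gam * u), 1, t_exp)
    exact <- (exp(-2 * x) + 2 * x - 1) / (2 * x^2)
    expect_equal(kf2, exact, tolerance = 1e-5)
  }
  # short-exposure limit approaches beta
  expect_equal(speckle_contrast_from_g1(function(u) exp(-gam * u), 0.3, 1e-9),
               0.3, tolerance = 1e-4)
  # monotone non-increasing in exposure for a decaying correlation
  kf2s <- vapply(10^seq(-5, -2, by = 0.5), function(te) {
    speckle_contrast_from_g1(function(u) exp(-gam * u), 0.5, te)
  }, numeric(1))
  expect_true(all(diff(kf2s) < 0))
  expect_error(speckle_contrast_from_g1(function(u) exp(-u), 0.5, -1), "t_exp")
})

test_that("contrast integral accepts a curve and extends it by zero", {
  gam <- 1e4
  tau <- tau_grid_multitau(first_bin = 1e-7, tau_max = 2e-3, include_zero = TRUE)
  curve <- correlation_curve(tau, exp(-gam * tau), "field_g1")
  for (te in c(1e-4, 1e-2)) {  # second exposure extends past the grid end
    x <- gam * te
    exact <- (exp(-2 * x) + 2 * x - 1) / (2 * x^2)
    expect_equal(speckle_contrast_from_g1(curve, 1, te), exact, tolerance = 1e-3)
  }
})

test_that("history-based g1 is normalized and matches the degenerate closed form", {
  # all photons identical: single tissue, constant Y and L
  k <- 2 * pi * 1.4 / (850e-7)
  tab <- parametric_histories(list(tissue = list(L = 5, Y = 40)), n_rows = 50,
                              seed = 1)
  g1 <- g1_from_histories(tab, list(tissue = optical_properties(0.164, 7.4, 1.4)),
                          flow_state(c(tissue = 1e-8)),
                          c(0, 1e-5, 1e-4), 1)
  expect_identical(g1$values[1], 1)
  expect_equal(g1$values[-1], exp(-2 * k^2 * 40 * 1e-8 * c(1e-5, 1e-4)),
               tolerance = 1e-12)
  # absorption cancels in the normalization: changing mu_a leaves g1 unchanged
  g1b <- g1_from_histories(tab, list(tissue = optical_properties(0.8, 7.4, 1.4)),
                           flow_state(c(tissue = 1e-8)), c(0, 1e-5, 1e-4), 1)
  expect_equal(g1$values, g1b$values, tolerance = 1e-12)
})

test_that("history-based g1 validates inputs", {
  tab <- parametric_histories(list(tissue = list(L = 5, Y = 40)), 10, seed = 1)
  fl <- flow_state(c(tissue = 1e-8))
  op <- list(tissue = optical_properties(0.1, 8, 1.4))
  expect_error(g1_from_histories(tab, op, fl, c(0, 1e-5), 2), "no detected photons")
  expect_error(g1_from_histories(tab, list(other = op$tissue), fl, c(0, 1e-5), 1),
               "missing labels")
  expect_error(
    g1_from_histories(tab, op, flow_state(c(other = 1e-8)), c(0, 1e-5), 1),
    "missing labels"
  )
})

test_that("a perturbed brain flow lowers g1 pointwise", {
  run <- head_run(15)
  tau <- tau_grid_multitau(include_zero = TRUE, tau_max = 1e-2)
  det <- which(run$histories$detectors$sds_mm == 25)
  g1b <- g1_from_histories(run$histories, tissue_optics(), baseline_flow(),
                           tau, det)
  g1p <- g1_from_histories(run$histories, tissue_optics(), perturbed_flow(),
                           tau, det)
  expect_true(all(g1p$values[-1] < g1b$values[-1]))
})
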