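# Speckle contrast noise: shot/read/dark terms, the dynamic speckle
# simulator, and the measured-contrast statistics.

test_that("shot, read and dark contrast terms follow variance propagation", {
  got <- shot_read_dark_contrast(100, 2.5, 0)
  expect_equal(got$ks2, 0.01)
  expect_equal(got$kr2, 6.25e-4)
  expect_equal(got$kd2, 0)
  for (pe in c(3, 50, 2000)) {
    expect_equal(shot_read_dark_contrast(pe)$ks2 * pe, 1)
  }
  expect_error(shot_read_dark_contrast(0), "mean_pe")
  # synthetic flat field: Poisson + Gaussian read noise variance reproduces
  # ks2 + kr2
  set.seed(17)
  pe <- 200; read <- 3
  frame <- stats::rpois(2e5, pe) + stats::rnorm(2e5, sd = read)
  expect_equal(var(frame) / mean(frame)^2, 1 / pe + read^2 / pe^2,
               tolerance = 0.03)
})

test_that("contrast budget sums its terms and validates", {
  b <- speckle_contrast_budget(1e-3, 0.04, 0.01, 6e-4)
  expect_equal(b$k2_total, 0.04 + 0.01 + 6e-4)
  expect_error(speckle_contrast_budget(1e-3, -0.1), "finite and >= 0")
})

test_that("static fully developed speckle has near-unit contrast at large s/p", {
  st <- speckle_field_sequence(function(u) rep(1, length(u)), s_over_p = 8,
                               grid_size = 128, substeps = 12, dt = 1,
                               seed = 3, polarized = TRUE)
  K <- sqrt(mean(apply(st$frames, 2, k2_stat)))
  expect_equal(K, 1, tolerance = 0.08)
  st2 <- speckle_field_sequence(function(u) rep(1, length(u)), s_over_p = 2,
                                grid_size = 128, substeps = 12, dt = 1,
                                seed = 3, polarized = TRUE)
  K2 <- sqrt(mean(apply(st2$frames, 2, k2_stat)))
  expect_equal(K2, 1, tolerance = 0.1)
})

test_that("substep field evolution reproduces the target correlation", {
  # intensity (Pearson) correlation between substeps equals |g1|^2 for
  # circular Gaussian speckle
  gam <- 1e3
  dt <- 5e-5
  st <- speckle_field_sequence(gam, s_over_p = 4, grid_size = 32,
                               substeps = 400, dt = dt, seed = 5,
                               polarized = TRUE)
  fr <- st$frames
  lags <- c(1, 4, 10)
  for (lag in lags) {
    n <- ncol(fr) - lag
    cc <- mean(vapply(seq(1, n, by = 3), function(i) {
      stats::cor(fr[, i], fr[, i + lag])
    }, numeric(1)))
    expect_equal(sqrt(max(cc, 0)), exp(-gam * lag * dt), tolerance = 0.05)
  }
  # determinism
  st2 <- speckle_field_sequence(gam, s_over_p = 4, grid_size = 32,
                                substeps = 400, dt = dt, seed = 5,
                                polarized = TRUE)
  expect_identical(st$frames, st2$frames)
})

test_that("integrated exposures reproduce the exposure-weighted contrast integral", {
  gam <- 1e4
  beta <- speckle_beta(1)
  for (r in c(0.1, 1, 10, 100)) {
    te <- r / gam
    nsub <- min(512, max(8, ceiling(8 * te * gam)))
    st <- speckle_field_sequence(gam, s_over_p = 1, grid_size = 32,
                                 substeps = nsub * 32, dt = te / nsub,
                                 seed = 7, substeps_per_exposure = nsub)
    ms <- measured_contrast_stats(st, te, photon_scale = 1e6)
    pred <- speckle_contrast_from_g1(function(u) exp(-gam * u), beta, te)
    expect_equal(ms$budget$kf2, pred, tolerance = 0.05)
  }
})

test_that("independent-observation count approaches 0.95 per pixel at s/p = 0.4", {
  stack <- speckle_field_sequence(function(u) ifelse(u == 0, 1, 0),
                                  s_over_p = 0.4, grid_size = 32,
                                  substeps = 800, dt = 1, seed = 11,
                                  polarized = FALSE)
  kf2 <- apply(stack$frames, 2, k2_stat)
  nio <- 2 * mean(kf2)^2 / var(kf2)
  expect_equal(nio / 32^2, 0.95, tolerance = 0.10)
})

test_that("contrast noise reaches the fundamental floor at high flux", {
  gam <- 5e3
  nsub <- 16
  st <- speckle_field_sequence(gam, s_over_p = 1, grid_size = 32,
                               substeps = nsub * 64, dt = 1e-4 / nsub,
                               seed = 13, substeps_per_exposure = nsub)
  fundamental <- sd(apply(st$frames / mean(st$frames), 2, k2_stat))
  high <- measured_contrast_stats(st, 1e-4, photon_scale = 1e7, seed = 2)
  low <- measured_contrast_stats(st, 1e-4, photon_scale = 2, seed = 2)
  expect_equal(high$sigma_k2, fundamental, tolerance = 0.05)
  expect_gt(low$sigma_k2, 2 * fundamental)
})

test_that("the spread of the mean contrast scales as one over sqrt(frames)", {
  stack <- speckle_field_sequence(function(u) ifelse(u == 0, 1, 0),
                                  s_over_p = 1, grid_size = 24,
                                  substeps = 1024, dt = 1, seed = 19,
                                  polarized = FALSE)
  kf2 <- apply(stack$frames, 2, k2_stat)
  sizes <- c(2, 8, 32)
  spread <- vapply(sizes, function(f) {
    groups <- matrix(kf2[seq_len(1024 - 1024 %% f)], nrow = f)
    sd(colMeans(groups))
  }, numeric(1))
  slope <- coef(lm(log(spread) ~ log(sizes)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("empirical beta decreases with speckle-to-pixel averaging", {
  b <- vapply(c(0.41, 1, 2), speckle_beta, numeric(1))
  expect_true(all(diff(b) > 0))
  expect_lt(b[1], 0.1)   # heavy per-pixel averaging
  expect_gt(b[3], 0.4)   # approaching the unpolarized two-mode ceiling 0.5
  expect_lte(b[3], 0.55)
})
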