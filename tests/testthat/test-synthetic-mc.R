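# Layered-slab Monte Carlo and the parametric history generator.

test_that("photon accounting is conserved", {
  # every launched photon either escapes the top surface or is terminated by
  # the pathlength (implicit-weight) cutoff
  geom <- slab_geometry(
    data.frame(tissue = "tissue", thickness_mm = Inf),
    data.frame(id = 1, sds_mm = 10, radius_mm = 10, na = 1)
  )
  run <- run_layered_mc(geom, list(tissue = optical_properties(0.164, 7.4, 1.4)),
                        2e4, seed = 7)
  acc <- run$accounting
  expect_equal(acc$exit_count_fraction + acc$terminated_fraction, 1,
               tolerance = 1e-12)
  expect_lte(acc$exit_weight_fraction, acc$exit_count_fraction)
  expect_true(all(run$reflectance$detected_fraction >= 0 &
                    run$reflectance$detected_fraction <= 1))
})

test_that("isotropic scattering gives unit momentum transfer per unit optical depth", {
  # E[1 - cos(theta)] = 1 per scattering event, and the expected number of
  # events per unit pathlength is mu_s', so E[Y] / E[L * mu_s'] -> 1
  run <- homogeneous_run()
  h <- run$histories
  ratio <- sum(h$Y) / (sum(h$L) * 7.4)
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("MC reflectance follows the semi-infinite diffusion-theory shape", {
  run <- homogeneous_run()
  op <- scalp_optics()
  # diffusion-theory reflectance (extrapolated boundary, two image sources)
  diffusion_R <- function(rho_cm) {
    mu_eff <- sqrt(3 * op$mu_a * op$mu_s_prime)
    l_star <- 1 / op$mu_s_prime
    Reff <- effective_reflection_coefficient(op$refractive_index)
    z_b <- (2 / (3 * op$mu_s_prime)) * (1 + Reff) / (1 - Reff)
    r1 <- sqrt(rho_cm^2 + l_star^2)
    r2 <- sqrt(rho_cm^2 + (l_star + 2 * z_b)^2)
    (1 / (4 * pi)) * (l_star * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
      (l_star + 2 * z_b) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
  }
  refl <- run$reflectance
  sel <- refl$sds_mm >= 10 / op$mu_s_prime * 10  # SDS >= 10 transport lengths
  ratio <- (refl$reflectance_per_mm2[sel] * 100) /  # per mm^2 -> per cm^2
    diffusion_R(refl$sds_mm[sel] / 10)
  # shape comparison: normalize out a global scale factor
  expect_true(all(abs(ratio / mean(ratio) - 1) < 0.15))
})

test_that("MC runs are reproducible and scale linearly in photon count", {
  geom <- slab_geometry(
    data.frame(tissue = "tissue", thickness_mm = Inf),
    data.frame(id = 1, sds_mm = 10, radius_mm = 1, na = 1)
  )
  op <- list(tissue = scalp_optics())
  r1 <- run_layered_mc(geom, op, 3e4, seed = 11)
  r2 <- run_layered_mc(geom, op, 3e4, seed = 11)
  expect_identical(r1$histories$L, r2$histories$L)
  expect_identical(r1$histories$Y, r2$histories$Y)
  r3 <- run_layered_mc(geom, op, 3e4, seed = 12)
  expect_false(identical(r1$histories$L, r3$histories$L))
  # detected count grows linearly in n_photons (within Poisson error)
  r4 <- run_layered_mc(geom, op, 1.2e5, seed = 13)
  n1 <- nrow(r1$histories$L); n4 <- nrow(r4$histories$L)
  expect_lt(abs(n4 - 4 * n1) / sqrt(n4 + 16 * n1), 5)
})

test_that("layered slab decorrelates slower than homogeneous brain at equal SDS", {
  # static superficial layers slow the overall decay relative to a medium
  # that is brain everywhere
  run <- head_run(15)
  tau <- tau_grid_multitau(include_zero = TRUE, tau_max = 1e-3)
  det <- which(run$histories$detectors$sds_mm == 25)
  g1_layered <- g1_from_histories(run$histories, tissue_optics(),
                                  baseline_flow(), tau, det)
  props <- head_tissue_properties(850)
  brain <- optical_properties(props$mu_a[4], props$mu_s_prime[4], 1.4)
  g1_brain <- semi_infinite_g1(semi_infinite_geometry(25, brain, 850), 6e-8, tau)
  mid <- tau > 1e-6 & g1_brain$values > 0.05
  expect_true(all(g1_layered$values[mid] > g1_brain$values[mid]))
})

test_that("parametric histories reproduce a quadrature oracle for exponential pathlengths", {
  # single tissue, L ~ Exp(mean s), Y = L * mu_s': g1 equals the normalized
  # Laplace transform of the pathlength density at the dynamic+static rate
  s_bar <- 3; musp <- 8; mua <- 0.15; bfi <- 1e-8
  k <- 2 * pi * 1.4 / 850e-7
  # joint sampler: Y = L * mu_s' row by row
  n <- 4e4
  set.seed(31)
  L <- stats::rexp(n, 1 / s_bar)
  tab <- photon_history_table(rep(1L, n), matrix(L), matrix(L * musp),
                              "tissue", n, 850,
                              data.frame(id = 1L, sds_mm = 25, radius_mm = 1,
                                         na = 1),
                              source = "synthetic-parametric")
  taus <- c(0, 1e-6, 1e-5, 5e-5)
  g1 <- g1_from_histories(tab, list(tissue = optical_properties(mua, musp, 1.4)),
                          flow_state(c(tissue = bfi)), taus, 1)
  oracle <- vapply(taus, function(t) {
    num <- stats::integrate(function(s) {
      exp(-s / s_bar) * exp(-(mua + 2 * k^2 * bfi * musp * t) * s)
    }, 0, Inf)$value
    den <- stats::integrate(function(s) exp(-s / s_bar) * exp(-mua * s),
                            0, Inf)$value
    num / den
  }, numeric(1))
  # MC sampling error at n = 4e4
  expect_equal(g1$values, oracle, tolerance = 0.02)
})

test_that("parametric histories are deterministic and validate", {
  spec <- list(a = list(L = function(n) stats::rexp(n, 2), Y = 3),
               b = list(L = 1, Y = function(n) stats::runif(n)))
  t1 <- parametric_histories(spec, 25, seed = 4)
  t2 <- parametric_histories(spec, 25, seed = 4)
  expect_identical(t1$L, t2$L)
  expect_identical(t1$Y, t2$Y)
  expect_equal(t1$source, "synthetic-parametric")
  expect_error(parametric_histories(spec, 0, seed = 1), "n_rows")
  bad <- list(a = list(L = function(n) rep(-1, n), Y = 1))
  expect_error(parametric_histories(bad, 5, seed = 1), ">= 0")
})

test_that("history tables round-trip through the text format", {
  run <- run_layered_mc(slab_head_model(15, sds_mm = c(10, 25)),
                        tissue_optics(), 2e4, seed = 3)
  tab <- run$histories
  path <- tempfile(fileext = ".tsv")
  write_history_table(tab, path)
  back <- read_history_table(path)
  expect_equal(back$L, tab$L, tolerance = 1e-15)
  expect_equal(back$Y, tab$Y, tolerance = 1e-15)
  expect_identical(back$detector_id, tab$detector_id)
  expect_identical(back$tissue_labels, tab$tissue_labels)
  expect_equal(back$n_launched, tab$n_launched)
  expect_equal(back$detectors$sds_mm, tab$detectors$sds_mm)
  # identical forward curves from the round-tripped table
  tau <- c(0, 1e-5, 1e-4)
  g_a <- g1_from_histories(tab, tissue_optics(), baseline_flow(), tau, 2)
  g_b <- g1_from_histories(back, tissue_optics(), baseline_flow(), tau, 2)
  expect_equal(g_a$values, g_b$values, tolerance = 1e-12)
})

test_that("malformed history files are rejected with a row reference", {
  tab <- parametric_histories(list(t1 = list(L = 2, Y = 5)), 4, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_history_table(tab, path)
  lines <- readLines(path)
  body_start <- max(grep("^#", lines)) + 2  # header row follows metadata
  lines[body_start + 1] <- "1\t-3.0\t5.0"
  writeLines(lines, path)
  expect_error(read_history_table(path), "row 2")
  # missing column
  write_history_table(tab, path)
  lines <- readLines(path)
  lines <- sub("\tY_t1$", "\tY_other", lines)
  writeLines(lines, path)
  expect_error(read_history_table(path), "missing columns")
})
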