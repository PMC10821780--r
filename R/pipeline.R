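#' Cerebral sensitivity of a blood-flow measurement
#'
#' Fraction of a true cerebral flow change recovered by the fitted index:
#' `(dBFi / BFi_baseline) / (dCBF / CBF_baseline)`.
#'
#' @param bfi_base,bfi_pert Fitted BFi means for the baseline and perturbed
#'   states.
#' @param cbf_base,cbf_pert True brain BFi in the two states (cm^2/s); the
#'   defaults are the baseline 6e-8 and the +20% activation 7.2e-8.
#' @return Sensitivity (dimensionless).
#' @export
sensitivity <- function(bfi_base, bfi_pert, cbf_base = 6e-8, cbf_pert = 7.2e-8) {
  if (bfi_base <= 0 || cbf_base <= 0) stop("baselines must be > 0")
  ((bfi_pert - bfi_base) / bfi_base) / ((cbf_pert - cbf_base) / cbf_base)
}

#' Coefficient of variation of a fitted ensemble
#'
#' Sample standard deviation divided by sample mean.
#'
#' @param fitted_bfi Numeric vector of fitted BFi values, length >= 2.
#' @return CoV (dimensionless).
#' @export
coefficient_of_variation <- function(fitted_bfi) {
  if (length(fitted_bfi) < 2) stop("ensemble must have at least 2 values")
  m <- mean(fitted_bfi)
  if (m <= 0) stop("invalid ensemble: mean must be > 0")
  stats::sd(fitted_bfi) / m
}

#' Contrast-to-noise ratio
#'
#' Ratio of cerebral sensitivity to the measurement CoV.
#'
#' @param sensitivity Sensitivity value.
#' @param cov Coefficient of variation; `cov = 0` yields `Inf` (flagged, not
#'   an error).
#' @return CNR (dimensionless).
#' @export
contrast_to_noise <- function(sensitivity, cov) {
  if (cov < 0) stop("cov must be >= 0")
  if (cov == 0) return(Inf)
  sensitivity / cov
}

#' Performance metrics container
#'
#' @param sensitivity,cov,cnr The three headline metrics.
#' @param bfi_base_mean,bfi_base_sd,bfi_pert_mean,bfi_pert_sd Ensemble
#'   statistics of the fitted BFi.
#' @param n_failed Number of excluded fits.
#' @param flags Named logical vector of condition flags.
#' @return An object of class `performance_metrics`. Acceptability flags
#'   follow the working thresholds: sensitivity >= 0.10, CoV <= 0.1, CNR >= 1.
#' @export
performance_metrics <- function(sensitivity, cov, cnr, bfi_base_mean,
                                bfi_base_sd, bfi_pert_mean, bfi_pert_sd,
                                n_failed = 0, flags = c()) {
  structure(list(
    sensitivity = sensitivity, cov = cov, cnr = cnr,
    bfi_base_mean = bfi_base_mean, bfi_base_sd = bfi_base_sd,
    bfi_pert_mean = bfi_pert_mean, bfi_pert_sd = bfi_pert_sd,
    n_failed = n_failed,
    sensitivity_ok = is.finite(sensitivity) && sensitivity >= 0.10,
    cov_ok = is.finite(cov) && cov <= 0.1,
    cnr_ok = !is.na(cnr) && cnr >= 1,
    flags = flags
  ), class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(
    "Performance: sensitivity %.3g [%s], CoV %.3g [%s], CNR %.3g [%s]\n",
    x$sensitivity, if (x$sensitivity_ok) "ok" else "low",
    x$cov, if (x$cov_ok) "ok" else "high",
    x$cnr, if (x$cnr_ok) "ok" else "low"
  ))
  if (length(x$flags) > 0 && any(x$flags)) {
    cat("  flags:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Measurement configuration
#'
#' Everything needed to evaluate one operating point of a DCS or SCOS system.
#'
#' @param technique `"dcs"` or `"scos"`.
#' @param sds_mm Source-detector separation (mm).
#' @param detector A [detector_model()].
#' @param laser A [laser_model()] (its wavelength fixes the tissue property
#'   set and flux calibration).
#' @param fiber A [fiber_model()]; used to derive the detected mode count.
#' @param strategy Laser delivery strategy (see [illumination_plan()]).
#' @param fit_fraction DCS: fraction of the g2 decay fitted.
#' @param t_exp SCOS: camera exposure time (s).
#' @param s_over_p SCOS: speckle-to-pixel size ratio.
#' @param n_modes Override the detected mode count (otherwise derived from the
#'   fiber: exact LP counting for single/few-mode fibers, V^2/2 per fiber for
#'   bundles).
#' @param sample_rate Output sample rate of the BFi time series (Hz).
#' @param n_realizations Noise realizations per flow state.
#' @param seed Root RNG seed for the configuration.
#' @param bin_width_T Correlator bin width (s) entering the DCS noise model.
#' @param per_mode_throughput_factor Optical throughput penalty on the
#'   per-mode flux (1 = lossless; 1/9 emulates a lossy camera coupling).
#' @param n_sources Optional source-count override for `cw_multi`.
#' @param scos_sim Options for the dynamic-speckle noise estimator: a list
#'   with `grid_size`, `n_frames`, `max_substeps`.
#' @return An object of class `measurement_config`.
#' @export
measurement_config <- function(technique = c("dcs", "scos"), sds_mm, detector,
                               laser, fiber = NULL, strategy = "cw_single",
                               fit_fraction = 1, t_exp = NULL, s_over_p = NULL,
                               n_modes = NULL, sample_rate = 10,
                               n_realizations = 100, seed = 1,
                               bin_width_T = 1e-6,
                               per_mode_throughput_factor = 1,
                               n_sources = NULL,
                               scos_sim = list()) {
  technique <- match.arg(technique)
  stopifnot(inherits(detector, "detector_model"), inherits(laser, "laser_model"))
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  wavelength_nm <- laser$wavelength_nm
  if (is.null(n_modes)) {
    if (is.null(fiber)) stop("provide a fiber or n_modes")
    n_modes <- if (fiber$n_fibers > 1) {
      bundle_mode_count(fiber, wavelength_nm)
    } else {
      count_guided_modes(fiber, wavelength_nm)
    }
  }
  if (technique == "dcs") {
    if (is.null(fit_fraction)) stop("fit_fraction is required for DCS")
  } else {
    if (is.null(t_exp) || is.null(s_over_p)) {
      stop("t_exp and s_over_p are required for SCOS")
    }
  }
  sim_defaults <- list(grid_size = 32, n_frames = 32, max_substeps = 1024)
  scos_sim <- utils::modifyList(sim_defaults, scos_sim)
  structure(list(
    technique = technique, wavelength_nm = wavelength_nm, sds_mm = sds_mm,
    detector = detector, laser = laser, fiber = fiber, strategy = strategy,
    fit_fraction = fit_fraction, t_exp = t_exp, s_over_p = s_over_p,
    n_modes = n_modes, sample_rate = sample_rate,
    n_realizations = n_realizations, seed = as.integer(seed),
    bin_width_T = bin_width_T,
    per_mode_throughput_factor = per_mode_throughput_factor,
    n_sources = n_sources, scos_sim = scos_sim
  ), class = "measurement_config")
}

#' Evaluate the performance of a measurement configuration
#'
#' Full pipeline for one operating point: history-based forward model for the
#' baseline and activated (+20% brain flow) states, absolute flux from the
#' calibrated reflectance curve and illumination plan, modality-specific noise
#' model, an ensemble of noisy realizations fitted for BFi with the assumed
#' homogeneous optics, and the sensitivity / CoV / CNR metrics.
#'
#' DCS: the Siegert g2 with `beta = 1/n_modes` (reduced by dark counts), the
#' analytic correlation noise model at the achieved count rate (capped at the
#' detector saturation limit) and averaging time `duty_cycle / sample_rate`,
#' Gaussian white noise realizations, semi-infinite fits over the configured
#' fraction of the decay.
#'
#' SCOS: the fundamental squared contrast at the configured exposure with the
#' empirical `beta(s/p)`, per-pixel photoelectrons from the flux and mode-to-
#' pixel allocation, the contrast-noise standard deviation from the dynamic
#' speckle simulator (rescaled to the camera's independent-observation count
#' and the number of frames averaged per output sample), Gaussian realizations
#' of the corrected Kf^2, single-exposure inverse fits. Shot and read
#' contrast terms are assumed perfectly subtracted.
#'
#' @param config A [measurement_config()].
#' @param histories_base A [photon_history_table()] for the baseline state
#'   (or an `mc_run_result`, whose reflectance curve is used by default).
#' @param histories_pert Histories for the perturbed state; defaults to
#'   `histories_base` (transport does not depend on flow).
#' @param reflectance Reflectance curve data frame (`sds_mm`,
#'   `reflectance_per_mm2`); taken from `histories_base` when it is an
#'   `mc_run_result`.
#' @param optics_by_tissue,flow_base,flow_pert Tissue optics and flow states;
#'   default to [head_tissue_properties()] at the configured wavelength.
#' @return A [performance_metrics()] object with attribute `"detail"` holding
#'   intermediate quantities (count rates, beta, Gamma or contrast budget).
#' @export
evaluate_configuration <- function(config, histories_base,
                                   histories_pert = NULL, reflectance = NULL,
                                   optics_by_tissue = NULL, flow_base = NULL,
                                   flow_pert = NULL) {
  stopifnot(inherits(config, "measurement_config"))
  if (inherits(histories_base, "mc_run_result")) {
    if (is.null(reflectance)) reflectance <- histories_base$reflectance
    histories_base <- histories_base$histories
  }
  if (is.null(histories_pert)) histories_pert <- histories_base
  if (inherits(histories_pert, "mc_run_result")) {
    histories_pert <- histories_pert$histories
  }
  if (is.null(reflectance)) stop("a reflectance curve is required")

  wl <- config$wavelength_nm
  props <- head_tissue_properties(wl)
  if (is.null(optics_by_tissue)) {
    optics_by_tissue <- stats::setNames(lapply(seq_len(nrow(props)), function(i) {
      optical_properties(props$mu_a[i], props$mu_s_prime[i],
                         props$refractive_index[i])
    }), props$tissue)
  }
  if (is.null(flow_base)) {
    flow_base <- flow_state(stats::setNames(props$bfi_baseline, props$tissue))
  }
  if (is.null(flow_pert)) {
    flow_pert <- flow_state(stats::setNames(props$bfi_perturbed, props$tissue))
  }
  # the cerebral reference flow: the "brain" tissue when present, otherwise
  # the deepest (last) layer of the history table
  brain_label <- if ("brain" %in% names(flow_base$bfi_by_tissue)) "brain" else {
    utils::tail(histories_base$tissue_labels, 1)
  }
  cbf_base <- flow_base$bfi_by_tissue[[brain_label]]
  cbf_pert <- flow_pert$bfi_by_tissue[[brain_label]]

  det_tab <- histories_base$detectors
  det_id <- det_tab$id[which.min(abs(det_tab$sds_mm - config$sds_mm))]
  if (abs(det_tab$sds_mm[det_tab$id == det_id] - config$sds_mm) > 1e-6) {
    stop("no detector at ", config$sds_mm, " mm in the history table")
  }

  plan <- illumination_plan(config$strategy, config$laser, config$technique,
                            t_exp = config$t_exp,
                            camera_max_fps = config$detector$max_frame_rate,
                            n_sources = config$n_sources)
  calib <- flux_calibration(wl)
  flux_mode <- photon_flux_per_mode(config$sds_mm, reflectance, calib, plan,
                                    config$per_mode_throughput_factor)

  # delay grid truncated once the field correlation has fully decayed
  tau <- tau_grid_multitau(first_bin = config$bin_width_T, bins_per_octave = 8,
                           tau_max = 0.1, include_zero = TRUE)
  g1_base <- g1_from_histories(histories_base, optics_by_tissue, flow_base,
                               tau, det_id)
  cut <- which(g1_base$values < 1e-3)
  if (length(cut) > 0 && cut[1] > 8) {
    tau <- tau[seq_len(cut[1])]
    g1_base <- correlation_curve(tau, g1_base$values[seq_len(cut[1])], "field_g1")
  }
  g1_pert <- g1_from_histories(histories_pert, optics_by_tissue, flow_pert,
                               tau, det_id)

  if (config$technique == "dcs") {
    evaluate_dcs(config, plan, flux_mode, g1_base, g1_pert, cbf_base, cbf_pert)
  } else {
    evaluate_scos(config, plan, flux_mode, g1_base, g1_pert, cbf_base, cbf_pert)
  }
}

evaluate_dcs <- function(config, plan, flux_mode, g1_base, g1_pert,
                         cbf_base, cbf_pert) {
  det <- config$detector
  beta0 <- 1 / config$n_modes
  signal <- flux_mode * config$n_modes * det$quantum_efficiency
  dark <- det$dark_count_rate
  sat <- saturation_limit(det$hold_off)
  total <- signal + dark
  capped <- is.finite(sat) && total > sat
  if (capped) {
    scale <- sat / total
    signal <- signal * scale
    dark <- dark * scale
    total <- sat
  }
  beta_eff <- beta0 * (signal / (signal + dark))^2

  g2_base <- siegert_g2(g1_base, beta_eff)
  g2_pert <- siegert_g2(g1_pert, beta_eff)
  gamma <- estimate_decay_rate(g2_base, beta_eff)
  params <- dcs_noise_params(
    bin_width_T = config$bin_width_T,
    averaging_time_t = plan$duty_cycle / config$sample_rate,
    beta = beta_eff, gamma = gamma,
    counts_per_bin_n = total * config$bin_width_T
  )
  sigma <- dcs_noise_sigma(params, g2_base$tau)
  tau_max <- fit_range_cutoff(g2_base, config$fit_fraction)

  settings <- fit_settings(fitting_optical_properties(config$wavelength_nm),
                           config$wavelength_nm, beta = beta_eff)
  geometry <- semi_infinite_geometry(config$sds_mm, settings$optics,
                                     config$wavelength_nm)
  fit_one <- function(y) {
    fit_bfi_from_g2(correlation_curve(g2_base$tau, y, "intensity_g2",
                                      beta = beta_eff),
                    settings, geometry, tau_max = tau_max)
  }
  # common random numbers across flow states: the sensitivity estimate is a
  # ratio of ensemble means, so sharing noise draws cancels most of its
  # sampling error without touching the CoV
  real_b <- gaussian_noise_realizations(g2_base, sigma, config$n_realizations,
                                        child_seed(config$seed, 1))
  real_p <- gaussian_noise_realizations(g2_pert, sigma, config$n_realizations,
                                        child_seed(config$seed, 1))
  ens_b <- fit_bfi_ensemble(real_b, fit_one)
  ens_p <- fit_bfi_ensemble(real_p, fit_one)

  build_metrics(ens_b, ens_p, cbf_base, cbf_pert,
                flags = c(saturation_capped = capped,
                          ensemble_invalid = ens_b$invalid || ens_p$invalid),
                detail = list(count_rate = total, signal_rate = signal,
                              beta = beta_eff, gamma = gamma,
                              sigma = sigma, tau_max = tau_max,
                              duty_cycle = plan$duty_cycle))
}

evaluate_scos <- function(config, plan, flux_mode, g1_base, g1_pert,
                          cbf_base, cbf_pert) {
  det <- config$detector
  sp <- config$s_over_p
  fs <- plan$effective_frame_rate
  frames_per_sample <- floor(fs / config$sample_rate)
  if (frames_per_sample < 1) {
    stop("exposure incompatible with sample rate: no complete frame per sample")
  }
  beta <- speckle_beta(sp, grid_size = config$scos_sim$grid_size)
  t_exp <- config$t_exp

  kf2_base <- speckle_contrast_from_g1(g1_base, beta, t_exp)
  kf2_pert <- speckle_contrast_from_g1(g1_pert, beta, t_exp)

  # mode-to-pixel allocation under uniform illumination: each mode occupies
  # (s/p)^2 pixels, so a sensor of n_pix pixels images at most n_pix/(s/p)^2
  # modes (the rest of the bundle output misses the sensor); conversely too
  # few modes underfill the sensor
  n_pix <- det$n_pixels
  n_modes_used <- min(config$n_modes, n_pix / sp^2)
  n_pix_used <- min(n_pix, config$n_modes * sp^2)
  pe_total <- flux_mode * n_modes_used * det$quantum_efficiency * t_exp
  pe_per_pixel <- pe_total / n_pix_used

  # dynamic-speckle noise estimate at this operating point
  tau_c <- decorrelation_time(g1_base)
  n_sub <- ceiling(t_exp / (tau_c / 8))
  coarse <- n_sub > config$scos_sim$max_substeps
  n_sub <- max(4L, min(n_sub, config$scos_sim$max_substeps))
  dt <- t_exp / n_sub
  n_frames <- config$scos_sim$n_frames
  stack <- suppressWarnings(speckle_field_sequence(
    g1_target = g1_as_function(g1_base), s_over_p = sp,
    grid_size = config$scos_sim$grid_size, substeps = n_sub * n_frames,
    dt = dt, seed = child_seed(config$seed, 3), polarized = FALSE,
    substeps_per_exposure = n_sub
  ))
  stats_sim <- measured_contrast_stats(stack, t_exp, pe_per_pixel,
                                       det$read_noise,
                                       seed = child_seed(config$seed, 4))
  n_pix_sim <- config$scos_sim$grid_size^2
  sigma_sample <- stats_sim$sigma_k2 * sqrt(n_pix_sim / n_pix_used) /
    sqrt(frames_per_sample)

  settings <- fit_settings(fitting_optical_properties(config$wavelength_nm),
                           config$wavelength_nm, beta = beta)
  geometry <- semi_infinite_geometry(config$sds_mm, settings$optics,
                                     config$wavelength_nm)
  fit_one <- function(kf2) {
    fit_bfi_from_contrast(data.frame(t_exp = t_exp, kf2 = kf2), settings,
                          geometry)
  }
  # common random numbers across flow states (see the DCS branch)
  old_seed <- set_local_seed(child_seed(config$seed, 5))
  draws <- stats::rnorm(config$n_realizations)
  restore_seed(old_seed)
  real_b <- matrix(kf2_base + sigma_sample * draws, nrow = 1)
  real_p <- matrix(kf2_pert + sigma_sample * draws, nrow = 1)
  ens_b <- fit_bfi_ensemble(real_b, fit_one)
  ens_p <- fit_bfi_ensemble(real_p, fit_one)

  build_metrics(ens_b, ens_p, cbf_base, cbf_pert,
                flags = c(underfilled = n_pix_used < n_pix,
                          modes_clipped = n_modes_used < config$n_modes,
                          coarse_substeps = coarse,
                          ensemble_invalid = ens_b$invalid || ens_p$invalid),
                detail = list(beta = beta, kf2_base = kf2_base,
                              kf2_pert = kf2_pert,
                              pe_per_pixel = pe_per_pixel,
                              n_modes_used = n_modes_used,
                              n_pix_used = n_pix_used,
                              sigma_k2_frame = stats_sim$sigma_k2,
                              sigma_k2_sample = sigma_sample,
                              nio_est_sim = stats_sim$nio_est,
                              frames_per_sample = frames_per_sample,
                              effective_frame_rate = fs,
                              budget = stats_sim$budget))
}

# delay at which a g1 curve first falls to 1/e
decorrelation_time <- function(g1) {
  idx <- which(g1$values <= exp(-1))
  if (length(idx) == 0) return(max(g1$tau))
  i <- idx[1]
  if (i == 1) return(g1$tau[1])
  # linear interpolation between grid points
  t0 <- g1$tau[i - 1]; t1 <- g1$tau[i]
  v0 <- g1$values[i - 1]; v1 <- g1$values[i]
  t0 + (v0 - exp(-1)) / (v0 - v1) * (t1 - t0)
}

build_metrics <- function(ens_b, ens_p, cbf_base, cbf_pert, flags, detail) {
  mb <- mean(ens_b$bfi); mp <- mean(ens_p$bfi)
  sens <- sensitivity(mb, mp, cbf_base, cbf_pert)
  cov <- coefficient_of_variation(ens_b$bfi)
  cnr <- contrast_to_noise(sens, cov)
  out <- performance_metrics(
    sensitivity = sens, cov = cov, cnr = cnr,
    bfi_base_mean = mb, bfi_base_sd = stats::sd(ens_b$bfi),
    bfi_pert_mean = mp, bfi_pert_sd = stats::sd(ens_p$bfi),
    n_failed = ens_b$n_failed + ens_p$n_failed, flags = flags
  )
  attr(out, "detail") <- detail
  out
}

#' Parameter sweeps over operating conditions
#'
#' Drivers reproducing the standard comparison studies on slab geometries:
#' * `"fit_range"`: DCS fit fraction (or SCOS exposure time) across
#'   separations, single CW ANSI source, single-mode fiber / s/p = 1.
#' * `"strategy"`: laser delivery strategies across separations.
#' * `"modes_sp"`: detected mode count (DCS fibers, with dark counts) or
#'   s/p ratio (SCOS) at fixed separations.
#' * `"thickness"`: performance across extracerebral thicknesses.
#'
#' @param preset Sweep preset name.
#' @param runs Named list of `mc_run_result` objects keyed by extracerebral
#'   depth in mm (e.g. `list("15" = run15)`); presets other than `"thickness"`
#'   use the `"15"` entry.
#' @param technique `"dcs"`, `"scos"`, or both.
#' @param sds_mm Separations to evaluate (must exist in the history tables).
#' @param values Swept values: fit fractions, exposure times (s), strategy
#'   names, s/p ratios / fiber presets, or depths, depending on the preset;
#'   sensible defaults per preset.
#' @param detector,laser,fiber Hardware models; default to the 850 nm presets
#'   per technique.
#' @param n_realizations Ensemble size per configuration.
#' @param seed Root seed.
#' @param t_exp SCOS exposure used by presets that fix it.
#' @param dark_count_rate Dark rate for the `modes_sp` DCS comparison.
#' @param ... Extra arguments forwarded to [measurement_config()].
#' @return A long-format data frame: one row per (technique, sds, value) with
#'   the metrics and threshold flags.
#' @export
sweep_performance <- function(preset = c("fit_range", "strategy", "modes_sp",
                                         "thickness"),
                              runs, technique = c("dcs", "scos"),
                              sds_mm = seq(5, 40, by = 5), values = NULL,
                              detector = NULL, laser = NULL, fiber = NULL,
                              n_realizations = 100, seed = 1, t_exp = 6.67e-3,
                              dark_count_rate = 0, ...) {
  preset <- match.arg(preset)
  technique <- match.arg(technique, several.ok = TRUE)
  if (inherits(runs, "mc_run_result")) runs <- list("15" = runs)
  rows <- list()
  idx <- 0L
  add_row <- function(tech, depth, sds, value_name, value, metrics) {
    idx <<- idx + 1L
    rows[[idx]] <<- data.frame(
      technique = tech, depth_mm = as.numeric(depth), sds_mm = sds,
      parameter = value_name, value = as.character(value),
      sensitivity = metrics$sensitivity, cov = metrics$cov, cnr = metrics$cnr,
      bfi_base_mean = metrics$bfi_base_mean,
      bfi_pert_mean = metrics$bfi_pert_mean,
      sensitivity_ok = metrics$sensitivity_ok, cov_ok = metrics$cov_ok,
      cnr_ok = metrics$cnr_ok, n_failed = metrics$n_failed,
      stringsAsFactors = FALSE
    )
  }

  eval_cfg <- function(tech, run, sds, strategy = "cw_single",
                       fit_fraction = 1, te = NULL, sp = NULL,
                       det = NULL, fib = NULL, las = NULL, n_modes = NULL,
                       dark = 0, cfg_seed = seed) {
    if (is.null(las)) {
      las <- if (is.null(laser)) laser_preset("laser_850") else laser
    }
    if (is.null(det)) {
      det <- if (!is.null(detector)) detector
      else if (tech == "dcs") detector_preset("dcs_850_sispad", dark)
      else detector_preset("scos_850_cmos")
    }
    if (is.null(fib) && is.null(n_modes)) {
      fib <- if (!is.null(fiber)) fiber
      else if (tech == "dcs") fiber_preset("smf_780hp")
      else fiber_preset("bundle_scos")
    }
    cfg <- measurement_config(
      technique = tech, sds_mm = sds, detector = det, laser = las,
      fiber = fib, strategy = strategy, fit_fraction = fit_fraction,
      t_exp = te, s_over_p = sp, n_modes = n_modes,
      n_realizations = n_realizations, seed = cfg_seed, ...
    )
    evaluate_configuration(cfg, run)
  }

  depth0 <- if ("15" %in% names(runs)) "15" else names(runs)[1]
  run0 <- runs[[depth0]]

  if (preset == "fit_range") {
    if ("dcs" %in% technique) {
      vals <- if (is.null(values)) c(0.25, 0.5, 0.75, 1) else values
      for (f in vals) for (s in sds_mm) {
        m <- eval_cfg("dcs", run0, s, fit_fraction = f,
                      cfg_seed = child_seed(seed, round(1e3 * f) + s))
        add_row("dcs", depth0, s, "fit_fraction", f, m)
      }
    }
    if ("scos" %in% technique) {
      vals <- if (is.null(values)) c(1e-4, 1e-3, 6.67e-3, 2e-2) else values
      for (te in vals) for (s in sds_mm) {
        m <- eval_cfg("scos", run0, s, te = te, sp = 1,
                      cfg_seed = child_seed(seed, round(1e6 * te) + s))
        add_row("scos", depth0, s, "t_exp", te, m)
      }
    }
  } else if (preset == "strategy") {
    strategies <- if (is.null(values)) {
      c("cw_single", "cw_multi", "pulsed_frame_limited")
    } else values
    for (tech in technique) for (st in strategies) for (s in sds_mm) {
      if (tech == "dcs" && st == "pulsed_power_limited") next
      m <- eval_cfg(tech, run0, s, strategy = st,
                    te = if (tech == "scos") t_exp else NULL,
                    sp = if (tech == "scos") 1 else NULL,
                    cfg_seed = child_seed(seed, s + match(st, strategies) * 100))
      add_row(tech, depth0, s, "strategy", st, m)
    }
  } else if (preset == "modes_sp") {
    if ("dcs" %in% technique) {
      fibers <- if (is.null(values)) c("smf_780hp", "fmf_smf28") else values
      for (fn in fibers) for (s in sds_mm) {
        m <- eval_cfg("dcs", run0, s, fib = fiber_preset(fn),
                      dark = dark_count_rate,
                      cfg_seed = child_seed(seed, s + match(fn, fibers) * 41))
        add_row("dcs", depth0, s, "fiber", fn, m)
      }
    }
    if ("scos" %in% technique) {
      sps <- if (is.null(values)) c(0.41, 1, 2) else values
      for (sp in sps) for (s in sds_mm) {
        m <- eval_cfg("scos", run0, s, strategy = "pulsed_frame_limited",
                      te = t_exp, sp = sp,
                      cfg_seed = child_seed(seed, s + round(sp * 100)))
        add_row("scos", depth0, s, "s_over_p", sp, m)
      }
    }
  } else {  # thickness
    for (depth in names(runs)) for (tech in technique) for (s in sds_mm) {
      m <- eval_cfg(tech, runs[[depth]], s,
                    strategy = if (tech == "scos") "pulsed_frame_limited"
                               else "cw_single",
                    te = if (tech == "scos") t_exp else NULL,
                    sp = if (tech == "scos") 0.41 else NULL,
                    cfg_seed = child_seed(seed, s + as.numeric(depth) * 17))
      add_row(tech, depth, s, "depth_mm", depth, m)
    }
  }
  do.call(rbind, rows)
}
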