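#' Detector, laser and fiber hardware models
#'
#' Plain containers with validation. Presets reproducing the three reference
#' detection systems are available through [detector_preset()] and
#' [laser_preset()].
#'
#' @param name Descriptive name.
#' @param quantum_efficiency Photon detection efficiency in (0, 1].
#' @param dark_count_rate Dark (or background) count rate, cps or e-/s.
#' @param read_noise Read noise (electrons RMS).
#' @param hold_off Dead time after each detection event (s); 0 if none.
#' @param max_frame_rate Maximum frame rate (Hz); NA for free-running photon
#'   counters.
#' @param n_pixels Number of pixels (1 for point detectors).
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(name, quantum_efficiency, dark_count_rate = 0,
                           read_noise = 0, hold_off = 0, max_frame_rate = NA,
                           n_pixels = 1) {
  if (quantum_efficiency <= 0 || quantum_efficiency > 1) {
    stop("quantum_efficiency must be in (0, 1]")
  }
  if (dark_count_rate < 0 || read_noise < 0 || hold_off < 0) {
    stop("noise parameters must be >= 0")
  }
  if (n_pixels < 1) stop("n_pixels must be >= 1")
  structure(list(name = name, quantum_efficiency = quantum_efficiency,
                 dark_count_rate = dark_count_rate, read_noise = read_noise,
                 hold_off = hold_off, max_frame_rate = max_frame_rate,
                 n_pixels = n_pixels),
            class = "detector_model")
}

#' @param wavelength_nm Laser wavelength (nm).
#' @param max_output_power_mw Maximum laser output power (mW).
#' @param spot_diameter_mm Illumination spot diameter on the skin (mm).
#' @param ansi_power_mw Skin-safe average power per spot (mW); defaults to the
#'   computed [ansi_limited_power()]. Presets store the nominal configuration
#'   value instead.
#' @rdname detector_model
#' @return `laser_model` returns an object of class `laser_model`.
#' @export
laser_model <- function(name, wavelength_nm, max_output_power_mw,
                        spot_diameter_mm = 3.5, ansi_power_mw = NULL) {
  if (max_output_power_mw <= 0 || spot_diameter_mm <= 0) {
    stop("powers and spot diameter must be > 0")
  }
  if (is.null(ansi_power_mw)) {
    ansi_power_mw <- ansi_limited_power(wavelength_nm, spot_diameter_mm)
  }
  structure(list(name = name, wavelength_nm = wavelength_nm,
                 max_output_power_mw = max_output_power_mw,
                 spot_diameter_mm = spot_diameter_mm,
                 ansi_power_mw = ansi_power_mw),
            class = "laser_model")
}

#' @param core_diameter_um Fiber core diameter (micrometres).
#' @param numerical_aperture Fiber NA in (0, 1).
#' @param n_fibers Number of fibers (1 for a single fiber, > 1 for a bundle).
#' @rdname detector_model
#' @return `fiber_model` returns an object of class `fiber_model`.
#' @export
fiber_model <- function(name, core_diameter_um, numerical_aperture,
                        n_fibers = 1) {
  if (core_diameter_um <= 0) stop("core_diameter_um must be > 0")
  if (numerical_aperture <= 0 || numerical_aperture >= 1) {
    stop("numerical_aperture must be in (0, 1)")
  }
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  structure(list(name = name, core_diameter_um = core_diameter_um,
                 numerical_aperture = numerical_aperture, n_fibers = n_fibers),
            class = "fiber_model")
}

#' Hardware presets for the three reference systems
#'
#' `dcs_850_sispad`: silicon SPAD (QE 55%, hold-off 22 ns, selectable dark
#' count rate). `dcs_1064_snspd`: superconducting nanowire detector (QE 90%,
#' hold-off 33 ns, no dark counts). `scos_850_cmos`: CMOS camera (QE 20%,
#' read noise 2.5 e-, 150 Hz maximum frame rate, 2.5 megapixels).
#'
#' @param name Preset name.
#' @param dark_count_rate Dark/background rate override for the Si SPAD
#'   (0, 500, 1000 or 1500 cps are the studied values).
#' @return A [detector_model()].
#' @export
detector_preset <- function(name = c("dcs_850_sispad", "dcs_1064_snspd",
                                     "scos_850_cmos"),
                            dark_count_rate = 0) {
  name <- match.arg(name)
  switch(name,
    dcs_850_sispad = detector_model("Si SPAD (850 nm DCS)", 0.55,
                                    dark_count_rate = dark_count_rate,
                                    hold_off = 22e-9),
    dcs_1064_snspd = detector_model("SNSPD (1064 nm DCS)", 0.90,
                                    hold_off = 33e-9),
    scos_850_cmos = detector_model("CMOS camera (850 nm SCOS)", 0.20,
                                   read_noise = 2.5, max_frame_rate = 150,
                                   n_pixels = 2.5e6)
  )
}

#' Laser presets for the two reference sources
#'
#' The 850 nm source: 300 mW maximum, 38 mW ANSI-limited per 3.5 mm spot
#' (7.9x ANSI). The 1064 nm source: 1 W maximum, 100 mW nominal ANSI-limited
#' per spot (10x ANSI).
#'
#' @param name Preset name.
#' @return A [laser_model()].
#' @export
laser_preset <- function(name = c("laser_850", "laser_1064")) {
  name <- match.arg(name)
  switch(name,
    laser_850 = laser_model("850 nm source", 850, 300, 3.5, ansi_power_mw = 38),
    laser_1064 = laser_model("1064 nm source", 1064, 1000, 3.5,
                             ansi_power_mw = 100)
  )
}

#' Fiber presets
#'
#' `smf_780hp`: single-mode fiber (4.4 um core, NA 0.13; two polarization
#' modes at 850 nm). `fmf_smf28`: few-mode fiber (8.2 um core, NA 0.14;
#' 12 modes at 850 nm, 6 at 1064 nm). `bundle_scos`: 2000-fiber bundle of
#' 50 um, NA 0.66 fibers (~1.5e7 modes at 850 nm).
#'
#' @param name Preset name.
#' @return A [fiber_model()].
#' @export
fiber_preset <- function(name = c("smf_780hp", "fmf_smf28", "bundle_scos")) {
  name <- match.arg(name)
  switch(name,
    smf_780hp = fiber_model("780 HP single-mode", 4.4, 0.13),
    fmf_smf28 = fiber_model("SMF-28 few-mode", 8.2, 0.14),
    bundle_scos = fiber_model("SCOS fiber bundle", 50, 0.66, n_fibers = 2000)
  )
}

#' ANSI skin maximum-permissible-exposure limited power
#'
#' Continuous-wave skin MPE per ANSI Z136.1 in the near infrared:
#' `0.2 * 10^(0.002 (lambda - 700)) W/cm^2` for 700-1050 nm and `1.0 W/cm^2`
#' for 1050-1400 nm, multiplied by the illumination spot area.
#'
#' @param wavelength_nm Wavelength in 700-1400 nm.
#' @param spot_diameter_mm Spot diameter (mm).
#' @return Skin-safe average power for the spot (mW).
#' @examples
#' ansi_limited_power(850, 3.5)   # ~38 mW
#' @export
ansi_limited_power <- function(wavelength_nm, spot_diameter_mm = 3.5) {
  if (wavelength_nm < 700 || wavelength_nm > 1400) {
    stop("unsupported band: wavelength must be within 700-1400 nm")
  }
  mpe_w_cm2 <- if (wavelength_nm <= 1050) {
    0.2 * 10^(0.002 * (wavelength_nm - 700))
  } else {
    1.0
  }
  area_cm2 <- pi * (spot_diameter_mm / 20)^2
  mpe_w_cm2 * area_cm2 * 1000
}

#' Number of guided modes of a step-index fiber
#'
#' Exact LP-mode counting from the V-number `V = pi d NA / lambda`: an LP(l,m)
#' mode is guided when its cutoff (a Bessel zero: the m-th zero of J(l-1) for
#' l >= 1, the (m-1)-th zero of J1 for l = 0, counting 0 as the first) is
#' below V. Each l = 0 mode contributes 2 polarization states; each l >= 1
#' mode contributes 2 orientations x 2 polarizations. For large V (> 15) the
#' `V^2/2` estimate is used.
#'
#' @param fiber A [fiber_model()] (a single fiber; see [bundle_mode_count()]
#'   for bundles).
#' @param wavelength_nm Wavelength (nm).
#' @return Total number of guided modes including polarization.
#' @examples
#' count_guided_modes(fiber_preset("fmf_smf28"), 850)   # 12
#' count_guided_modes(fiber_preset("fmf_smf28"), 1064)  # 6
#' @export
count_guided_modes <- function(fiber, wavelength_nm) {
  stopifnot(inherits(fiber, "fiber_model"))
  V <- fiber_v_number(fiber, wavelength_nm)
  if (V > 15) return(round(V^2 / 2))
  total <- 0
  for (l in 0:ceiling(V + 2)) {
    cutoffs <- lp_mode_cutoffs(l, V)
    n_guided <- sum(cutoffs < V)
    if (n_guided == 0 && l > 0) break
    total <- total + n_guided * (if (l == 0) 2 else 4)
  }
  total
}

fiber_v_number <- function(fiber, wavelength_nm) {
  pi * fiber$core_diameter_um * fiber$numerical_aperture /
    (wavelength_nm * 1e-3)
}

# Cutoff V of LP(l, m) for m = 1, 2, ...: zeros of J_{l-1} (J_1 for l = 0,
# counting the origin as the first zero).
lp_mode_cutoffs <- function(l, v_max) {
  nu <- if (l == 0) 1 else l - 1
  zeros <- bessel_j_zeros(nu, v_max)
  if (l == 0) c(0, zeros) else zeros
}

# Positive zeros of J_nu below x_max, by sign-change scanning + uniroot.
bessel_j_zeros <- function(nu, x_max) {
  if (x_max <= 0) return(numeric(0))
  xs <- seq(1e-6, x_max + 1, by = 0.05)
  fx <- besselJ(xs, nu)
  idx <- which(fx[-1] * fx[-length(fx)] < 0)
  vapply(idx, function(i) {
    stats::uniroot(function(x) besselJ(x, nu), c(xs[i], xs[i + 1]),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Mode count of a multimode fiber bundle
#'
#' Modes per fiber estimated as `V^2/2` (or `V^2` when both polarizations per
#' spatial mode are counted separately), times the number of fibers.
#'
#' @param bundle A [fiber_model()] with `n_fibers >= 1`.
#' @param wavelength_nm Wavelength (nm).
#' @param both_polarizations Count `V^2` per fiber instead of `V^2/2`.
#' @return Estimated total number of modes.
#' @examples
#' bundle_mode_count(fiber_preset("bundle_scos"), 850)  # ~1.49e7
#' @export
bundle_mode_count <- function(bundle, wavelength_nm, both_polarizations = FALSE) {
  stopifnot(inherits(bundle, "fiber_model"))
  V <- fiber_v_number(bundle, wavelength_nm)
  if (V < 5) warning("bundle mode estimate V^2/2 assumes a highly multimode fiber")
  per_fiber <- if (both_polarizations) V^2 else V^2 / 2
  bundle$n_fibers * per_fiber
}

#' Minimum usable speckle-to-pixel ratio
#'
#' With `n_modes` speckles uniformly filling an `n_pixels` sensor, shrinking
#' the speckle below `sqrt(n_pixels / n_modes)` pixels underfills the sensor.
#'
#' @param n_pixels Number of sensor pixels.
#' @param n_modes Number of detected fiber modes.
#' @return The minimum s/p ratio `sqrt(n_pixels / n_modes)`.
#' @export
min_speckle_to_pixel <- function(n_pixels, n_modes) {
  if (n_modes <= 0) stop("n_modes must be > 0")
  sqrt(n_pixels / n_modes)
}

#' Detector saturation limit from its hold-off time
#'
#' A detector blind for `hold_off` seconds after each event sustains at most
#' `1/hold_off` counts per second.
#'
#' @param hold_off Dead time (s).
#' @return Saturation count rate (cps); `Inf` when `hold_off = 0`.
#' @export
saturation_limit <- function(hold_off) {
  if (hold_off < 0) stop("hold_off must be >= 0")
  if (hold_off == 0) return(Inf)
  1 / hold_off
}

#' Laser delivery plan
#'
#' Resolves one of four delivery strategies into instantaneous power, duty
#' cycle, number of source spots and (for cameras) the effective frame rate,
#' always keeping the average delivered power per spot at or below the ANSI
#' limit:
#' * `cw_single`: one continuous source at the ANSI limit.
#' * `cw_multi`: `floor(P_max / P_ANSI)` continuous sources at the ANSI limit
#'   each (override `n_sources` to split the full laser power across more,
#'   sub-ANSI, spots).
#' * `pulsed_power_limited` (SCOS): the frame rate is kept at
#'   `min(camera_max_fps, 1/t_exp)` and the pulse power is raised to
#'   `min(P_max, P_ANSI / (fs t_exp))`.
#' * `pulsed_frame_limited`: full laser power during the exposure and the
#'   frame rate reduced so `P_max fs t_exp <= P_ANSI`. For DCS (no camera)
#'   this reduces to a duty cycle of `P_ANSI / P_max` at full power.
#'
#' @param strategy One of `"cw_single"`, `"cw_multi"`, `"pulsed_power_limited"`,
#'   `"pulsed_frame_limited"`.
#' @param laser A [laser_model()].
#' @param technique `"dcs"` or `"scos"`.
#' @param t_exp Camera exposure time (s); required for SCOS pulsed plans.
#' @param camera_max_fps Camera maximum frame rate (Hz); required for SCOS.
#' @param n_sources Optional override of the source count for `cw_multi`.
#' @return An object of class `illumination_plan` with fields `strategy`,
#'   `instantaneous_power` (mW per spot), `duty_cycle`, `n_sources`,
#'   `effective_frame_rate` (Hz, SCOS only).
#' @export
illumination_plan <- function(strategy = c("cw_single", "cw_multi",
                                           "pulsed_power_limited",
                                           "pulsed_frame_limited"),
                              laser, technique = c("dcs", "scos"),
                              t_exp = NULL, camera_max_fps = NULL,
                              n_sources = NULL) {
  strategy <- match.arg(strategy)
  technique <- match.arg(technique)
  stopifnot(inherits(laser, "laser_model"))
  p_ansi <- laser$ansi_power_mw
  p_max <- laser$max_output_power_mw

  if (strategy == "cw_single") {
    plan <- list(instantaneous_power = p_ansi, duty_cycle = 1, n_sources = 1L,
                 effective_frame_rate = camera_fps(technique, t_exp, camera_max_fps))
  } else if (strategy == "cw_multi") {
    n_def <- max(1L, as.integer(floor(p_max / p_ansi)))
    n_src <- if (is.null(n_sources)) n_def else as.integer(n_sources)
    per_spot <- min(p_ansi, p_max / n_src)
    plan <- list(instantaneous_power = per_spot, duty_cycle = 1,
                 n_sources = n_src,
                 effective_frame_rate = camera_fps(technique, t_exp, camera_max_fps))
  } else if (technique == "dcs") {
    # pulsed DCS: full laser power with duty cycle P_ANSI / P_max
    duty <- min(1, p_ansi / p_max)
    plan <- list(instantaneous_power = p_max, duty_cycle = duty, n_sources = 1L,
                 effective_frame_rate = NA_real_)
  } else {
    if (is.null(t_exp)) stop("t_exp is required for SCOS pulsed plans")
    if (is.null(camera_max_fps)) stop("camera_max_fps is required for SCOS plans")
    if (strategy == "pulsed_power_limited") {
      fs <- min(camera_max_fps, 1 / t_exp)
      p_inst <- min(p_max, p_ansi / (fs * t_exp))
      plan <- list(instantaneous_power = p_inst, duty_cycle = fs * t_exp,
                   n_sources = 1L, effective_frame_rate = fs)
    } else {
      fs <- min(camera_max_fps, p_ansi / (p_max * t_exp), 1 / t_exp)
      plan <- list(instantaneous_power = p_max, duty_cycle = fs * t_exp,
                   n_sources = 1L, effective_frame_rate = fs)
    }
  }
  avg_per_spot <- plan$instantaneous_power * plan$duty_cycle
  if (avg_per_spot > p_ansi * (1 + 1e-9)) {
    stop("plan violates the ANSI average-power limit per spot")
  }
  structure(c(plan, list(strategy = strategy, technique = technique,
                         laser = laser, t_exp = t_exp,
                         ansi_power_mw = p_ansi)),
            class = "illumination_plan")
}

camera_fps <- function(technique, t_exp, camera_max_fps) {
  if (technique != "scos") return(NA_real_)
  if (is.null(t_exp) || is.null(camera_max_fps)) {
    stop("t_exp and camera_max_fps are required for SCOS plans")
  }
  min(camera_max_fps, 1 / t_exp)
}

#' @export
print.illumination_plan <- function(x, ...) {
  cat(sprintf(
    "Illumination plan [%s, %s]: %d source(s) x %.3g mW, duty %.3g%s\n",
    x$strategy, x$technique, x$n_sources, x$instantaneous_power, x$duty_cycle,
    if (!is.na(x$effective_frame_rate))
      sprintf(", fs = %.3g Hz", x$effective_frame_rate) else ""
  ))
  invisible(x)
}

#' Photon flux calibration
#'
#' Anchors the absolute detected photon flux: the counts per second per mode
#' delivered by one ANSI-limited continuous source at a reference separation.
#' The native calibrations are 10 kcps/mode at 850 nm and 67.1 kcps/mode at
#' 1064 nm, both at a 25 mm separation.
#'
#' @param wavelength_nm 850 or 1064 for presets; any value with explicit cps.
#' @param cps_per_mode_at_reference Override the preset calibration.
#' @param reference_sds_mm Reference separation (mm).
#' @return An object of class `flux_calibration`.
#' @export
flux_calibration <- function(wavelength_nm,
                             cps_per_mode_at_reference = NULL,
                             reference_sds_mm = 25) {
  if (is.null(cps_per_mode_at_reference)) {
    cps_per_mode_at_reference <- switch(as.character(wavelength_nm),
      "850" = 10e3, "1064" = 67.1e3,
      stop("no preset flux calibration at ", wavelength_nm, " nm"))
  }
  if (cps_per_mode_at_reference <= 0) stop("calibration cps must be > 0")
  structure(list(reference_sds_mm = reference_sds_mm,
                 cps_per_mode_at_reference = cps_per_mode_at_reference,
                 wavelength_nm = wavelength_nm),
            class = "flux_calibration")
}

#' Detected photon flux per mode at a separation
#'
#' Scales the calibrated reference flux by the ratio of diffuse reflectance at
#' the requested separation to the reflectance at the calibration separation
#' (interpolated log-linearly in separation), by the delivered power relative
#' to a single ANSI source, and by an optional per-mode throughput factor
#' (e.g. 1/9 for a lossy camera coupling). Detector quantum efficiency is
#' applied downstream.
#'
#' @param sds_mm Source-detector separation (mm).
#' @param reflectance_curve Data frame with columns `sds_mm` and
#'   `reflectance_per_mm2` (e.g. from [run_layered_mc()]).
#' @param calibration A [flux_calibration()].
#' @param plan An [illumination_plan()].
#' @param per_mode_throughput_factor Scalar multiplier on the per-mode flux.
#' @return Incident photon flux per mode (cps).
#' @export
photon_flux_per_mode <- function(sds_mm, reflectance_curve, calibration, plan,
                                 per_mode_throughput_factor = 1) {
  stopifnot(inherits(calibration, "flux_calibration"),
            inherits(plan, "illumination_plan"))
  rng <- range(reflectance_curve$sds_mm)
  for (s in c(sds_mm, calibration$reference_sds_mm)) {
    if (s < rng[1] || s > rng[2]) {
      stop("separation ", s, " mm outside the reflectance curve range")
    }
  }
  if (any(reflectance_curve$reflectance_per_mm2 <= 0)) {
    stop("reflectance curve must be positive everywhere for log interpolation")
  }
  interp <- function(s) {
    exp(stats::approx(reflectance_curve$sds_mm,
                      log(reflectance_curve$reflectance_per_mm2),
                      xout = s)$y)
  }
  power_scale <- plan$instantaneous_power * plan$n_sources / plan$ansi_power_mw
  calibration$cps_per_mode_at_reference *
    interp(sds_mm) / interp(calibration$reference_sds_mm) *
    power_scale * per_mode_throughput_factor
}
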