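# Shared fixtures, built lazily and cached for the whole test run. All seeds
# are fixed so every fixture is deterministic.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

tissue_optics <- function(wavelength_nm = 850) {
  props <- head_tissue_properties(wavelength_nm)
  stats::setNames(lapply(seq_len(nrow(props)), function(i) {
    optical_properties(props$mu_a[i], props$mu_s_prime[i],
                       props$refractive_index[i])
  }), props$tissue)
}

baseline_flow <- function(wavelength_nm = 850) {
  props <- head_tissue_properties(wavelength_nm)
  flow_state(stats::setNames(props$bfi_baseline, props$tissue))
}

perturbed_flow <- function(wavelength_nm = 850) {
  props <- head_tissue_properties(wavelength_nm)
  flow_state(stats::setNames(props$bfi_perturbed, props$tissue))
}

# Homogeneous semi-infinite medium with the scalp optical properties:
# the substrate for the Monte Carlo vs diffusion-theory comparisons.
scalp_optics <- function() optical_properties(0.164, 7.4, 1.4)

homogeneous_run <- function(n_photons = 1e6) {
  fixture(sprintf("homog_%g", n_photons), function() {
    geom <- slab_geometry(
      data.frame(tissue = "tissue", thickness_mm = Inf),
      data.frame(id = 1:4, sds_mm = c(10, 15, 25, 40), radius_mm = 1, na = 1)
    )
    run_layered_mc(geom, list(tissue = scalp_optics()), n_photons, seed = 42,
                   wavelength_nm = 850)
  })
}

# Four-layer head slab runs at the three extracerebral depths.
head_run <- function(depth_mm = 15, n_photons = 1e6) {
  fixture(sprintf("head_%d_%g", depth_mm, n_photons), function() {
    run_layered_mc(slab_head_model(depth_mm), tissue_optics(), n_photons,
                   seed = 100 + depth_mm, wavelength_nm = 850)
  })
}

dcs_config <- function(sds_mm, strategy = "cw_single", fit_fraction = 1,
                       fiber = "smf_780hp", dark = 0, n_realizations = 200,
                       seed = 5, ...) {
  measurement_config(
    "dcs", sds_mm = sds_mm, detector = detector_preset("dcs_850_sispad", dark),
    laser = laser_preset("laser_850"), fiber = fiber_preset(fiber),
    strategy = strategy, fit_fraction = fit_fraction,
    n_realizations = n_realizations, seed = seed, ...
  )
}

scos_config <- function(sds_mm, t_exp = 1e-3, s_over_p = 1,
                        strategy = "pulsed_frame_limited",
                        n_realizations = 100, seed = 5, ...) {
  measurement_config(
    "scos", sds_mm = sds_mm, detector = detector_preset("scos_850_cmos"),
    laser = laser_preset("laser_850"), fiber = fiber_preset("bundle_scos"),
    strategy = strategy, t_exp = t_exp, s_over_p = s_over_p,
    n_realizations = n_realizations, seed = seed,
    scos_sim = list(grid_size = 24, n_frames = 32, max_substeps = 512), ...
  )
}

# squared-contrast statistic of a vector of pixel intensities
k2_stat <- function(v) stats::var(v) / mean(v)^2

# plain vectorized semi-infinite g1 (no container) for building integrands
semi_infinite_g1_values_for_test <- function(geom, bfi, u) {
  speckleflow:::semi_infinite_g1_values(geom, bfi, u)
}
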