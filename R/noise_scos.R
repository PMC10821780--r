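#' Shot, read and dark noise contributions to squared speckle contrast
#'
#' Variance propagation into squared contrast, in photoelectron units:
#' `Ks^2 = 1/<S>`, `Kr^2 = sigma_r^2 / <S>^2`, `Kd^2 = S_dark / <S>^2`
#' where `<S>` is the mean photoelectrons per pixel per exposure. Dark noise
#' defaults to zero (negligible at sub-10-ms exposures).
#'
#' @param mean_pe Mean photoelectrons per pixel per exposure, > 0.
#' @param read_noise_e Read noise (electrons RMS).
#' @param dark_e Mean dark photoelectrons per pixel per exposure.
#' @return Named list `ks2`, `kr2`, `kd2`.
#' @export
shot_read_dark_contrast <- function(mean_pe, read_noise_e = 0, dark_e = 0) {
  if (!is.finite(mean_pe) || mean_pe <= 0) stop("mean_pe must be > 0")
  list(ks2 = 1 / mean_pe,
       kr2 = read_noise_e^2 / mean_pe^2,
       kd2 = dark_e / mean_pe^2)
}

#' Squared speckle contrast budget
#'
#' @param t_exp Exposure time (s).
#' @param kf2 Fundamental squared contrast.
#' @param ks2,kr2,kd2 Shot, read and dark squared contrast terms.
#' @return An object of class `speckle_contrast_budget`; `k2_total` is the sum
#'   of the four terms.
#' @export
speckle_contrast_budget <- function(t_exp, kf2, ks2 = 0, kr2 = 0, kd2 = 0) {
  terms <- c(t_exp = t_exp, kf2 = kf2, ks2 = ks2, kr2 = kr2, kd2 = kd2)
  if (any(!is.finite(terms)) || any(terms < 0)) {
    stop("all contrast terms and t_exp must be finite and >= 0")
  }
  structure(list(t_exp = t_exp, kf2 = kf2, ks2 = ks2, kr2 = kr2, kd2 = kd2,
                 k2_total = kf2 + ks2 + kr2 + kd2),
            class = "speckle_contrast_budget")
}

#' @export
print.speckle_contrast_budget <- function(x, ...) {
  cat(sprintf(
    "K^2 budget at Texp = %.3g s: total %.4g = Kf2 %.4g + Ks2 %.4g + Kr2 %.4g + Kd2 %.4g\n",
    x$t_exp, x$k2_total, x$kf2, x$ks2, x$kr2, x$kd2
  ))
  invisible(x)
}

#' Dynamic speckle frame stack
#'
#' Synthesizes a time-evolving, fully developed speckle intensity pattern.
#' Spatial statistics come from a circular Fourier aperture sized so that the
#' number of speckle modes on the sensor equals `n_pixels / s_over_p^2`
#' (the convention under which the minimum usable s/p ratio is
#' `sqrt(n_pixels / n_modes)`). Temporal statistics come from autoregressive
#' mixing of the aperture modes: the step coefficients are chosen so the field
#' lag correlation from any substep to a later one equals the target g1 ratio,
#' which is exact for the stationary single-exponential case. Unpolarized
#' detection averages two independent polarization fields. Fields are sampled
#' on a fine grid of `ceil(2/s_over_p)`-fold oversampling so the speckle grain
#' is always resolved, then intensity is block-summed into sensor pixels.
#'
#' @param g1_target Either a positive decay rate (1/s) for a single-exponential
#'   field correlation, a function `g1(tau)`, or a [correlation_curve()] of
#'   kind `field_g1`.
#' @param s_over_p Speckle-to-pixel size ratio, > 0.
#' @param grid_size Sensor pixels per side (total pixels = grid_size^2).
#' @param substeps Total number of substeps to generate.
#' @param dt Substep duration (s).
#' @param seed Integer RNG seed; the same seed reproduces the stack.
#' @param polarized Single polarization if TRUE; default unpolarized.
#' @param substeps_per_exposure If > 0, substeps are integrated in
#'   non-overlapping groups of this size and the stack holds exposure frames
#'   instead of substep frames (memory-friendly for long exposures).
#' @return An object of class `speckle_frame_stack`: `frames` is a
#'   (grid_size^2 x n_frames) matrix of intensities normalized to unit mean,
#'   plus the generation metadata.
#' @export
speckle_field_sequence <- function(g1_target, s_over_p, grid_size = 32,
                                   substeps = 64, dt = 1e-5, seed = 1,
                                   polarized = FALSE,
                                   substeps_per_exposure = 0) {
  if (s_over_p <= 0) stop("s_over_p must be > 0")
  if (substeps < 1) stop("substeps must be >= 1")
  oversample <- max(1L, as.integer(ceiling(2 / s_over_p)))
  nf <- grid_size * oversample
  s_fine <- s_over_p * oversample
  mask_radius <- nf / (sqrt(pi) * s_fine)
  g1f <- g1_target_function(g1_target)
  # AR step coefficients: ratio of the target g1 between consecutive substeps,
  # anchored to the start of each exposure (exposure frames are independent;
  # within a frame the correlation to the frame start reproduces g1 exactly).
  anchor <- if (substeps_per_exposure > 0) substeps_per_exposure else substeps
  t_local <- ((seq_len(substeps) - 1) %% anchor) * dt
  g1v <- pmax(g1f(t_local), 0)
  if (substeps > 1) {
    prev <- g1v[-substeps]
    cur <- g1v[-1]
    ratio <- ifelse(prev > 0, pmin(1, cur / prev), 0)
    ratio[!is.finite(ratio)] <- 0
    ratio[t_local[-1] == 0] <- 0  # fresh field at each exposure start
    a <- c(1, ratio)
  } else {
    a <- 1
  }
  g1dt <- g1f(dt)
  if (is.finite(g1dt) && g1dt > 1e-6 && g1dt < 0.5) {
    warning("substep grid is coarse relative to the field decorrelation time")
  }
  frames <- speckle_stack_cpp(grid_size, oversample, substeps, a, mask_radius,
                              polarized, as.integer(substeps_per_exposure),
                              as.integer(seed))
  n_modes <- attr(frames, "n_modes")
  frames <- frames / mean(frames)
  structure(
    list(frames = frames, s_over_p = s_over_p, grid_size = grid_size,
         oversample = oversample, dt = dt,
         substeps_per_exposure = substeps_per_exposure,
         integrated = substeps_per_exposure > 0,
         n_aperture_modes = n_modes, polarized = polarized,
         g1_target = g1f, seed = as.integer(seed)),
    class = "speckle_frame_stack"
  )
}

#' @export
print.speckle_frame_stack <- function(x, ...) {
  cat(sprintf(
    "Speckle stack: %dx%d pixels, %d %s frames, s/p = %.3g, %s\n",
    x$grid_size, x$grid_size, ncol(x$frames),
    if (x$integrated) "integrated-exposure" else "substep",
    x$s_over_p, if (x$polarized) "polarized" else "unpolarized"
  ))
  invisible(x)
}

# Coerce a g1 target spec into a vectorized function of tau.
g1_target_function <- function(g1_target) {
  if (is.function(g1_target)) return(g1_target)
  if (inherits(g1_target, "correlation_curve")) return(g1_as_function(g1_target))
  if (is.numeric(g1_target) && length(g1_target) == 1 && g1_target >= 0) {
    gamma <- g1_target
    return(function(u) exp(-gamma * u))
  }
  stop("g1_target must be a decay rate, a function, or a field g1 curve")
}

#' Measured speckle contrast statistics from a frame stack
#'
#' Integrates substeps into exposures of duration `t_exp` (unless the stack is
#' already integrated), applies Poisson shot noise and Gaussian read noise at
#' the requested photoelectron level, and computes per-frame squared contrast
#' statistics: the mean contrast budget, the standard deviation of the
#' shot/read-corrected squared contrast across frames (`sigma_k2`), the
#' empirical coherence parameter (`beta_est`, the squared contrast of a single
#' noiseless substep), and the effective number of independent observations
#' `nio_est = 2 mean(Kf^2)^2 / var(Kf^2)` across frames.
#'
#' @param stack A [speckle_field_sequence()] stack.
#' @param t_exp Exposure time (s); must be a multiple of the substep length
#'   within rounding (ignored when the stack holds integrated frames).
#' @param photon_scale Mean photoelectrons per pixel per exposure, > 0.
#' @param read_noise_e Read noise (electrons RMS).
#' @param seed Integer RNG seed for the shot/read noise draw.
#' @return A list: `budget` (a [speckle_contrast_budget()] of the per-frame
#'   means), `sigma_k2`, `beta_est`, `nio_est`, `n_frames`, `kf2_frames`
#'   (per-frame noiseless squared contrast).
#' @export
measured_contrast_stats <- function(stack, t_exp, photon_scale,
                                    read_noise_e = 0, seed = 1) {
  stopifnot(inherits(stack, "speckle_frame_stack"))
  if (!is.finite(photon_scale) || photon_scale <= 0) {
    stop("photon_scale must be > 0")
  }
  if (stack$integrated) {
    frames <- stack$frames
  } else {
    n_int <- max(1L, as.integer(round(t_exp / stack$dt)))
    n_frames <- ncol(stack$frames) %/% n_int
    if (n_frames < 2) stop("stack too short for the requested exposure time")
    npx <- nrow(stack$frames)
    frames <- matrix(0, npx, n_frames)
    for (f in seq_len(n_frames)) {
      idx <- ((f - 1) * n_int + 1):(f * n_int)
      frames[, f] <- rowSums(stack$frames[, idx, drop = FALSE])
    }
  }
  frames <- frames / mean(frames)  # unit-mean noiseless exposures
  n_frames <- ncol(frames)

  k2_of <- function(v) stats::var(v) / mean(v)^2
  kf2_frames <- apply(frames, 2, k2_of)

  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  pe <- frames * photon_scale
  counts <- matrix(stats::rpois(length(pe), pe), nrow(pe)) +
    matrix(stats::rnorm(length(pe), sd = read_noise_e), nrow(pe))
  k2_total_frames <- apply(counts, 2, k2_of)
  mean_pe_frames <- colMeans(counts)
  corr <- shot_read_dark_contrast(photon_scale, read_noise_e)
  # per-frame shot/read-corrected contrast, as an experimenter would form it
  kf2_hat <- k2_total_frames - 1 / pmax(mean_pe_frames, 1e-12) -
    read_noise_e^2 / pmax(mean_pe_frames, 1e-12)^2

  beta_est <- if (stack$integrated) NA_real_ else {
    mean(apply(stack$frames[, seq_len(min(16, ncol(stack$frames))), drop = FALSE],
               2, k2_of))
  }
  nio_est <- 2 * mean(kf2_frames)^2 / stats::var(kf2_frames)

  list(
    budget = speckle_contrast_budget(
      t_exp, kf2 = mean(kf2_frames), ks2 = corr$ks2, kr2 = corr$kr2, kd2 = 0
    ),
    sigma_k2 = stats::sd(kf2_hat),
    mean_kf2_hat = mean(kf2_hat),
    beta_est = beta_est,
    nio_est = nio_est,
    n_frames = n_frames,
    kf2_frames = kf2_frames
  )
}

#' Empirical coherence parameter of unpolarized speckle sampling
#'
#' The short-exposure squared contrast beta(s/p): computed once per
#' speckle-to-pixel ratio from independent snapshots of the field simulator
#' and cached for the session (a fixed internal seed keeps the calibration
#' deterministic across sessions).
#'
#' @param s_over_p Speckle-to-pixel size ratio.
#' @param grid_size Sensor pixels per side used for the calibration.
#' @param n_frames Number of independent snapshots.
#' @param polarized Single polarization if TRUE.
#' @return beta, the expected zero-exposure squared contrast.
#' @export
speckle_beta <- function(s_over_p, grid_size = 32, n_frames = 128,
                         polarized = FALSE) {
  key <- sprintf("beta_%g_%d_%d_%d", s_over_p, grid_size, n_frames, polarized)
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)
  # a == 0 between substeps: each "frame" is an independent speckle pattern
  stack <- speckle_field_sequence(
    g1_target = function(u) ifelse(u == 0, 1, 0),
    s_over_p = s_over_p, grid_size = grid_size, substeps = n_frames,
    dt = 1, seed = 715517, polarized = polarized
  )
  k2 <- apply(stack$frames, 2, function(v) stats::var(v) / mean(v)^2)
  beta <- mean(k2)
  cache_set(key, beta)
  beta
}

.speckleflow_cache <- new.env(parent = emptyenv())
cache_get <- function(key) {
  if (exists(key, envir = .speckleflow_cache)) get(key, envir = .speckleflow_cache)
  else NULL
}
cache_set <- function(key, value) assign(key, value, envir = .speckleflow_cache)
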