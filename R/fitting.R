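#' Settings for blood-flow-index fitting
#'
#' The assumed homogeneous optical properties, coherence parameter and search
#' bounds used by the semi-infinite inverse models. Defaults follow the
#' standard fitting assumptions: mu_a = 0.15 1/cm, mu_s' per wavelength, beta
#' known.
#'
#' @param optics Assumed [optical_properties()] (see
#'   [fitting_optical_properties()]).
#' @param wavelength_nm Wavelength (nm) fixing the in-medium wavenumber.
#' @param beta Assumed (known) coherence parameter.
#' @param fit_fraction Fraction of the g2 decay used for fitting, in (0, 1].
#' @param bfi_bounds Search bounds for BFi (cm^2/s).
#' @param tol Relative optimizer tolerance on log10(BFi).
#' @return An object of class `fit_settings`.
#' @export
fit_settings <- function(optics = fitting_optical_properties(850),
                         wavelength_nm = 850, beta = 0.5, fit_fraction = 1,
                         bfi_bounds = c(1e-12, 1e-4), tol = 1e-8) {
  stopifnot(inherits(optics, "optical_properties"))
  if (fit_fraction <= 0 || fit_fraction > 1) stop("fit_fraction must be in (0, 1]")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  if (any(bfi_bounds <= 0) || bfi_bounds[1] >= bfi_bounds[2]) {
    stop("bfi_bounds must be positive with lower < upper")
  }
  structure(list(optics = optics, wavelength_nm = wavelength_nm, beta = beta,
                 fit_fraction = fit_fraction, bfi_bounds = bfi_bounds,
                 tol = tol),
            class = "fit_settings")
}

#' Effective single-exponential decay rate of g2
#'
#' Least-squares fit of `g2(tau) = 1 + beta * exp(-Gamma * tau)`. When `beta`
#' is not supplied it is profiled out analytically at each candidate Gamma.
#' This is the Gamma entering the correlation noise model.
#'
#' @param g2 A [correlation_curve()] of kind `intensity_g2`.
#' @param beta Known coherence parameter; default uses the curve's own beta,
#'   or profiles it when absent.
#' @return Gamma (1/s).
#' @export
estimate_decay_rate <- function(g2, beta = NULL) {
  stopifnot(inherits(g2, "correlation_curve"))
  if (g2$kind != "intensity_g2") stop("estimate_decay_rate expects a g2 curve")
  if (is.null(beta)) beta <- g2$beta
  tau <- g2$tau
  y <- g2$values - 1
  amp <- max(y)
  if (amp < 0.1 * (if (is.null(beta)) amp + 1 else beta)) {
    stop("no visible decay in the g2 curve")
  }
  sse <- function(log10_gamma) {
    e <- exp(-10^log10_gamma * tau)
    b <- if (is.null(beta)) sum(y * e) / sum(e^2) else beta
    sum((y - b * e)^2)
  }
  # bracket the decay rate: delays where the curve has halved
  half_idx <- which(y <= amp / 2)
  g0 <- if (length(half_idx) > 0 && tau[half_idx[1]] > 0) {
    log(2) / tau[half_idx[1]]
  } else {
    1 / max(tau[tau > 0])
  }
  opt <- stats::optimize(sse, log10(g0) + c(-3, 3), tol = 1e-9)
  10^opt$minimum
}

#' Fit-range cutoff on the g2 decay
#'
#' The smallest grid delay at which the fraction
#' `(g2(0) - g2(tau)) / (g2(0) - 1)` of the total decay amplitude has been
#' completed. Computed on a noiseless reference curve; `fraction = 1` returns
#' the last grid point.
#'
#' @param g2 A noiseless [correlation_curve()] of kind `intensity_g2`.
#' @param fraction Fraction of the decay amplitude, in (0, 1].
#' @return The cutoff delay tau_max (s).
#' @export
fit_range_cutoff <- function(g2, fraction) {
  stopifnot(inherits(g2, "correlation_curve"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (fraction == 1) return(g2$tau[length(g2$tau)])
  v <- g2$values
  done <- (v[1] - v) / (v[1] - 1)
  idx <- which(done >= fraction)
  if (length(idx) == 0) return(g2$tau[length(g2$tau)])
  g2$tau[idx[1]]
}

#' Fit the blood flow index from a noisy g2 curve
#'
#' Nonlinear least squares of the semi-infinite correlation diffusion model
#' (through the Siegert relation) against a measured g2 curve, over BFi alone:
#' beta and the optical properties are fixed at their assumed values. The fit
#' is a bounded scalar minimization on log10(BFi).
#'
#' @param noisy_g2 A [correlation_curve()] of kind `intensity_g2`.
#' @param settings A [fit_settings()].
#' @param geometry A [semi_infinite_geometry()] built from the assumed optics
#'   at the measurement separation; if NULL it is built from `settings` and
#'   `sds_mm`.
#' @param sds_mm Separation (mm), used when `geometry` is NULL.
#' @param tau_max Restrict the fit to delays <= tau_max (from
#'   [fit_range_cutoff()]); NULL uses the whole grid.
#' @return An object of class `bfi_fit` with fields `bfi` (cm^2/s),
#'   `residual_norm`, `converged`, `n_eval`, `modality`.
#' @export
fit_bfi_from_g2 <- function(noisy_g2, settings, geometry = NULL, sds_mm = NULL,
                            tau_max = NULL) {
  stopifnot(inherits(noisy_g2, "correlation_curve"),
            inherits(settings, "fit_settings"))
  if (is.null(geometry)) {
    if (is.null(sds_mm)) stop("provide geometry or sds_mm")
    geometry <- semi_infinite_geometry(sds_mm, settings$optics,
                                       settings$wavelength_nm)
  }
  tau <- noisy_g2$tau
  y <- noisy_g2$values
  if (!is.null(tau_max)) {
    keep <- tau <= tau_max
    tau <- tau[keep]; y <- y[keep]
  }
  beta <- settings$beta
  n_eval <- 0L
  sse <- function(log_bfi) {
    n_eval <<- n_eval + 1L
    g1 <- semi_infinite_g1_values(geometry, 10^log_bfi, tau)
    sum((y - 1 - beta * g1^2)^2)
  }
  lb <- log10(settings$bfi_bounds[1]); ub <- log10(settings$bfi_bounds[2])
  opt <- stats::optimize(sse, c(lb, ub), tol = max(settings$tol, 1e-10) * (ub - lb))
  bfi <- 10^opt$minimum
  converged <- opt$minimum > lb + 1e-3 && opt$minimum < ub - 1e-3 &&
    is.finite(opt$objective)
  new_bfi_fit(bfi, sqrt(opt$objective), converged, n_eval, "dcs")
}

#' Fit the blood flow index from squared speckle contrast
#'
#' Minimizes the squared error between observed fundamental squared contrast
#' values and the model prediction (the exposure-weighted integral of the
#' squared semi-infinite field correlation) over BFi, for one or several
#' exposures.
#'
#' @param kf2_samples Data frame with columns `t_exp` (s) and `kf2`, one row
#'   per exposure sample (a single row is the standard single-exposure case).
#' @param settings A [fit_settings()].
#' @param geometry,sds_mm As in [fit_bfi_from_g2()].
#' @return An object of class `bfi_fit`.
#' @export
fit_bfi_from_contrast <- function(kf2_samples, settings, geometry = NULL,
                                  sds_mm = NULL) {
  stopifnot(inherits(settings, "fit_settings"))
  if (is.numeric(kf2_samples) && length(kf2_samples) == 2 &&
      !is.data.frame(kf2_samples)) {
    kf2_samples <- data.frame(t_exp = kf2_samples[1], kf2 = kf2_samples[2])
  }
  if (nrow(kf2_samples) < 1) stop("at least one (t_exp, kf2) sample required")
  beta <- settings$beta
  if (any(kf2_samples$kf2 <= 0) || any(kf2_samples$kf2 >= beta)) {
    stop("kf2 out of range: must lie in (0, beta)")
  }
  if (is.null(geometry)) {
    if (is.null(sds_mm)) stop("provide geometry or sds_mm")
    geometry <- semi_infinite_geometry(sds_mm, settings$optics,
                                       settings$wavelength_nm)
  }
  n_eval <- 0L
  model_kf2 <- function(bfi, t_exp) {
    g1f <- function(u) semi_infinite_g1_values(geometry, bfi, u)
    speckle_contrast_from_g1(g1f, beta, t_exp)
  }
  sse <- function(log_bfi) {
    n_eval <<- n_eval + 1L
    bfi <- 10^log_bfi
    pred <- vapply(kf2_samples$t_exp, function(te) model_kf2(bfi, te), numeric(1))
    sum((kf2_samples$kf2 - pred)^2)
  }
  lb <- log10(settings$bfi_bounds[1]); ub <- log10(settings$bfi_bounds[2])
  opt <- stats::optimize(sse, c(lb, ub), tol = max(settings$tol, 1e-10) * (ub - lb))
  bfi <- 10^opt$minimum
  converged <- opt$minimum > lb + 1e-3 && opt$minimum < ub - 1e-3 &&
    is.finite(opt$objective)
  new_bfi_fit(bfi, sqrt(opt$objective), converged, n_eval, "scos")
}

new_bfi_fit <- function(bfi, residual_norm, converged, n_eval, modality) {
  structure(list(bfi = bfi, residual_norm = residual_norm,
                 converged = converged, n_eval = n_eval, modality = modality),
            class = "bfi_fit")
}

#' @export
print.bfi_fit <- function(x, ...) {
  cat(sprintf("BFi fit (%s): %.4g cm^2/s, residual %.3g, %sconverged (%d evals)\n",
              x$modality, x$bfi, x$residual_norm,
              if (x$converged) "" else "NOT ", x$n_eval))
  invisible(x)
}

#' @export
coef.bfi_fit <- function(object, ...) c(bfi = object$bfi)

# Ensemble fitting over noise realizations; failed / out-of-range fits are
# excluded and counted. Returns the fitted BFi vector and a failure count.
fit_bfi_ensemble <- function(realizations, fit_one) {
  n <- ncol(realizations)
  bfi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch(fit_one(realizations[, i]), error = function(e) NULL)
    if (!is.null(res) && res$converged) bfi[i] <- res$bfi
  }
  failed <- sum(is.na(bfi))
  if (failed > 0.05 * n) {
    warning(sprintf("ensemble flagged invalid: %d of %d fits failed", failed, n))
  }
  list(bfi = bfi[!is.na(bfi)], n_failed = failed, invalid = failed > 0.05 * n)
}
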