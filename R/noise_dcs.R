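#' Correlation-function noise model parameters
#'
#' Parameters of the analytic noise model for the standard deviation of a
#' photon-counting intensity autocorrelation estimate: correlator bin width
#' `T`, averaging time `t`, coherence parameter `beta`, effective
#' single-exponential decay rate `Gamma` of g2, and the mean photon counts per
#' bin `n = rate * T`.
#'
#' @param bin_width_T Correlator bin width (s), > 0.
#' @param averaging_time_t Averaging time (s), >= T.
#' @param beta Coherence parameter in (0, 1].
#' @param gamma Effective decay rate of g2 (1/s), > 0.
#' @param counts_per_bin_n Mean photon counts per bin, > 0.
#' @return An object of class `dcs_noise_params`.
#' @export
dcs_noise_params <- function(bin_width_T, averaging_time_t, beta, gamma,
                             counts_per_bin_n) {
  if (!is.finite(bin_width_T) || bin_width_T <= 0) stop("T must be > 0")
  if (!is.finite(averaging_time_t) || averaging_time_t < bin_width_T) {
    stop("averaging time t must be >= T")
  }
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.finite(counts_per_bin_n) || counts_per_bin_n <= 0) {
    stop("counts_per_bin_n must be > 0")
  }
  structure(list(bin_width_T = bin_width_T, averaging_time_t = averaging_time_t,
                 beta = beta, gamma = gamma,
                 counts_per_bin_n = counts_per_bin_n),
            class = "dcs_noise_params")
}

#' Standard deviation of the intensity autocorrelation estimate
#'
#' Analytic shot-noise/speckle-noise model for the per-delay standard
#' deviation of g2 measured with a photon-counting correlator:
#' \deqn{\sigma(\tau) = \sqrt{T/t}\,\Big[
#'   \beta^2 \frac{(1+e^{-2\Gamma T})(1+e^{-2\Gamma\tau})
#'     + 2\frac{\tau}{T}(1-e^{-2\Gamma T}) e^{-2\Gamma\tau}}{1-e^{-2\Gamma T}}
#'   + 2\langle n\rangle^{-1}\beta(1+e^{-2\Gamma\tau})
#'   + \langle n\rangle^{-2}(1+\beta e^{-\Gamma\tau})\Big]^{1/2}.}
#' The first bracket term is count-rate independent (speckle noise); the
#' remaining terms are the shot-noise contributions.
#'
#' @param params A [dcs_noise_params()] object.
#' @param tau Delay grid (s), >= 0.
#' @return Numeric vector sigma(tau), same length as `tau`.
#' @export
dcs_noise_sigma <- function(params, tau) {
  stopifnot(inherits(params, "dcs_noise_params"))
  if (any(!is.finite(tau)) || any(tau < 0)) stop("tau must be finite and >= 0")
  Tb <- params$bin_width_T
  t_avg <- params$averaging_time_t
  beta <- params$beta
  G <- params$gamma
  n <- params$counts_per_bin_n
  if (G * Tb == 0) stop("Gamma * T must be > 0")
  e2T <- exp(-2 * G * Tb)
  e2t <- exp(-2 * G * tau)
  e1t <- exp(-G * tau)
  bracket <- beta^2 * ((1 + e2T) * (1 + e2t) + 2 * (tau / Tb) * (1 - e2T) * e2t) /
    (1 - e2T) +
    2 / n * beta * (1 + e2t) +
    1 / n^2 * (1 + beta * e1t)
  sqrt(Tb / t_avg) * sqrt(bracket)
}

#' Gaussian noise realizations of a correlation curve
#'
#' Adds independent zero-mean Gaussian perturbations with per-delay standard
#' deviation `sigma` to the input curve, one column per realization.
#'
#' @param curve A [correlation_curve()].
#' @param sigma Per-delay noise standard deviation, same length as the curve's
#'   tau grid (or a scalar).
#' @param n_real Number of realizations, >= 1.
#' @param seed Integer RNG seed; the same seed reproduces the same set.
#' @return Numeric matrix with `length(curve$tau)` rows and `n_real` columns.
#' @export
gaussian_noise_realizations <- function(curve, sigma, n_real, seed) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(sigma) == 1) sigma <- rep(sigma, length(curve$tau))
  if (length(sigma) != length(curve$tau)) {
    stop("sigma must align with the curve's delay grid")
  }
  if (any(!is.finite(sigma)) || any(sigma < 0)) stop("sigma must be >= 0")
  if (n_real < 1) stop("n_real must be >= 1")
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  nt <- length(curve$tau)
  noise <- matrix(stats::rnorm(nt * n_real), nrow = nt) * sigma
  curve$values + noise
}
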