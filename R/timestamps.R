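#' Simulated photon timestamp series
#'
#' Doubly stochastic Poisson arrivals driven by a fluctuating speckle
#' intensity: the intensity is the sum of `1/beta` independent speckle
#' channels, each the squared modulus of a complex AR(1) Gaussian process with
#' field correlation `exp(-gamma_field * tau)`; dark counts add an independent
#' homogeneous Poisson stream; a detector hold-off (dead time) discards any
#' event arriving within `hold_off` of the previously accepted event.
#'
#' For a single-exponential field correlation the resulting intensity
#' autocorrelation is `g2 = 1 + beta exp(-2 gamma_field tau)`, i.e. an
#' effective g2 decay rate `Gamma = 2 * gamma_field`.
#'
#' @param mean_rate Mean signal count rate (counts/s) before dead-time losses.
#' @param duration Series duration (s).
#' @param gamma_field Field decay rate (1/s); ignored when
#'   `constant_intensity = TRUE`.
#' @param beta Target coherence parameter; `round(1/beta)` speckle channels
#'   are summed.
#' @param dark_rate Dark count rate (counts/s).
#' @param hold_off Detector dead time (s), >= 0.
#' @param seed Integer RNG seed.
#' @param constant_intensity If TRUE the intensity is constant (homogeneous
#'   Poisson signal).
#' @param substep Intensity sampling interval (s); defaults to
#'   `min(1 / (16 * gamma_field), 16e-6)`. Use `substep = first_bin` of the
#'   downstream correlator when sub-bin fidelity matters.
#' @return An object of class `timestamp_series` with fields `event_times`
#'   (strictly increasing, s), `duration` and `applied_hold_off`.
#' @export
photon_timestamps <- function(mean_rate, duration, gamma_field = NULL,
                              beta = 0.5, dark_rate = 0, hold_off = 0, seed = 1,
                              constant_intensity = FALSE, substep = NULL) {
  if (hold_off < 0) stop("hold_off must be >= 0")
  if (mean_rate < 0 || dark_rate < 0) stop("rates must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  fluct <- !constant_intensity
  if (fluct) {
    if (is.null(gamma_field) || gamma_field <= 0) {
      stop("gamma_field must be > 0 for a fluctuating intensity")
    }
    if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
    if (is.null(substep)) substep <- min(1 / (16 * gamma_field), 1e-6 * 16)
    n_modes <- max(1L, as.integer(round(1 / beta)))
  } else {
    gamma_field <- 1
    if (is.null(substep)) substep <- duration / 1e5
    n_modes <- 1L
  }
  times <- photon_timestamps_cpp(mean_rate, duration, n_modes, gamma_field,
                                 substep, dark_rate, hold_off, fluct,
                                 as.integer(seed))
  structure(
    list(event_times = times, duration = duration, applied_hold_off = hold_off,
         mean_rate = mean_rate, dark_rate = dark_rate,
         beta_target = if (fluct) 1 / n_modes else NA_real_),
    class = "timestamp_series"
  )
}

#' @export
print.timestamp_series <- function(x, ...) {
  cat(sprintf(
    "Timestamp series: %d events over %.3g s (%.4g cps), hold-off %.3g s\n",
    length(x$event_times), x$duration,
    length(x$event_times) / x$duration, x$applied_hold_off
  ))
  invisible(x)
}

#' Multi-tau autocorrelation of a timestamp series
#'
#' Software correlator: counts are binned at `first_bin` width; lags
#' `1..2m` bins are evaluated, the bin stream is coarsened by summing adjacent
#' pairs, and lags `m+1..2m` are evaluated at each coarser level
#' (`m = bins_per_octave`). Normalization is symmetric (the raw pair average
#' divided by the means of the leading and trailing count windows).
#'
#' @param series A [timestamp_series()] (or a numeric vector of event times
#'   with a `duration` attribute supplied via the `duration` argument).
#' @param first_bin Width of the finest correlator bin (s).
#' @param bins_per_octave Lags per octave before coarsening.
#' @param tau_max Largest delay evaluated (s).
#' @param duration Series duration; taken from `series` when it is a
#'   `timestamp_series`.
#' @param coarsen Coarsen bins by two per octave (the multi-tau scheme). With
#'   `coarsen = FALSE` the same quasi-logarithmic lag ladder is evaluated on
#'   the fixed `first_bin` width at every lag, matching the fixed-bin-width
#'   assumption of the analytic correlation noise model.
#' @return A list: `g2` (a [correlation_curve()] of kind `intensity_g2` with
#'   `beta` set to the observed zero-delay excess), `counts_per_bin` (mean
#'   counts in the finest bin, the `<n>` of the noise model), and `n_events`.
#' @export
multitau_autocorrelation <- function(series, first_bin = 1e-6,
                                     bins_per_octave = 8, tau_max = 0.1,
                                     duration = NULL, coarsen = TRUE) {
  if (inherits(series, "timestamp_series")) {
    times <- series$event_times
    duration <- series$duration
  } else {
    times <- as.numeric(series)
    if (is.null(duration)) stop("duration must be supplied for a raw series")
  }
  if (length(times) < 100) stop("insufficient data: fewer than 100 events")
  res <- multitau_cpp(times, duration, first_bin, as.integer(bins_per_octave),
                      tau_max, coarsen)
  beta_obs <- max(res$g2[1] - 1, 1e-6)
  g2 <- correlation_curve(res$tau, res$g2, "intensity_g2",
                          beta = min(beta_obs, 1))
  list(g2 = g2, counts_per_bin = res$counts_per_bin, n_events = res$n_events)
}
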