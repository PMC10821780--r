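#' Correlation curve container
#'
#' A delay grid together with field (`g1`) or intensity (`g2`) autocorrelation
#' values. For `g2` curves the coherence parameter `beta` is carried along.
#'
#' @param tau Delay grid (s), non-negative, strictly increasing.
#' @param values Correlation values, same length as `tau`.
#' @param kind Either `"field_g1"` or `"intensity_g2"`.
#' @param beta Coherence parameter in (0, 1]; required for `g2` curves.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(tau, values, kind = c("field_g1", "intensity_g2"),
                              beta = NULL) {
  kind <- match.arg(kind)
  if (length(tau) != length(values)) stop("tau and values must have equal length")
  if (any(!is.finite(tau)) || tau[1] < 0 || any(diff(tau) <= 0)) {
    stop("tau must be non-negative and strictly increasing")
  }
  if (any(!is.finite(values))) stop("correlation values must be finite")
  if (kind == "intensity_g2") {
    if (is.null(beta)) stop("beta is required for an intensity g2 curve")
    if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  }
  structure(
    list(tau = as.numeric(tau), values = as.numeric(values), kind = kind,
         beta = beta),
    class = "correlation_curve"
  )
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "Correlation curve (%s): %d delays on [%.3g, %.3g] s%s\n",
    x$kind, length(x$tau), min(x$tau), max(x$tau),
    if (!is.null(x$beta)) sprintf(", beta = %.3g", x$beta) else ""
  ))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  tau <- x$tau
  pos <- tau > 0
  plot(tau[pos], x$values[pos], log = "x", type = "l",
       xlab = expression(tau ~ "(s)"),
       ylab = if (x$kind == "field_g1") expression(g[1](tau)) else expression(g[2](tau)),
       ...)
  invisible(x)
}

#' Quasi-logarithmic delay grid
#'
#' Delay grid mimicking a multi-tau hardware correlator: linear spacing
#' `first_bin` over the first octave, then the spacing doubles every
#' `bins_per_octave` bins.
#'
#' @param first_bin Width of the first delay bin (s).
#' @param bins_per_octave Number of bins before the bin width doubles.
#' @param tau_max Largest delay (s).
#' @param include_zero Prepend tau = 0 (useful for normalized curves).
#' @return Numeric vector of delays (s).
#' @export
tau_grid_multitau <- function(first_bin = 1e-6, bins_per_octave = 8,
                              tau_max = 0.1, include_zero = FALSE) {
  if (first_bin <= 0 || tau_max <= first_bin) stop("invalid grid parameters")
  taus <- numeric(0)
  width <- first_bin
  tau <- 0
  repeat {
    for (i in seq_len(bins_per_octave)) {
      tau <- tau + width
      if (tau > tau_max * (1 + 1e-12)) break
      taus <- c(taus, tau)
    }
    if (tau > tau_max * (1 + 1e-12)) break
    width <- width * 2
  }
  if (include_zero) taus <- c(0, taus)
  taus
}

#' Field autocorrelation of a semi-infinite diffusing medium
#'
#' Normalized field autocorrelation g1(tau) for a point source and detector on
#' the surface of a homogeneous semi-infinite medium (reflectance geometry):
#' \deqn{g_1(\tau) = \frac{r_b e^{-K(\tau) r_1} - r_1 e^{-K(\tau) r_b}}
#'                       {r_b e^{-K_0 r_1} - r_1 e^{-K_0 r_b}}}
#' with \eqn{K(\tau) = \sqrt{3\mu_a\mu_s' + 6 k^2 \mu_s'^2 \mathrm{BFi}\,\tau}},
#' \eqn{K_0 = K(0)}, and `k` the in-medium wavenumber.
#'
#' @param geometry A [semi_infinite_geometry()] object.
#' @param bfi Blood flow index (cm^2/s), >= 0.
#' @param tau Delay grid (s), non-negative, increasing.
#' @return A [correlation_curve()] of kind `field_g1`; g1(0) = 1 exactly.
#' @examples
#' geom <- semi_infinite_geometry(25, optical_properties(0.15, 8.5, 1.4), 850)
#' g1 <- semi_infinite_g1(geom, 6e-8, tau_grid_multitau(include_zero = TRUE))
#' @export
semi_infinite_g1 <- function(geometry, bfi, tau) {
  stopifnot(inherits(geometry, "semi_infinite_geometry"))
  if (!is.finite(bfi) || bfi < 0) stop("bfi must be finite and >= 0")
  if (any(!is.finite(tau)) || any(tau < 0)) stop("tau must be finite and >= 0")
  vals <- semi_infinite_g1_values(geometry, bfi, tau)
  correlation_curve(tau, vals, "field_g1")
}

# Vectorized evaluation without the container (hot path for fitting).
semi_infinite_g1_values <- function(geometry, bfi, tau) {
  g <- geometry
  op <- g$optics
  K0 <- sqrt(3 * op$mu_a * op$mu_s_prime)
  Kt <- sqrt(3 * op$mu_a * op$mu_s_prime +
               6 * g$k^2 * op$mu_s_prime^2 * bfi * tau)
  denom <- g$r_b * exp(-K0 * g$r1) - g$r1 * exp(-K0 * g$r_b)
  num <- g$r_b * exp(-Kt * g$r1) - g$r1 * exp(-Kt * g$r_b)
  num / denom
}

#' Siegert relation: intensity autocorrelation from field autocorrelation
#'
#' `g2(tau) = 1 + beta * g1(tau)^2`, where beta is the coherence parameter set
#' by the source coherence and the number of detected speckle modes.
#'
#' @param g1 A [correlation_curve()] of kind `field_g1`.
#' @param beta Coherence parameter in (0, 1].
#' @return A [correlation_curve()] of kind `intensity_g2`.
#' @export
siegert_g2 <- function(g1, beta) {
  stopifnot(inherits(g1, "correlation_curve"))
  if (g1$kind != "field_g1") stop("siegert_g2 expects a field g1 curve")
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  correlation_curve(g1$tau, 1 + beta * g1$values^2, "intensity_g2", beta = beta)
}

#' Fundamental squared speckle contrast from a field autocorrelation
#'
#' Exposure-time-weighted integral of the squared field autocorrelation:
#' \deqn{K_f^2 = \frac{2\beta}{T_{exp}} \int_0^{T_{exp}} g_1^2(\tau)
#'              \left(1 - \frac{\tau}{T_{exp}}\right) d\tau.}
#' As the exposure shrinks to zero `Kf^2 -> beta`; it decreases monotonically
#' with exposure for any decaying g1.
#'
#' @param g1 Either a [correlation_curve()] of kind `field_g1` (interpolated
#'   linearly in tau, extended by zero past the last grid point) or a function
#'   `g1(tau)` vectorized over tau.
#' @param beta Coherence parameter in (0, 1].
#' @param t_exp Exposure time (s), > 0.
#' @param rel_tol Relative quadrature tolerance.
#' @return The fundamental squared contrast Kf^2, a scalar in (0, beta].
#' @export
speckle_contrast_from_g1 <- function(g1, beta, t_exp, rel_tol = 1e-6) {
  if (!is.finite(t_exp) || t_exp <= 0) stop("t_exp must be finite and > 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  f <- g1_as_function(g1)
  integrand <- function(u) f(u)^2 * (1 - u / t_exp)
  # Truncate where g1^2 is negligible: a correlation decaying orders of
  # magnitude faster than the exposure otherwise defeats adaptive quadrature.
  probe <- t_exp * 10^seq(-9, 0, length.out = 46)
  alive <- which(f(probe) > 1e-7)
  upper <- if (length(alive) == 0) probe[1] else {
    min(t_exp, probe[min(length(probe), max(alive) + 1)])
  }
  val <- stats::integrate(integrand, 0, upper, rel.tol = rel_tol,
                          subdivisions = 400L)$value
  2 * beta / t_exp * val
}

# Coerce a g1 curve or function to a vectorized function of tau.
g1_as_function <- function(g1) {
  if (is.function(g1)) return(g1)
  stopifnot(inherits(g1, "correlation_curve"))
  if (g1$kind != "field_g1") stop("expected a field g1 curve")
  tau <- g1$tau
  val <- g1$values
  if (tau[1] > 0) {  # anchor the normalized zero-delay value
    tau <- c(0, tau)
    val <- c(1, val)
  }
  function(u) {
    out <- stats::approx(tau, val, xout = pmin(u, max(tau)), rule = 2)$y
    out[u > max(tau)] <- 0
    out
  }
}
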