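#' Optical properties of a tissue
#'
#' Container for the absorption coefficient, reduced scattering coefficient
#' and refractive index of a single tissue type. Internal units are
#' centimetres: `mu_a` and `mu_s_prime` in 1/cm.
#'
#' @param mu_a Absorption coefficient (1/cm), >= 0.
#' @param mu_s_prime Reduced scattering coefficient (1/cm), > 0.
#' @param refractive_index Refractive index (dimensionless), >= 1.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(0.17, 11.6, 1.4)
#' @export
optical_properties <- function(mu_a, mu_s_prime, refractive_index = 1.4) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s_prime), is.numeric(refractive_index))
  if (!is.finite(mu_a) || mu_a < 0) stop("mu_a must be finite and >= 0")
  if (!is.finite(mu_s_prime) || mu_s_prime <= 0) stop("mu_s_prime must be finite and > 0")
  if (!is.finite(refractive_index) || refractive_index < 1) {
    stop("refractive_index must be finite and >= 1")
  }
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, refractive_index = refractive_index),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mu_a = %.4g 1/cm, mu_s' = %.4g 1/cm, n = %.3g\n",
    x$mu_a, x$mu_s_prime, x$refractive_index
  ))
  invisible(x)
}

#' Flow state: blood flow index per tissue
#'
#' The blood flow index (BFi, cm^2/s) is the effective Brownian diffusion
#' coefficient of the moving scatterers; the mean squared displacement over a
#' delay tau is `6 * BFi * tau`.
#'
#' @param bfi_by_tissue Named numeric vector mapping tissue label to BFi
#'   (cm^2/s), all >= 0.
#' @return An object of class `flow_state`.
#' @examples
#' flow_state(c(scalp = 1e-8, skull = 1e-10, csf = 1e-10, brain = 6e-8))
#' @export
flow_state <- function(bfi_by_tissue) {
  if (is.null(names(bfi_by_tissue)) || any(!nzchar(names(bfi_by_tissue)))) {
    stop("bfi_by_tissue must be a named numeric vector")
  }
  if (any(!is.finite(bfi_by_tissue)) || any(bfi_by_tissue < 0)) {
    stop("all BFi values must be finite and >= 0")
  }
  structure(list(bfi_by_tissue = bfi_by_tissue), class = "flow_state")
}

#' Effective reflection coefficient at a tissue-air boundary
#'
#' Polynomial approximation of the effective Fresnel reflection coefficient
#' used in the extrapolated-boundary condition of the diffusion model:
#' `Reff(n) = -1.440 n^-2 + 0.71 n^-1 + 0.668 + 0.0636 n`.
#'
#' @param n Refractive index of the medium (>= 1).
#' @return The effective reflection coefficient (dimensionless).
#' @examples
#' effective_reflection_coefficient(1.4)
#' @export
effective_reflection_coefficient <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) stop("refractive index must be finite and >= 1")
  -1.440 / n^2 + 0.71 / n + 0.668 + 0.0636 * n
}

#' Semi-infinite reflectance geometry for the correlation diffusion model
#'
#' Precomputes the image-source distances entering the semi-infinite solution
#' of the correlation diffusion equation: the reduced mean free path
#' `l* = 1/mu_s'`, the extrapolated boundary distance
#' `z_b = (2 / (3 mu_s')) (1 + Reff) / (1 - Reff)`, the source-detector
#' distances `r1 = sqrt(rho^2 + l*^2)` and `rb = sqrt(rho^2 + (l* + 2 z_b)^2)`,
#' and the in-medium wavenumber `k = 2 pi n / lambda`.
#'
#' @param sds_mm Source-detector separation on the surface (mm).
#' @param optics An [optical_properties()] object (the homogeneous-medium
#'   properties assumed by the model).
#' @param wavelength_nm Vacuum wavelength (nm).
#' @return An object of class `semi_infinite_geometry` with fields `rho`,
#'   `l_star`, `z_b`, `r1`, `r_b`, `R_eff`, `k` (all cm or 1/cm) plus the
#'   optics used.
#' @examples
#' semi_infinite_geometry(25, optical_properties(0.15, 8.5, 1.4), 850)
#' @export
semi_infinite_geometry <- function(sds_mm, optics, wavelength_nm) {
  stopifnot(inherits(optics, "optical_properties"))
  if (!is.finite(sds_mm) || sds_mm <= 0) stop("sds_mm must be finite and > 0")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0) stop("wavelength_nm must be > 0")
  rho <- sds_mm / 10                      # cm
  l_star <- 1 / optics$mu_s_prime        # cm
  R_eff <- effective_reflection_coefficient(optics$refractive_index)
  z_b <- (2 / (3 * optics$mu_s_prime)) * (1 + R_eff) / (1 - R_eff)
  r1 <- sqrt(rho^2 + l_star^2)
  r_b <- sqrt(rho^2 + (l_star + 2 * z_b)^2)
  k <- 2 * pi * optics$refractive_index / (wavelength_nm * 1e-7)  # 1/cm
  structure(
    list(
      rho = rho, l_star = l_star, z_b = z_b, r1 = r1, r_b = r_b,
      R_eff = R_eff, k = k, optics = optics, wavelength_nm = wavelength_nm,
      sds_mm = sds_mm
    ),
    class = "semi_infinite_geometry"
  )
}

#' @export
print.semi_infinite_geometry <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Semi-infinite geometry: rho = %.3g cm, l* = %.4g cm, z_b = %.4g cm,\n",
      "  r1 = %.4g cm, r_b = %.4g cm, Reff = %.4g, k = %.6g 1/cm (%g nm)\n"
    ),
    x$rho, x$l_star, x$z_b, x$r1, x$r_b, x$R_eff, x$k, x$wavelength_nm
  ))
  invisible(x)
}

#' Head-tissue optical and flow properties used throughout the package
#'
#' Returns the per-tissue absorption, reduced scattering, baseline and
#' activated ("perturbed", +20% brain flow) blood flow indices for the
#' four-layer head model (scalp, skull, CSF, brain) at the two operating
#' wavelengths the package supports natively.
#'
#' @param wavelength_nm 850 or 1064.
#' @return A data frame with one row per tissue and columns `tissue`, `mu_a`
#'   (1/cm), `mu_s_prime` (1/cm), `bfi_baseline` (cm^2/s), `bfi_perturbed`
#'   (cm^2/s), `refractive_index`.
#' @examples
#' head_tissue_properties(850)
#' @export
head_tissue_properties <- function(wavelength_nm = 850) {
  if (wavelength_nm == 850) {
    mu_a <- c(scalp = 0.164, skull = 0.155, csf = 0.017, brain = 0.170)
    mu_sp <- c(scalp = 7.4, skull = 8.1, csf = 0.1, brain = 11.6)
  } else if (wavelength_nm == 1064) {
    mu_a <- c(scalp = 0.11, skull = 0.13, csf = 0.122, brain = 0.17)
    mu_sp <- c(scalp = 5.3, skull = 5.8, csf = 0.07, brain = 8.3)
  } else {
    stop("native tissue property presets exist only at 850 and 1064 nm")
  }
  data.frame(
    tissue = c("scalp", "skull", "csf", "brain"),
    mu_a = unname(mu_a),
    mu_s_prime = unname(mu_sp),
    bfi_baseline = c(1e-8, 1e-10, 1e-10, 6e-8),
    bfi_perturbed = c(1e-8, 1e-10, 1e-10, 7.2e-8),
    refractive_index = 1.4,
    stringsAsFactors = FALSE
  )
}

#' Optical properties assumed when fitting blood flow
#'
#' Homogeneous-medium properties used by the semi-infinite inverse model
#' (independent of the layered truth): mu_a = 0.15 1/cm at both wavelengths,
#' mu_s' = 8.5 1/cm at 850 nm and 6.2 1/cm at 1064 nm, n = 1.4.
#'
#' @param wavelength_nm 850 or 1064.
#' @return An [optical_properties()] object.
#' @export
fitting_optical_properties <- function(wavelength_nm = 850) {
  if (wavelength_nm == 850) {
    optical_properties(0.15, 8.5, 1.4)
  } else if (wavelength_nm == 1064) {
    optical_properties(0.15, 6.2, 1.4)
  } else {
    stop("fitting property presets exist only at 850 and 1064 nm")
  }
}
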