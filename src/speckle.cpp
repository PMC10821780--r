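// Dynamic speckle field simulator.
//
// A fully developed speckle field is synthesized in the Fourier domain:
// independent circular-Gaussian amplitudes on the modes inside a circular
// aperture, inverse-transformed to a fine spatial grid. Temporal evolution is
// an AR(1) mixing of the k-space amplitudes: E_t = a_t E_{t-1} +
// sqrt(1 - a_t^2) * xi, which leaves the spatial statistics stationary and
// gives the field a lag correlation equal to the product of the step
// coefficients. Pixel intensities are block sums of the fine-grid intensity
// (oversample^2 fine cells per pixel); exposures integrate consecutive
// substeps. Unpolarized detection averages two independent field components.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix speckle_stack_cpp(int n_pix, int oversample, int n_substeps,
                                NumericVector a_coef,  // length n_substeps; a_coef[0] ignored
                                double mask_radius,    // k-space radius (fine-grid units)
                                bool polarized,
                                int substeps_per_frame, // 0: return substep frames
                                int seed) {
  const int nf = n_pix * oversample;       // fine grid side
  const int n_pol = polarized ? 1 : 2;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);

  // k-space mask (FFT layout: frequencies 0..nf/2, -nf/2..-1)
  arma::Mat<unsigned char> mask(nf, nf, arma::fill::zeros);
  int n_modes = 0;
  const double r2 = mask_radius * mask_radius;
  for (int i = 0; i < nf; ++i) {
    double ki = (i <= nf / 2) ? i : i - nf;
    for (int j = 0; j < nf; ++j) {
      double kj = (j <= nf / 2) ? j : j - nf;
      if (ki * ki + kj * kj <= r2) { mask(i, j) = 1; ++n_modes; }
    }
  }
  if (n_modes < 4) stop("aperture too small: fewer than 4 speckle modes");

  const int n_frames = (substeps_per_frame > 0)
      ? n_substeps / substeps_per_frame : n_substeps;
  if (n_frames < 1) stop("no complete frames: too few substeps");
  NumericMatrix out(n_pix * n_pix, n_frames);

  std::vector<arma::cx_mat> Ek(n_pol, arma::cx_mat(nf, nf, arma::fill::zeros));
  const double sqrt_half = std::sqrt(0.5);
  for (int p = 0; p < n_pol; ++p) {
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < nf; ++j)
        if (mask(i, j))
          Ek[p](i, j) = std::complex<double>(sqrt_half * N(rng), sqrt_half * N(rng));
  }

  arma::mat inten(nf, nf);
  arma::mat accum(nf, nf, arma::fill::zeros);
  int in_frame = 0, frame = 0;

  for (int t = 0; t < n_substeps; ++t) {
    if (t > 0) {
      double a = a_coef[t];
      double s = std::sqrt(std::max(0.0, 1.0 - a * a));
      for (int p = 0; p < n_pol; ++p) {
        for (int i = 0; i < nf; ++i)
          for (int j = 0; j < nf; ++j)
            if (mask(i, j))
              Ek[p](i, j) = a * Ek[p](i, j) +
                s * std::complex<double>(sqrt_half * N(rng), sqrt_half * N(rng));
      }
    }
    inten.zeros();
    for (int p = 0; p < n_pol; ++p) {
      arma::cx_mat field = arma::ifft2(Ek[p]);
      inten += arma::square(arma::real(field)) + arma::square(arma::imag(field));
    }

    if (substeps_per_frame > 0) {
      accum += inten;
      if (++in_frame == substeps_per_frame) {
        // block-sum fine grid into pixels
        for (int px = 0; px < n_pix; ++px)
          for (int py = 0; py < n_pix; ++py) {
            double v = 0.0;
            for (int ix = 0; ix < oversample; ++ix)
              for (int iy = 0; iy < oversample; ++iy)
                v += accum(px * oversample + ix, py * oversample + iy);
            out(px + n_pix * py, frame) = v;
          }
        accum.zeros();
        in_frame = 0;
        if (++frame >= n_frames) break;
      }
    } else {
      for (int px = 0; px < n_pix; ++px)
        for (int py = 0; py < n_pix; ++py) {
          double v = 0.0;
          for (int ix = 0; ix < oversample; ++ix)
            for (int iy = 0; iy < oversample; ++iy)
              v += inten(px * oversample + ix, py * oversample + iy);
          out(px + n_pix * py, t) = v;
        }
    }
  }
  out.attr("n_modes") = n_modes;
  return out;
}

// Lag correlation of the k-space field process itself is not observable from
// intensities; for validation the substep *field* is needed. This helper
// returns the complex field time series at a probe set of fine-grid points.
// [[Rcpp::export]]
ComplexMatrix speckle_field_probe_cpp(int nf, int n_substeps,
                                      NumericVector a_coef, double mask_radius,
                                      int n_probe, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  arma::Mat<unsigned char> mask(nf, nf, arma::fill::zeros);
  const double r2 = mask_radius * mask_radius;
  for (int i = 0; i < nf; ++i) {
    double ki = (i <= nf / 2) ? i : i - nf;
    for (int j = 0; j < nf; ++j) {
      double kj = (j <= nf / 2) ? j : j - nf;
      if (ki * ki + kj * kj <= r2) mask(i, j) = 1;
    }
  }
  arma::cx_mat Ek(nf, nf, arma::fill::zeros);
  const double sqrt_half = std::sqrt(0.5);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < nf; ++j)
      if (mask(i, j))
        Ek(i, j) = std::complex<double>(sqrt_half * N(rng), sqrt_half * N(rng));

  int stride = std::max(1, nf * nf / n_probe);
  ComplexMatrix out(n_probe, n_substeps);
  for (int t = 0; t < n_substeps; ++t) {
    if (t > 0) {
      double a = a_coef[t];
      double s = std::sqrt(std::max(0.0, 1.0 - a * a));
      for (int i = 0; i < nf; ++i)
        for (int j = 0; j < nf; ++j)
          if (mask(i, j))
            Ek(i, j) = a * Ek(i, j) +
              s * std::complex<double>(sqrt_half * N(rng), sqrt_half * N(rng));
    }
    arma::cx_mat field = arma::ifft2(Ek);
    for (int q = 0; q < n_probe; ++q) {
      std::complex<double> v = field(((size_t)q * stride) % (nf * nf));
      Rcomplex rc; rc.r = v.real(); rc.i = v.imag();
      out(q, t) = rc;
    }
  }
  return out;
}
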