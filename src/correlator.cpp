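// Photon timestamp generation (doubly stochastic Poisson process driven by a
// simulated speckle intensity) and a multi-tau software correlator with
// symmetric normalization.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Generate photon arrival times on [0, duration).
//
// The signal intensity is a sum of n_modes independent speckle channels, each
// the squared modulus of a complex AR(1) Gaussian field process with field
// correlation exp(-gamma * tau), sampled on substeps of width dt. Photon
// counts per substep are Poisson with mean (rate * I/<I> + dark_rate) * dt;
// event times are uniform within the substep. A detector hold-off discards
// any event closer than hold_off to the previously accepted event.
// [[Rcpp::export]]
NumericVector photon_timestamps_cpp(double rate, double duration,
                                    int n_modes, double gamma_field,
                                    double dt, double dark_rate,
                                    double hold_off, bool fluctuating,
                                    int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::normal_distribution<double> N(0.0, 1.0);

  const long long n_sub = (long long)std::ceil(duration / dt);
  const double a = std::exp(-gamma_field * dt);
  const double s = std::sqrt((1.0 - a * a) / 2.0);  // per real component
  std::vector<double> er(n_modes), ei(n_modes);
  const double sqrt_half = std::sqrt(0.5);
  for (int m = 0; m < n_modes; ++m) {
    er[m] = sqrt_half * N(rng);
    ei[m] = sqrt_half * N(rng);
  }

  std::vector<double> times;
  times.reserve((size_t)std::min(1e8, (rate + dark_rate) * duration * 1.3 + 100));
  std::vector<double> buf;

  double last_kept = -1e18;
  for (long long i = 0; i < n_sub; ++i) {
    double t0 = i * dt;
    double inten = 1.0;
    if (fluctuating) {
      double I = 0.0;
      for (int m = 0; m < n_modes; ++m) {
        er[m] = a * er[m] + s * N(rng);
        ei[m] = a * ei[m] + s * N(rng);
        I += er[m] * er[m] + ei[m] * ei[m];
      }
      inten = I / n_modes;  // unit mean
    }
    double lam = (rate * inten + dark_rate) * dt;
    std::poisson_distribution<int> P(lam);
    int k = P(rng);
    if (k <= 0) continue;
    buf.resize(k);
    for (int j = 0; j < k; ++j) buf[j] = t0 + U(rng) * dt;
    std::sort(buf.begin(), buf.end());
    for (int j = 0; j < k; ++j) {
      if (buf[j] >= duration) break;
      if (buf[j] - last_kept >= hold_off) {
        times.push_back(buf[j]);
        last_kept = buf[j];
      }
    }
  }
  return NumericVector(times.begin(), times.end());
}

// Multi-tau autocorrelation of a timestamp series, on bins of width first_bin
// coarsened by factors of two. Lags 1..2m are evaluated at level 0; each
// subsequent level sums adjacent bins and evaluates lags m+1..2m, where
// m = bins_per_octave. Symmetric normalization divides the raw pair average
// by the means of the leading and trailing windows.
// When coarsen = false the same quasi-logarithmic lag ladder is evaluated on
// the original (uncoarsened) bins of width first_bin at every lag, matching
// the fixed-bin-width assumption of the analytic correlation noise model.
// [[Rcpp::export]]
List multitau_cpp(NumericVector times, double duration, double first_bin,
                  int bins_per_octave, double tau_max, bool coarsen = true) {
  const int m = bins_per_octave;
  long long n0 = (long long)std::floor(duration / first_bin);
  if (n0 < 4 * m) stop("series too short for the requested correlator scheme");
  std::vector<double> c((size_t)n0, 0.0);
  for (int i = 0; i < times.size(); ++i) {
    long long b = (long long)std::floor(times[i] / first_bin);
    if (b >= 0 && b < n0) c[(size_t)b] += 1.0;
  }
  double mean_counts = 0.0;
  for (double v : c) mean_counts += v;
  mean_counts /= (double)n0;

  std::vector<double> tau_out, g2_out;
  double width = first_bin;
  int level = 0;
  long long k_scale = 1;  // lag multiplier when not coarsening
  std::vector<double> cur = c;
  while (true) {
    long long n = (long long)cur.size();
    int k_lo = (level == 0) ? 1 : (m + 1);
    int k_hi = 2 * m;
    if (n <= 2 * (long long)(k_hi * k_scale)) break;
    // prefix sums for symmetric normalization
    std::vector<double> ps(n + 1, 0.0);
    for (long long i = 0; i < n; ++i) ps[i + 1] = ps[i] + cur[i];
    for (int kk = k_lo; kk <= k_hi; ++kk) {
      long long k = (long long)kk * k_scale;
      double tau = kk * width;
      if (tau > tau_max) break;
      long long M = n - k;
      if (M < 2) break;
      double G = 0.0;
      for (long long i = 0; i < M; ++i) G += cur[i] * cur[i + k];
      double mean_l = ps[M] / (double)M;
      double mean_r = (ps[n] - ps[k]) / (double)M;
      if (mean_l <= 0.0 || mean_r <= 0.0) continue;
      tau_out.push_back(tau);
      g2_out.push_back((G / (double)M) / (mean_l * mean_r));
    }
    if (k_lo * width > tau_max) break;
    if (coarsen) {
      long long nh = n / 2;
      if (nh <= 4 * m) break;
      std::vector<double> nxt((size_t)nh);
      for (long long i = 0; i < nh; ++i) nxt[(size_t)i] = cur[(size_t)(2 * i)] + cur[(size_t)(2 * i + 1)];
      cur.swap(nxt);
    } else {
      k_scale *= 2;
    }
    width *= 2.0;
    ++level;
  }
  return List::create(_["tau"] = NumericVector(tau_out.begin(), tau_out.end()),
                      _["g2"] = NumericVector(g2_out.begin(), g2_out.end()),
                      _["counts_per_bin"] = mean_counts,
                      _["n_events"] = (double)times.size());
}
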