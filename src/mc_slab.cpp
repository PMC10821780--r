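// Layered-slab dynamic light scattering Monte Carlo.
//
// Transport uses the similarity relation: isotropic scattering at the reduced
// scattering coefficient mu_s'. Absorption is never applied during flight;
// each photon carries its per-layer partial pathlength L and momentum
// transfer Y = sum(1 - cos(theta)), and the absorption weight exp(-sum mu_a L)
// is applied analytically at detection. Photons are terminated once their
// potential absorption weight falls below a cutoff (default 1e-7), which
// bounds the pathlength without biasing detected statistics above the cutoff.
//
// The top surface (z = 0) has a refractive index step to air (n_out = 1):
// photons undergo unpolarized Fresnel reflection / total internal reflection.
// Detectors are concentric annuli centred on the source; azimuthal symmetry
// makes a thin annulus equivalent to a small detector at that separation.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline double fresnel_unpolarized(double n1, double n2, double cos_i) {
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List mc_slab_cpp(NumericVector thickness_cm,   // per layer; last entry may be Inf
                 NumericVector mu_a,           // 1/cm per layer
                 NumericVector mu_sp,          // 1/cm per layer
                 double n_medium,              // refractive index (uniform)
                 NumericVector det_r_lo,       // annulus inner radii (cm)
                 NumericVector det_r_hi,       // annulus outer radii (cm)
                 NumericVector det_na,         // numerical aperture (in air)
                 double n_photons,
                 int seed,
                 double weight_cutoff = 1e-7,
                 bool fresnel_surface = true) {
  const int n_layers = thickness_cm.size();
  const int n_det = det_r_lo.size();
  std::vector<double> z_hi(n_layers);  // cumulative lower boundaries
  {
    double z = 0.0;
    for (int l = 0; l < n_layers; ++l) {
      z += thickness_cm[l];
      z_hi[l] = z;
    }
    z_hi[n_layers - 1] = std::numeric_limits<double>::infinity();
  }
  const double max_att = -std::log(weight_cutoff);  // cap on sum(mu_a * L)

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<int> out_det;
  std::vector<double> out_L, out_Y;  // row-major blocks of n_layers per photon
  std::vector<double> refl_weight(n_det, 0.0);
  std::vector<double> refl_count(n_det, 0.0);
  double total_exit_weight = 0.0;
  long long total_exit_count = 0, terminated_count = 0;

  std::vector<double> L(n_layers), Y(n_layers);
  const long long np = static_cast<long long>(n_photons);

  for (long long ph = 0; ph < np; ++ph) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(Y.begin(), Y.end(), 0.0);
    double att = 0.0;  // sum mu_a * L so far
    bool alive = true;

    double od = -std::log(U(rng));  // optical depth to next scattering event

    while (alive) {
      // geometric distance to scattering event in current layer
      double s_scat = od / mu_sp[layer];
      // distance to layer boundary along uz
      double z_lo = (layer == 0) ? 0.0 : z_hi[layer - 1];
      double s_bound = std::numeric_limits<double>::infinity();
      int next_layer = layer;
      if (uz > 0.0) {
        s_bound = (z_hi[layer] - z) / uz;
        next_layer = layer + 1;
      } else if (uz < 0.0) {
        s_bound = (z_lo - z) / uz;
        next_layer = layer - 1;
      }

      if (s_scat < s_bound) {
        // scattering event inside the layer
        x += ux * s_scat; y += uy * s_scat; z += uz * s_scat;
        L[layer] += s_scat;
        att += mu_a[layer] * s_scat;
        if (att > max_att) { ++terminated_count; break; }
        // isotropic new direction
        double ct = 2.0 * U(rng) - 1.0;
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double phi = 2.0 * M_PI * U(rng);
        double nx = st * std::cos(phi), ny = st * std::sin(phi), nz = ct;
        double cos_sc = ux * nx + uy * ny + uz * nz;
        Y[layer] += 1.0 - cos_sc;
        ux = nx; uy = ny; uz = nz;
        od = -std::log(U(rng));
      } else {
        // move to boundary
        x += ux * s_bound; y += uy * s_bound; z += uz * s_bound;
        L[layer] += s_bound;
        att += mu_a[layer] * s_bound;
        od -= s_bound * mu_sp[layer];
        if (att > max_att) { ++terminated_count; break; }
        if (next_layer < 0) {
          // hit the top surface going up
          double cos_i = -uz;
          double R = fresnel_surface ? fresnel_unpolarized(n_medium, 1.0, cos_i)
                                     : 0.0;
          if (U(rng) < R) {
            uz = -uz;        // specular internal reflection
            z = 0.0;
            layer = 0;
          } else {
            // photon escapes: tally and test detectors
            double w = std::exp(-att);
            total_exit_weight += w;
            ++total_exit_count;
            double r = std::sqrt(x * x + y * y);
            double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
            double sin_air = fresnel_surface ? (n_medium * sin_i) : sin_i;
            for (int d = 0; d < n_det; ++d) {
              if (r >= det_r_lo[d] && r < det_r_hi[d] && sin_air <= det_na[d]) {
                refl_weight[d] += w;
                refl_count[d] += 1.0;
                out_det.push_back(d + 1);
                for (int l = 0; l < n_layers; ++l) out_L.push_back(L[l]);
                for (int l = 0; l < n_layers; ++l) out_Y.push_back(Y[l]);
                break;
              }
            }
            break;
          }
        } else {
          z = (next_layer > layer) ? z_hi[layer] : z_lo;
          layer = next_layer;
        }
      }
    }
  }

  const int n_hit = static_cast<int>(out_det.size());
  IntegerVector det_id(n_hit);
  NumericMatrix Lm(n_hit, n_layers), Ym(n_hit, n_layers);
  for (int i = 0; i < n_hit; ++i) {
    det_id[i] = out_det[i];
    for (int l = 0; l < n_layers; ++l) {
      Lm(i, l) = out_L[(size_t)i * n_layers + l];
      Ym(i, l) = out_Y[(size_t)i * n_layers + l];
    }
  }
  return List::create(
    _["detector_id"] = det_id, _["L"] = Lm, _["Y"] = Ym,
    _["reflectance_weight"] = NumericVector(refl_weight.begin(), refl_weight.end()),
    _["reflectance_count"] = NumericVector(refl_count.begin(), refl_count.end()),
    _["total_exit_weight"] = total_exit_weight,
    _["total_exit_count"] = (double)total_exit_count,
    _["terminated_count"] = (double)terminated_count,
    _["n_launched"] = (double)np);
}
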