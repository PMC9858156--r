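// Weighted-photon Monte Carlo transport kernel for a layered slab in
// reflection geometry (pencil beam at the origin, +z into the tissue).
//
// Conventions: lengths in mm, z = 0 at the surface, layer boundaries at
// strictly increasing depths.  Step sampling either at the total interaction
// rate mu_t = mu_a + mu_s (unbiased MCML scheme) or at the scattering rate
// mu_s alone (the literal free-path density of the source model); in both
// cases each interaction deposits w * mu_a / (mu_a + mu_s).
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// splitmix64 used only to expand the (seed, stream) pair into xoshiro state
inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// xoshiro256++: deterministic across platforms, one generator per
// (base seed, replicate stream) so replicates are individually reproducible
struct Xoshiro256 {
  uint64_t s[4];
  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x9e3779b97f4a7c15ULL + 0x7f4a7c15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]: safe as the argument of log()
  inline double runif_oc() {
    return (double)((next() >> 11) + 1) * 0x1.0p-53;
  }
};

inline double fresnel_unpolarized(double n1, double n2, double cos_i) {
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_t = n1 / n2 * std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein polar cosine by inverse CDF; isotropic at g = 0
inline double hg_cos(double g, double u) {
  double ct;
  if (std::fabs(g) < 1e-12) {
    ct = 2.0 * u - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
    ct = (1.0 + g * g - t * t) / (2.0 * g);
  }
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

inline void rotate_direction(double ct, double phi,
                             double &ux, double &uy, double &uz) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    nz = -denom * st * cp + uz * ct;
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nn; uy = ny / nn; uz = nz / nn;
}

struct Segment { float x, y, z, len; };

} // namespace

// Core loop shared by the ledger run and the sensitivity-map run.  When
// `map` is non-null, trajectory segments of photons detected inside
// [map_lo, map_hi) on the detector coordinate are deposited (weight x
// segment length) into the (lateral, depth) histogram.
static List transport_impl(NumericVector thickness, NumericVector mua,
                           NumericVector mus, NumericVector g,
                           NumericVector n_layer, double n_ambient,
                           NumericVector bin_edges, int detector_mode,
                           double n_photons, int seed, int stream,
                           int step_mode, bool semi_infinite,
                           bool matched_boundaries, bool roulette_on,
                           double roulette_threshold, double roulette_survival,
                           double max_path,
                           NumericMatrix *map, double map_lo, double map_hi,
                           NumericVector map_x_edges, NumericVector map_z_edges) {
  const int L = thickness.size();
  const int K = bin_edges.size() - 1;
  const long n = (long)n_photons;
  if (L < 1 || L > 64) stop("between 1 and 64 layers supported");
  if (K < 1) stop("at least one detector bin required");
  if (n < 1) stop("photon budget must be at least 1");
  for (int i = 0; i < L; ++i) {
    if (mua[i] < 0) stop("mu_a must be non-negative");
    if (mus[i] < 0) stop("mu_s must be non-negative");
    if (std::fabs(g[i]) >= 1) stop("|g| must be < 1");
    if (thickness[i] <= 0 && !(semi_infinite && i == L - 1))
      stop("layer thickness must be strictly positive");
  }
  if (roulette_on && (roulette_survival <= 0 || roulette_survival >= 1))
    stop("roulette survival probability must lie in (0, 1)");

  std::vector<double> zb(L + 1);
  zb[0] = 0.0;
  for (int i = 0; i < L; ++i) zb[i + 1] = zb[i] + thickness[i];
  const double e_lo = bin_edges[0], e_hi = bin_edges[K];

  std::vector<double> det_w(K, 0.0), s_wp(K, 0.0), s_p(K, 0.0);
  std::vector<double> s_wpl(K * L, 0.0), s_pl(K * L, 0.0);
  std::vector<double> ndet(K, 0.0);
  double specular = 0.0, reflected = 0.0, transmitted = 0.0, absorbed = 0.0;
  double truncated = 0.0, roulette_killed = 0.0, roulette_boost = 0.0;

  // sensitivity-map bookkeeping
  const bool want_map = (map != nullptr);
  int MX = 0, MZ = 0;
  double mx0 = 0, mdx = 1, mz0 = 0, mdz = 1, chunk = 1;
  std::vector<Segment> segs;
  if (want_map) {
    MX = map_x_edges.size() - 1;
    MZ = map_z_edges.size() - 1;
    mx0 = map_x_edges[0];
    mdx = (map_x_edges[MX] - mx0) / MX;   // uniform grids only
    mz0 = map_z_edges[0];
    mdz = (map_z_edges[MZ] - mz0) / MZ;
    chunk = 0.5 * std::min(mdx, mdz);
    segs.reserve(4096);
  }

  // specular reflection of the normally incident pencil beam
  double r_sp = matched_boundaries ? 0.0
    : fresnel_unpolarized(n_ambient, n_layer[0], 1.0);
  const double w0 = 1.0 - r_sp;

  Xoshiro256 rng((uint64_t)(uint32_t)seed, (uint64_t)(uint32_t)stream);
  std::vector<double> pl(L);

  for (long ph = 0; ph < n; ++ph) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    double w = w0, path = 0;
    int lay = 0;
    bool alive = true;
    specular += r_sp;
    std::fill(pl.begin(), pl.end(), 0.0);
    if (want_map) segs.clear();

    while (alive) {
      double sopt = -std::log(rng.runif_oc());  // optical depth to next event
      while (sopt > 0 && alive) {
        double rate = (step_mode == 0) ? (mua[lay] + mus[lay]) : mus[lay];
        double s = (rate > 0) ? sopt / rate : 2.0 * max_path;
        double db = std::numeric_limits<double>::infinity();
        if (uz > 0) {
          db = (semi_infinite && lay == L - 1)
            ? std::numeric_limits<double>::infinity()
            : (zb[lay + 1] - z) / uz;
        } else if (uz < 0) {
          db = (zb[lay] - z) / uz;
        }
        double m = std::min(s, db);
        if (path + m > max_path) {             // safety cap, kill in place
          m = max_path - path;
          x += ux * m; y += uy * m; z += uz * m;
          pl[lay] += m; path += m;
          truncated += w;
          alive = false;
          break;
        }
        if (want_map && m > 0) {
          // store subdivided so each chunk is short against the map bins
          int npc = std::max(1, (int)std::ceil(m / chunk));
          double dl = m / npc;
          for (int c = 0; c < npc; ++c) {
            double f = (c + 0.5) * dl;
            segs.push_back({(float)(x + ux * f), (float)(y + uy * f),
                            (float)(z + uz * f), (float)dl});
          }
        }
        if (s < db) {
          x += ux * s; y += uy * s; z += uz * s;
          pl[lay] += s; path += s;
          sopt = 0;
        } else {
          x += ux * db; y += uy * db; z += uz * db;
          pl[lay] += db; path += db;
          sopt -= db * rate;
          if (uz < 0 && lay == 0) {
            // air-tissue interface
            double ci = -uz;
            double R = matched_boundaries ? 0.0
              : fresnel_unpolarized(n_layer[0], n_ambient, ci);
            if (rng.runif_oc() <= R) {
              uz = -uz; z = zb[0];
            } else {
              reflected += w;
              double coord = (detector_mode == 0)
                ? std::sqrt(x * x + y * y) : std::fabs(x);
              if (coord >= e_lo && coord < e_hi) {
                int k = (int)(std::upper_bound(bin_edges.begin(),
                              bin_edges.end(), coord) - bin_edges.begin()) - 1;
                if (k >= 0 && k < K) {
                  ndet[k] += 1; det_w[k] += w;
                  s_wp[k] += w * path; s_p[k] += path;
                  for (int l = 0; l < L; ++l) {
                    s_wpl[k * L + l] += w * pl[l];
                    s_pl[k * L + l] += pl[l];
                  }
                  if (want_map && coord >= map_lo && coord < map_hi) {
                    // rotate (ring) or mirror (strip) so the exit lands on +x
                    double ce = 1, se = 0;
                    if (detector_mode == 0) {
                      double re = std::sqrt(x * x + y * y);
                      if (re > 0) { ce = x / re; se = y / re; }
                    } else if (x < 0) {
                      ce = -1;
                    }
                    for (const Segment &sg : segs) {
                      double xr = (detector_mode == 0)
                        ? sg.x * ce + sg.y * se
                        : sg.x * ce;
                      int ix = (int)std::floor((xr - mx0) / mdx);
                      int iz = (int)std::floor((sg.z - mz0) / mdz);
                      if (ix >= 0 && ix < MX && iz >= 0 && iz < MZ)
                        (*map)(ix, iz) += w * sg.len;
                    }
                  }
                }
              }
              alive = false;
            }
          } else if (uz > 0 && lay == L - 1) {
            transmitted += w;                  // escaped through the bottom
            alive = false;
          } else {
            // internal interface
            int nxt = (uz > 0) ? lay + 1 : lay - 1;
            double n1 = n_layer[lay], n2 = n_layer[nxt];
            if (matched_boundaries || n1 == n2) {
              lay = nxt;
            } else {
              double ci = std::fabs(uz);
              double R = fresnel_unpolarized(n1, n2, ci);
              if (rng.runif_oc() <= R) {
                uz = -uz;
              } else {
                double ratio = n1 / n2;
                double sin2 = ratio * ratio * (1.0 - ci * ci);
                double ct = std::sqrt(std::max(0.0, 1.0 - sin2));
                ux *= ratio; uy *= ratio;
                uz = (uz > 0) ? ct : -ct;
                double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
                ux /= nn; uy /= nn; uz /= nn;
                lay = nxt;
              }
            }
          }
        }
      }
      if (!alive) break;

      // interaction: deposit, scatter, roulette
      double mt = mua[lay] + mus[lay];
      if (mt <= 0) { truncated += w; break; }  // vacuum layer, cannot interact
      double dw = w * mua[lay] / mt;
      w -= dw; absorbed += dw;
      if (w <= 0) break;
      double ct = hg_cos(g[lay], rng.runif_oc());
      double phi = 2.0 * M_PI * rng.runif_oc();
      rotate_direction(ct, phi, ux, uy, uz);
      if (roulette_on && w < roulette_threshold) {
        if (rng.runif_oc() <= roulette_survival) {
          roulette_boost += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          roulette_killed += w;
          break;
        }
      }
      if (!std::isfinite(w) || !std::isfinite(path) || !std::isfinite(z))
        stop("non-finite photon state encountered (photon %ld)", ph);
    }
  }

  NumericMatrix swpl(K, L), spl(K, L);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      swpl(k, l) = s_wpl[k * L + l];
      spl(k, l) = s_pl[k * L + l];
    }
  return List::create(
    _["launched"] = (double)n,
    _["launched_weight"] = (double)n,
    _["specular_weight"] = specular,
    _["reflected_weight"] = reflected,
    _["transmitted_weight"] = transmitted,
    _["absorbed_weight"] = absorbed,
    _["truncated_weight"] = truncated,
    _["roulette_killed"] = roulette_killed,
    _["roulette_boost"] = roulette_boost,
    _["n_detected"] = NumericVector(ndet.begin(), ndet.end()),
    _["detected_weight"] = NumericVector(det_w.begin(), det_w.end()),
    _["sum_weighted_path"] = NumericVector(s_wp.begin(), s_wp.end()),
    _["sum_path"] = NumericVector(s_p.begin(), s_p.end()),
    _["sum_weighted_path_by_layer"] = swpl,
    _["sum_path_by_layer"] = spl);
}

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport_cpp(NumericVector thickness, NumericVector mua,
                      NumericVector mus, NumericVector g,
                      NumericVector n_layer, double n_ambient,
                      NumericVector bin_edges, int detector_mode,
                      double n_photons, int seed, int stream, int step_mode,
                      bool semi_infinite, bool matched_boundaries,
                      bool roulette_on, double roulette_threshold,
                      double roulette_survival, double max_path) {
  return transport_impl(thickness, mua, mus, g, n_layer, n_ambient, bin_edges,
                        detector_mode, n_photons, seed, stream, step_mode,
                        semi_infinite, matched_boundaries, roulette_on,
                        roulette_threshold, roulette_survival, max_path,
                        nullptr, 0, 0, NumericVector(2), NumericVector(2));
}

// [[Rcpp::export(name = ".mc_sensitivity")]]
List mc_sensitivity_cpp(NumericVector thickness, NumericVector mua,
                        NumericVector mus, NumericVector g,
                        NumericVector n_layer, double n_ambient,
                        NumericVector bin_edges, int detector_mode,
                        double n_photons, int seed, int stream, int step_mode,
                        bool semi_infinite, bool matched_boundaries,
                        bool roulette_on, double roulette_threshold,
                        double roulette_survival, double max_path,
                        double target_lo, double target_hi,
                        NumericVector map_x_edges, NumericVector map_z_edges) {
  if (map_x_edges.size() < 2 || map_z_edges.size() < 2)
    stop("map grids need at least two edges");
  NumericMatrix map(map_x_edges.size() - 1, map_z_edges.size() - 1);
  List led = transport_impl(thickness, mua, mus, g, n_layer, n_ambient,
                            bin_edges, detector_mode, n_photons, seed, stream,
                            step_mode, semi_infinite, matched_boundaries,
                            roulette_on, roulette_threshold, roulette_survival,
                            max_path, &map, target_lo, target_hi,
                            map_x_edges, map_z_edges);
  led["map"] = map;
  return led;
}
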