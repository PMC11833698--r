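#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted-photon Monte Carlo transport on a voxelized medium.
//
// Implicit-capture weighting: at each collision a fraction mu_a/mu_t of the
// photon weight is deposited in the current voxel, the remainder scatters
// with a Henyey-Greenstein deflection. Two fluence tallies are kept: the
// collision estimator (deposited energy / (mu_a V)) and the track-length
// estimator (weighted path length / V), the latter with much lower variance
// in voxels that see few collisions. Free paths are resampled per voxel
// (valid by the memorylessness of the exponential). Voxels with mu_t = 0
// are traversed ballistically. Refractive-index-matched boundaries: photons
// leaving the grid are tallied as escaped. Russian roulette below wmin with
// survival multiplier msurv keeps the estimator unbiased; the signed weight
// created/destroyed by roulette is returned for diagnostics.
//
// Uses R's RNG stream, so results are bit-reproducible given set.seed().

static inline double boundary_distance(double p, double u, double edge) {
  // distance along component u from p to the next voxel face (voxel size edge)
  if (u > 0) {
    double next = (std::floor(p / edge) + 1.0) * edge;
    return (next - p) / u;
  } else if (u < 0) {
    double next = std::floor(p / edge) * edge;
    if (next == p) next -= edge;
    return (next - p) / u;
  }
  return R_PosInf;
}

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(IntegerVector labels, IntegerVector dims, double voxel_cm,
                  NumericVector mua, NumericVector mus, NumericVector gg,
                  double beam_cx, double beam_cy, double beam_radius_cm,
                  int n_photons, double wmin, double msurv,
                  double max_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double lx = nx * voxel_cm, ly = ny * voxel_cm, lz = nz * voxel_cm;
  NumericVector dep(nx * ny * nz);   // collision-estimator energy deposits
  NumericVector tlen(nx * ny * nz);  // track-length tally (weight * path)
  double escaped = 0.0, absorbed = 0.0, truncated = 0.0, roulette_net = 0.0;
  const double eps = 1e-12 + 1e-9 * voxel_cm;

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch uniformly on the beam disk, normal incidence along +z
    double r = beam_radius_cm * std::sqrt(unif_rand());
    double th = 2.0 * M_PI * unif_rand();
    double x = beam_cx + r * std::cos(th);
    double y = beam_cy + r * std::sin(th);
    double z = 1e-9 * voxel_cm;  // just inside the entry face
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    double events = 0.0;
    bool alive = (x >= 0 && x < lx && y >= 0 && y < ly);
    if (!alive) { escaped += w; continue; }

    while (alive) {
      if (x < 0 || x >= lx || y < 0 || y >= ly || z < 0 || z >= lz) {
        escaped += w;
        break;
      }
      int ix = (int)(x / voxel_cm), iy = (int)(y / voxel_cm),
          iz = (int)(z / voxel_cm);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped += w;
        break;
      }
      int lab = labels[ix + nx * (iy + ny * (size_t)iz)] - 1;
      double ma = mua[lab], ms = mus[lab], mt = ma + ms;

      double db = std::min(boundary_distance(x, ux, voxel_cm),
                  std::min(boundary_distance(y, uy, voxel_cm),
                           boundary_distance(z, uz, voxel_cm)));
      double s;
      const size_t vox = ix + nx * (iy + ny * (size_t)iz);
      if (mt <= 0.0) {
        s = db + eps;  // ballistic traversal of a vacuum voxel
        tlen[vox] += w * s;
        x += s * ux; y += s * uy; z += s * uz;
        continue;
      }
      s = -std::log(unif_rand()) / mt;
      if (s >= db) {  // cross into the next voxel, resample there
        s = db + eps;
        tlen[vox] += w * s;
        x += s * ux; y += s * uy; z += s * uz;
        continue;
      }
      // collide inside this voxel
      tlen[vox] += w * s;
      x += s * ux; y += s * uy; z += s * uz;
      double d = w * ma / mt;
      dep[vox] += d;
      absorbed += d;
      w -= d;

      // Henyey-Greenstein deflection
      double g = gg[lab], ct;
      if (std::fabs(g) < 1e-8) {
        ct = 1.0 - 2.0 * unif_rand();
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }

      events += 1.0;
      if (events >= max_events) {  // safeguard, never expected to trigger
        truncated += w;
        break;
      }
      if (w < wmin) {  // Russian roulette
        if (unif_rand() < 1.0 / msurv) {
          roulette_net += w * (msurv - 1.0);
          w *= msurv;
        } else {
          roulette_net -= w;
          break;
        }
      }
    }
  }

  return List::create(_["dep"] = dep, _["tlen"] = tlen,
                      _["absorbed"] = absorbed,
                      _["escaped"] = escaped, _["truncated"] = truncated,
                      _["roulette_net"] = roulette_net);
}

// Sample n Henyey-Greenstein deflection cosines (test hook for the phase
// function used above).
// [[Rcpp::export(name = ".hg_sample")]]
NumericVector hg_sample(int n, double g) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (std::fabs(g) < 1e-8) {
      out[i] = 1.0 - 2.0 * unif_rand();
    } else {
      double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
      double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
      out[i] = std::min(1.0, std::max(-1.0, ct));
    }
  }
  return out;
}
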