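#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxelized Monte Carlo photon transport: hop-drop-spin with
// Henyey-Greenstein scattering, voxel-exact path splitting, Fresnel
// reflection at the top surface (z = 0) only, absorbing side/bottom walls,
// Russian roulette below a weight threshold. Uses R's RNG so runs are
// reproducible under set.seed().

static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline double fresnel_unpolarized(double n1, double n2, double cosi) {
  // reflectance for incidence cosine cosi, medium n1 -> n2
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List cpp_run_photons(NumericVector mua, NumericVector mus, NumericVector g,
                     IntegerVector dims, double dx,
                     double beam_radius, double n_medium, double n_outside,
                     int n_photons, double w_threshold, double roulette_m,
                     bool specular, bool top_fresnel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lx = nx * dx, Ly = ny * dx, Lz = nz * dx;
  const double cx = 0.5 * Lx, cy = 0.5 * Ly;
  NumericVector dep(static_cast<R_xlen_t>(nx) * ny * nz);
  double escaped_top = 0.0, escaped_other = 0.0, specular_total = 0.0;
  double roulette_net = 0.0;
  const double eps = 1e-9 * dx;

  double r_sp = 0.0;
  if (specular) {
    double r = (n_outside - n_medium) / (n_outside + n_medium);
    r_sp = r * r;
  }

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch: uniform disk, normal incidence at top face center
    double rr = beam_radius * std::sqrt(unif_rand());
    double phi0 = 2.0 * M_PI * unif_rand();
    double x = cx + rr * std::cos(phi0);
    double y = cy + rr * std::sin(phi0);
    double z = eps;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    if (specular) { specular_total += w * r_sp; w *= (1.0 - r_sp); }

    double tau = -std::log(unif_rand());
    bool alive = true;
    while (alive) {
      int ix = static_cast<int>(x / dx);
      int iy = static_cast<int>(y / dx);
      int iz = static_cast<int>(z / dx);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        escaped_other += w;  // numerical safety net; walls handled below
        break;
      }
      R_xlen_t vox = static_cast<R_xlen_t>(ix) +
        static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
      double ma = mua[vox], ms = mus[vox];
      double mt = ma + ms;

      // distance to the nearest voxel face along the current direction
      double db = R_PosInf;
      if (ux > 0) db = std::min(db, ((ix + 1) * dx - x) / ux);
      else if (ux < 0) db = std::min(db, (ix * dx - x) / ux);
      if (uy > 0) db = std::min(db, ((iy + 1) * dx - y) / uy);
      else if (uy < 0) db = std::min(db, (iy * dx - y) / uy);
      if (uz > 0) db = std::min(db, ((iz + 1) * dx - z) / uz);
      else if (uz < 0) db = std::min(db, (iz * dx - z) / uz);
      if (db < 0) db = 0;

      if (mt * db < tau) {
        // hop to the voxel boundary, consume optical depth, maybe leave grid
        tau -= mt * db;
        x += ux * (db + eps);
        y += uy * (db + eps);
        z += uz * (db + eps);
        if (z < 0.0) {
          if (top_fresnel) {
            double R = fresnel_unpolarized(n_medium, n_outside, std::fabs(uz));
            if (unif_rand() < R) { z = -z; uz = -uz; continue; }
          }
          escaped_top += w; alive = false; continue;
        }
        if (x < 0.0 || x >= Lx || y < 0.0 || y >= Ly || z >= Lz) {
          escaped_other += w; alive = false; continue;
        }
        continue;
      }

      // interaction inside this voxel
      double s = (mt > 0.0) ? tau / mt : db;  // mt==0 guarded by caller
      x += ux * s; y += uy * s; z += uz * s;
      double dw = (mt > 0.0) ? w * ma / mt : 0.0;
      dep[vox] += dw;
      w -= dw;
      tau = -std::log(unif_rand());

      // spin: Henyey-Greenstein polar angle, uniform azimuth
      double ct = hg_cos(g[vox], unif_rand());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = (uz >= 0 ? ct : -ct);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }

      if (w < w_threshold) {
        if (roulette_m <= 1.0) { roulette_net += w; alive = false; continue; }
        if (unif_rand() < 1.0 / roulette_m) {
          roulette_net -= w * (roulette_m - 1.0);
          w *= roulette_m;
        } else {
          roulette_net += w; alive = false;
        }
      }
    }
  }

  return List::create(_["deposited"] = dep,
                      _["escaped_top"] = escaped_top,
                      _["escaped_other"] = escaped_other,
                      _["specular"] = specular_total,
                      _["roulette_net"] = roulette_net);
}

// [[Rcpp::export]]
NumericVector cpp_hg_sample(double g, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, unif_rand());
  return out;
}
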