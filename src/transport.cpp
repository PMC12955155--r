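#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Condensed-history electron transport with fixed step length:
//  - CSDA collisional loss deposited in the current voxel,
//  - radiative loss removed without local deposition (bremsstrahlung
//    photons assumed to escape),
//  - Highland small-angle multiple scattering, two independent Gaussian
//    kicks per step in the plane transverse to the direction,
//  - history terminates at E <= ecut (residual deposited locally) or on
//    phantom exit.
// All media are density-scaled water. Uses R's RNG (norm_rand) so runs
// are reproducible under set.seed(). Batch scoring (contiguous equal
// blocks of histories) supports the batch uncertainty estimate.

static const double ME = 0.510998946; // electron rest mass, MeV

// log-log interpolation of a stopping-power table; clamps outside range
static double interp_loglog(const std::vector<double> &logE,
                            const std::vector<double> &logS,
                            double E) {
  const int n = logE.size();
  double le = std::log(E);
  if (le <= logE[0]) return std::exp(logS[0]);
  if (le >= logE[n - 1]) return std::exp(logS[n - 1]);
  int hi = std::upper_bound(logE.begin(), logE.end(), le) - logE.begin();
  int lo = hi - 1;
  double f = (le - logE[lo]) / (logE[hi] - logE[lo]);
  return std::exp(logS[lo] + f * (logS[hi] - logS[lo]));
}

// [[Rcpp::export]]
List transport_cpp(NumericVector density, IntegerVector dims,
                   NumericVector origin, NumericVector spacing,
                   NumericMatrix pos0, NumericMatrix dir0,
                   NumericVector energy0, NumericVector weight,
                   NumericVector egrid, NumericVector scol,
                   NumericVector srad, double X0, double ds,
                   double ecut, int nbatch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int nhist = pos0.nrow();
  if (nhist < 1) stop("transport: empty RaySet");
  if (nbatch < 2) stop("transport: n_batches must be >= 2");

  const int ng = egrid.size();
  std::vector<double> logE(ng), logC(ng), logR(ng);
  for (int i = 0; i < ng; ++i) {
    logE[i] = std::log(egrid[i]);
    logC[i] = std::log(scol[i]);
    logR[i] = std::log(srad[i]);
  }

  // grid AABB (voxel faces, not centers)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }

  std::vector<double> cur(nvox, 0.0), bsum(nvox, 0.0), bsumsq(nvox, 0.0);
  double e_col = 0, e_cut = 0, e_rad = 0, e_esc = 0, e_in = 0;

  const long max_steps = 2000000L;
  int batch = 0;

  for (int h = 0; h < nhist; ++h) {
    int hb = (int)(((long long)h * nbatch) / nhist);
    if (hb != batch) { // fold finished batch into moment accumulators
      for (R_xlen_t v = 0; v < nvox; ++v) {
        bsum[v] += cur[v];
        bsumsq[v] += cur[v] * cur[v];
        cur[v] = 0.0;
      }
      batch = hb;
    }
    double p[3] = {pos0(h, 0), pos0(h, 1), pos0(h, 2)};
    double d[3] = {dir0(h, 0), dir0(h, 1), dir0(h, 2)};
    double E = energy0[h], w = weight[h];
    e_in += w * E;

    // advance to the phantom bounding box if starting outside
    bool inside = p[0] >= lo[0] && p[0] <= hi[0] && p[1] >= lo[1] &&
                  p[1] <= hi[1] && p[2] >= lo[2] && p[2] <= hi[2];
    if (!inside) {
      double tmin = -1e300, tmax = 1e300;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-12) {
          if (p[a] < lo[a] || p[a] > hi[a]) { miss = true; break; }
        } else {
          double t1 = (lo[a] - p[a]) / d[a], t2 = (hi[a] - p[a]) / d[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (miss || tmax < tmin || tmax < 0) { e_esc += w * E; continue; }
      double t = (tmin > 0 ? tmin : 0) + 1e-9;
      p[0] += d[0] * t; p[1] += d[1] * t; p[2] += d[2] * t;
    }

    for (long step = 0; step < max_steps; ++step) {
      int ix = (int)std::floor((p[0] - lo[0]) / spacing[0]);
      int iy = (int)std::floor((p[1] - lo[1]) / spacing[1]);
      int iz = (int)std::floor((p[2] - lo[2]) / spacing[2]);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        e_esc += w * E;
        break;
      }
      R_xlen_t v = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      double rho = density[v];
      if (rho > 0) {
        double sc = interp_loglog(logE, logC, E);
        double sr = interp_loglog(logE, logR, E);
        double dEc = sc * rho * ds, dEr = sr * rho * ds;
        double tot = dEc + dEr;
        if (tot > E) { double f = E / tot; dEc *= f; dEr *= f; }
        cur[v] += w * dEc;
        e_col += w * dEc;
        e_rad += w * dEr;
        E -= dEc + dEr;
        if (E <= ecut) {
          cur[v] += w * E;
          e_cut += w * E;
          break;
        }
        // Highland multiple-scattering kick
        double t = rho * ds / X0;
        double Etot = E + ME;
        double pc2 = Etot * Etot - ME * ME;
        double betapc = pc2 / Etot;
        double corr = 1.0 + 0.038 * std::log(t);
        if (corr < 0) corr = 0;
        double th0 = 13.6 / betapc * std::sqrt(t) * corr;
        if (th0 > 0) {
          double ax = th0 * norm_rand(), ay = th0 * norm_rand();
          // transverse basis
          double ux, uy, uz;
          if (std::fabs(d[2]) < 0.9) { ux = -d[1]; uy = d[0]; uz = 0; }
          else { ux = 0; uy = -d[2]; uz = d[1]; }
          double un = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= un; uy /= un; uz /= un;
          double vx = d[1] * uz - d[2] * uy;
          double vy = d[2] * ux - d[0] * uz;
          double vz = d[0] * uy - d[1] * ux;
          d[0] += ax * ux + ay * vx;
          d[1] += ax * uy + ay * vy;
          d[2] += ax * uz + ay * vz;
          double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
          d[0] /= dn; d[1] /= dn; d[2] /= dn;
        }
      }
      p[0] += d[0] * ds; p[1] += d[1] * ds; p[2] += d[2] * ds;
    }
  }
  // fold the last batch
  for (R_xlen_t v = 0; v < nvox; ++v) {
    bsum[v] += cur[v];
    bsumsq[v] += cur[v] * cur[v];
  }

  NumericVector edep(nvox), relunc(nvox);
  const double B = nbatch;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double m = bsum[v] / B;
    edep[v] = bsum[v];
    if (m > 0) {
      double var = (bsumsq[v] - B * m * m) / (B * (B - 1));
      if (var < 0) var = 0;
      relunc[v] = std::sqrt(var) / m; // rel. sigma of the mean-of-batches
    } else {
      relunc[v] = 0.0;
    }
  }
  return List::create(
      _["edep"] = edep, _["rel_unc"] = relunc,
      _["ledger"] = NumericVector::create(
          _["input"] = e_in, _["collisional"] = e_col,
          _["sub_cutoff"] = e_cut, _["radiative"] = e_rad,
          _["escaped"] = e_esc));
}
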