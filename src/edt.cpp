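#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas), separable per axis, with per-axis sample
// spacing so anisotropic voxels are handled correctly. Distances are from
// voxel centers to the nearest center of a 'true' voxel, in cm^2.

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1; // parabolas are inserted only for finite f (INF ones never win)
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * h;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // displaced the last remaining parabola
      v[k] = q;
      z[k + 1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  if (k < 0) { // no finite input along this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d2(nx * ny * nz);
  for (int i = 0; i < d2.size(); ++i) d2[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // x axis
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const int base = j * nx + k * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = d2[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d2[base + i] = d[i];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const int base = i + k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = d2[base + j * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d2[base + j * nx] = d[j];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const int base = i + j * nx;
      for (int k = 0; k < nz; ++k) f[k] = d2[base + k * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d2[base + k * nx * ny] = d[k];
    }
  return d2;
}
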