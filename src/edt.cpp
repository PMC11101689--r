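#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher
// 2012) generalised to anisotropic voxel spacing. Distances are between voxel
// centers, in physical units (mm).

static const double INF = std::numeric_limits<double>::max() / 4.0;

// 1D lower envelope of parabolas y = f[q] + (s*(x-q))^2 sampled at grid points.
static void dt1d(const std::vector<double>& f, double s, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sep;
    while (true) {
      int p = v[k];
      sep = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sep > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dx = s * (q - p);
    d[q] = dx * dx + f[p];
  }
}

// Squared EDT of a 3D logical array: for every voxel, squared distance (mm^2)
// to the nearest TRUE voxel center. Voxels of an all-FALSE input get INF.
// [[Rcpp::export]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) f[i] = out[base + i];
        dt1d(f, spacing[0], d);
        for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + i;
        for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
        dt1d(f, spacing[1], d);
        for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = (R_xlen_t)j * nx + i;
        for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
        dt1d(f, spacing[2], d);
        for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
      }
  }
  return out;
}
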