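#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb-Huttenlocher exact 1-D squared distance transform of a
// sampled function f; positions are the integer grid 0..n-1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest FALSE voxel of `mask`. Voxels outside the grid are ignored (treated
// as if the structure continued), so a phase spanning the grid keeps the
// distances implied by in-grid opposite-phase voxels only. If the mask has no
// FALSE voxel the result is Inf everywhere on the mask. Internally a large
// finite sentinel replaces infinity so the parabola envelope stays
// well-defined; any true distance is smaller and wins.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double LARGE = 1e30;
  NumericVector out(n);
  bool any_bg = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = mask[i] ? LARGE : 0.0;
    if (!mask[i]) any_bg = true;
  }
  if (!any_bg) {
    for (R_xlen_t i = 0; i < n; ++i) out[i] = R_PosInf;
    return out;
  }

  std::vector<double> f, d;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)z * nxy + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + z * nxy];
      dt1d(f, d);
      for (int z = 0; z < nz; ++z) out[base + z * nxy] = d[z];
    }
  return out;
}
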