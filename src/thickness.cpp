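#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Hildebrand-Rueegsegger local thickness by sphere painting.
// For every phase voxel p, the largest sphere centred at a phase voxel that
// contains p determines its thickness (sphere diameter). Sphere radii come
// from the exact EDT: r(p) = sqrt(d2(p)) - 0.5, the distance from the voxel
// centre to the phase boundary (half a voxel inside the nearest opposite
// voxel centre). Returns the thickness map in voxel units (0 outside phase,
// Inf if the grid holds no opposite-phase voxel).
// [[Rcpp::export(name = ".local_thickness_map")]]
NumericVector local_thickness_map(LogicalVector mask, NumericVector d2,
                                  IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  NumericVector th(n);

  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  bool any_inf = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) {
      if (!R_finite(d2[i])) { any_inf = true; }
      idx.push_back(i);
    }
  }
  if (any_inf) {  // no opposite phase anywhere: thickness unbounded
    for (R_xlen_t i = 0; i < n; ++i) th[i] = mask[i] ? R_PosInf : 0.0;
    return th;
  }
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return d2[a] > d2[b]; });

  for (R_xlen_t t = 0; t < (R_xlen_t)idx.size(); ++t) {
    const R_xlen_t p = idx[t];
    const double r = std::sqrt(d2[p]) - 0.5;
    if (r <= 0) { if (th[p] < 1.0) th[p] = 1.0; continue; }
    const double dia = 2.0 * r, r2 = r * r;
    const int pz = (int)(p / nxy), py = (int)((p % nxy) / nx), px = (int)(p % nx);
    const int rr = (int)std::floor(r);
    const int z0 = std::max(0, pz - rr), z1 = std::min(nz - 1, pz + rr);
    const int y0 = std::max(0, py - rr), y1 = std::min(ny - 1, py + rr);
    const int x0 = std::max(0, px - rr), x1 = std::min(nx - 1, px + rr);
    for (int z = z0; z <= z1; ++z) {
      const double dz2 = (double)(z - pz) * (z - pz);
      for (int y = y0; y <= y1; ++y) {
        const double dyz2 = dz2 + (double)(y - py) * (y - py);
        if (dyz2 > r2) continue;
        const R_xlen_t base = (R_xlen_t)z * nxy + (R_xlen_t)y * nx;
        for (int x = x0; x <= x1; ++x) {
          if (dyz2 + (double)(x - px) * (x - px) <= r2) {
            const R_xlen_t q = base + x;
            if (th[q] < dia) th[q] = dia;
          }
        }
      }
    }
  }
  // voxels whose maximal sphere has r <= 0.5 (isolated or 1-thick): the
  // inscribed sphere is the voxel itself, one voxel across
  for (R_xlen_t t = 0; t < (R_xlen_t)idx.size(); ++t)
    if (th[idx[t]] < 1.0) th[idx[t]] = 1.0;
  return th;
}

// 6-connected component labelling (flood fill); labels 1..k by decreasing
// arbitrary discovery order; returns integer labels, 0 = background.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny, n = nxy * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      const int pz = (int)(p / nxy), py = (int)((p % nxy) / nx), px = (int)(p % nx);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int x = px + dx[k], y = py + dy[k], z = pz + dz[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t q = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}
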