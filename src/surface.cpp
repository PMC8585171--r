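#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Triangulated isosurface area by marching tetrahedra. Each grid cell (the
// cube spanned by 8 neighbouring voxel centres) is split into 6 tetrahedra
// sharing the main diagonal; iso-crossings are placed by linear
// interpolation along tetrahedron edges. The caller pads the field with a
// background layer so surfaces close at the grid boundary. Returns the total
// area in voxel units squared.

static inline void interp(const double* pa, const double* pb, double fa,
                          double fb, double iso, double* out) {
  const double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
  for (int i = 0; i < 3; ++i) out[i] = pa[i] + t * (pb[i] - pa[i]);
}

static inline double tri_area(const double* a, const double* b,
                              const double* c) {
  const double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  const double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  const double cx = u[1] * v[2] - u[2] * v[1];
  const double cy = u[2] * v[0] - u[0] * v[2];
  const double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// area contributed by one tetrahedron with vertex positions P[4], values f[4]
static double tet_area(const double P[4][3], const double f[4], double iso) {
  bool above[4];
  int na = 0;
  for (int i = 0; i < 4; ++i) { above[i] = f[i] >= iso; if (above[i]) ++na; }
  if (na == 0 || na == 4) return 0.0;
  int A[4], B[4], ka = 0, kb = 0;
  for (int i = 0; i < 4; ++i) (above[i] ? A[ka++] : B[kb++]) = i;
  double q[4][3];
  if (na == 1 || na == 3) {
    const int lone = (na == 1) ? A[0] : B[0];
    const int* oth = (na == 1) ? B : A;
    for (int i = 0; i < 3; ++i)
      interp(P[lone], P[oth[i]], f[lone], f[oth[i]], iso, q[i]);
    return tri_area(q[0], q[1], q[2]);
  }
  // 2-2 case: crossings on edges A0-B0, A0-B1, A1-B1, A1-B0 form a quad
  interp(P[A[0]], P[B[0]], f[A[0]], f[B[0]], iso, q[0]);
  interp(P[A[0]], P[B[1]], f[A[0]], f[B[1]], iso, q[1]);
  interp(P[A[1]], P[B[1]], f[A[1]], f[B[1]], iso, q[2]);
  interp(P[A[1]], P[B[0]], f[A[1]], f[B[0]], iso, q[3]);
  return tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
}

// [[Rcpp::export(name = ".isosurface_area")]]
double isosurface_area(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // cube corner offsets, v0..v7
  static const int C[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                              {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // six tetrahedra around the v0-v6 diagonal
  static const int T[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                              {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  double total = 0.0;
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double fv[8];
        double pv[8][3];
        bool lo = false, hi = false;
        for (int c = 0; c < 8; ++c) {
          const int cx = x + C[c][0], cy = y + C[c][1], cz = z + C[c][2];
          fv[c] = field[(R_xlen_t)cz * nxy + (R_xlen_t)cy * nx + cx];
          pv[c][0] = cx; pv[c][1] = cy; pv[c][2] = cz;
          (fv[c] >= iso ? hi : lo) = true;
        }
        if (!lo || !hi) continue;
        for (int t = 0; t < 6; ++t) {
          double P[4][3], f[4];
          for (int i = 0; i < 4; ++i) {
            const int c = T[t][i];
            P[i][0] = pv[c][0]; P[i][1] = pv[c][1]; P[i][2] = pv[c][2];
            f[i] = fv[c];
          }
          total += tet_area(P, f, iso);
        }
      }
  return total;
}
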