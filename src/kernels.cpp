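#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of a 3D scalar array at continuous 0-based voxel indices.
// Points outside the index box [0, n-1] on any axis return `fill`.
// [[Rcpp::export]]
NumericVector c_trilinear(const NumericVector& vals, const IntegerVector& dim,
                          const NumericMatrix& pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vals.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int i1 = (nx == 1) ? i0 : i0 + 1;
    const int j1 = (ny == 1) ? j0 : j0 + 1;
    const int k1 = (nz == 1) ? k0 : k0 + 1;
    const double c000 = v[i0 * sx + j0 * sy + k0 * sz];
    const double c100 = v[i1 * sx + j0 * sy + k0 * sz];
    const double c010 = v[i0 * sx + j1 * sy + k0 * sz];
    const double c110 = v[i1 * sx + j1 * sy + k0 * sz];
    const double c001 = v[i0 * sx + j0 * sy + k1 * sz];
    const double c101 = v[i1 * sx + j0 * sy + k1 * sz];
    const double c011 = v[i0 * sx + j1 * sy + k1 * sz];
    const double c111 = v[i1 * sx + j1 * sy + k1 * sz];
    const double c00 = c000 * (1 - fx) + c100 * fx;
    const double c10 = c010 * (1 - fx) + c110 * fx;
    const double c01 = c001 * (1 - fx) + c101 * fx;
    const double c11 = c011 * (1 - fx) + c111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling, same conventions as c_trilinear.
// [[Rcpp::export]]
NumericVector c_nearest(const NumericVector& vals, const IntegerVector& dim,
                        const NumericMatrix& pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vals.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = fill;
      continue;
    }
    const int i = (int)std::floor(x + 0.5);
    const int j = (int)std::floor(y + 0.5);
    const int k = (int)std::floor(z + 0.5);
    out[p] = v[i + j * sy + k * sz];
  }
  return out;
}

// Fixed-point inversion of a displacement field u (mm) on its own grid:
// v_{k+1}(y) = -u(y + v_k(y)), with u extended by edge clamping so the
// iteration stays contractive near the borders. Returns the inverse field;
// attributes carry the composition residual and convergence flag.
static inline double tri_clamped(const double* v, int nx, int ny, int nz,
                                 double x, double y, double z) {
  if (x < 0) x = 0; else if (x > nx - 1.0) x = nx - 1.0;
  if (y < 0) y = 0; else if (y > ny - 1.0) y = ny - 1.0;
  if (z < 0) z = 0; else if (z > nz - 1.0) z = nz - 1.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 >= nx - 1) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 >= ny - 1) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 >= nz - 1) k0 = nz - 2; if (k0 < 0) k0 = 0;
  const int i1 = (nx == 1) ? i0 : i0 + 1;
  const int j1 = (ny == 1) ? j0 : j0 + 1;
  const int k1 = (nz == 1) ? k0 : k0 + 1;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const double c00 = v[i0 + j0 * sy + k0 * sz] * (1 - fx) + v[i1 + j0 * sy + k0 * sz] * fx;
  const double c10 = v[i0 + j1 * sy + k0 * sz] * (1 - fx) + v[i1 + j1 * sy + k0 * sz] * fx;
  const double c01 = v[i0 + j0 * sy + k1 * sz] * (1 - fx) + v[i1 + j0 * sy + k1 * sz] * fx;
  const double c11 = v[i0 + j1 * sy + k1 * sz] * (1 - fx) + v[i1 + j1 * sy + k1 * sz] * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
List c_invert_dvf(const NumericVector& u, const IntegerVector& dim,
                  const NumericVector& spacing, double tol_mm, int max_iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* ux = u.begin();
  const double* uy = u.begin() + n;
  const double* uz = u.begin() + 2 * n;
  NumericVector v(3 * n);
  double* vx = v.begin();
  double* vy = v.begin() + n;
  double* vz = v.begin() + 2 * n;
  for (R_xlen_t i = 0; i < n; ++i) { vx[i] = -ux[i]; vy[i] = -uy[i]; vz[i] = -uz[i]; }
  bool converged = false;
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    double upd = 0.0;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i, ++idx) {
      const double px = i + vx[idx] / spacing[0];
      const double py = j + vy[idx] / spacing[1];
      const double pz = k + vz[idx] / spacing[2];
      const double nvx = -tri_clamped(ux, nx, ny, nz, px, py, pz);
      const double nvy = -tri_clamped(uy, nx, ny, nz, px, py, pz);
      const double nvz = -tri_clamped(uz, nx, ny, nz, px, py, pz);
      const double d = std::max(std::fabs(nvx - vx[idx]),
                       std::max(std::fabs(nvy - vy[idx]), std::fabs(nvz - vz[idx])));
      if (d > upd) upd = d;
      vx[idx] = nvx; vy[idx] = nvy; vz[idx] = nvz;
    }
    iters = it + 1;
    if (upd < tol_mm) { converged = true; break; }
  }
  double resid = 0.0;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i, ++idx) {
    const double px = i + vx[idx] / spacing[0];
    const double py = j + vy[idx] / spacing[1];
    const double pz = k + vz[idx] / spacing[2];
    const double rx = tri_clamped(ux, nx, ny, nz, px, py, pz) + vx[idx];
    const double ry = tri_clamped(uy, nx, ny, nz, px, py, pz) + vy[idx];
    const double rz = tri_clamped(uz, nx, ny, nz, px, py, pz) + vz[idx];
    const double r = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (r > resid) resid = r;
  }
  return List::create(_["v"] = v, _["residual"] = resid,
                      _["converged"] = converged, _["iterations"] = iters);
}

// For each row of `a` (n x 3, world mm), the Euclidean distance to the nearest
// row of `b` (m x 3). Brute force; intended for surface voxel sets (n, m ~ 1e3-1e4).
// [[Rcpp::export]]
NumericVector c_min_dists(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
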