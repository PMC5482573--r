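#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Trilinear sample of a 3D array at coordinate (x,y,z), 0-based voxel-center.
// Out-of-bounds samples return 0 (maps are assumed to decay to solvent level).
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  double c000 = v[x0 * sx + y0 * sy + z0 * sz];
  double c100 = v[x1 * sx + y0 * sy + z0 * sz];
  double c010 = v[x0 * sx + y1 * sy + z0 * sz];
  double c110 = v[x1 * sx + y1 * sy + z0 * sz];
  double c001 = v[x0 * sx + y0 * sy + z1 * sz];
  double c101 = v[x1 * sx + y0 * sy + z1 * sz];
  double c011 = v[x0 * sx + y1 * sy + z1 * sz];
  double c111 = v[x1 * sx + y1 * sy + z1 * sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom cubic kernel weights for fractional position t in [0,1).
static inline void cr_weights(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// Tricubic (Catmull-Rom) sample; edge voxels clamped, outside returns 0.
static inline double tricubic(const double* v, int nx, int ny, int nz,
                              double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cr_weights(x - x0, wx);
  cr_weights(y - y0, wy);
  cr_weights(z - z0, wz);
  const long sy = nx, sz = (long)nx * ny;
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int zz = z0 - 1 + c;
    if (zz < 0) zz = 0; else if (zz > nz - 1) zz = nz - 1;
    double accy = 0.0;
    for (int bq = 0; bq < 4; ++bq) {
      int yy = y0 - 1 + bq;
      if (yy < 0) yy = 0; else if (yy > ny - 1) yy = ny - 1;
      double accx = 0.0;
      for (int a = 0; a < 4; ++a) {
        int xx = x0 - 1 + a;
        if (xx < 0) xx = 0; else if (xx > nx - 1) xx = nx - 1;
        accx += wx[a] * v[xx + yy * sy + zz * sz];
      }
      accy += wy[bq] * accx;
    }
    acc += wz[c] * accy;
  }
  return acc;
}

// out(p) = vol(A p + b) with p the 0-based output voxel coordinate.
// order: 1 = trilinear, 3 = tricubic (Catmull-Rom).
// [[Rcpp::export]]
NumericVector c_affine_sample(NumericVector vol, IntegerVector dims,
                              NumericMatrix A, NumericVector b,
                              int order = 1) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* v = vol.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = a00 * i + a01 * j + a02 * k + b[0];
        double y = a10 * i + a11 * j + a12 * k + b[1];
        double z = a20 * i + a21 * j + a22 * k + b[2];
        out[idx] = (order == 3) ? tricubic(v, nx, ny, nz, x, y, z)
                                : trilinear(v, nx, ny, nz, x, y, z);
      }
  return out;
}

// Weighted back-projection accumulator. Images are (n x n x ntilt); the tilt
// axis is the grid Y axis and the beam runs along Z at zero tilt. For voxel p
// (centered coordinates) and tilt a, the image is sampled bilinearly at the
// (x,y) components of R_y(a)^T p.
// [[Rcpp::export]]
NumericVector c_backproject(NumericVector images, IntegerVector idims,
                            NumericVector angles_deg, int size) {
  int n = idims[0], ntilt = idims[2];
  NumericVector out((R_xlen_t)size * size * size);
  double c = (size - 1) / 2.0, ci = (n - 1) / 2.0;
  for (int t = 0; t < ntilt; ++t) {
    double a = angles_deg[t] * M_PI / 180.0;
    double ca = std::cos(a), sa = std::sin(a);
    const double* img = images.begin() + (R_xlen_t)n * n * t;
    R_xlen_t idx = 0;
    for (int k = 0; k < size; ++k) {
      double z = k - c;
      for (int j = 0; j < size; ++j) {
        double y = j - c;
        for (int i = 0; i < size; ++i, ++idx) {
          double x = i - c;
          // u = (R_y(a)^T p)_x ; v stays on the tilt axis
          double u = ca * x - sa * z + ci;
          double v = y + ci;
          if (u < 0 || u > n - 1 || v < 0 || v > n - 1) continue;
          int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
          int u1 = std::min(u0 + 1, n - 1), v1 = std::min(v0 + 1, n - 1);
          double fu = u - u0, fv = v - v0;
          double val = img[u0 + (R_xlen_t)n * v0] * (1 - fu) * (1 - fv) +
                       img[u1 + (R_xlen_t)n * v0] * fu * (1 - fv) +
                       img[u0 + (R_xlen_t)n * v1] * (1 - fu) * fv +
                       img[u1 + (R_xlen_t)n * v1] * fu * fv;
          out[idx] += val;
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a 3D logical mask; connectivity 6, 18, 26.
// [[Rcpp::export]]
IntegerVector c_label_components(LogicalVector mask, IntegerVector dims,
                                 int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (auto& o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * jj + (R_xlen_t)nx * ny * kk;
        if (mask[nb] && labels[nb] == 0) { labels[nb] = next; q.push(nb); }
      }
    }
  }
  return labels;
}
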