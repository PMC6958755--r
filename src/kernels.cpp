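#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D volume stored column-major (x fastest) at a
// continuous 0-based voxel index. Edge-clamped within half a voxel of the
// domain; points beyond that return `fill`.
static inline double trilinear(const double* v, const int* d,
                               double x, double y, double z, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d[0] - 0.5 || y > d[1] - 0.5 || z > d[2] - 0.5)
    return fill;
  if (x < 0) x = 0; if (x > d[0] - 1) x = d[0] - 1;
  if (y < 0) y = 0; if (y > d[1] - 1) y = d[1] - 1;
  if (z < 0) z = 0; if (z > d[2] - 1) z = d[2] - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > d[0] - 2) x0 = d[0] - 2; if (x0 < 0) x0 = 0;
  if (y0 > d[1] - 2) y0 = d[1] - 2; if (y0 < 0) y0 = 0;
  if (z0 > d[2] - 2) z0 = d[2] - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const long sx = 1, sy = d[0], sz = (long)d[0] * d[1];
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nearestsamp(const double* v, const int* d,
                                 double x, double y, double z, double fill) {
  long xi = (long)std::lround(x), yi = (long)std::lround(y), zi = (long)std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2])
    return fill;
  return v[xi + (long)d[0] * (yi + (long)d[1] * zi)];
}

// [[Rcpp::export]]
NumericVector interp_cpp(NumericVector vol, IntegerVector dims,
                         NumericMatrix pts, bool nearest, double fill) {
  const int d[3] = { dims[0], dims[1], dims[2] };
  const double* v = vol.begin();
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    out[i] = nearest ? nearestsamp(v, d, x, y, z, fill)
                     : trilinear(v, d, x, y, z, fill);
  }
  return out;
}

// Connected-component labelling; labels assigned in raster (array) order of
// each component's first voxel, so labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const long n = (long)dx * dy * dz;
  std::vector<std::array<int, 3>> nb;
  for (int k = -1; k <= 1; k++)
    for (int j = -1; j <= 1; j++)
      for (int i = -1; i <= 1; i++) {
        int s = std::abs(i) + std::abs(j) + std::abs(k);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        nb.push_back({ i, j, k });
      }
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<long> stack;
  for (long p = 0; p < n; p++) {
    if (!mask[p] || labels[p] != 0) continue;
    next++;
    labels[p] = next;
    stack.push_back(p);
    while (!stack.empty()) {
      long q = stack.back(); stack.pop_back();
      int x = (int)(q % dx), y = (int)((q / dx) % dy), z = (int)(q / ((long)dx * dy));
      for (size_t a = 0; a < nb.size(); a++) {
        int xx = x + nb[a][0], yy = y + nb[a][1], zz = z + nb[a][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= dx || yy >= dy || zz >= dz) continue;
        long r = xx + (long)dx * (yy + (long)dy * zz);
        if (mask[r] && labels[r] == 0) { labels[r] = next; stack.push_back(r); }
      }
    }
  }
  return labels;
}

// Binary dilation by an explicit offset list (precomputed from the physical
// ball radius and the voxel spacing).
// [[Rcpp::export]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const long n = (long)dx * dy * dz;
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (long p = 0; p < n; p++) {
    if (!mask[p]) continue;
    int x = (int)(p % dx), y = (int)((p / dx) % dy), z = (int)(p / ((long)dx * dy));
    for (int a = 0; a < no; a++) {
      int xx = x + offsets(a, 0), yy = y + offsets(a, 1), zz = z + offsets(a, 2);
      if (xx < 0 || yy < 0 || zz < 0 || xx >= dx || yy >= dy || zz >= dz) continue;
      out[xx + (long)dx * (yy + (long)dy * zz)] = true;
    }
  }
  return out;
}

// Binary erosion by an explicit offset list: a voxel survives iff every
// offset stays inside both the grid and the mask. Only mask voxels are
// visited, so cost scales with the mask support, not the volume.
// [[Rcpp::export]]
LogicalVector erode_cpp(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const long n = (long)dx * dy * dz;
  LogicalVector out(n, false);
  const int no = offsets.nrow();
  for (long p = 0; p < n; p++) {
    if (!mask[p]) continue;
    int x = (int)(p % dx), y = (int)((p / dx) % dy), z = (int)(p / ((long)dx * dy));
    bool ok = true;
    for (int a = 0; a < no && ok; a++) {
      int xx = x + offsets(a, 0), yy = y + offsets(a, 1), zz = z + offsets(a, 2);
      if (xx < 0 || yy < 0 || zz < 0 || xx >= dx || yy >= dy || zz >= dz ||
          !mask[xx + (long)dx * (yy + (long)dy * zz)])
        ok = false;
    }
    if (ok) out[p] = true;
  }
  return out;
}

// Separable 1D convolution along one axis with reflected borders.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const long n = (long)dx * dy * dz;
  const int kr = (kernel.size() - 1) / 2;
  NumericVector out(n);
  const int dd[3] = { dx, dy, dz };
  const long strides[3] = { 1, dx, (long)dx * dy };
  const long s = strides[axis];
  const int m = dd[axis];
  for (long p = 0; p < n; p++) {
    int coord;
    if (axis == 0) coord = (int)(p % dx);
    else if (axis == 1) coord = (int)((p / dx) % dy);
    else coord = (int)(p / ((long)dx * dy));
    double acc = 0;
    for (int a = -kr; a <= kr; a++) {
      int c = coord + a;
      if (c < 0) c = -c;               // reflect
      if (c > m - 1) c = 2 * (m - 1) - c;
      acc += kernel[a + kr] * vol[p + (long)(c - coord) * s];
    }
    out[p] = acc;
  }
  return out;
}

// Cubic B-spline basis at u in [0,1).
static inline void bspline_w(double u, double* w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  w[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  w[3] = u3 / 6.0;
}

// Precompute per-point control-grid base indices and 1D basis weights for a
// free-form deformation grid with isotropic spacing h and origin gorigin.
// [[Rcpp::export]]
List ffd_precompute_cpp(NumericMatrix pts, NumericVector gorigin, double h,
                        IntegerVector gdims) {
  const int n = pts.nrow();
  IntegerMatrix base(n, 3);
  NumericMatrix w(n, 12);
  for (int i = 0; i < n; i++) {
    for (int a = 0; a < 3; a++) {
      double t = (pts(i, a) - gorigin[a]) / h;
      int fi = (int)std::floor(t);
      int b = fi - 1;
      if (b < 0) b = 0;
      if (b > gdims[a] - 4) b = gdims[a] - 4;
      double u = t - (b + 1);
      double ww[4];
      bspline_w(u, ww);
      base(i, a) = b;
      for (int k = 0; k < 4; k++) w(i, 4 * a + k) = ww[k];
    }
  }
  return List::create(_["base"] = base, _["w"] = w);
}

// Displacement of each point under B-spline coefficients (ncp x 3).
// [[Rcpp::export]]
NumericMatrix ffd_disp_cpp(IntegerMatrix base, NumericMatrix w,
                           IntegerVector gdims, NumericMatrix coefs) {
  const int n = base.nrow();
  const int gx = gdims[0], gy = gdims[1];
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; c++) {
      double wz = w(i, 8 + c);
      if (wz == 0) continue;
      for (int b = 0; b < 4; b++) {
        double wyz = w(i, 4 + b) * wz;
        if (wyz == 0) continue;
        long row0 = base(i, 0) + (long)gx * ((base(i, 1) + b) + (long)gy * (base(i, 2) + c));
        for (int a = 0; a < 4; a++) {
          double wt = w(i, a) * wyz;
          long cp = row0 + a;
          dx += wt * coefs(cp, 0);
          dy += wt * coefs(cp, 1);
          dz += wt * coefs(cp, 2);
        }
      }
    }
    out(i, 0) = dx; out(i, 1) = dy; out(i, 2) = dz;
  }
  return out;
}

// Sum-of-squared-differences objective and its gradient with respect to the
// B-spline control-point displacements. y0 holds the points already mapped by
// the linear (rigid+affine) part; the FFD displacement is additive. gxv/gyv/gzv
// are the moving image's index-space gradient volumes; invjt maps index-space
// gradients to physical space. Points landing outside the moving volume
// contribute nothing.
// [[Rcpp::export]]
List ffd_ssd_grad_cpp(IntegerMatrix base, NumericMatrix w, IntegerVector gdims,
                      NumericMatrix coefs, NumericMatrix y0, NumericVector fvals,
                      NumericVector mov, IntegerVector movdims, NumericMatrix w2i,
                      NumericVector gxv, NumericVector gyv, NumericVector gzv,
                      NumericMatrix invjt, bool want_grad) {
  const int n = base.nrow();
  const int gx = gdims[0], gy = gdims[1];
  const int d[3] = { movdims[0], movdims[1], movdims[2] };
  const double* mv = mov.begin();
  NumericMatrix grad(want_grad ? coefs.nrow() : 1, 3);
  double ssd = 0;
  long inside = 0;
  for (int i = 0; i < n; i++) {
    // displacement at this point
    double dxp = 0, dyp = 0, dzp = 0;
    for (int c = 0; c < 4; c++) {
      double wz = w(i, 8 + c);
      for (int b = 0; b < 4; b++) {
        double wyz = w(i, 4 + b) * wz;
        long row0 = base(i, 0) + (long)gx * ((base(i, 1) + b) + (long)gy * (base(i, 2) + c));
        for (int a = 0; a < 4; a++) {
          double wt = w(i, a) * wyz;
          dxp += wt * coefs(row0 + a, 0);
          dyp += wt * coefs(row0 + a, 1);
          dzp += wt * coefs(row0 + a, 2);
        }
      }
    }
    double px = y0(i, 0) + dxp, py = y0(i, 1) + dyp, pz = y0(i, 2) + dzp;
    double ix = w2i(0, 0) * px + w2i(0, 1) * py + w2i(0, 2) * pz + w2i(0, 3);
    double iy = w2i(1, 0) * px + w2i(1, 1) * py + w2i(1, 2) * pz + w2i(1, 3);
    double iz = w2i(2, 0) * px + w2i(2, 1) * py + w2i(2, 2) * pz + w2i(2, 3);
    if (ix < 0 || iy < 0 || iz < 0 || ix > d[0] - 1 || iy > d[1] - 1 || iz > d[2] - 1)
      continue;
    inside++;
    double m = trilinear(mv, d, ix, iy, iz, 0.0);
    double r = m - fvals[i];
    ssd += r * r;
    if (!want_grad) continue;
    double gi = trilinear(gxv.begin(), d, ix, iy, iz, 0.0);
    double gj = trilinear(gyv.begin(), d, ix, iy, iz, 0.0);
    double gk = trilinear(gzv.begin(), d, ix, iy, iz, 0.0);
    double gpx = invjt(0, 0) * gi + invjt(0, 1) * gj + invjt(0, 2) * gk;
    double gpy = invjt(1, 0) * gi + invjt(1, 1) * gj + invjt(1, 2) * gk;
    double gpz = invjt(2, 0) * gi + invjt(2, 1) * gj + invjt(2, 2) * gk;
    double f2r = 2.0 * r;
    for (int c = 0; c < 4; c++) {
      double wz = w(i, 8 + c);
      for (int b = 0; b < 4; b++) {
        double wyz = w(i, 4 + b) * wz;
        long row0 = base(i, 0) + (long)gx * ((base(i, 1) + b) + (long)gy * (base(i, 2) + c));
        for (int a = 0; a < 4; a++) {
          double wt = w(i, a) * wyz * f2r;
          grad(row0 + a, 0) += wt * gpx;
          grad(row0 + a, 1) += wt * gpy;
          grad(row0 + a, 2) += wt * gpz;
        }
      }
    }
  }
  return List::create(_["ssd"] = ssd, _["grad"] = grad, _["n_inside"] = inside);
}
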