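// Numerical kernels for B-spline free-form deformation registration:
// FFD evaluation and spatial derivatives, gradient projection onto the
// control-point parameters, image interpolation, separable Gaussian
// smoothing, Parzen joint histograms and surface-distance primitives.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Uniform cubic B-spline basis for local fraction u in [0,1), support
// offsets -1..2 relative to floor(t).  w, dw, d2w are derivatives with
// respect to t (grid units).
static inline void bspline_weights(double u, double* w) {
  double v = 1.0 - u;
  w[0] = v * v * v / 6.0;
  w[1] = (3.0 * u * u * u - 6.0 * u * u + 4.0) / 6.0;
  w[2] = (-3.0 * u * u * u + 3.0 * u * u + 3.0 * u + 1.0) / 6.0;
  w[3] = u * u * u / 6.0;
}
static inline void bspline_dweights(double u, double* dw) {
  double v = 1.0 - u;
  dw[0] = -v * v / 2.0;
  dw[1] = (9.0 * u * u - 12.0 * u) / 6.0;
  dw[2] = (-9.0 * u * u + 6.0 * u + 3.0) / 6.0;
  dw[3] = u * u / 2.0;
}
static inline void bspline_d2weights(double u, double* d2w) {
  d2w[0] = 1.0 - u;
  d2w[1] = 3.0 * u - 2.0;
  d2w[2] = 1.0 - 3.0 * u;
  d2w[3] = u;
}

// Centered cubic B-spline kernel (Parzen window), support (-2, 2).
static inline double bspline3_kernel(double x) {
  double a = std::fabs(x);
  if (a >= 2.0) return 0.0;
  if (a >= 1.0) { double t = 2.0 - a; return t * t * t / 6.0; }
  return 2.0 / 3.0 - a * a + a * a * a / 2.0;
}
static inline double bspline3_kernel_deriv(double x) {
  double a = std::fabs(x), s = (x < 0.0) ? -1.0 : 1.0;
  if (a >= 2.0) return 0.0;
  if (a >= 1.0) { double t = 2.0 - a; return -s * t * t / 2.0; }
  return s * (1.5 * a * a - 2.0 * a);
}

struct GridInfo {
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
};

static GridInfo grid_info(const NumericVector& coef, const NumericVector& origin,
                          const NumericVector& spacing) {
  IntegerVector d = coef.attr("dim");
  if (d.size() != 4 || d[3] != 3) stop("coefficient array must have dim (nx, ny, nz, 3)");
  GridInfo g;
  g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  return g;
}

static inline bool grid_local(const GridInfo& g, double x, double y, double z,
                              int& i0, int& j0, int& k0,
                              double& ux, double& uy, double& uz) {
  double tx = (x - g.ox) / g.sx, ty = (y - g.oy) / g.sy, tz = (z - g.oz) / g.sz;
  i0 = (int)std::floor(tx); j0 = (int)std::floor(ty); k0 = (int)std::floor(tz);
  ux = tx - i0; uy = ty - j0; uz = tz - k0;
  return (i0 >= 1 && i0 + 2 <= g.nx - 1 &&
          j0 >= 1 && j0 + 2 <= g.ny - 1 &&
          k0 >= 1 && k0 + 2 <= g.nz - 1);
}

static inline int cidx(const GridInfo& g, int i, int j, int k, int e) {
  return i + g.nx * (j + g.ny * (k + (long)g.nz * e));
}

// [[Rcpp::export]]
NumericMatrix cpp_ffd_eval(NumericVector coef, NumericVector origin,
                           NumericVector spacing, NumericMatrix pts,
                           bool extrapolate) {
  GridInfo g = grid_info(coef, origin, spacing);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    int i0, j0, k0; double ux, uy, uz;
    bool ok = grid_local(g, pts(p, 0), pts(p, 1), pts(p, 2), i0, j0, k0, ux, uy, uz);
    if (!ok) {
      if (!extrapolate) stop("point outside the fully-supported B-spline domain");
      continue;  // zero displacement
    }
    bspline_weights(ux, wx); bspline_weights(uy, wy); bspline_weights(uz, wz);
    for (int e = 0; e < 3; ++e) {
      double acc = 0.0;
      for (int c = 0; c < 4; ++c)
        for (int b = 0; b < 4; ++b) {
          double wyz = wy[b] * wz[c];
          for (int a = 0; a < 4; ++a)
            acc += wx[a] * wyz * coef[cidx(g, i0 - 1 + a, j0 - 1 + b, k0 - 1 + c, e)];
        }
      out(p, e) = acc;
    }
  }
  return out;
}

// Jacobian of the displacement field: out(p, k + 3*d) = d u_k / d x_d.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_jacobian(NumericVector coef, NumericVector origin,
                               NumericVector spacing, NumericMatrix pts,
                               bool extrapolate) {
  GridInfo g = grid_info(coef, origin, spacing);
  int n = pts.nrow();
  NumericMatrix out(n, 9);
  double w[3][4], dw[3][4];
  double sp[3] = {g.sx, g.sy, g.sz};
  for (int p = 0; p < n; ++p) {
    int i0, j0, k0; double ux, uy, uz;
    bool ok = grid_local(g, pts(p, 0), pts(p, 1), pts(p, 2), i0, j0, k0, ux, uy, uz);
    if (!ok) {
      if (!extrapolate) stop("point outside the fully-supported B-spline domain");
      continue;
    }
    double u3[3] = {ux, uy, uz};
    for (int ax = 0; ax < 3; ++ax) {
      bspline_weights(u3[ax], w[ax]);
      bspline_dweights(u3[ax], dw[ax]);
    }
    for (int d = 0; d < 3; ++d) {
      for (int e = 0; e < 3; ++e) {
        double acc = 0.0;
        for (int c = 0; c < 4; ++c)
          for (int b = 0; b < 4; ++b) {
            double wyz = (d == 1 ? dw[1][b] : w[1][b]) * (d == 2 ? dw[2][c] : w[2][c]);
            for (int a = 0; a < 4; ++a) {
              double wxx = (d == 0 ? dw[0][a] : w[0][a]);
              acc += wxx * wyz * coef[cidx(g, i0 - 1 + a, j0 - 1 + b, k0 - 1 + c, e)];
            }
          }
        out(p, e + 3 * d) = acc / sp[d];
      }
    }
  }
  return out;
}

// Second derivatives: out(p, k + 3*i + 9*j) = d^2 u_k / d x_i d x_j.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_hessian(NumericVector coef, NumericVector origin,
                              NumericVector spacing, NumericMatrix pts,
                              bool extrapolate) {
  GridInfo g = grid_info(coef, origin, spacing);
  int n = pts.nrow();
  NumericMatrix out(n, 27);
  double w[3][4], dw[3][4], d2w[3][4];
  double sp[3] = {g.sx, g.sy, g.sz};
  for (int p = 0; p < n; ++p) {
    int i0, j0, k0; double ux, uy, uz;
    bool ok = grid_local(g, pts(p, 0), pts(p, 1), pts(p, 2), i0, j0, k0, ux, uy, uz);
    if (!ok) {
      if (!extrapolate) stop("point outside the fully-supported B-spline domain");
      continue;
    }
    double u3[3] = {ux, uy, uz};
    for (int ax = 0; ax < 3; ++ax) {
      bspline_weights(u3[ax], w[ax]);
      bspline_dweights(u3[ax], dw[ax]);
      bspline_d2weights(u3[ax], d2w[ax]);
    }
    for (int di = 0; di < 3; ++di)
      for (int dj = di; dj < 3; ++dj) {
        int ord[3] = {0, 0, 0};
        ord[di] += 1; ord[dj] += 1;  // derivative order per axis (0,1,2)
        for (int e = 0; e < 3; ++e) {
          double acc = 0.0;
          for (int c = 0; c < 4; ++c)
            for (int b = 0; b < 4; ++b) {
              double wy_ = ord[1] == 0 ? w[1][b] : (ord[1] == 1 ? dw[1][b] : d2w[1][b]);
              double wz_ = ord[2] == 0 ? w[2][c] : (ord[2] == 1 ? dw[2][c] : d2w[2][c]);
              double wyz = wy_ * wz_;
              for (int a = 0; a < 4; ++a) {
                double wx_ = ord[0] == 0 ? w[0][a] : (ord[0] == 1 ? dw[0][a] : d2w[0][a]);
                acc += wx_ * wyz * coef[cidx(g, i0 - 1 + a, j0 - 1 + b, k0 - 1 + c, e)];
              }
            }
          double val = acc / (sp[di] * sp[dj]);
          out(p, e + 3 * di + 9 * dj) = val;
          out(p, e + 3 * dj + 9 * di) = val;
        }
      }
  }
  return out;
}

// Accumulate a cost gradient onto the control-point parameters.
// S0 (n x 3):  per-point d cost / d u_e            -> weight w
// A  (n x 9):  per-point d cost / d (du_e/dx_d)    -> weight dw/dx_d
// B  (n x 27): per-point d cost / d (d2u_e/dx_i dx_j) -> weight d2w
// Points with incomplete support are skipped (their basis support reaches
// outside the grid; callers arrange grids so this does not happen for
// evaluation points that matter).
// [[Rcpp::export]]
NumericVector cpp_ffd_project(NumericVector coef, NumericVector origin,
                              NumericVector spacing, NumericMatrix pts,
                              Nullable<NumericMatrix> S0,
                              Nullable<NumericMatrix> A,
                              Nullable<NumericMatrix> B) {
  GridInfo g = grid_info(coef, origin, spacing);
  int n = pts.nrow();
  NumericVector out((long)g.nx * g.ny * g.nz * 3);
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz, 3);
  bool hs = S0.isNotNull(), ha = A.isNotNull(), hb = B.isNotNull();
  NumericMatrix S0m = hs ? NumericMatrix(S0) : NumericMatrix(0, 0);
  NumericMatrix Am = ha ? NumericMatrix(A) : NumericMatrix(0, 0);
  NumericMatrix Bm = hb ? NumericMatrix(B) : NumericMatrix(0, 0);
  double w[3][4], dw[3][4], d2w[3][4];
  double sp[3] = {g.sx, g.sy, g.sz};
  for (int p = 0; p < n; ++p) {
    int i0, j0, k0; double ux, uy, uz;
    bool ok = grid_local(g, pts(p, 0), pts(p, 1), pts(p, 2), i0, j0, k0, ux, uy, uz);
    if (!ok) continue;
    double u3[3] = {ux, uy, uz};
    for (int ax = 0; ax < 3; ++ax) {
      bspline_weights(u3[ax], w[ax]);
      bspline_dweights(u3[ax], dw[ax]);
      bspline_d2weights(u3[ax], d2w[ax]);
    }
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a) {
          double w0 = w[0][a] * w[1][b] * w[2][c];
          double wd[3];
          wd[0] = dw[0][a] * w[1][b] * w[2][c] / sp[0];
          wd[1] = w[0][a] * dw[1][b] * w[2][c] / sp[1];
          wd[2] = w[0][a] * w[1][b] * dw[2][c] / sp[2];
          double whess[3][3];
          if (hb) {
            double fx[3] = {w[0][a], dw[0][a], d2w[0][a]};
            double fy[3] = {w[1][b], dw[1][b], d2w[1][b]};
            double fz[3] = {w[2][c], dw[2][c], d2w[2][c]};
            for (int di = 0; di < 3; ++di)
              for (int dj = di; dj < 3; ++dj) {
                int ord[3] = {0, 0, 0};
                ord[di] += 1; ord[dj] += 1;
                double v = fx[ord[0]] * fy[ord[1]] * fz[ord[2]] / (sp[di] * sp[dj]);
                whess[di][dj] = v; whess[dj][di] = v;
              }
          }
          for (int e = 0; e < 3; ++e) {
            double acc = 0.0;
            if (hs) acc += S0m(p, e) * w0;
            if (ha)
              for (int d = 0; d < 3; ++d) acc += Am(p, e + 3 * d) * wd[d];
            if (hb)
              for (int di = 0; di < 3; ++di)
                for (int dj = 0; dj < 3; ++dj)
                  acc += Bm(p, e + 3 * di + 9 * dj) * whess[di][dj];
            out[cidx(g, i0 - 1 + a, j0 - 1 + b, k0 - 1 + c, e)] += acc;
          }
        }
  }
  return out;
}

static inline double vol_at(const NumericVector& vol, int nx, int ny, int nz,
                            int i, int j, int k) {
  if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
  if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;
  if (k < 0) k = 0; if (k > nz - 1) k = nz - 1;
  return vol[i + (long)nx * (j + (long)ny * k)];
}

// Interpolate a volume at continuous 0-based voxel indices.
// method: 0 = nearest, 1 = trilinear, 3 = cubic (Keys, a = -0.5).
// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector vol, NumericMatrix cidx_pts, int method,
                         double default_value) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = cidx_pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = cidx_pts(p, 0), y = cidx_pts(p, 1), z = cidx_pts(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = default_value;
      continue;
    }
    if (method == 0) {
      int i = (int)std::round(x), j = (int)std::round(y), k = (int)std::round(z);
      out[p] = vol_at(vol, nx, ny, nz, i, j, k);
    } else if (method == 1) {
      int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
      if (i > nx - 2) i = nx - 2; if (j > ny - 2) j = ny - 2; if (k > nz - 2) k = nz - 2;
      if (nx == 1) i = 0; if (ny == 1) j = 0; if (nz == 1) k = 0;
      double fx = x - i, fy = y - j, fz = z - k;
      double acc = 0.0;
      for (int c = 0; c <= 1; ++c)
        for (int b = 0; b <= 1; ++b)
          for (int a = 0; a <= 1; ++a) {
            double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fz : 1 - fz);
            if (w != 0.0)
              acc += w * vol_at(vol, nx, ny, nz, i + a, j + b, k + c);
          }
      out[p] = acc;
    } else {
      // Keys cubic convolution, a = -0.5; clamped borders.
      int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
      double fx = x - i, fy = y - j, fz = z - k;
      double wx[4], wy[4], wz[4];
      for (int t = -1; t <= 2; ++t) {
        double keys;
        double sx_ = std::fabs(t - fx);
        keys = sx_ <= 1 ? (1.5 * sx_ - 2.5) * sx_ * sx_ + 1
                        : sx_ < 2 ? ((-0.5 * sx_ + 2.5) * sx_ - 4) * sx_ + 2 : 0;
        wx[t + 1] = keys;
        double sy_ = std::fabs(t - fy);
        keys = sy_ <= 1 ? (1.5 * sy_ - 2.5) * sy_ * sy_ + 1
                        : sy_ < 2 ? ((-0.5 * sy_ + 2.5) * sy_ - 4) * sy_ + 2 : 0;
        wy[t + 1] = keys;
        double sz_ = std::fabs(t - fz);
        keys = sz_ <= 1 ? (1.5 * sz_ - 2.5) * sz_ * sz_ + 1
                        : sz_ < 2 ? ((-0.5 * sz_ + 2.5) * sz_ - 4) * sz_ + 2 : 0;
        wz[t + 1] = keys;
      }
      double acc = 0.0;
      for (int c = -1; c <= 2; ++c)
        for (int b = -1; b <= 2; ++b)
          for (int a = -1; a <= 2; ++a) {
            double w = wx[a + 1] * wy[b + 1] * wz[c + 1];
            if (w != 0.0)
              acc += w * vol_at(vol, nx, ny, nz, i + a, j + b, k + c);
          }
      out[p] = acc;
    }
  }
  return out;
}

// Trilinear value + gradient with respect to continuous index coordinates.
// Out-of-domain points get the default value and zero gradient.
// [[Rcpp::export]]
List cpp_interp_grad(NumericVector vol, NumericMatrix cidx_pts,
                     double default_value) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = cidx_pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);
  LogicalVector inside(n);
  for (int p = 0; p < n; ++p) {
    double x = cidx_pts(p, 0), y = cidx_pts(p, 1), z = cidx_pts(p, 2);
    bool in = (x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
               z >= 0.0 && z <= nz - 1.0);
    inside[p] = in;
    if (!in) { val[p] = default_value; continue; }
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    if (i > nx - 2) i = nx - 2; if (j > ny - 2) j = ny - 2; if (k > nz - 2) k = nz - 2;
    if (nx == 1) i = 0; if (ny == 1) j = 0; if (nz == 1) k = 0;
    double fx = x - i, fy = y - j, fz = z - k;
    double v = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
    for (int c = 0; c <= 1; ++c)
      for (int b = 0; b <= 1; ++b)
        for (int a = 0; a <= 1; ++a) {
          double vx = vol_at(vol, nx, ny, nz, i + a, j + b, k + c);
          double wa = a ? fx : 1 - fx, wb = b ? fy : 1 - fy, wc = c ? fz : 1 - fz;
          double da = a ? 1.0 : -1.0, db = b ? 1.0 : -1.0, dc = c ? 1.0 : -1.0;
          v += wa * wb * wc * vx;
          gx += da * wb * wc * vx;
          gy += wa * db * wc * vx;
          gz += wa * wb * dc * vx;
        }
    val[p] = v; grad(p, 0) = gx; grad(p, 1) = gy; grad(p, 2) = gz;
  }
  return List::create(_["value"] = val, _["gradient"] = grad,
                      _["inside"] = inside);
}

// Separable Gaussian smoothing with per-axis sigma in voxel units;
// replicated borders; sigma <= 0 leaves an axis untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, NumericVector sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector cur = clone(vol);
  int dims[3] = {nx, ny, nz};
  long strides[3] = {1, nx, (long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0.0 || dims[ax] == 1) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += ker[t + r];
    }
    for (int t = 0; t < 2 * r + 1; ++t) ker[t] /= tot;
    NumericVector nxt((long)nx * ny * nz);
    int n0 = dims[ax];
    long st = strides[ax];
    // iterate over all lines along axis ax
    int oax1 = (ax + 1) % 3, oax2 = (ax + 2) % 3;
    for (int b = 0; b < dims[oax2]; ++b)
      for (int a = 0; a < dims[oax1]; ++a) {
        long base = a * strides[oax1] + b * strides[oax2];
        for (int i = 0; i < n0; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = 0;
            if (ii > n0 - 1) ii = n0 - 1;
            acc += ker[t + r] * cur[base + ii * st];
          }
          nxt[base + i * st] = acc;
        }
      }
    cur = nxt;
  }
  cur.attr("dim") = d;
  return cur;
}

// Parzen joint histogram: cubic B-spline windows on BOTH intensity
// axes (continuous bin coordinates fb, mb, assumed at least 1 bin away
// from the histogram edges so the 4-bin supports stay inside).  A
// smooth window on the fixed axis as well as the moving one removes
// the bin-center attraction artifact a box window would create.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector fb, NumericVector mb,
                             int nbins_f, int nbins_m) {
  int n = fb.size();
  NumericMatrix h(nbins_f, nbins_m);
  for (int p = 0; p < n; ++p) {
    int f0 = (int)std::floor(fb[p]);
    int m0 = (int)std::floor(mb[p]);
    for (int s = -1; s <= 2; ++s) {
      int fi = f0 + s;
      if (fi < 0 || fi > nbins_f - 1) continue;
      double wf = bspline3_kernel(fb[p] - fi);
      if (wf == 0.0) continue;
      for (int t = -1; t <= 2; ++t) {
        int mi = m0 + t;
        if (mi < 0 || mi > nbins_m - 1) continue;
        h(fi, mi) += wf * bspline3_kernel(mb[p] - mi);
      }
    }
  }
  return h;
}

// Per-sample derivative of MI with respect to the continuous moving bin
// coordinate: sum over the two Parzen supports of
// kernel_f * kernel_m' * L(f_bin, m_bin), where L is
// log(p / (pF * pM)) with empty bins zeroed.  The caller multiplies by
// 1/N and by d(bin)/d(intensity).
// [[Rcpp::export]]
NumericVector cpp_mi_sample_deriv(NumericVector fb, NumericVector mb,
                                  NumericMatrix L) {
  int n = fb.size();
  int nbf = L.nrow(), nbm = L.ncol();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    int f0 = (int)std::floor(fb[p]);
    int m0 = (int)std::floor(mb[p]);
    double acc = 0.0;
    for (int s = -1; s <= 2; ++s) {
      int fi = f0 + s;
      if (fi < 0 || fi > nbf - 1) continue;
      double wf = bspline3_kernel(fb[p] - fi);
      if (wf == 0.0) continue;
      for (int t = -1; t <= 2; ++t) {
        int mi = m0 + t;
        if (mi < 0 || mi > nbm - 1) continue;
        acc += wf * bspline3_kernel_deriv(mb[p] - mi) * L(fi, mi);
      }
    }
    out[p] = acc;
  }
  return out;
}

// For each row of A, the minimum Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
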