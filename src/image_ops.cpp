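#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;
using namespace sct;

static void get_dims(SEXP x, int& nx, int& ny, int& nz) {
  IntegerVector d = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 3) stop("expected a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// ---- 1D squared distance transform (lower envelope of parabolas) --------
static void dt1d(std::vector<double>& f, int n, double s2,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& zb) {
  int k = 0;
  v[0] = 0; zb[0] = -1e30; zb[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double sp;
    while (true) {
      sp = ((f[q] + (double)q * q * s2) - (f[v[k]] + (double)v[k] * v[k] * s2)) /
           (2.0 * s2 * (q - v[k]));
      if (sp <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = sp; zb[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, NumericVector spacing) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  size_t N = (size_t)nx * ny * nz;
  std::vector<double> g(N);
  bool any = false;
  for (size_t i = 0; i < N; ++i) {
    g[i] = mask[i] ? 0.0 : 1e20;
    if (mask[i]) any = true;
  }
  if (!any) stop("distance transform of an empty mask");
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  double s2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, nx, s2, d, v, zb);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
    }
  // along y
  s2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, ny, s2, d, v, zb);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  // along z
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, nz, s2, d, v, zb);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }
  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = mask.attr("dim");
  return out;
}

// 6-connected component labels (0 = background), labels ordered by first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N, 0);
  lab.attr("dim") = mask.attr("dim");
  std::vector<int> stack;
  int next = 0;
  for (size_t seed = 0; seed < N; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.clear();
    stack.push_back((int)seed);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int z = i / (nx * ny), r = i % (nx * ny), y = r / nx, x = r % nx;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Backward warp of a 3D volume by a displacement field in mm
// (4D array nx x ny x nz x 3). method: 0 = trilinear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, NumericVector dvf,
                       NumericVector spacing, int method) {
  int nx, ny, nz; get_dims(vol, nx, ny, nz);
  size_t N = (size_t)nx * ny * nz;
  if ((size_t)dvf.size() != 3 * N) stop("displacement field does not match volume grid");
  NumericVector out(N);
  if (method == 1)
    warp_nearest(REAL(vol), REAL(dvf), nx, ny, nz, REAL(spacing), REAL(out));
  else
    warp_trilinear(REAL(vol), REAL(dvf), nx, ny, nz, REAL(spacing), REAL(out), NULL);
  out.attr("dim") = vol.attr("dim");
  return out;
}

// General resampler: out(i) = vol(M %*% i + t) in 0-based voxel coordinates.
// method: 0 trilinear, 1 nearest; border: 0 = pad with `pad`, 1 = clamp.
// [[Rcpp::export]]
NumericVector cpp_affine_sample(NumericVector vol, IntegerVector out_dim,
                                NumericMatrix M, NumericVector t,
                                int method, double pad, int border) {
  int nx, ny, nz; get_dims(vol, nx, ny, nz);
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = REAL(vol);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + t[0];
        double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + t[1];
        double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + t[2];
        double val;
        if (border == 0 &&
            (sx < 0 || sx > nx - 1 || sy < 0 || sy > ny - 1 || sz < 0 || sz > nz - 1)) {
          val = pad;
        } else if (method == 1) {
          val = nn_sample(v, nx, ny, nz, sx, sy, sz);
        } else {
          val = tri_sample(v, nx, ny, nz, sx, sy, sz);
        }
        out[idx3(x, y, z, ox, oy)] = val;
      }
  out.attr("dim") = out_dim;
  return out;
}

// Mean SSIM over fully-contained w^3 windows (inputs already on [0,1]).
// [[Rcpp::export]]
double cpp_ssim(NumericVector a, NumericVector b, int w, double c1, double c2) {
  int nx, ny, nz; get_dims(a, nx, ny, nz);
  if (a.size() != b.size()) stop("images differ in size");
  if (w > nx || w > ny || w > nz) stop("SSIM window larger than volume");
  std::vector<double> x(a.begin(), a.end()), y(b.begin(), b.end());
  return ssim3d(x, y, nx, ny, nz, w, c1, c2, NULL);
}

// Windowed universal quality index: per-window Wang-Bovik Q averaged over
// fully-contained w^3 windows, skipping windows with zero denominator.
// [[Rcpp::export]]
double cpp_uqi_win(NumericVector a, NumericVector b, int w) {
  int nx, ny, nz; get_dims(a, nx, ny, nz);
  if (a.size() != b.size()) stop("images differ in size");
  if (w > nx || w > ny || w > nz) stop("UQI window larger than volume");
  std::vector<double> x(a.begin(), a.end()), y(b.begin(), b.end());
  std::vector<double> x2(x.size()), y2(y.size()), xy(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    x2[i] = x[i]*x[i]; y2[i] = y[i]*y[i]; xy[i] = x[i]*y[i];
  }
  int mx, my, mz;
  std::vector<double> sx, sy, sxx, syy, sxy;
  box_sum_valid(x,  nx, ny, nz, w, sx,  mx, my, mz);
  box_sum_valid(y,  nx, ny, nz, w, sy,  mx, my, mz);
  box_sum_valid(x2, nx, ny, nz, w, sxx, mx, my, mz);
  box_sum_valid(y2, nx, ny, nz, w, syy, mx, my, mz);
  box_sum_valid(xy, nx, ny, nz, w, sxy, mx, my, mz);
  const double N = (double)w * w * w;
  double acc = 0; size_t cnt = 0;
  for (size_t i = 0; i < sx.size(); ++i) {
    double mux = sx[i]/N, muy = sy[i]/N;
    double vx = sxx[i]/N - mux*mux, vy = syy[i]/N - muy*muy;
    double cv = sxy[i]/N - mux*muy;
    double den = (vx + vy) * (mux*mux + muy*muy);
    if (den <= 0) continue;
    acc += 4.0 * cv * mux * muy / den;
    ++cnt;
  }
  if (cnt == 0) stop("UQI undefined: all windows degenerate (constant images)");
  return acc / (double)cnt;
}

// SSIM value plus gradient with respect to the first image (for checking
// the analytic gradient and for custom optimizers).
// [[Rcpp::export]]
List cpp_ssim_grad(NumericVector a, NumericVector b, int w, double c1, double c2) {
  int nx, ny, nz; get_dims(a, nx, ny, nz);
  if (w > nx || w > ny || w > nz) stop("SSIM window larger than volume");
  std::vector<double> x(a.begin(), a.end()), y(b.begin(), b.end()), g;
  double val = ssim3d(x, y, nx, ny, nz, w, c1, c2, &g);
  NumericVector gr(g.begin(), g.end());
  gr.attr("dim") = a.attr("dim");
  return List::create(_["value"] = val, _["grad"] = gr);
}
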