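#ifndef SCTSELECT_CORE_H
#define SCTSELECT_CORE_H

#include <vector>
#include <cmath>
#include <cstddef>
#include <algorithm>

namespace sct {

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// clamped trilinear sample at continuous voxel coordinate (sx, sy, sz)
inline double tri_sample(const double* v, int nx, int ny, int nz,
                         double sx, double sy, double sz) {
  sx = std::min(std::max(sx, 0.0), (double)(nx - 1));
  sy = std::min(std::max(sy, 0.0), (double)(ny - 1));
  sz = std::min(std::max(sz, 0.0), (double)(nz - 1));
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  double c00 = v[idx3(x0,y0,z0,nx,ny)]   * (1-fx) + v[idx3(x0+1,y0,z0,nx,ny)]   * fx;
  double c10 = v[idx3(x0,y0+1,z0,nx,ny)] * (1-fx) + v[idx3(x0+1,y0+1,z0,nx,ny)] * fx;
  double c01 = v[idx3(x0,y0,z0+1,nx,ny)] * (1-fx) + v[idx3(x0+1,y0,z0+1,nx,ny)] * fx;
  double c11 = v[idx3(x0,y0+1,z0+1,nx,ny)]*(1-fx) + v[idx3(x0+1,y0+1,z0+1,nx,ny)]*fx;
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

inline double nn_sample(const double* v, int nx, int ny, int nz,
                        double sx, double sy, double sz) {
  int x = (int)std::lround(std::min(std::max(sx, 0.0), (double)(nx - 1)));
  int y = (int)std::lround(std::min(std::max(sy, 0.0), (double)(ny - 1)));
  int z = (int)std::lround(std::min(std::max(sz, 0.0), (double)(nz - 1)));
  return v[idx3(x, y, z, nx, ny)];
}

// Backward warp: out(x) = vol(x + u(x)/spacing), u in mm, 3 displacement
// planes of length N each.  If gderiv != NULL it receives d out / d u_d
// (per mm) for d = 0,1,2 (3 planes of length N); derivative is zero where
// the sample clamps at the border along that axis.
inline void warp_trilinear(const double* vol, const double* u,
                           int nx, int ny, int nz, const double* spacing,
                           double* out, double* gderiv) {
  const int N = nx * ny * nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        double sx = x + u[i]         / spacing[0];
        double sy = y + u[i + N]     / spacing[1];
        double sz = z + u[i + 2 * N] / spacing[2];
        bool cx = (sx <= 0.0 || sx >= nx - 1);
        bool cy = (sy <= 0.0 || sy >= ny - 1);
        bool cz = (sz <= 0.0 || sz >= nz - 1);
        sx = std::min(std::max(sx, 0.0), (double)(nx - 1));
        sy = std::min(std::max(sy, 0.0), (double)(ny - 1));
        sz = std::min(std::max(sz, 0.0), (double)(nz - 1));
        int x0 = std::min((int)std::floor(sx), nx - 2);
        int y0 = std::min((int)std::floor(sy), ny - 2);
        int z0 = std::min((int)std::floor(sz), nz - 2);
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double v000 = vol[idx3(x0,  y0,  z0,  nx,ny)];
        double v100 = vol[idx3(x0+1,y0,  z0,  nx,ny)];
        double v010 = vol[idx3(x0,  y0+1,z0,  nx,ny)];
        double v110 = vol[idx3(x0+1,y0+1,z0,  nx,ny)];
        double v001 = vol[idx3(x0,  y0,  z0+1,nx,ny)];
        double v101 = vol[idx3(x0+1,y0,  z0+1,nx,ny)];
        double v011 = vol[idx3(x0,  y0+1,z0+1,nx,ny)];
        double v111 = vol[idx3(x0+1,y0+1,z0+1,nx,ny)];
        double c00 = v000*(1-fx) + v100*fx;
        double c10 = v010*(1-fx) + v110*fx;
        double c01 = v001*(1-fx) + v101*fx;
        double c11 = v011*(1-fx) + v111*fx;
        double c0 = c00*(1-fy) + c10*fy;
        double c1 = c01*(1-fy) + c11*fy;
        out[i] = c0*(1-fz) + c1*fz;
        if (gderiv) {
          // d/dsx
          double dx00 = v100 - v000, dx10 = v110 - v010;
          double dx01 = v101 - v001, dx11 = v111 - v011;
          double dsx = ((dx00*(1-fy) + dx10*fy)*(1-fz) + (dx01*(1-fy) + dx11*fy)*fz);
          // d/dsy
          double dsy = ((c10 - c00)*(1-fz) + (c11 - c01)*fz);
          // d/dsz
          double dsz = c1 - c0;
          gderiv[i]         = cx ? 0.0 : dsx / spacing[0];
          gderiv[i + N]     = cy ? 0.0 : dsy / spacing[1];
          gderiv[i + 2 * N] = cz ? 0.0 : dsz / spacing[2];
        }
      }
}

inline void warp_nearest(const double* vol, const double* u,
                         int nx, int ny, int nz, const double* spacing,
                         double* out) {
  const int N = nx * ny * nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        out[i] = nn_sample(vol, nx, ny, nz,
                           x + u[i] / spacing[0],
                           y + u[i + N] / spacing[1],
                           z + u[i + 2 * N] / spacing[2]);
      }
}

// ---- sliding (box) sums ------------------------------------------------
// valid-window sums: out dims (nx-w+1, ny-w+1, nz-w+1)
inline void box_sum_valid(const std::vector<double>& a, int nx, int ny, int nz,
                          int w, std::vector<double>& out,
                          int& mx, int& my, int& mz) {
  mx = nx - w + 1; my = ny - w + 1; mz = nz - w + 1;
  std::vector<double> t1((size_t)mx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const double* row = &a[(size_t)idx3(0, y, z, nx, ny)];
      double* orow = &t1[(size_t)idx3(0, y, z, mx, ny)];
      double s = 0;
      for (int x = 0; x < w; ++x) s += row[x];
      orow[0] = s;
      for (int x = 1; x < mx; ++x) { s += row[x + w - 1] - row[x - 1]; orow[x] = s; }
    }
  std::vector<double> t2((size_t)mx * my * nz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < mx; ++x) {
      double s = 0;
      for (int y = 0; y < w; ++y) s += t1[(size_t)idx3(x, y, z, mx, ny)];
      t2[(size_t)idx3(x, 0, z, mx, my)] = s;
      for (int y = 1; y < my; ++y) {
        s += t1[(size_t)idx3(x, y + w - 1, z, mx, ny)] - t1[(size_t)idx3(x, y - 1, z, mx, ny)];
        t2[(size_t)idx3(x, y, z, mx, my)] = s;
      }
    }
  out.assign((size_t)mx * my * mz, 0.0);
  for (int y = 0; y < my; ++y)
    for (int x = 0; x < mx; ++x) {
      double s = 0;
      for (int z = 0; z < w; ++z) s += t2[(size_t)idx3(x, y, z, mx, my)];
      out[(size_t)idx3(x, y, 0, mx, my)] = s;
      for (int z = 1; z < mz; ++z) {
        s += t2[(size_t)idx3(x, y, z + w - 1, mx, my)] - t2[(size_t)idx3(x, y, z - 1, mx, my)];
        out[(size_t)idx3(x, y, z, mx, my)] = s;
      }
    }
}

// scatter: given per-window-origin coefficients a (dims mx,my,mz), produce
// full-grid sums out(i) = sum over window origins o with o <= i <= o+w-1.
inline void box_scatter(const std::vector<double>& a, int mx, int my, int mz,
                        int w, int nx, int ny, int nz, std::vector<double>& out) {
  std::vector<double> t1((size_t)nx * my * mz);
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y) {
      const double* row = &a[(size_t)idx3(0, y, z, mx, my)];
      double* orow = &t1[(size_t)idx3(0, y, z, nx, my)];
      for (int x = 0; x < nx; ++x) {
        int lo = std::max(0, x - w + 1), hi = std::min(mx - 1, x);
        double s = 0;
        for (int o = lo; o <= hi; ++o) s += row[o];
        orow[x] = s;
      }
    }
  std::vector<double> t2((size_t)nx * ny * mz);
  for (int z = 0; z < mz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int lo = std::max(0, y - w + 1), hi = std::min(my - 1, y);
        double s = 0;
        for (int o = lo; o <= hi; ++o) s += t1[(size_t)idx3(x, o, z, nx, my)];
        t2[(size_t)idx3(x, y, z, nx, ny)] = s;
      }
  out.assign((size_t)nx * ny * nz, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int lo = std::max(0, z - w + 1), hi = std::min(mz - 1, z);
        double s = 0;
        for (int o = lo; o <= hi; ++o) s += t2[(size_t)idx3(x, y, o, nx, ny)];
        out[(size_t)idx3(x, y, z, nx, ny)] = s;
      }
}

// mean SSIM over all fully-contained w^3 windows; optionally the gradient
// of (mean SSIM) with respect to x.
inline double ssim3d(const std::vector<double>& x, const std::vector<double>& y,
                     int nx, int ny, int nz, int w, double c1, double c2,
                     std::vector<double>* grad_x) {
  int mx, my, mz;
  std::vector<double> sx, sy, sxx, syy, sxy;
  std::vector<double> x2(x.size()), y2(y.size()), xy(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    x2[i] = x[i] * x[i]; y2[i] = y[i] * y[i]; xy[i] = x[i] * y[i];
  }
  box_sum_valid(x,  nx, ny, nz, w, sx,  mx, my, mz);
  box_sum_valid(y,  nx, ny, nz, w, sy,  mx, my, mz);
  box_sum_valid(x2, nx, ny, nz, w, sxx, mx, my, mz);
  box_sum_valid(y2, nx, ny, nz, w, syy, mx, my, mz);
  box_sum_valid(xy, nx, ny, nz, w, sxy, mx, my, mz);
  const double N = (double)w * w * w;
  const size_t W = sx.size();
  double acc = 0;
  std::vector<double> c0v, cxv, cyv;
  if (grad_x) { c0v.resize(W); cxv.resize(W); cyv.resize(W); }
  for (size_t i = 0; i < W; ++i) {
    double mux = sx[i] / N, muy = sy[i] / N;
    double vx = sxx[i] / N - mux * mux;
    double vy = syy[i] / N - muy * muy;
    double cv = sxy[i] / N - mux * muy;
    double A1 = 2 * mux * muy + c1, A2 = 2 * cv + c2;
    double B1 = mux * mux + muy * muy + c1, B2 = vx + vy + c2;
    double S = (A1 * A2) / (B1 * B2);
    acc += S;
    if (grad_x) {
      double D = B1 * B2; D = D * D;
      double t1 = A1 * B1 * B2;      // coeff of (y_i - muy)
      double t2 = A1 * A2 * B1;      // coeff of -(x_i - mux)
      double pre = 2.0 / (N * D);
      cyv[i] = pre * t1;
      cxv[i] = -pre * t2;
      c0v[i] = pre * (muy * A2 * B1 * B2) - cyv[i] * muy + pre * (mux * t2)
               - pre * (mux * A1 * A2 * B2);
    }
  }
  double val = acc / (double)W;
  if (grad_x) {
    std::vector<double> B0, Bx, By;
    box_scatter(c0v, mx, my, mz, w, nx, ny, nz, B0);
    box_scatter(cxv, mx, my, mz, w, nx, ny, nz, Bx);
    box_scatter(cyv, mx, my, mz, w, nx, ny, nz, By);
    grad_x->assign(x.size(), 0.0);
    for (size_t i = 0; i < x.size(); ++i)
      (*grad_x)[i] = (B0[i] + Bx[i] * x[i] + By[i] * y[i]) / (double)W;
  }
  return val;
}

} // namespace sct

#endif
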