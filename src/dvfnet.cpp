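// 3D encoder-decoder predicting a dense displacement field from a single
// CT volume, with hand-written backpropagation (conv3, per-volume batch
// normalization, leaky-ReLU, 2x average pooling, nearest upsampling,
// skip concatenation, zero-initialized output head) and an Adam training
// loop minimizing (1 - SSIM(warp(dct, dvf), pct)) + lambda * R(dvf).
#include <Rcpp.h>
#include <random>
#include "core.h"
using namespace Rcpp;
using namespace sct;

namespace {

struct Dims { int nx, ny, nz; int N() const { return nx * ny * nz; } };

struct ConvDef {
  int cin, cout;
  bool has_bn;
  int wofs, bofs, gofs, betofs; // offsets into theta
};

struct NetSpec {
  int L, F, K;
  std::vector<ConvDef> defs;
  int nparams;
};

NetSpec build_spec(int L, int F, int K) {
  NetSpec s; s.L = L; s.F = F; s.K = K;
  int ofs = 0;
  auto add = [&](int cin, int cout, bool bn) {
    ConvDef d; d.cin = cin; d.cout = cout; d.has_bn = bn;
    d.wofs = ofs; ofs += cout * cin * 27;
    d.bofs = ofs; ofs += cout;
    if (bn) { d.gofs = ofs; ofs += cout; d.betofs = ofs; ofs += cout; }
    else { d.gofs = d.betofs = -1; }
    s.defs.push_back(d);
  };
  // encoder blocks
  for (int b = 0; b < L; ++b) {
    int cout = F << b;
    int cin = (b == 0) ? 1 : (F << (b - 1));
    for (int k = 0; k < K; ++k) { add(k == 0 ? cin : cout, cout, true); }
  }
  // bottom
  {
    int cin = F << (L - 1), cout = F << L;
    for (int k = 0; k < K; ++k) add(k == 0 ? cin : cout, cout, true);
  }
  // decoder blocks, executed b = L-1 .. 0
  for (int b = L - 1; b >= 0; --b) {
    int cup = F << (b + 1), cskip = F << b, cout = F << b;
    for (int k = 0; k < K; ++k) add(k == 0 ? (cup + cskip) : cout, cout, true);
  }
  // head
  add(F, 3, false);
  s.nparams = ofs;
  return s;
}

void pad_channels(const std::vector<double>& in, int C, Dims d,
                  std::vector<double>& pbuf) {
  int PX = d.nx + 2, PY = d.ny + 2, PZ = d.nz + 2;
  size_t PN = (size_t)PX * PY * PZ;
  pbuf.assign((size_t)C * PN, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* src = &in[(size_t)c * d.N()];
    double* dst = &pbuf[(size_t)c * PN];
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y) {
        const double* srow = src + (size_t)idx3(0, y, z, d.nx, d.ny);
        double* drow = dst + (size_t)(1 + PX * ((y + 1) + (size_t)PY * (z + 1)));
        std::copy(srow, srow + d.nx, drow);
      }
  }
}

void conv3_forward(const double* W, const double* bias,
                   const std::vector<double>& pbuf, int cin, Dims d, int cout,
                   std::vector<double>& out) {
  int PX = d.nx + 2, PY = d.ny + 2;
  size_t PN = (size_t)PX * PY * (d.nz + 2);
  size_t N = (size_t)d.N();
  out.assign((size_t)cout * N, 0.0);
  for (int co = 0; co < cout; ++co) {
    double* oc = &out[(size_t)co * N];
    for (size_t i = 0; i < N; ++i) oc[i] = bias[co];
    for (int ci = 0; ci < cin; ++ci) {
      const double* pc = &pbuf[(size_t)ci * PN];
      const double* wk = W + ((size_t)co * cin + ci) * 27;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            double w = wk[kz * 9 + ky * 3 + kx];
            for (int z = 0; z < d.nz; ++z)
              for (int y = 0; y < d.ny; ++y) {
                const double* prow = pc + (size_t)(kx + PX * ((y + ky) + (size_t)PY * (z + kz)));
                double* orow = oc + (size_t)idx3(0, y, z, d.nx, d.ny);
                for (int x = 0; x < d.nx; ++x) orow[x] += w * prow[x];
              }
          }
    }
  }
}

// gradient wrt weights/bias and (optionally) wrt input
void conv3_backward(const double* W, const std::vector<double>& pad_in,
                    int cin, Dims d, int cout,
                    const std::vector<double>& gout,
                    double* gW, double* gb,
                    std::vector<double>* gin, std::vector<double>& pad_g) {
  int PX = d.nx + 2, PY = d.ny + 2;
  size_t PN = (size_t)PX * PY * (d.nz + 2);
  size_t N = (size_t)d.N();
  for (int co = 0; co < cout; ++co) {
    const double* gc = &gout[(size_t)co * N];
    double sb = 0;
    for (size_t i = 0; i < N; ++i) sb += gc[i];
    gb[co] += sb;
    for (int ci = 0; ci < cin; ++ci) {
      const double* pc = &pad_in[(size_t)ci * PN];
      double* gwk = gW + ((size_t)co * cin + ci) * 27;
      for (int kz = 0; kz < 3; ++kz)
        for (int ky = 0; ky < 3; ++ky)
          for (int kx = 0; kx < 3; ++kx) {
            double acc = 0;
            for (int z = 0; z < d.nz; ++z)
              for (int y = 0; y < d.ny; ++y) {
                const double* prow = pc + (size_t)(kx + PX * ((y + ky) + (size_t)PY * (z + kz)));
                const double* grow = gc + (size_t)idx3(0, y, z, d.nx, d.ny);
                for (int x = 0; x < d.nx; ++x) acc += grow[x] * prow[x];
              }
            gwk[kz * 9 + ky * 3 + kx] += acc;
          }
    }
  }
  if (gin) {
    pad_channels(gout, cout, d, pad_g);
    gin->assign((size_t)cin * N, 0.0);
    for (int ci = 0; ci < cin; ++ci) {
      double* gi = &(*gin)[(size_t)ci * N];
      for (int co = 0; co < cout; ++co) {
        const double* pg = &pad_g[(size_t)co * PN];
        const double* wk = W + ((size_t)co * cin + ci) * 27;
        for (int kz = 0; kz < 3; ++kz)
          for (int ky = 0; ky < 3; ++ky)
            for (int kx = 0; kx < 3; ++kx) {
              double w = wk[kz * 9 + ky * 3 + kx];
              for (int z = 0; z < d.nz; ++z)
                for (int y = 0; y < d.ny; ++y) {
                  const double* prow = pg + (size_t)((2 - kx) + PX * ((y + 2 - ky) + (size_t)PY * (z + 2 - kz)));
                  double* grow = gi + (size_t)idx3(0, y, z, d.nx, d.ny);
                  for (int x = 0; x < d.nx; ++x) grow[x] += w * prow[x];
                }
            }
      }
    }
  }
}

const double BN_EPS = 1e-5;
const double LRELU = 0.1;

struct ConvCache {
  std::vector<double> pad_in;   // padded input (for dW and din)
  Dims d;
  std::vector<double> xhat;     // BN normalized pre-affine
  std::vector<double> invstd;   // per channel
  std::vector<double> out;      // post activation (or raw conv for head)
};

struct Net {
  NetSpec spec;
  Dims d0;
  std::vector<ConvCache> cc;
  std::vector<std::vector<double>> skips;
  std::vector<Dims> skipd;

  // run one conv(+BN+act) layer, caching what backward needs
  std::vector<double> layer(const double* theta, int def_i,
                            const std::vector<double>& in, Dims d) {
    const ConvDef& df = spec.defs[def_i];
    ConvCache cache; cache.d = d;
    pad_channels(in, df.cin, d, cache.pad_in);
    std::vector<double> z;
    conv3_forward(theta + df.wofs, theta + df.bofs, cache.pad_in, df.cin, d, df.cout, z);
    size_t N = (size_t)d.N();
    if (df.has_bn) {
      cache.xhat.resize(z.size());
      cache.invstd.resize(df.cout);
      const double* g = theta + df.gofs;
      const double* be = theta + df.betofs;
      for (int c = 0; c < df.cout; ++c) {
        double* zc = &z[(size_t)c * N];
        double mu = 0;
        for (size_t i = 0; i < N; ++i) mu += zc[i];
        mu /= N;
        double var = 0;
        for (size_t i = 0; i < N; ++i) { double dd = zc[i] - mu; var += dd * dd; }
        var /= N;
        double is = 1.0 / std::sqrt(var + BN_EPS);
        cache.invstd[c] = is;
        double* xh = &cache.xhat[(size_t)c * N];
        for (size_t i = 0; i < N; ++i) {
          xh[i] = (zc[i] - mu) * is;
          double a = g[c] * xh[i] + be[c];
          zc[i] = a > 0 ? a : LRELU * a;
        }
      }
    }
    cache.out = z;
    cc.push_back(std::move(cache));
    return cc.back().out;
  }

  // backward through one conv(+BN+act); cache index ci corresponds to def_i
  std::vector<double> layer_bw(const double* theta, int def_i, int ci_idx,
                               const std::vector<double>& gout_in,
                               double* gtheta, bool need_gin,
                               std::vector<double>& pad_scratch) {
    const ConvDef& df = spec.defs[def_i];
    ConvCache& cache = cc[ci_idx];
    Dims d = cache.d;
    size_t N = (size_t)d.N();
    std::vector<double> gz = gout_in; // will become grad wrt conv output
    if (df.has_bn) {
      const double* g = theta + df.gofs;
      for (int c = 0; c < df.cout; ++c) {
        double* gc = &gz[(size_t)c * N];
        const double* oc = &cache.out[(size_t)c * N];
        const double* xh = &cache.xhat[(size_t)c * N];
        // leaky ReLU backward (out > 0 <=> pre-activation > 0)
        for (size_t i = 0; i < N; ++i) if (oc[i] <= 0) gc[i] *= LRELU;
        // BN backward
        double sdy = 0, sdyx = 0;
        for (size_t i = 0; i < N; ++i) { sdy += gc[i]; sdyx += gc[i] * xh[i]; }
        gtheta[df.gofs + c] += sdyx;
        gtheta[df.betofs + c] += sdy;
        double is = cache.invstd[c], gam = g[c];
        double a = sdy / N, b = sdyx / N;
        for (size_t i = 0; i < N; ++i)
          gc[i] = gam * is * (gc[i] - a - xh[i] * b);
      }
    }
    std::vector<double> gin;
    conv3_backward(theta + df.wofs, cache.pad_in, df.cin, d, df.cout, gz,
                   gtheta + df.wofs, gtheta + df.bofs,
                   need_gin ? &gin : NULL, pad_scratch);
    return gin;
  }

  std::vector<double> forward(const double* theta, const std::vector<double>& input,
                              Dims d) {
    d0 = d;
    cc.clear(); skips.assign(spec.L, {}); skipd.assign(spec.L, Dims());
    std::vector<double> cur = input;
    Dims cd = d;
    int di = 0;
    for (int b = 0; b < spec.L; ++b) {
      for (int k = 0; k < spec.K; ++k) cur = layer(theta, di++, cur, cd);
      skips[b] = cur; skipd[b] = cd;
      // 2x average pool
      int C = spec.F << b;
      Dims pd = { cd.nx / 2, cd.ny / 2, cd.nz / 2 };
      std::vector<double> pooled((size_t)C * pd.N());
      for (int c = 0; c < C; ++c) {
        const double* src = &cur[(size_t)c * cd.N()];
        double* dst = &pooled[(size_t)c * pd.N()];
        for (int z = 0; z < pd.nz; ++z)
          for (int y = 0; y < pd.ny; ++y)
            for (int x = 0; x < pd.nx; ++x) {
              double s = 0;
              for (int dz = 0; dz < 2; ++dz)
                for (int dy = 0; dy < 2; ++dy)
                  for (int dx = 0; dx < 2; ++dx)
                    s += src[idx3(2 * x + dx, 2 * y + dy, 2 * z + dz, cd.nx, cd.ny)];
              dst[idx3(x, y, z, pd.nx, pd.ny)] = s / 8.0;
            }
      }
      cur = std::move(pooled); cd = pd;
    }
    for (int k = 0; k < spec.K; ++k) cur = layer(theta, di++, cur, cd);
    for (int b = spec.L - 1; b >= 0; --b) {
      // nearest upsample 2x
      int C = spec.F << (b + 1);
      Dims ud = skipd[b];
      std::vector<double> up((size_t)C * ud.N());
      for (int c = 0; c < C; ++c) {
        const double* src = &cur[(size_t)c * cd.N()];
        double* dst = &up[(size_t)c * ud.N()];
        for (int z = 0; z < ud.nz; ++z)
          for (int y = 0; y < ud.ny; ++y)
            for (int x = 0; x < ud.nx; ++x)
              dst[idx3(x, y, z, ud.nx, ud.ny)] =
                src[idx3(x / 2, y / 2, z / 2, cd.nx, cd.ny)];
      }
      // concat(up, skip)
      int Cs = spec.F << b;
      std::vector<double> cat((size_t)(C + Cs) * ud.N());
      std::copy(up.begin(), up.end(), cat.begin());
      std::copy(skips[b].begin(), skips[b].end(), cat.begin() + up.size());
      cur = std::move(cat); cd = ud;
      for (int k = 0; k < spec.K; ++k) cur = layer(theta, di++, cur, cd);
    }
    cur = layer(theta, di++, cur, cd); // head, 3 channels
    return cur;
  }

  void backward(const double* theta, const std::vector<double>& gdvf,
                double* gtheta) {
    std::vector<double> pad_scratch;
    int L = spec.L, K = spec.K;
    int head_def = (2 * L + 1) * K;
    int ci = (int)cc.size() - 1;
    std::vector<double> g = layer_bw(theta, head_def, ci--, gdvf, gtheta, true, pad_scratch);
    std::vector<std::vector<double>> gskip(L);
    Dims cd = d0;
    // decoder blocks in reverse execution order: b = 0 .. L-1
    for (int b = 0; b < L; ++b) {
      int first_def = (L + 1) * K + (L - 1 - b) * K;
      for (int k = K - 1; k >= 0; --k)
        g = layer_bw(theta, first_def + k, ci--, g, gtheta, true, pad_scratch);
      // split concat grad
      int Cup = spec.F << (b + 1), Cs = spec.F << b;
      Dims ud = skipd[b];
      size_t nUp = (size_t)Cup * ud.N();
      gskip[b].assign(g.begin() + nUp, g.begin() + nUp + (size_t)Cs * ud.N());
      // upsample backward: sum children
      Dims ld = { ud.nx / 2, ud.ny / 2, ud.nz / 2 };
      std::vector<double> gl((size_t)Cup * ld.N(), 0.0);
      for (int c = 0; c < Cup; ++c) {
        const double* src = &g[(size_t)c * ud.N()];
        double* dst = &gl[(size_t)c * ld.N()];
        for (int z = 0; z < ud.nz; ++z)
          for (int y = 0; y < ud.ny; ++y)
            for (int x = 0; x < ud.nx; ++x)
              dst[idx3(x / 2, y / 2, z / 2, ld.nx, ld.ny)] +=
                src[idx3(x, y, z, ud.nx, ud.ny)];
      }
      g = std::move(gl); cd = ld;
    }
    // bottom
    for (int k = K - 1; k >= 0; --k)
      g = layer_bw(theta, L * K + k, ci--, g, gtheta, true, pad_scratch);
    // encoder blocks b = L-1 .. 0
    for (int b = L - 1; b >= 0; --b) {
      // pool backward: distribute /8, then add skip grad
      Dims ud = skipd[b];
      int C = spec.F << b;
      std::vector<double> gu((size_t)C * ud.N());
      Dims pd = { ud.nx / 2, ud.ny / 2, ud.nz / 2 };
      for (int c = 0; c < C; ++c) {
        const double* src = &g[(size_t)c * pd.N()];
        double* dst = &gu[(size_t)c * ud.N()];
        for (int z = 0; z < ud.nz; ++z)
          for (int y = 0; y < ud.ny; ++y)
            for (int x = 0; x < ud.nx; ++x)
              dst[idx3(x, y, z, ud.nx, ud.ny)] =
                src[idx3(x / 2, y / 2, z / 2, pd.nx, pd.ny)] / 8.0;
      }
      for (size_t i = 0; i < gu.size(); ++i) gu[i] += gskip[b][i];
      g = std::move(gu);
      bool need = true;
      for (int k = K - 1; k >= 0; --k) {
        if (b == 0 && k == 0) need = false; // input gradient unused
        g = layer_bw(theta, b * K + k, ci--, g, gtheta, need, pad_scratch);
      }
    }
  }
};

// diffusion regularizer: mean squared forward difference of each
// displacement component (mm^2), plus gradient
double reg_value_grad(const std::vector<double>& u, Dims d,
                      std::vector<double>* grad) {
  size_t N = (size_t)d.N();
  double acc = 0;
  size_t cnt = 0;
  if (grad) grad->assign(3 * N, 0.0);
  for (int c = 0; c < 3; ++c) {
    const double* uc = &u[(size_t)c * N];
    double* gc = grad ? &(*grad)[(size_t)c * N] : NULL;
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y)
        for (int x = 0; x < d.nx; ++x) {
          int i = idx3(x, y, z, d.nx, d.ny);
          if (x + 1 < d.nx) {
            double dd = uc[idx3(x + 1, y, z, d.nx, d.ny)] - uc[i];
            acc += dd * dd; ++cnt;
            if (gc) { gc[idx3(x + 1, y, z, d.nx, d.ny)] += 2 * dd; gc[i] -= 2 * dd; }
          }
          if (y + 1 < d.ny) {
            double dd = uc[idx3(x, y + 1, z, d.nx, d.ny)] - uc[i];
            acc += dd * dd; ++cnt;
            if (gc) { gc[idx3(x, y + 1, z, d.nx, d.ny)] += 2 * dd; gc[i] -= 2 * dd; }
          }
          if (z + 1 < d.nz) {
            double dd = uc[idx3(x, y, z + 1, d.nx, d.ny)] - uc[i];
            acc += dd * dd; ++cnt;
            if (gc) { gc[idx3(x, y, z + 1, d.nx, d.ny)] += 2 * dd; gc[i] -= 2 * dd; }
          }
        }
  }
  if (grad) for (size_t i = 0; i < grad->size(); ++i) (*grad)[i] /= (double)cnt;
  return acc / (double)cnt;
}

Dims dims_of(SEXP x) {
  IntegerVector dm = as<IntegerVector>(Rf_getAttrib(x, R_DimSymbol));
  Dims d; d.nx = dm[0]; d.ny = dm[1]; d.nz = dm[2];
  return d;
}

} // anonymous namespace

// [[Rcpp::export]]
int cpp_nn_nparams(int levels, int base_ch, int convs_per_block) {
  return build_spec(levels, base_ch, convs_per_block).nparams;
}

// He-normal initialization; output head zero so the initial prediction is
// the identity transform.
// [[Rcpp::export]]
NumericVector cpp_nn_init(int levels, int base_ch, int convs_per_block, int seed) {
  NetSpec s = build_spec(levels, base_ch, convs_per_block);
  NumericVector theta(s.nparams);
  std::mt19937 rng((unsigned)seed);
  auto runif01 = [&]() { return (rng() + 0.5) / 4294967296.0; };
  auto rnorm_ = [&]() {
    double u1 = runif01(), u2 = runif01();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  };
  for (size_t li = 0; li < s.defs.size(); ++li) {
    const ConvDef& df = s.defs[li];
    bool head = (li == s.defs.size() - 1);
    double sd = head ? 0.0 : std::sqrt(2.0 / (df.cin * 27.0));
    for (int i = 0; i < df.cout * df.cin * 27; ++i)
      theta[df.wofs + i] = head ? 0.0 : sd * rnorm_();
    for (int i = 0; i < df.cout; ++i) theta[df.bofs + i] = 0.0;
    if (df.has_bn)
      for (int i = 0; i < df.cout; ++i) {
        theta[df.gofs + i] = 1.0;
        theta[df.betofs + i] = 0.0;
      }
  }
  return theta;
}

// [[Rcpp::export]]
NumericVector cpp_nn_forward(int levels, int base_ch, int convs_per_block,
                             NumericVector theta, NumericVector input) {
  NetSpec s = build_spec(levels, base_ch, convs_per_block);
  if (theta.size() != s.nparams) stop("parameter vector does not match network spec");
  Dims d = dims_of(input);
  Net net; net.spec = s;
  std::vector<double> in(input.begin(), input.end());
  std::vector<double> dvf = net.forward(REAL(theta), in, d);
  NumericVector out(dvf.begin(), dvf.end());
  out.attr("dim") = IntegerVector::create(d.nx, d.ny, d.nz, 3);
  return out;
}

// [[Rcpp::export]]
double cpp_reg_value(NumericVector dvf) {
  IntegerVector dm = as<IntegerVector>(Rf_getAttrib(dvf, R_DimSymbol));
  Dims d; d.nx = dm[0]; d.ny = dm[1]; d.nz = dm[2];
  std::vector<double> u(dvf.begin(), dvf.end());
  return reg_value_grad(u, d, NULL);
}

// [[Rcpp::export]]
List cpp_nn_train(int levels, int base_ch, int convs_per_block,
                  NumericVector theta0, List dct_list, List pct_list,
                  NumericVector spacing, double lr, int epochs, double lambda,
                  int win, int batch_size, double hu_lo, double hu_hi,
                  double c1, double c2) {
  NetSpec s = build_spec(levels, base_ch, convs_per_block);
  if (theta0.size() != s.nparams) stop("parameter vector does not match network spec");
  int n = dct_list.size();
  if (n < 1) stop("no training pairs");
  Dims d = dims_of(dct_list[0]);
  size_t N = (size_t)d.N();
  double range = hu_hi - hu_lo;
  std::vector<std::vector<double>> dct_hu(n), dct_n(n), pct_n(n);
  for (int i = 0; i < n; ++i) {
    NumericVector a = dct_list[i], b = pct_list[i];
    if ((size_t)a.size() != N || (size_t)b.size() != N)
      stop("training pairs differ in shape");
    dct_hu[i].assign(a.begin(), a.end());
    dct_n[i].resize(N); pct_n[i].resize(N);
    for (size_t j = 0; j < N; ++j) {
      dct_n[i][j] = std::min(std::max((a[j] - hu_lo) / range, 0.0), 1.0);
      pct_n[i][j] = std::min(std::max((b[j] - hu_lo) / range, 0.0), 1.0);
    }
  }
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> m(theta.size(), 0.0), v(theta.size(), 0.0);
  std::vector<double> grad(theta.size());
  NumericVector history(epochs);
  Net net; net.spec = s;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<double> warped(N), wn(N);
  std::vector<char> clampmask(N);
  std::vector<double> gderiv(3 * N), gssim, gdvf(3 * N), rgrad;
  for (int ep = 0; ep < epochs; ++ep) {
    double lsum = 0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      int nb = std::min(batch_size, n - b0);
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int si = b0; si < b0 + nb; ++si) {
        std::vector<double> dvf = net.forward(theta.data(), dct_n[si], d);
        warp_trilinear(dct_hu[si].data(), dvf.data(), d.nx, d.ny, d.nz,
                       REAL(spacing), warped.data(), gderiv.data());
        for (size_t j = 0; j < N; ++j) {
          double z = (warped[j] - hu_lo) / range;
          clampmask[j] = (z > 0.0 && z < 1.0);
          wn[j] = std::min(std::max(z, 0.0), 1.0);
        }
        double sval = ssim3d(wn, pct_n[si], d.nx, d.ny, d.nz, win, c1, c2, &gssim);
        double rv = reg_value_grad(dvf, d, &rgrad);
        double loss = (1.0 - sval) + lambda * rv;
        lsum += loss;
        for (size_t j = 0; j < N; ++j) {
          double gw = clampmask[j] ? (-gssim[j] / range) : 0.0;
          gdvf[j]         = gw * gderiv[j]         + lambda * rgrad[j];
          gdvf[j + N]     = gw * gderiv[j + N]     + lambda * rgrad[j + N];
          gdvf[j + 2 * N] = gw * gderiv[j + 2 * N] + lambda * rgrad[j + 2 * N];
        }
        net.backward(theta.data(), gdvf, grad.data());
      }
      // Adam step on the batch-mean gradient
      ++t;
      double bc1 = 1.0 - std::pow(b1, (double)t);
      double bc2 = 1.0 - std::pow(b2, (double)t);
      for (size_t j = 0; j < theta.size(); ++j) {
        double gj = grad[j] / nb;
        m[j] = b1 * m[j] + (1 - b1) * gj;
        v[j] = b2 * v[j] + (1 - b2) * gj * gj;
        theta[j] -= lr * (m[j] / bc1) / (std::sqrt(v[j] / bc2) + eps);
      }
    }
    double mean_loss = lsum / n;
    if (!std::isfinite(mean_loss))
      stop("non-finite training loss at epoch %d (learning rate %g)", ep + 1, lr);
    history[ep] = mean_loss;
    if ((ep & 15) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector th(theta.begin(), theta.end());
  return List::create(_["theta"] = th, _["history"] = history);
}
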