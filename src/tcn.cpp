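// Four-pathway 2-D convolutional text classifier: training engine.
//
// The input is a single-channel tokens x dimensions embedding plane. Each of
// the four pathways applies three stacked same-padded 2-D convolutions with
// its own kernel shape, then dropout, rectification, and 2x2 max pooling.
// Pathway outputs are concatenated, flattened, passed through one rectified
// dense layer and a sigmoid unit. Optimization is mini-batch Adam on binary
// cross-entropy. All randomness (init, shuffling, dropout) comes from an
// internal xorshift generator seeded from the config, so runs are
// bit-reproducible on a given platform regardless of R's RNG state.
//
// Convolutions are evaluated in single precision as one GEMM per layer over
// a column-height patch matrix: for a kh x kw kernel on an H x W plane with
// C channels, Py holds the kh vertical taps of every (channel, padded
// column) position, Py * W yields per-horizontal-tap partial sums, and the
// kw partial planes are reduced by contiguous shifted adds. This keeps the
// patch matrix ~kw times smaller than a full im2col expansion and makes the
// GEMM wide enough (kw*filters columns) to run near BLAS peak; the backward
// pass is the exact transpose of the same three steps.
//
// Weight layout per conv layer: (kh*C) x (kw*F); row index c*kh + dy,
// column index dx*F + f. Total parameters match kh*kw*C*F + F per layer.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;

namespace {

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed)
    : s(seed * 6364136223846793005ULL + 1442695040888963407ULL) {
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  float unif() { return (next() >> 40) * (1.0f / 16777216.0f); }
  uint64_t below(uint64_t n) { return next() % n; }
};

struct Cfg {
  int H, W, F, dense, pool, batch, epochs;
  float dropout, lr;
  uint64_t seed;
  int kh[4], kw[4];
  int H2, W2, Ptot;
};

Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.H = Rcpp::as<int>(cfg["max_tokens"]);
  c.W = Rcpp::as<int>(cfg["dims"]);
  c.F = Rcpp::as<int>(cfg["filters"]);
  c.dense = Rcpp::as<int>(cfg["dense_units"]);
  c.pool = Rcpp::as<int>(cfg["pool"]);
  c.batch = Rcpp::as<int>(cfg["batch_size"]);
  c.epochs = Rcpp::as<int>(cfg["epochs"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.lr = Rcpp::as<double>(cfg["learning_rate"]);
  c.seed = (uint64_t)Rcpp::as<double>(cfg["seed"]);
  Rcpp::IntegerMatrix k = cfg["kernel_matrix"];  // 4 x 2, rows = pathways
  for (int p = 0; p < 4; ++p) { c.kh[p] = k(p, 0); c.kw[p] = k(p, 1); }
  c.H2 = c.H / c.pool;
  c.W2 = c.W / c.pool;
  c.Ptot = 4 * c.F * c.H2 * c.W2;
  return c;
}

struct Param {
  fmat w, g, m, v;
  void init_state() {
    g.zeros(w.n_rows, w.n_cols);
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
};

void glorot(fmat& w, int fan_in, int fan_out, RNG& rng) {
  float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
  for (uword i = 0; i < w.n_elem; ++i) w[i] = (2.0f * rng.unif() - 1.0f) * lim;
}

struct Net {
  Cfg c;
  Param W1[4], b1[4], W2[4], b2[4], W3[4], b3[4];
  Param Wd, bd, Wo, bo;
  std::vector<Param*> params;
  long t_adam = 0;

  void collect() {
    params.clear();
    for (int p = 0; p < 4; ++p) {
      params.push_back(&W1[p]); params.push_back(&b1[p]);
      params.push_back(&W2[p]); params.push_back(&b2[p]);
      params.push_back(&W3[p]); params.push_back(&b3[p]);
    }
    params.push_back(&Wd); params.push_back(&bd);
    params.push_back(&Wo); params.push_back(&bo);
    for (auto* pr : params) pr->init_state();
  }

  void init(const Cfg& cfg) {
    c = cfg;
    RNG rng(c.seed ^ 0xA5A5A5A5ULL);
    for (int p = 0; p < 4; ++p) {
      const int kh = c.kh[p], kw = c.kw[p];
      const int K = kh * kw;  // receptive field per input channel
      W1[p].w.set_size(kh, kw * c.F);
      glorot(W1[p].w, K, c.F, rng);
      W2[p].w.set_size(kh * c.F, kw * c.F);
      glorot(W2[p].w, K * c.F, c.F, rng);
      W3[p].w.set_size(kh * c.F, kw * c.F);
      glorot(W3[p].w, K * c.F, c.F, rng);
      b1[p].w.zeros(1, c.F); b2[p].w.zeros(1, c.F); b3[p].w.zeros(1, c.F);
    }
    Wd.w.set_size(c.Ptot, c.dense); glorot(Wd.w, c.Ptot, c.dense, rng);
    bd.w.zeros(1, c.dense);
    Wo.w.set_size(c.dense, 1); glorot(Wo.w, c.dense, 1, rng);
    bo.w.zeros(1, 1);
    collect();
  }

  void zero_grads() { for (auto* pr : params) pr->g.zeros(); }

  void adam_step(float scale) {
    ++t_adam;
    const float b1c = 1.0f - std::pow(0.9f, (float)t_adam);
    const float b2c = 1.0f - std::pow(0.999f, (float)t_adam);
    for (auto* pr : params) {
      pr->g *= scale;
      pr->m = 0.9f * pr->m + 0.1f * pr->g;
      pr->v = 0.999f * pr->v + 0.001f * square(pr->g);
      pr->w -= c.lr * (pr->m / b1c) / (sqrt(pr->v / b2c) + 1e-8f);
    }
  }
};

// Column-height patch matrix. A is HW x C (plane flat index y + H*x);
// Py is (H*Wp) x (kh*C) with Wp = W + kw - 1 and column q = c*kh + dy:
// Py(y + H*u, q) = A(y + dy - pt, u - pl, channel c), zero outside the
// plane. Same padding: pt = (kh-1)/2 rows on top, pl = (kw-1)/2 columns
// on the left.
void im2col_y(const fmat& A, int H, int W, int C, int kh, int kw, fmat& Py) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  const int Wp = W + kw - 1;
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    for (int dy = 0; dy < kh; ++dy) {
      float* p = Py.colptr((uword)c * kh + dy);
      std::memset(p, 0, (size_t)H * Wp * sizeof(float));
      const int sy = dy - pt;
      const int y0 = std::max(0, -sy), y1 = std::min(H, H - sy);
      const int len = y1 - y0;
      if (len <= 0) continue;
      for (int x = 0; x < W; ++x) {
        std::memcpy(p + (size_t)(x + pl) * H + y0,
                    a + (size_t)x * H + (y0 + sy),
                    len * sizeof(float));
      }
    }
  }
}

// transpose of im2col_y: accumulate patch gradients back onto the plane
void col2im_y(const fmat& dPy, int H, int W, int C, int kh, int kw,
              fmat& dA) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  dA.zeros();
  for (int c = 0; c < C; ++c) {
    float* a = dA.colptr(c);
    for (int dy = 0; dy < kh; ++dy) {
      const float* p = dPy.colptr((uword)c * kh + dy);
      const int sy = dy - pt;
      const int y0 = std::max(0, -sy), y1 = std::min(H, H - sy);
      const int len = y1 - y0;
      if (len <= 0) continue;
      for (int x = 0; x < W; ++x) {
        float* dst = a + (size_t)x * H + (y0 + sy);
        const float* src = p + (size_t)(x + pl) * H + y0;
        for (int i = 0; i < len; ++i) dst[i] += src[i];
      }
    }
  }
}

// reduce per-tap partial sums: Z(y + H*x, f) = b(f) +
//   sum_dx Cp(y + H*(x + dx), dx*F + f); the shift is a flat row offset
// dx*H, so every (dx, f) pair contributes one contiguous vector add.
void reduce_taps(const fmat& Cp, const fmat& b, int H, int W, int kw, int F,
                 fmat& Z) {
  const uword HW = (uword)H * W;
  for (int f = 0; f < F; ++f) {
    float* z = Z.colptr(f);
    const float bf = b(0, f);
    for (uword i = 0; i < HW; ++i) z[i] = bf;
    for (int dx = 0; dx < kw; ++dx) {
      const float* s = Cp.colptr((uword)dx * F + f) + (size_t)dx * H;
      for (uword i = 0; i < HW; ++i) z[i] += s[i];
    }
  }
}

// transpose of reduce_taps: scatter dZ into the per-tap partial planes
void scatter_taps(const fmat& dZ, int H, int W, int kw, int F, fmat& dCp) {
  const uword HW = (uword)H * W;
  const size_t col_len = (size_t)H * (W + kw - 1);
  for (int f = 0; f < F; ++f) {
    const float* z = dZ.colptr(f);
    for (int dx = 0; dx < kw; ++dx) {
      float* d = dCp.colptr((uword)dx * F + f);
      std::memset(d, 0, col_len * sizeof(float));
      std::memcpy(d + (size_t)dx * H, z, HW * sizeof(float));
    }
  }
}

// per-sample activation caches and batch buffers, preallocated once
struct Cache {
  fmat Py1[4], Py2[4], Py3[4];
  fmat Z1[4], Z2[4], Z3[4];
  fmat M[4];      // dropout scale mask
  fmat R[4];      // post-dropout, post-relu
  fmat pooled[4];
  Mat<uword> amax[4];
  fvec v, hpre, h;
  fmat Cp, dCp;   // partial-sum scratch, max size over pathways
  fmat dR, dZ, dPy, dZprev;
  fvec dv, dhp;
  fmat Vbuf, Hbuf;  // dense-layer batch buffers

  void alloc(const Cfg& c) {
    const uword HW = (uword)c.H * c.W;
    uword maxP = 0, maxC = 0;
    for (int p = 0; p < 4; ++p) {
      const uword HWp = (uword)c.H * (c.W + c.kw[p] - 1);
      Py1[p].set_size(HWp, c.kh[p]);
      Py2[p].set_size(HWp, (uword)c.kh[p] * c.F);
      Py3[p].set_size(HWp, (uword)c.kh[p] * c.F);
      maxP = std::max(maxP, HWp * (uword)c.kh[p] * c.F);
      maxC = std::max(maxC, HWp * (uword)c.kw[p] * c.F);
      Z1[p].set_size(HW, c.F);
      Z2[p].set_size(HW, c.F);
      Z3[p].set_size(HW, c.F);
      M[p].set_size(HW, c.F);
      R[p].set_size(HW, c.F);
      pooled[p].set_size((uword)c.H2 * c.W2, c.F);
      amax[p].set_size((uword)c.H2 * c.W2, c.F);
    }
    v.set_size(c.Ptot);
    Cp.set_size(maxC, 1); Cp.reshape(maxC, 1);
    dCp.set_size(maxC, 1);
    dPy.set_size(maxP, 1);
    dR.set_size(HW, c.F);
    dZ.set_size(HW, c.F);
    dZprev.set_size(HW, c.F);
    dv.set_size(c.Ptot);
    Vbuf.set_size(c.Ptot, c.batch);
    Hbuf.set_size(c.dense, c.batch);
  }
};

// one conv layer forward: A (HW x C) -> Z (HW x F), using Py and Cp scratch
void conv_fwd(const fmat& A, const fmat& W, const fmat& b, int H, int Wd,
              int C, int kh, int kw, int F, fmat& Py, fmat& Cp_store,
              fmat& Z) {
  im2col_y(A, H, Wd, C, kh, kw, Py);
  const uword HWp = Py.n_rows;
  fmat Cp(Cp_store.memptr(), HWp, (uword)kw * F, false, true);
  Cp = Py * W;
  reduce_taps(Cp, b, H, Wd, kw, F, Z);
}

// one conv layer backward: consumes dZ, Py (from forward), emits weight
// gradients and (optionally) the input gradient dA
void conv_bwd(const fmat& Py, const fmat& W, fmat& gW, fmat& gb,
              const fmat& dZ, int H, int Wd, int C, int kh, int kw, int F,
              fmat& dCp_store, fmat& dPy_store, fmat* dA) {
  const uword HWp = Py.n_rows;
  fmat dCp(dCp_store.memptr(), HWp, (uword)kw * F, false, true);
  scatter_taps(dZ, H, Wd, kw, F, dCp);
  gW += Py.t() * dCp;
  gb += sum(dZ, 0);
  if (dA) {
    fmat dPy(dPy_store.memptr(), HWp, (uword)kh * C, false, true);
    dPy = dCp * W.t();
    col2im_y(dPy, H, Wd, C, kh, kw, *dA);
  }
}

// forward one sample; X is the H x W plane as an HW x 1 matrix
float forward(Net& net, Cache& cc, const fmat& X, bool train, RNG& rng) {
  const Cfg& c = net.c;
  const float keep = 1.0f - c.dropout;
  uword off = 0;
  for (int p = 0; p < 4; ++p) {
    conv_fwd(X, net.W1[p].w, net.b1[p].w, c.H, c.W, 1, c.kh[p], c.kw[p],
             c.F, cc.Py1[p], cc.Cp, cc.Z1[p]);
    conv_fwd(cc.Z1[p], net.W2[p].w, net.b2[p].w, c.H, c.W, c.F, c.kh[p],
             c.kw[p], c.F, cc.Py2[p], cc.Cp, cc.Z2[p]);
    conv_fwd(cc.Z2[p], net.W3[p].w, net.b3[p].w, c.H, c.W, c.F, c.kh[p],
             c.kw[p], c.F, cc.Py3[p], cc.Cp, cc.Z3[p]);
    // dropout before the rectification, then relu (fused)
    if (train && c.dropout > 0.0f) {
      for (uword i = 0; i < cc.M[p].n_elem; ++i) {
        cc.M[p][i] = (rng.unif() < c.dropout) ? 0.0f : 1.0f / keep;
        const float d = cc.Z3[p][i] * cc.M[p][i];
        cc.R[p][i] = d > 0 ? d : 0.0f;
      }
    } else {
      for (uword i = 0; i < cc.R[p].n_elem; ++i) {
        const float z = cc.Z3[p][i];
        cc.R[p][i] = z > 0 ? z : 0.0f;
      }
    }
    // 2-D max pooling, window = stride = c.pool
    for (int f = 0; f < c.F; ++f) {
      const float* r = cc.R[p].colptr(f);
      float* po = cc.pooled[p].colptr(f);
      uword* am = cc.amax[p].colptr(f);
      for (int x2 = 0; x2 < c.W2; ++x2) {
        for (int y2 = 0; y2 < c.H2; ++y2) {
          float best = -std::numeric_limits<float>::infinity();
          uword arg = 0;
          for (int dx = 0; dx < c.pool; ++dx) {
            for (int dy = 0; dy < c.pool; ++dy) {
              const uword idx = (uword)(x2 * c.pool + dx) * c.H +
                (uword)(y2 * c.pool + dy);
              if (r[idx] > best) { best = r[idx]; arg = idx; }
            }
          }
          po[(uword)x2 * c.H2 + y2] = best;
          am[(uword)x2 * c.H2 + y2] = arg;
        }
      }
    }
    std::memcpy(cc.v.memptr() + off, cc.pooled[p].memptr(),
                cc.pooled[p].n_elem * sizeof(float));
    off += cc.pooled[p].n_elem;
  }
  cc.hpre = net.Wd.w.t() * cc.v + net.bd.w.t();
  cc.h = cc.hpre;
  cc.h.for_each([](float& x) { if (x < 0) x = 0; });
  float logit = dot(net.Wo.w.col(0), cc.h) + net.bo.w(0, 0);
  return 1.0f / (1.0f + std::exp(-logit));
}

// accumulate gradients for one sample; bslot >= 0 defers the dense weight
// gradient to the per-batch GEMM over Vbuf/Hbuf
void backward(Net& net, Cache& cc, float prob, float y, bool train,
              int bslot) {
  const Cfg& c = net.c;
  const float dlogit = prob - y;
  net.Wo.g.col(0) += dlogit * cc.h;
  net.bo.g(0, 0) += dlogit;
  fvec dh = net.Wo.w.col(0) * dlogit;
  cc.dhp = dh;
  for (uword i = 0; i < cc.dhp.n_elem; ++i) {
    if (cc.hpre[i] <= 0) cc.dhp[i] = 0;
  }
  if (bslot >= 0) {
    std::memcpy(cc.Vbuf.colptr(bslot), cc.v.memptr(),
                cc.v.n_elem * sizeof(float));
    std::memcpy(cc.Hbuf.colptr(bslot), cc.dhp.memptr(),
                cc.dhp.n_elem * sizeof(float));
  } else {
    net.Wd.g += cc.v * cc.dhp.t();
  }
  net.bd.g += cc.dhp.t();
  cc.dv = net.Wd.w * cc.dhp;
  uword off = 0;
  for (int p = 0; p < 4; ++p) {
    // unpool into dR
    cc.dR.zeros();
    for (int f = 0; f < c.F; ++f) {
      const uword* am = cc.amax[p].colptr(f);
      float* dr = cc.dR.colptr(f);
      const float* dvp = cc.dv.memptr() + off + (uword)f * c.H2 * c.W2;
      for (uword i = 0; i < (uword)c.H2 * c.W2; ++i) dr[am[i]] += dvp[i];
    }
    off += cc.pooled[p].n_elem;
    // relu (mask = positive post-dropout activation), then dropout scale
    if (train && c.dropout > 0.0f) {
      for (uword i = 0; i < cc.dR.n_elem; ++i) {
        cc.dZ[i] = (cc.R[p][i] > 0) ? cc.dR[i] * cc.M[p][i] : 0.0f;
      }
    } else {
      for (uword i = 0; i < cc.dR.n_elem; ++i) {
        cc.dZ[i] = (cc.R[p][i] > 0) ? cc.dR[i] : 0.0f;
      }
    }
    conv_bwd(cc.Py3[p], net.W3[p].w, net.W3[p].g, net.b3[p].g, cc.dZ,
             c.H, c.W, c.F, c.kh[p], c.kw[p], c.F, cc.dCp, cc.dPy,
             &cc.dZprev);
    conv_bwd(cc.Py2[p], net.W2[p].w, net.W2[p].g, net.b2[p].g, cc.dZprev,
             c.H, c.W, c.F, c.kh[p], c.kw[p], c.F, cc.dCp, cc.dPy, &cc.dZ);
    conv_bwd(cc.Py1[p], net.W1[p].w, net.W1[p].g, net.b1[p].g, cc.dZ,
             c.H, c.W, 1, c.kh[p], c.kw[p], c.F, cc.dCp, cc.dPy, nullptr);
  }
}

float bce(float p, float y) {
  const float eps = 1e-7f;
  p = std::min(std::max(p, eps), 1.0f - eps);
  return -(y * std::log(p) + (1.0f - y) * std::log(1.0f - p));
}

List weights_to_r(const Net& net) {
  List paths(4);
  for (int p = 0; p < 4; ++p) {
    paths[p] = List::create(
      Named("W1") = Rcpp::wrap(conv_to<mat>::from(net.W1[p].w)),
      Named("b1") = Rcpp::wrap(conv_to<mat>::from(net.b1[p].w)),
      Named("W2") = Rcpp::wrap(conv_to<mat>::from(net.W2[p].w)),
      Named("b2") = Rcpp::wrap(conv_to<mat>::from(net.b2[p].w)),
      Named("W3") = Rcpp::wrap(conv_to<mat>::from(net.W3[p].w)),
      Named("b3") = Rcpp::wrap(conv_to<mat>::from(net.b3[p].w)));
  }
  return List::create(
    Named("pathways") = paths,
    Named("Wd") = Rcpp::wrap(conv_to<mat>::from(net.Wd.w)),
    Named("bd") = Rcpp::wrap(conv_to<mat>::from(net.bd.w)),
    Named("Wo") = Rcpp::wrap(conv_to<mat>::from(net.Wo.w)),
    Named("bo") = Rcpp::wrap(conv_to<mat>::from(net.bo.w)));
}

void weights_from_r(Net& net, const List& w) {
  List paths = w["pathways"];
  for (int p = 0; p < 4; ++p) {
    List pw = paths[p];
    net.W1[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["W1"]));
    net.b1[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["b1"]));
    net.W2[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["W2"]));
    net.b2[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["b2"]));
    net.W3[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["W3"]));
    net.b3[p].w = conv_to<fmat>::from(Rcpp::as<mat>(pw["b3"]));
  }
  net.Wd.w = conv_to<fmat>::from(Rcpp::as<mat>(w["Wd"]));
  net.bd.w = conv_to<fmat>::from(Rcpp::as<mat>(w["bd"]));
  net.Wo.w = conv_to<fmat>::from(Rcpp::as<mat>(w["Wo"]));
  net.bo.w = conv_to<fmat>::from(Rcpp::as<mat>(w["bo"]));
  net.collect();
}

// pull sample k of an H x W x n array into an HW x 1 float matrix
void slice_to(const cube& x, uword k, fmat& X) {
  const mat& sl = x.slice(k);
  for (uword i = 0; i < sl.n_elem; ++i) X[i] = (float)sl[i];
}

} // namespace

// [[Rcpp::export]]
List tcn_init_cpp(List cfg) {
  Net net;
  net.init(parse_cfg(cfg));
  return weights_to_r(net);
}

// [[Rcpp::export]]
List tcn_train_cpp(List cfg, List weights, arma::cube x, arma::vec y,
                   arma::cube xv, arma::vec yv, bool verbose) {
  Net net;
  net.c = parse_cfg(cfg);
  weights_from_r(net, weights);
  Cache cc;
  cc.alloc(net.c);
  RNG rng(net.c.seed);
  const uword n = x.n_slices, nv = xv.n_slices;
  fmat X((uword)net.c.H * net.c.W, 1);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  mat history(net.c.epochs, 4);
  for (int ep = 0; ep < net.c.epochs; ++ep) {
    for (uword i = n - 1; i > 0; --i) {  // Fisher-Yates shuffle
      uword j = rng.below(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0; uword ep_correct = 0;
    for (uword start = 0; start < n; start += net.c.batch) {
      const uword stop = std::min(n, start + (uword)net.c.batch);
      const uword bn = stop - start;
      net.zero_grads();
      for (uword s = start; s < stop; ++s) {
        const uword k = idx[s];
        slice_to(x, k, X);
        float p = forward(net, cc, X, true, rng);
        backward(net, cc, p, (float)y[k], true, (int)(s - start));
        ep_loss += bce(p, (float)y[k]);
        ep_correct += ((p > 0.5f) == (y[k] > 0.5)) ? 1 : 0;
      }
      {  // deferred dense-layer weight gradient: one GEMM per batch
        fmat V(cc.Vbuf.memptr(), cc.Vbuf.n_rows, bn, false, true);
        fmat Hb(cc.Hbuf.memptr(), cc.Hbuf.n_rows, bn, false, true);
        net.Wd.g = V * Hb.t();
      }
      net.adam_step(1.0f / (float)bn);
      Rcpp::checkUserInterrupt();
    }
    double vl = NA_REAL, va = NA_REAL;
    if (nv > 0) {
      double vloss = 0.0; uword vcorrect = 0;
      for (uword k = 0; k < nv; ++k) {
        slice_to(xv, k, X);
        float p = forward(net, cc, X, false, rng);
        vloss += bce(p, (float)yv[k]);
        vcorrect += ((p > 0.5f) == (yv[k] > 0.5)) ? 1 : 0;
      }
      vl = vloss / nv; va = (double)vcorrect / nv;
    }
    history(ep, 0) = ep_loss / n;
    history(ep, 1) = (double)ep_correct / n;
    history(ep, 2) = vl;
    history(ep, 3) = va;
    if (verbose) {
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << net.c.epochs
                  << " loss " << history(ep, 0) << " acc " << history(ep, 1);
      if (nv > 0) Rcpp::Rcout << " val_loss " << vl << " val_acc " << va;
      Rcpp::Rcout << std::endl;
    }
  }
  return List::create(Named("weights") = weights_to_r(net),
                      Named("history") = Rcpp::wrap(history));
}

// [[Rcpp::export]]
NumericVector tcn_predict_cpp(List cfg, List weights, arma::cube x) {
  Net net;
  net.c = parse_cfg(cfg);
  weights_from_r(net, weights);
  Cache cc;
  cc.alloc(net.c);
  RNG rng(net.c.seed);
  const uword n = x.n_slices;
  fmat X((uword)net.c.H * net.c.W, 1);
  NumericVector out(n);
  for (uword k = 0; k < n; ++k) {
    slice_to(x, k, X);
    out[k] = forward(net, cc, X, false, rng);
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// mean loss and mean gradients over a sample set with dropout disabled;
// used by finite-difference gradient checks
// [[Rcpp::export]]
List tcn_loss_grad_cpp(List cfg, List weights, arma::cube x, arma::vec y) {
  Net net;
  net.c = parse_cfg(cfg);
  weights_from_r(net, weights);
  Cache cc;
  cc.alloc(net.c);
  RNG rng(net.c.seed);
  const uword n = x.n_slices;
  fmat X((uword)net.c.H * net.c.W, 1);
  net.zero_grads();
  double loss = 0.0;
  for (uword k = 0; k < n; ++k) {
    slice_to(x, k, X);
    float p = forward(net, cc, X, false, rng);
    backward(net, cc, p, (float)y[k], false, -1);
    loss += bce(p, (float)y[k]);
  }
  List gp(4);
  auto gw = [&](const Param& pr) {
    return Rcpp::wrap(conv_to<mat>::from(pr.g / (float)n));
  };
  for (int p = 0; p < 4; ++p) {
    gp[p] = List::create(
      Named("W1") = gw(net.W1[p]), Named("b1") = gw(net.b1[p]),
      Named("W2") = gw(net.W2[p]), Named("b2") = gw(net.b2[p]),
      Named("W3") = gw(net.W3[p]), Named("b3") = gw(net.b3[p]));
  }
  return List::create(
    Named("loss") = loss / n,
    Named("grads") = List::create(
      Named("pathways") = gp, Named("Wd") = gw(net.Wd),
      Named("bd") = gw(net.bd), Named("Wo") = gw(net.Wo),
      Named("bo") = gw(net.bo)));
}
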