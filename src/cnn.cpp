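// Small fully-convolutional classifier: float32 im2col + BLAS sgemm engine
// with batch normalization, ReLU, 2x2 max pooling, softmax cross-entropy and
// SGD-with-momentum backprop.  Single-threaded and deterministic for a fixed
// parameter state, data and visiting order.
//
// Activation layout: a layer's activation is an arma::fmat of shape
// (channels x H*W*B) where the column index is b*H*W + c*H + r (column-major
// spatial flattening, matching R arrays).  Convolution weights are stored as
// (C_out x k*k*C_in) matrices with column index ci + C_in*(dr + k*dc).

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const float BN_EPS = 1e-5f;

// keep the large per-batch work buffers on the heap across batches: without
// this glibc mmaps and trims them on every allocate/free cycle and the page
// faults dominate the runtime
static const int mallopt_once = [] {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
  return 0;
}();

struct Stage {
  int k, cin, cout;
  bool bn, relu, pool;
};

struct Shape { int H, W; };

// im2col: output column j = (b, oc, or) holds the receptive-field pixels of
// output location (or, oc); rows are ordered channel-fastest, then dr, then
// dc.  For fixed dc the k pixels (or+dr, oc+dc), dr = 0..k-1 are contiguous
// in the activation memory (channel-major pixels), so each output column is
// assembled from k contiguous chunks of C*k floats.
static fmat im2col(const fmat &A, int H, int W, int B, int k) {
  const int C = A.n_rows, oH = H - k + 1, oW = W - k + 1;
  const uword K = (uword)C * k * k;
  const uword chunk = (uword)C * k;
  fmat col(K, (uword)oH * oW * B);
  const float *Amem = A.memptr();
  float *colmem = col.memptr();
  uword j = 0;
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * H * W;
    for (int oc = 0; oc < oW; ++oc) {
      for (int r = 0; r < oH; ++r, ++j) {
        float *dst = colmem + j * K;
        const float *src0 = Amem + (base + (uword)oc * H + r) * C;
        switch (chunk) {  // fixed-size copies inline to SIMD moves
        case 9:
          for (int dc = 0; dc < k; ++dc)
            std::memcpy(dst + 9 * dc, src0 + (uword)dc * H * C, 9 * sizeof(float));
          break;
        case 48:
          for (int dc = 0; dc < k; ++dc)
            std::memcpy(dst + 48 * dc, src0 + (uword)dc * H * C, 48 * sizeof(float));
          break;
        case 72:
          for (int dc = 0; dc < k; ++dc)
            std::memcpy(dst + 72 * dc, src0 + (uword)dc * H * C, 72 * sizeof(float));
          break;
        default:
          for (int dc = 0; dc < k; ++dc)
            std::memcpy(dst + chunk * dc, src0 + (uword)dc * H * C,
                        chunk * sizeof(float));
        }
      }
    }
  }
  return col;
}

static void col2im_add(fmat &dA, const fmat &dcol, int H, int W, int B, int k) {
  const int C = dA.n_rows, oH = H - k + 1, oW = W - k + 1;
  const uword K = dcol.n_rows;
  const int chunk = C * k;
  float *Amem = dA.memptr();
  const float *colmem = dcol.memptr();
  uword j = 0;
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * H * W;
    for (int oc = 0; oc < oW; ++oc) {
      for (int r = 0; r < oH; ++r, ++j) {
        const float *src = colmem + j * K;
        float *dst0 = Amem + (base + (uword)oc * H + r) * C;
        for (int dc = 0; dc < k; ++dc) {
          float *d = dst0 + (uword)dc * H * C;
          const float *s = src + (uword)chunk * dc;
          for (int q = 0; q < chunk; ++q) d[q] += s[q];
        }
      }
    }
  }
}

// 2x2 max pool (stride 2, floor); pick records the winning input column per
// (row, output column) element, first-equal tie rule.
static fmat maxpool(const fmat &A, int H, int W, int B, Mat<uword> &pick) {
  const int C = A.n_rows, oH = H / 2, oW = W / 2;
  fmat out(C, (uword)oH * oW * B);
  pick.set_size(C, out.n_cols);
  uword j = 0;
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * H * W;
    for (int oc = 0; oc < oW; ++oc)
      for (int r = 0; r < oH; ++r, ++j) {
        const uword c00 = base + (uword)(2 * oc) * H + 2 * r;
        const uword cands[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        const float *src[4] = {A.colptr(cands[0]), A.colptr(cands[1]),
                               A.colptr(cands[2]), A.colptr(cands[3])};
        float *op = out.colptr(j);
        uword *pp = pick.colptr(j);
        for (int ch = 0; ch < C; ++ch) {
          float best = src[0][ch];
          int bq = 0;
          for (int q = 1; q < 4; ++q)
            if (src[q][ch] > best) { best = src[q][ch]; bq = q; }
          op[ch] = best;
          pp[ch] = cands[bq];
        }
      }
  }
  return out;
}


// ---- batch-norm passes templated on the channel count so the inner loops
// vectorize (CT = 0 instantiates a runtime-channel fallback) ----

template <int CT>
static void bn_fwd_pass(int Crt, float *zp, float *xp, const float *mu,
                        const float *inv, const float *g, const float *be,
                        uword M) {
  const int C = CT > 0 ? CT : Crt;
  for (uword j = 0; j < M; ++j, zp += C, xp += C)
    for (int c2 = 0; c2 < C; ++c2) {
      const float x = (zp[c2] - mu[c2]) * inv[c2];
      xp[c2] = x;
      zp[c2] = g[c2] * x + be[c2];
    }
}

template <int CT>
static void bn_moment_pass(int Crt, const float *zp, double *sum,
                           double *sumsq, uword M) {
  const int C = CT > 0 ? CT : Crt;
  float s1[64], s2[64];
  for (int c2 = 0; c2 < C; ++c2) s1[c2] = s2[c2] = 0.0f;
  // accumulate in float over 64k-column blocks, fold into double between
  // blocks (bounds the float rounding while keeping the loop vectorizable)
  uword j = 0;
  while (j < M) {
    const uword stop = std::min(M, j + (uword)65536);
    for (; j < stop; ++j, zp += C)
      for (int c2 = 0; c2 < C; ++c2) {
        s1[c2] += zp[c2];
        s2[c2] += zp[c2] * zp[c2];
      }
    for (int c2 = 0; c2 < C; ++c2) {
      sum[c2] += s1[c2]; sumsq[c2] += s2[c2];
      s1[c2] = s2[c2] = 0.0f;
    }
  }
}

template <int CT>
static void bn_bwd_pass1(int Crt, float *dp, const float *xp, const float *g,
                         const float *be, float *ag, float *ab, uword M,
                         bool masked) {
  const int C = CT > 0 ? CT : Crt;
  float a1[64], a2[64];
  for (int c2 = 0; c2 < C; ++c2) a1[c2] = a2[c2] = 0.0f;
  if (masked) {
    for (uword j = 0; j < M; ++j, dp += C, xp += C)
      for (int c2 = 0; c2 < C; ++c2) {
        const float on = (g[c2] * xp[c2] + be[c2] > 0.0f) ? 1.0f : 0.0f;
        const float d = dp[c2] * on;
        dp[c2] = d;
        a1[c2] += d * xp[c2];
        a2[c2] += d;
      }
  } else {
    for (uword j = 0; j < M; ++j, dp += C, xp += C)
      for (int c2 = 0; c2 < C; ++c2) {
        a1[c2] += dp[c2] * xp[c2];
        a2[c2] += dp[c2];
      }
  }
  for (int c2 = 0; c2 < C; ++c2) { ag[c2] = a1[c2]; ab[c2] = a2[c2]; }
}

template <int CT>
static void bn_bwd_pass2(int Crt, float *dp, const float *xp, const float *sc,
                         const float *dg, const float *db, float Nf, uword M) {
  const int C = CT > 0 ? CT : Crt;
  for (uword j = 0; j < M; ++j, dp += C, xp += C)
    for (int c2 = 0; c2 < C; ++c2)
      dp[c2] = sc[c2] * (Nf * dp[c2] - db[c2] - xp[c2] * dg[c2]);
}

#define BN_DISPATCH(fn, C, ...)              \
  switch (C) {                               \
    case 16: fn<16>(C, __VA_ARGS__); break;  \
    case 24: fn<24>(C, __VA_ARGS__); break;  \
    case 30: fn<30>(C, __VA_ARGS__); break;  \
    case 32: fn<32>(C, __VA_ARGS__); break;  \
    default: fn<0>(C, __VA_ARGS__); break;   \
  }

static std::vector<Stage> parse_stages(const List &arch) {
  IntegerMatrix sm = arch["stage_matrix"]; // rows: k, cout, bn, relu, pool
  int cin = as<int>(arch["input_channels"]);
  std::vector<Stage> st(sm.nrow());
  for (int i = 0; i < sm.nrow(); ++i) {
    st[i].k = sm(i, 0);
    st[i].cout = sm(i, 1);
    st[i].bn = sm(i, 2) != 0;
    st[i].relu = sm(i, 3) != 0;
    st[i].pool = sm(i, 4) != 0;
    st[i].cin = cin;
    cin = st[i].cout;
  }
  return st;
}

static fmat get_f(const List &L, const std::string &nm) {
  return conv_to<fmat>::from(as<mat>(L[nm]));
}
static fvec get_fv(const List &L, const std::string &nm) {
  return conv_to<fvec>::from(as<vec>(L[nm]));
}

// load raw (p, p, 3, N) samples `sel` (0-based) into a (3 x p*p*B) batch
static fmat load_batch(const RawVector &x, int p, const std::vector<int> &sel) {
  const size_t pp = (size_t)p * p;
  const int B = sel.size();
  fmat A(3, pp * B);
  const Rbyte *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)sel[b] * 3 * pp;
    for (int ch = 0; ch < 3; ++ch) {
      const Rbyte *src = xp + off + (size_t)ch * pp;
      float *dst = A.memptr() + (uword)b * pp * 3 + ch;
      for (size_t s = 0; s < pp; ++s) dst[s * 3] = src[s] * (1.0f / 255.0f);
    }
  }
  return A;
}

struct Cache {
  std::vector<Shape> conv_in_shape;  // shape of the activation entering each conv
  std::vector<fmat> col;       // im2col matrix per stage
  std::vector<fmat> xhat;      // BN normalized activations
  std::vector<fvec> invstd;    // BN inverse std
  std::vector<fmat> act;       // post-ReLU (pre-pool) activation
  std::vector<Shape> act_shape;
  std::vector<Mat<uword>> pick;
  fmat head_in, head_col;      // activation and col entering the head
  Shape head_in_shape;
};

// full forward pass; when `training` is true batch statistics are used and
// intermediate activations are cached (running stats updated in place)
static fmat forward_pass(const std::vector<Stage> &st, std::vector<fmat> &W,
                         std::vector<fvec> &gamma, std::vector<fvec> &beta,
                         std::vector<fvec> &bias, std::vector<fvec> &rmean,
                         std::vector<fvec> &rvar, const fmat &Wh,
                         const fvec &bh, int head_k, fmat A, int H, int Wd,
                         int B, bool training, float bn_momentum, Cache *cache,
                         int &oH_out, int &oW_out) {
  for (size_t i = 0; i < st.size(); ++i) {
    const Stage &s = st[i];
    if (training) cache->conv_in_shape.push_back({H, Wd});
    fmat col = im2col(A, H, Wd, B, s.k);
    H -= s.k - 1; Wd -= s.k - 1;
    fmat Z = W[i] * col;
    if (training) cache->col.push_back(std::move(col));
    if (s.bn) {
      if (training) {
        const int C = Z.n_rows;
        if (C > 64) stop("batch-norm stages support at most 64 channels");
        const uword M = Z.n_cols;
        fvec mu(C), var(C), inv(C);
        {
          std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
          BN_DISPATCH(bn_moment_pass, C, Z.memptr(), sum.data(), sumsq.data(), M);
          for (int c2 = 0; c2 < C; ++c2) {
            mu[c2] = (float)(sum[c2] / M);
            double v = sumsq[c2] / M - (double)mu[c2] * mu[c2];
            var[c2] = v > 0 ? (float)v : 0.0f;
            inv[c2] = 1.0f / std::sqrt(var[c2] + BN_EPS);
          }
        }
        rmean[i] = (1.0f - bn_momentum) * rmean[i] + bn_momentum * mu;
        rvar[i] = (1.0f - bn_momentum) * rvar[i] + bn_momentum * var;
        fmat xh(C, M);
        BN_DISPATCH(bn_fwd_pass, C, Z.memptr(), xh.memptr(), mu.memptr(),
                    inv.memptr(), gamma[i].memptr(), beta[i].memptr(), M);
        cache->xhat.push_back(std::move(xh));
        cache->invstd.push_back(std::move(inv));
      } else {
        fvec scale = gamma[i] / sqrt(rvar[i] + BN_EPS);
        Z.each_col() -= rmean[i];
        Z.each_col() %= scale;
        Z.each_col() += beta[i];
      }
    } else {
      Z.each_col() += bias[i];
      if (training) { cache->xhat.emplace_back(); cache->invstd.emplace_back(); }
    }
    if (s.relu) Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (training) {
      // the ReLU mask is recoverable from the cached BN xhat; keep a copy of
      // the activation only for the (unusual) relu-without-BN stage
      if (s.relu && !s.bn) cache->act.push_back(Z); else cache->act.emplace_back();
      cache->act_shape.push_back({H, Wd});
    }
    if (s.pool) {
      Mat<uword> pick;
      Z = maxpool(Z, H, Wd, B, pick);
      H /= 2; Wd /= 2;
      if (training) cache->pick.push_back(std::move(pick));
    } else if (training) {
      cache->pick.emplace_back();
    }
    A = std::move(Z);
  }
  if (training) {
    cache->head_in = A;
    cache->head_in_shape = {H, Wd};
  }
  fmat col = im2col(A, H, Wd, B, head_k);
  fmat Z = Wh * col;
  Z.each_col() += bh;
  if (training) cache->head_col = std::move(col);
  oH_out = H - head_k + 1;
  oW_out = Wd - head_k + 1;
  return Z;  // logits (n_classes x oH*oW*B)
}

static fmat softmax_cols(const fmat &Z) {
  fmat P = Z.each_row() - max(Z, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// [[Rcpp::export]]
List cnn_forward_cpp(List arch, List params, RawVector x, IntegerVector dims) {
  std::vector<Stage> st = parse_stages(arch);
  const int head_k = as<int>(arch["head_kernel"]);
  const int H = dims[0], Wd = dims[1], B = dims[3];
  std::vector<fmat> W(st.size());
  std::vector<fvec> gamma(st.size()), beta(st.size()), bias(st.size()),
      rmean(st.size()), rvar(st.size());
  for (size_t i = 0; i < st.size(); ++i) {
    const std::string s = std::to_string(i + 1);
    W[i] = get_f(params, "W" + s);
    if (st[i].bn) {
      gamma[i] = get_fv(params, "gamma" + s);
      beta[i] = get_fv(params, "beta" + s);
      rmean[i] = get_fv(params, "rmean" + s);
      rvar[i] = get_fv(params, "rvar" + s);
    } else {
      bias[i] = get_fv(params, "b" + s);
    }
  }
  fmat Wh = get_f(params, "Wh");
  fvec bh = get_fv(params, "bh");
  std::vector<int> sel(B);
  for (int b = 0; b < B; ++b) sel[b] = b;
  // load all samples (inference batches are kept modest by the R caller)
  const size_t pp = (size_t)H * Wd;
  fmat A(3, pp * B);
  const Rbyte *xp = x.begin();
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * 3 * pp;
    for (int ch = 0; ch < 3; ++ch) {
      const Rbyte *src = xp + off + (size_t)ch * pp;
      for (size_t s2 = 0; s2 < pp; ++s2)
        A(ch, (uword)b * pp + s2) = src[s2] / 255.0f;
    }
  }
  int oH, oW;
  fmat Z = forward_pass(st, W, gamma, beta, bias, rmean, rvar, Wh, bh, head_k,
                        std::move(A), H, Wd, B, false, 0.0f, nullptr, oH, oW);
  fmat P = softmax_cols(Z);
  return List::create(_["probs"] = conv_to<mat>::from(P), _["oh"] = oH,
                      _["ow"] = oW);
}

// [[Rcpp::export]]
List cnn_train_epoch_cpp(List arch, List params, List velocity, RawVector x,
                         IntegerVector dims, IntegerVector y,
                         IntegerVector order, double lr, double momentum,
                         double weight_decay, int batch_size,
                         double bn_momentum) {
  std::vector<Stage> st = parse_stages(arch);
  const int head_k = as<int>(arch["head_kernel"]);
  const int n_classes = as<int>(arch["n_classes"]);
  const int p = dims[0];
  const int ns = st.size();
  std::vector<fmat> W(ns), vW(ns);
  std::vector<fvec> gamma(ns), beta(ns), bias(ns), rmean(ns), rvar(ns),
      vgamma(ns), vbeta(ns), vbias(ns);
  for (int i = 0; i < ns; ++i) {
    const std::string s = std::to_string(i + 1);
    W[i] = get_f(params, "W" + s);
    vW[i] = get_f(velocity, "W" + s);
    if (st[i].bn) {
      gamma[i] = get_fv(params, "gamma" + s);
      beta[i] = get_fv(params, "beta" + s);
      rmean[i] = get_fv(params, "rmean" + s);
      rvar[i] = get_fv(params, "rvar" + s);
      vgamma[i] = get_fv(velocity, "gamma" + s);
      vbeta[i] = get_fv(velocity, "beta" + s);
    } else {
      bias[i] = get_fv(params, "b" + s);
      vbias[i] = get_fv(velocity, "b" + s);
    }
  }
  fmat Wh = get_f(params, "Wh"), vWh = get_f(velocity, "Wh");
  fvec bh = get_fv(params, "bh"), vbh = get_fv(velocity, "bh");

  const float flr = (float)lr, fmom = (float)momentum, fwd = (float)weight_decay;
  const int N = order.size();
  double loss_sum = 0.0;
  long correct = 0, seen = 0;

  for (int start = 0; start < N; start += batch_size) {
    const int Bb = std::min(batch_size, N - start);
    if (Bb < 2 && N >= 2) break;  // drop degenerate trailing mini-batch
    std::vector<int> sel(Bb);
    for (int b = 0; b < Bb; ++b) sel[b] = order[start + b];
    fmat A = load_batch(x, p, sel);
    Cache cache;
    int oH, oW;
    fmat Z = forward_pass(st, W, gamma, beta, bias, rmean, rvar, Wh, bh,
                          head_k, std::move(A), p, p, Bb, true,
                          (float)bn_momentum, &cache, oH, oW);
    const int M = Z.n_cols;  // oH*oW*Bb; patches give oH = oW = 1
    const int per = M / Bb;
    fmat P = softmax_cols(Z);
    // loss/accuracy + gradient at the logits
    fmat dZ = P;
    for (int b = 0; b < Bb; ++b) {
      const int cls = y[sel[b]];
      for (int q = 0; q < per; ++q) {
        const int j = b * per + q;
        const float *pc = P.colptr(j);
        loss_sum += -std::log(std::max(pc[cls], 1e-12f));
        dZ.colptr(j)[cls] -= 1.0f;
        int am = 0;
        for (int c2 = 1; c2 < n_classes; ++c2)
          if (pc[c2] > pc[am]) am = c2;
        if (am == cls) ++correct;
        ++seen;
      }
    }
    dZ /= (float)M;
    // head backward
    fmat dWh = dZ * cache.head_col.t();
    fvec dbh = sum(dZ, 1);
    fmat dcol = Wh.t() * dZ;
    Shape hs = cache.head_in_shape;
    fmat dA(cache.head_in.n_rows, cache.head_in.n_cols, fill::zeros);
    col2im_add(dA, dcol, hs.H, hs.W, Bb, head_k);
    // SGD on head
    vWh = fmom * vWh - flr * (dWh + fwd * Wh); Wh += vWh;
    vbh = fmom * vbh - flr * dbh; bh += vbh;
    // stages backward
    for (int i = ns - 1; i >= 0; --i) {
      const Stage &s = st[i];
      fmat dZi;
      if (s.pool) {
        const Shape as = cache.act_shape[i];
        dZi.zeros(s.cout, (uword)as.H * as.W * Bb);
        const Mat<uword> &pick = cache.pick[i];
        const uword nr = dA.n_rows;
        for (uword j = 0; j < dA.n_cols; ++j) {
          const float *dap = dA.colptr(j);
          const uword *pp = pick.colptr(j);
          for (uword r = 0; r < nr; ++r)
            dZi.colptr(pp[r])[r] += dap[r];
        }
        (void)as;  // shape consumed above
      } else {
        dZi = std::move(dA);
      }
      if (s.relu && !s.bn) {
        const fmat &act = cache.act[i];
        const float *ap = act.memptr();
        float *dp = dZi.memptr();
        for (uword t = 0; t < dZi.n_elem; ++t)
          if (ap[t] <= 0.0f) dp[t] = 0.0f;
      }
      if (s.bn) {
        const fmat &xh = cache.xhat[i];
        const fvec &inv = cache.invstd[i];
        const int C = dZi.n_rows;
        const uword M = dZi.n_cols;
        const float Nf = (float)M;
        fvec dgamma(C), dbeta(C);
        BN_DISPATCH(bn_bwd_pass1, C, dZi.memptr(), xh.memptr(),
                    gamma[i].memptr(), beta[i].memptr(), dgamma.memptr(),
                    dbeta.memptr(), M, s.relu);
        {
          fvec sc = (gamma[i] % inv) / Nf;
          BN_DISPATCH(bn_bwd_pass2, C, dZi.memptr(), xh.memptr(), sc.memptr(),
                      dgamma.memptr(), dbeta.memptr(), Nf, M);
        }
        vgamma[i] = fmom * vgamma[i] - flr * dgamma; gamma[i] += vgamma[i];
        vbeta[i] = fmom * vbeta[i] - flr * dbeta; beta[i] += vbeta[i];
      } else {
        fvec dbi = sum(dZi, 1);
        vbias[i] = fmom * vbias[i] - flr * dbi; bias[i] += vbias[i];
      }
      fmat dWi = dZi * cache.col[i].t();
      if (i > 0) {  // no need to propagate into the input raster
        const Shape is = cache.conv_in_shape[i];
        dcol = W[i].t() * dZi;
        dA.zeros(s.cin, (uword)is.H * is.W * Bb);
        col2im_add(dA, dcol, is.H, is.W, Bb, s.k);
      }
      vW[i] = fmom * vW[i] - flr * (dWi + fwd * W[i]); W[i] += vW[i];
    }
  }

  // write back (double precision R storage)
  List pout = clone(params), vout = clone(velocity);
  for (int i = 0; i < ns; ++i) {
    const std::string s = std::to_string(i + 1);
    pout["W" + s] = conv_to<mat>::from(W[i]);
    vout["W" + s] = conv_to<mat>::from(vW[i]);
    if (st[i].bn) {
      pout["gamma" + s] = conv_to<vec>::from(gamma[i]);
      pout["beta" + s] = conv_to<vec>::from(beta[i]);
      pout["rmean" + s] = conv_to<vec>::from(rmean[i]);
      pout["rvar" + s] = conv_to<vec>::from(rvar[i]);
      vout["gamma" + s] = conv_to<vec>::from(vgamma[i]);
      vout["beta" + s] = conv_to<vec>::from(vbeta[i]);
    } else {
      pout["b" + s] = conv_to<vec>::from(bias[i]);
      vout["b" + s] = conv_to<vec>::from(vbias[i]);
    }
  }
  pout["Wh"] = conv_to<mat>::from(Wh);
  pout["bh"] = conv_to<vec>::from(bh);
  vout["Wh"] = conv_to<mat>::from(vWh);
  vout["bh"] = conv_to<vec>::from(vbh);
  return List::create(_["params"] = pout, _["velocity"] = vout,
                      _["loss"] = loss_sum / std::max(1L, seen),
                      _["acc"] = (double)correct / std::max(1L, seen),
                      _["n_classes"] = n_classes);
}
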