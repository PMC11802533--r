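// Conditional U-Net noise predictor with hand-written backpropagation.
//
// No deep-learning framework is available to R here, so the denoiser is
// implemented directly: single-precision tensors, im2col + GEMM
// convolutions, group normalization, SiLU activations, residual blocks
// with additive noise-level embeddings, bottleneck self-attention, and an
// AdamW optimizer with global-norm gradient clipping.
//
// Feature-map layout: arma::fmat of shape (C, H*W*B); the column index of
// pixel (i, j) of sample b is b*H*W + j*H + i (column-major spatial order,
// matching R arrays (H, W, B)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <sstream>
#include <vector>
#include <memory>

using arma::fmat;
using arma::fvec;

struct Param {
  fmat W, g, m, v, ema;
  bool has_moments = false, has_ema = false;
  void init(int r, int c) { W.set_size(r, c); g.zeros(r, c); }
  void ensure_moments() {
    if (!has_moments) { m.zeros(W.n_rows, W.n_cols); v.zeros(W.n_rows, W.n_cols); has_moments = true; }
  }
};

// ---------------------------------------------------------------- im2col
static void im2col3(const fmat& x, fmat& col, int C, int H, int W, int B) {
  const int HW = H * W;
  col.set_size(9 * C, (size_t)HW * B);   // zero only the border entries below
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;   // row / col offsets
      const int j0 = std::max(0, -dx), j1 = W - 1 - std::max(0, dx);
      const int i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
      for (int j = 0; j < W; ++j) {
        const size_t base = (size_t)b * HW + (size_t)j * H;
        if (j < j0 || j > j1) {
          col.submat(o * C, base, o * C + C - 1, base + H - 1).zeros();
          continue;
        }
        if (i0 > 0)
          col.submat(o * C, base, o * C + C - 1, base + i0 - 1).zeros();
        if (i1 < H - 1)
          col.submat(o * C, base + i1 + 1, o * C + C - 1, base + H - 1).zeros();
        const size_t src0 = (size_t)b * HW + (size_t)(j + dx) * H + (i0 + dy);
        col.submat(o * C, base + i0, o * C + C - 1, base + i1) =
          x.cols(src0, src0 + (i1 - i0));
      }
    }
  }
}

static void col2im3(const fmat& dcol, fmat& dx, int C, int H, int W, int B) {
  const int HW = H * W;
  dx.zeros(C, (size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx_ = o / 3 - 1;
      const int j0 = std::max(0, -dx_), j1 = W - 1 - std::max(0, dx_);
      const int i0 = std::max(0, -dy), i1 = H - 1 - std::max(0, dy);
      if (j0 > j1 || i0 > i1) continue;
      for (int j = j0; j <= j1; ++j) {
        const size_t dst0 = (size_t)b * HW + (size_t)j * H + i0;
        const size_t src0 = (size_t)b * HW + (size_t)(j + dx_) * H + (i0 + dy);
        const int len = i1 - i0 + 1;
        dx.cols(src0, src0 + len - 1) +=
          dcol.submat(o * C, dst0, o * C + C - 1, dst0 + len - 1);
      }
    }
  }
}

// ------------------------------------------------------------------ layers
struct Conv {
  int Cin = 0, Cout = 0, k = 3;
  Param W, b;
  fmat col;      // cached im2col (k = 3) or input (k = 1)
  int H_ = 0, Wd_ = 0, B_ = 0;
  bool cached = false;

  void init(int cin, int cout, int kk, std::mt19937& rng, bool zero_init = false) {
    Cin = cin; Cout = cout; k = kk;
    W.init(cout, kk * kk * cin);
    b.init(cout, 1); b.W.zeros();
    if (zero_init) { W.W.zeros(); return; }
    const float sd = std::sqrt(2.0f / (kk * kk * cin));
    std::normal_distribution<float> nd(0.0f, sd);
    for (auto& w : W.W) w = nd(rng);
  }
  fmat forward(const fmat& x, int H, int Wd, int B, bool train) {
    H_ = H; Wd_ = Wd; B_ = B; cached = train;
    fmat y;
    if (k == 3) {
      fmat c; im2col3(x, c, Cin, H, Wd, B);
      y = W.W * c;
      if (train) col = std::move(c); else col.reset();
    } else {
      y = W.W * x;
      if (train) col = x; else col.reset();
    }
    y.each_col() += b.W.col(0);
    return y;
  }
  fmat backward(const fmat& dy) {
    W.g += dy * col.t();
    b.g += arma::sum(dy, 1);
    fmat dcol = W.W.t() * dy;
    if (k == 3) { fmat dx; col2im3(dcol, dx, Cin, H_, Wd_, B_); return dx; }
    return dcol;
  }
};

struct Linear {
  Param W, b;
  fmat x_;
  void init(int in, int out, std::mt19937& rng) {
    W.init(out, in); b.init(out, 1); b.W.zeros();
    const float sd = std::sqrt(1.0f / in);
    std::normal_distribution<float> nd(0.0f, sd);
    for (auto& w : W.W) w = nd(rng);
  }
  fmat forward(const fmat& x, bool train) {
    if (train) x_ = x;
    fmat y = W.W * x; y.each_col() += b.W.col(0); return y;
  }
  fmat backward(const fmat& dy) {
    W.g += dy * x_.t();
    b.g += arma::sum(dy, 1);
    return W.W.t() * dy;
  }
};

struct SiLU {
  fmat x_;
  fmat forward(const fmat& x, bool train) {
    if (train) x_ = x;
    fmat y(x.n_rows, x.n_cols);
    const float* px = x.memptr(); float* py = y.memptr();
    const size_t n = x.n_elem;
    for (size_t i = 0; i < n; ++i) {
      const float s = 1.0f / (1.0f + std::exp(-px[i]));
      py[i] = px[i] * s;
    }
    return y;
  }
  fmat backward(const fmat& dy) {
    fmat dx(dy.n_rows, dy.n_cols);
    const float* px = x_.memptr(); const float* pd = dy.memptr();
    float* po = dx.memptr();
    const size_t n = dy.n_elem;
    for (size_t i = 0; i < n; ++i) {
      const float s = 1.0f / (1.0f + std::exp(-px[i]));
      po[i] = pd[i] * s * (1.0f + px[i] * (1.0f - s));
    }
    return dx;
  }
};

struct GroupNorm {
  int C = 0, G = 1, gs = 1;
  Param gamma, beta;
  fmat xhat;            // cached normalized input
  fmat invstd;          // (G, B)
  static const constexpr float eps = 1e-5f;

  void init(int c) {
    C = c; G = std::min(32, C);
    while (C % G != 0) --G;
    gs = C / G;
    gamma.init(C, 1); gamma.W.ones();
    beta.init(C, 1);  beta.W.zeros();
  }
  fmat forward(const fmat& x, int HW, int B, bool train) {
    fmat y(C, (size_t)HW * B);
    if (train) invstd.set_size(G, B);
    for (int b = 0; b < B; ++b) {
      const size_t c0 = (size_t)b * HW, c1 = c0 + HW - 1;
      for (int g = 0; g < G; ++g) {
        auto sub = x.submat(g * gs, c0, g * gs + gs - 1, c1);
        const float mu = arma::accu(sub) / (gs * (float)HW);
        const float var = arma::accu(arma::square(sub - mu)) / (gs * (float)HW);
        const float is = 1.0f / std::sqrt(var + eps);
        y.submat(g * gs, c0, g * gs + gs - 1, c1) = (sub - mu) * is;
        if (train) invstd(g, b) = is;
      }
    }
    if (train) xhat = y;                       // normalized input, pre scale/shift
    y.each_col() %= gamma.W.col(0);
    y.each_col() += beta.W.col(0);
    return y;
  }
  fmat backward(const fmat& dy, int HW, int B) {
    // parameter grads
    gamma.g += arma::sum(dy % xhat, 1);
    beta.g += arma::sum(dy, 1);
    fmat dx = dy;
    dx.each_col() %= gamma.W.col(0);           // now d(xhat)
    for (int b = 0; b < B; ++b) {
      const size_t c0 = (size_t)b * HW, c1 = c0 + HW - 1;
      for (int g = 0; g < G; ++g) {
        auto dxh = dx.submat(g * gs, c0, g * gs + gs - 1, c1);
        auto xh = xhat.submat(g * gs, c0, g * gs + gs - 1, c1);
        const float m = gs * (float)HW;
        const float s1 = arma::accu(dxh);
        const float s2 = arma::accu(dxh % xh);
        const fmat tmp = (invstd(g, b) / m) * (m * dxh - s1 - xh * s2);
        dx.submat(g * gs, c0, g * gs + gs - 1, c1) = tmp;
      }
    }
    return dx;
  }
};

struct Dropout {
  float p = 0.0f;
  fmat mask;
  fmat forward(const fmat& x, bool train, std::mt19937& rng) {
    if (!train || p <= 0.0f) { mask.reset(); return x; }
    std::uniform_real_distribution<float> u(0.0f, 1.0f);
    mask.set_size(x.n_rows, x.n_cols);
    const float scale = 1.0f / (1.0f - p);
    for (auto& m : mask) m = (u(rng) < p) ? 0.0f : scale;
    return x % mask;
  }
  fmat backward(const fmat& dy) {
    if (mask.is_empty()) return dy;
    return dy % mask;
  }
};

static fmat avgpool2(const fmat& x, int H, int W, int B) {
  const int C = x.n_rows, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  fmat y(C, (size_t)HW2 * B);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const size_t q = (size_t)b * HW2 + (size_t)j * H2 + i;
        const size_t p = (size_t)b * HW + (size_t)(2 * j) * H + 2 * i;
        y.col(q) = 0.25f * (x.col(p) + x.col(p + 1) + x.col(p + H) + x.col(p + H + 1));
      }
  return y;
}
static fmat avgpool2_back(const fmat& dy, int H, int W, int B) {
  const int C = dy.n_rows, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  fmat dx(C, (size_t)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const size_t q = (size_t)b * HW2 + (size_t)j * H2 + i;
        const size_t p = (size_t)b * HW + (size_t)(2 * j) * H + 2 * i;
        const fvec g = 0.25f * dy.col(q);
        dx.col(p) += g; dx.col(p + 1) += g; dx.col(p + H) += g; dx.col(p + H + 1) += g;
      }
  return dx;
}
static fmat upnearest2(const fmat& x, int H, int W, int B) {
  const int C = x.n_rows, H2 = H * 2, W2 = W * 2, HW = H * W, HW2 = H2 * W2;
  fmat y(C, (size_t)HW2 * B);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        y.col((size_t)b * HW2 + (size_t)j * H2 + i) =
          x.col((size_t)b * HW + (size_t)(j / 2) * H + i / 2);
  return y;
}
static fmat upnearest2_back(const fmat& dy, int H, int W, int B) {
  const int C = dy.n_rows, H2 = H * 2, W2 = W * 2, HW = H * W, HW2 = H2 * W2;
  fmat dx(C, (size_t)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i)
        dx.col((size_t)b * HW + (size_t)(j / 2) * H + i / 2) +=
          dy.col((size_t)b * HW2 + (size_t)j * H2 + i);
  return dx;
}

struct ResBlock {
  int Cin = 0, Cout = 0;
  GroupNorm gn1, gn2;
  SiLU s1, s2;
  Conv conv1, conv2, skip;
  Linear embp;
  Dropout drop;
  bool has_skip = false;
  int H_ = 0, W_ = 0, B_ = 0;

  void init(int cin, int cout, int E, float dropout_p, std::mt19937& rng) {
    Cin = cin; Cout = cout;
    gn1.init(cin); gn2.init(cout);
    conv1.init(cin, cout, 3, rng);
    conv2.init(cout, cout, 3, rng, /*zero_init=*/true);
    embp.init(E, cout, rng);
    drop.p = dropout_p;
    has_skip = (cin != cout);
    if (has_skip) skip.init(cin, cout, 1, rng);
  }
  fmat forward(const fmat& x, const fmat& emb, int H, int W, int B,
               bool train, std::mt19937& rng) {
    H_ = H; W_ = W; B_ = B;
    const int HW = H * W;
    fmat h = gn1.forward(x, HW, B, train);
    h = s1.forward(h, train);
    h = conv1.forward(h, H, W, B, train);
    h = gn2.forward(h, HW, B, train);
    // per-channel noise-level bias enters after normalization so the mean
    // subtraction cannot cancel it (critical when the group size is 1)
    fmat e = embp.forward(emb, train);            // Cout x B
    for (int b = 0; b < B; ++b)
      h.cols((size_t)b * HW, (size_t)b * HW + HW - 1).each_col() += e.col(b);
    h = s2.forward(h, train);
    h = drop.forward(h, train, rng);
    h = conv2.forward(h, H, W, B, train);
    if (has_skip) return h + skip.forward(x, H, W, B, train);
    return h + x;
  }
  fmat backward(const fmat& dy, fmat& demb) {
    const int HW = H_ * W_;
    fmat dh = conv2.backward(dy);
    dh = drop.backward(dh);
    dh = s2.backward(dh);
    fmat de(embp.W.W.n_rows, B_);
    for (int b = 0; b < B_; ++b)
      de.col(b) = arma::sum(dh.cols((size_t)b * HW, (size_t)b * HW + HW - 1), 1);
    demb += embp.backward(de);
    dh = gn2.backward(dh, HW, B_);
    dh = conv1.backward(dh);
    dh = s1.backward(dh);
    dh = gn1.backward(dh, HW, B_);
    if (has_skip) return dh + skip.backward(dy);
    return dh + dy;
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&conv1.W); ps.push_back(&conv1.b);
    ps.push_back(&conv2.W); ps.push_back(&conv2.b);
    ps.push_back(&embp.W);  ps.push_back(&embp.b);
    ps.push_back(&gn1.gamma); ps.push_back(&gn1.beta);
    ps.push_back(&gn2.gamma); ps.push_back(&gn2.beta);
    if (has_skip) { ps.push_back(&skip.W); ps.push_back(&skip.b); }
  }
};

struct Attention {
  int C = 0;
  GroupNorm gn;
  Conv q, k, v, proj;
  int H_ = 0, W_ = 0, B_ = 0;
  fmat xn_, qm_, km_, vm_;
  std::vector<fmat> A_;

  void init(int c, std::mt19937& rng) {
    C = c; gn.init(c);
    q.init(c, c, 1, rng); k.init(c, c, 1, rng); v.init(c, c, 1, rng);
    proj.init(c, c, 1, rng, /*zero_init=*/true);
  }
  fmat forward(const fmat& x, int H, int W, int B, bool train, std::mt19937&) {
    H_ = H; W_ = W; B_ = B;
    const int HW = H * W;
    fmat xn = gn.forward(x, HW, B, train);
    fmat qm = q.forward(xn, H, W, B, train);
    fmat km = k.forward(xn, H, W, B, train);
    fmat vm = v.forward(xn, H, W, B, train);
    const float scale = 1.0f / std::sqrt((float)C);
    fmat out(C, (size_t)HW * B);
    if (train) A_.assign(B, fmat());
    for (int b = 0; b < B; ++b) {
      const size_t c0 = (size_t)b * HW, c1 = c0 + HW - 1;
      fmat S = qm.cols(c0, c1).t() * km.cols(c0, c1) * scale;  // HW x HW
      // row-wise softmax
      for (arma::uword i = 0; i < S.n_rows; ++i) {
        arma::frowvec r = S.row(i);
        r -= r.max();
        r = arma::exp(r);
        S.row(i) = r / arma::accu(r);
      }
      out.cols(c0, c1) = vm.cols(c0, c1) * S.t();
      if (train) A_[b] = std::move(S);
    }
    if (train) { xn_ = xn; qm_ = std::move(qm); km_ = std::move(km); vm_ = std::move(vm); }
    fmat y = proj.forward(out, H, W, B, train);
    return y + x;
  }
  fmat backward(const fmat& dy) {
    const int HW = H_ * W_;
    const float scale = 1.0f / std::sqrt((float)C);
    fmat dout = proj.backward(dy);
    fmat dqm(C, (size_t)HW * B_), dkm(C, (size_t)HW * B_), dvm(C, (size_t)HW * B_);
    for (int b = 0; b < B_; ++b) {
      const size_t c0 = (size_t)b * HW, c1 = c0 + HW - 1;
      const fmat& A = A_[b];
      fmat dO = dout.cols(c0, c1);
      dvm.cols(c0, c1) = dO * A;                       // C x HW
      fmat dA = dO.t() * vm_.cols(c0, c1);             // HW x HW
      // softmax (row-wise) backward
      fmat dS(A.n_rows, A.n_cols);
      for (arma::uword i = 0; i < A.n_rows; ++i) {
        const float dot = arma::dot(dA.row(i), A.row(i));
        dS.row(i) = A.row(i) % (dA.row(i) - dot);
      }
      dqm.cols(c0, c1) = km_.cols(c0, c1) * dS.t() * scale;
      dkm.cols(c0, c1) = qm_.cols(c0, c1) * dS * scale;
    }
    fmat dxn = q.backward(dqm) + k.backward(dkm) + v.backward(dvm);
    return gn.backward(dxn, HW, B_) + dy;
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&q.W); ps.push_back(&q.b);
    ps.push_back(&k.W); ps.push_back(&k.b);
    ps.push_back(&v.W); ps.push_back(&v.b);
    ps.push_back(&proj.W); ps.push_back(&proj.b);
    ps.push_back(&gn.gamma); ps.push_back(&gn.beta);
  }
};

// -------------------------------------------------------------------- UNet
struct UNet {
  int L = 0, R = 2, E = 0, d0 = 0, in_ch = 2;
  std::vector<int> ch;
  float dropout_p = 0.0f;
  bool attention = true;

  Conv head, tail;
  GroupNorm gn_tail;
  SiLU s_tail, s_emb;
  Linear emb1, emb2;
  std::vector<ResBlock> enc;       // L*R blocks, level-major
  ResBlock mid1, mid2;
  Attention attn;
  std::vector<ResBlock> dec;       // L*(R+1) blocks, top-down level order
  std::vector<Conv> upconv;        // L-1 convs (levels L-1 .. 1)

  std::mt19937 rng;
  std::vector<Param*> ps;
  long long adam_t = 0;

  // forward caches
  std::vector<fmat> skips;
  std::vector<int> dec_skip_idx;   // which skip each decoder block consumed
  int Hin = 0, Win = 0, Bin = 0;
  fmat emb_cache;

  void build(const std::vector<int>& channels, int res_blocks, float dropout,
             bool with_attention, int emb_dim, unsigned seed) {
    ch = channels; L = ch.size(); R = res_blocks;
    dropout_p = dropout; attention = with_attention;
    d0 = ch[0]; E = emb_dim > 0 ? emb_dim : 4 * ch[0];
    rng.seed(seed);

    head.init(in_ch, ch[0], 3, rng);
    emb1.init(d0, E, rng);
    emb2.init(E, E, rng);

    std::vector<int> skip_ch;
    skip_ch.push_back(ch[0]);
    int cur = ch[0];
    for (int l = 0; l < L; ++l) {
      for (int r = 0; r < R; ++r) {
        enc.emplace_back();
        enc.back().init(cur, ch[l], E, dropout_p, rng);
        cur = ch[l];
        skip_ch.push_back(cur);
      }
      if (l < L - 1) skip_ch.push_back(cur);   // downsample output
    }
    mid1.init(cur, cur, E, dropout_p, rng);
    if (attention) attn.init(cur, rng);
    mid2.init(cur, cur, E, dropout_p, rng);
    for (int l = L - 1; l >= 0; --l) {
      for (int r = 0; r <= R; ++r) {
        const int s = skip_ch.back(); skip_ch.pop_back();
        dec.emplace_back();
        dec.back().init(cur + s, ch[l], E, dropout_p, rng);
        cur = ch[l];
      }
      if (l > 0) {
        upconv.emplace_back();
        upconv.back().init(cur, cur, 3, rng);
      }
    }
    gn_tail.init(ch[0]);
    tail.init(ch[0], 1, 3, rng, /*zero_init=*/true);

    ps.push_back(&head.W); ps.push_back(&head.b);
    ps.push_back(&emb1.W); ps.push_back(&emb1.b);
    ps.push_back(&emb2.W); ps.push_back(&emb2.b);
    for (auto& blk : enc) blk.collect(ps);
    mid1.collect(ps);
    if (attention) attn.collect(ps);
    mid2.collect(ps);
    for (auto& blk : dec) blk.collect(ps);
    for (auto& c : upconv) { ps.push_back(&c.W); ps.push_back(&c.b); }
    ps.push_back(&gn_tail.gamma); ps.push_back(&gn_tail.beta);
    ps.push_back(&tail.W); ps.push_back(&tail.b);
  }

  size_t n_params() const {
    size_t n = 0;
    for (auto* p : ps) n += p->W.n_elem;
    return n;
  }

  // sinusoidal embedding of sqrt(gamma), scaled into a t-like range
  fmat sinusoidal(const fvec& gamma) const {
    const int half = d0 / 2;
    fmat e(d0, gamma.n_elem);
    for (arma::uword b = 0; b < gamma.n_elem; ++b) {
      const float s = std::sqrt(std::max(gamma(b), 0.0f)) * 1000.0f;
      for (int i = 0; i < half; ++i) {
        const float w = std::exp(-std::log(10000.0f) * i / std::max(half - 1, 1));
        e(2 * i, b) = std::sin(s * w);
        e(2 * i + 1, b) = std::cos(s * w);
      }
    }
    return e;
  }

  fmat forward(const fmat& xin, const fvec& gamma, int H, int W, int B, bool train) {
    Hin = H; Win = W; Bin = B;
    fmat e0 = sinusoidal(gamma);
    fmat emb = emb2.forward(s_emb.forward(emb1.forward(e0, train), train), train);
    emb_cache = emb;

    skips.clear(); dec_skip_idx.clear();
    fmat h = head.forward(xin, H, W, B, train);
    skips.push_back(h);
    int hh = H, ww = W;
    int ei = 0;
    for (int l = 0; l < L; ++l) {
      for (int r = 0; r < R; ++r) {
        h = enc[ei++].forward(h, emb, hh, ww, B, train, rng);
        skips.push_back(h);
      }
      if (l < L - 1) {
        h = avgpool2(h, hh, ww, B);
        hh /= 2; ww /= 2;
        skips.push_back(h);
      }
    }
    h = mid1.forward(h, emb, hh, ww, B, train, rng);
    if (attention) h = attn.forward(h, hh, ww, B, train, rng);
    h = mid2.forward(h, emb, hh, ww, B, train, rng);

    int di = 0, ui = 0;
    int top = (int)skips.size();
    for (int l = L - 1; l >= 0; --l) {
      for (int r = 0; r <= R; ++r) {
        const fmat& s = skips[--top];
        dec_skip_idx.push_back(top);
        fmat cat = arma::join_cols(h, s);
        h = dec[di++].forward(cat, emb, hh, ww, B, train, rng);
      }
      if (l > 0) {
        h = upnearest2(h, hh, ww, B);
        hh *= 2; ww *= 2;
        h = upconv[ui++].forward(h, hh, ww, B, train);
      }
    }
    h = gn_tail.forward(h, hh * ww, B, train);
    h = s_tail.forward(h, train);
    return tail.forward(h, hh, ww, B, train);
  }

  void backward(const fmat& dout) {
    const int B = Bin;
    fmat demb(E, B, arma::fill::zeros);
    std::vector<fmat> dskips(skips.size());

    fmat dh = tail.backward(dout);
    dh = s_tail.backward(dh);
    dh = gn_tail.backward(dh, Hin * Win, B);

    int hh = Hin, ww = Win;
    int di = (int)dec.size() - 1, ui = (int)upconv.size() - 1;
    int si = (int)dec_skip_idx.size() - 1;
    for (int l = 0; l < L; ++l) {
      if (l > 0) {
        dh = upconv[ui--].backward(dh);
        dh = upnearest2_back(dh, hh / 2, ww / 2, B);
        hh /= 2; ww /= 2;
      }
      for (int r = 0; r <= R; ++r) {
        fmat dcat = dec[di].backward(dh, demb);
        const int c_top = dec[di].Cin - (int)skips[dec_skip_idx[si]].n_rows;
        dh = dcat.rows(0, c_top - 1);
        dskips[dec_skip_idx[si]] = dcat.rows(c_top, dcat.n_rows - 1);
        --di; --si;
      }
    }
    dh = mid2.backward(dh, demb);
    if (attention) dh = attn.backward(dh);
    dh = mid1.backward(dh, demb);

    int ei = (int)enc.size() - 1;
    int top = (int)skips.size() - 1;
    for (int l = L - 1; l >= 0; --l) {
      if (l < L - 1) {
        dh += dskips[top--];                 // downsample output skip
        dh = avgpool2_back(dh, hh * 2, ww * 2, B);
        hh *= 2; ww *= 2;
      }
      for (int r = R - 1; r >= 0; --r) {
        dh += dskips[top--];                 // res-block output skip
        dh = enc[ei--].backward(dh, demb);
      }
    }
    dh += dskips[top--];                     // head output skip
    head.backward(dh);

    fmat de = emb1.backward(s_emb.backward(emb2.backward(demb)));
    (void)de;  // no gradient flows to gamma itself
  }

  void zero_grad() { for (auto* p : ps) p->g.zeros(); }

  // exponential moving average of the weights, tracked for sampling
  void ema_update(float decay) {
    for (auto* p : ps) {
      if (!p->has_ema) { p->ema = p->W; p->has_ema = true; }
      else p->ema = decay * p->ema + (1.0f - decay) * p->W;
    }
  }
  void swap_ema() {
    for (auto* p : ps) if (p->has_ema) p->W.swap(p->ema);
  }

  void adam_step(float lr, float wd, float clipnorm,
                 float b1 = 0.9f, float b2 = 0.999f, float eps = 1e-8f) {
    double total = 0;
    for (auto* p : ps) total += arma::accu(arma::square(arma::conv_to<arma::mat>::from(p->g)));
    const double norm = std::sqrt(total);
    const float scale = (clipnorm > 0 && norm > clipnorm) ? (float)(clipnorm / norm) : 1.0f;
    ++adam_t;
    const float bc1 = 1.0f - std::pow(b1, (float)adam_t);
    const float bc2 = 1.0f - std::pow(b2, (float)adam_t);
    for (auto* p : ps) {
      p->ensure_moments();
      fmat g = p->g * scale;
      p->m = b1 * p->m + (1.0f - b1) * g;
      p->v = b2 * p->v + (1.0f - b2) * (g % g);
      p->W -= lr * ((p->m / bc1) / (arma::sqrt(p->v / bc2) + eps) + wd * p->W);
    }
  }
};

// -------------------------------------------------------------- R bindings
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

static UNet* get_net(SEXP ptr) {
  Rcpp::XPtr<UNet> xp(ptr);
  return xp.get();
}

// R array (H, W, C, B) -> fmat (C, H*W*B)
static fmat array_to_fmat(const NumericVector& x, int H, int W, int C, int B) {
  fmat out(C, (size_t)H * W * B);
  const double* px = x.begin();
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* src = px + HW * (c + (size_t)C * b);
      for (size_t p = 0; p < HW; ++p) out(c, b * HW + p) = (float)src[p];
    }
  return out;
}

// fmat (1, H*W*B) -> R array (H, W, B)
static NumericVector fmat_to_array(const fmat& y, int H, int W, int B) {
  NumericVector out((size_t)H * W * B);
  for (size_t i = 0; i < (size_t)H * W * B; ++i) out[i] = y(0, i);
  out.attr("dim") = IntegerVector::create(H, W, B);
  return out;
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(List config, int seed) {
  std::vector<int> channels = Rcpp::as<std::vector<int>>(config["channels"]);
  int res_blocks = Rcpp::as<int>(config["res_blocks"]);
  double dropout = Rcpp::as<double>(config["dropout"]);
  bool attention = Rcpp::as<bool>(config["attention"]);
  int emb_dim = config.containsElementNamed("emb_dim") ? Rcpp::as<int>(config["emb_dim"]) : 0;
  UNet* net = new UNet();
  net->build(channels, res_blocks, (float)dropout, attention, emb_dim, (unsigned)seed);
  Rcpp::XPtr<UNet> xp(net, true);
  return xp;
}

// [[Rcpp::export(name = ".unet_n_params")]]
double unet_n_params(SEXP ptr) { return (double)get_net(ptr)->n_params(); }

// [[Rcpp::export(name = ".unet_forward")]]
NumericVector unet_forward(SEXP ptr, NumericVector x, NumericVector gamma, bool train) {
  UNet* net = get_net(ptr);
  IntegerVector d = x.attr("dim");
  if (d.size() != 4 || d[2] != net->in_ch) Rcpp::stop("input must be (H, W, 2, B)");
  const int H = d[0], W = d[1], B = d[3];
  fmat xin = array_to_fmat(x, H, W, net->in_ch, B);
  fvec g(gamma.size());
  for (int i = 0; i < gamma.size(); ++i) g(i) = (float)gamma[i];
  if ((int)g.n_elem == 1 && B > 1) g = fvec(B, arma::fill::value(g(0)));
  fmat y = net->forward(xin, g, H, W, B, train);
  return fmat_to_array(y, H, W, B);
}

// forward + L1 loss against target noise; optionally backprop (grads kept)
// [[Rcpp::export(name = ".unet_loss_grad")]]
double unet_loss_grad(SEXP ptr, NumericVector x, NumericVector target,
                      NumericVector gamma, bool compute_grad) {
  UNet* net = get_net(ptr);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], B = d[3];
  fmat xin = array_to_fmat(x, H, W, net->in_ch, B);
  fvec g(gamma.size());
  for (int i = 0; i < gamma.size(); ++i) g(i) = (float)gamma[i];
  if ((int)g.n_elem == 1 && B > 1) g = fvec(B, arma::fill::value(g(0)));
  fmat y = net->forward(xin, g, H, W, B, compute_grad);
  fmat t(1, y.n_cols);
  for (size_t i = 0; i < (size_t)y.n_cols; ++i) t(0, i) = (float)target[i];
  fmat diff = y - t;
  const double loss = arma::accu(arma::abs(diff)) / diff.n_elem;
  if (compute_grad) {
    net->zero_grad();
    fmat dout = arma::sign(diff) / (float)diff.n_elem;
    net->backward(dout);
  }
  return loss;
}

// [[Rcpp::export(name = ".unet_adam_step")]]
void unet_adam_step(SEXP ptr, double lr, double weight_decay, double clipnorm) {
  get_net(ptr)->adam_step((float)lr, (float)weight_decay, (float)clipnorm);
}

// [[Rcpp::export(name = ".unet_ema_update")]]
void unet_ema_update(SEXP ptr, double decay) {
  get_net(ptr)->ema_update((float)decay);
}

// swaps the live weights with the EMA shadow (call once to sample from
// the average, again to restore)
// [[Rcpp::export(name = ".unet_swap_ema")]]
void unet_swap_ema(SEXP ptr) { get_net(ptr)->swap_ema(); }

// [[Rcpp::export(name = ".unet_get_params")]]
List unet_get_params(SEXP ptr) {
  UNet* net = get_net(ptr);
  List out(net->ps.size());
  for (size_t i = 0; i < net->ps.size(); ++i) {
    const fmat& w = net->ps[i]->W;
    Rcpp::NumericMatrix m(w.n_rows, w.n_cols);
    for (size_t j = 0; j < w.n_elem; ++j) m[j] = w(j);
    out[i] = m;
  }
  return out;
}

// [[Rcpp::export(name = ".unet_set_params")]]
void unet_set_params(SEXP ptr, List params) {
  UNet* net = get_net(ptr);
  if ((size_t)params.size() != net->ps.size()) Rcpp::stop("parameter list length mismatch");
  for (size_t i = 0; i < net->ps.size(); ++i) {
    Rcpp::NumericMatrix m = params[i];
    fmat& w = net->ps[i]->W;
    if ((size_t)m.nrow() != w.n_rows || (size_t)m.ncol() != w.n_cols)
      Rcpp::stop("parameter %d shape mismatch", (int)i + 1);
    for (size_t j = 0; j < w.n_elem; ++j) w(j) = (float)m[j];
  }
}

// [[Rcpp::export(name = ".unet_get_grads")]]
List unet_get_grads(SEXP ptr) {
  UNet* net = get_net(ptr);
  List out(net->ps.size());
  for (size_t i = 0; i < net->ps.size(); ++i) {
    const fmat& g = net->ps[i]->g;
    Rcpp::NumericMatrix m(g.n_rows, g.n_cols);
    for (size_t j = 0; j < g.n_elem; ++j) m[j] = g(j);
    out[i] = m;
  }
  return out;
}

// optimizer + RNG state for bit-exact checkpoint resumption
// [[Rcpp::export(name = ".unet_get_state")]]
List unet_get_state(SEXP ptr) {
  UNet* net = get_net(ptr);
  List ms(net->ps.size()), vs(net->ps.size());
  for (size_t i = 0; i < net->ps.size(); ++i) {
    net->ps[i]->ensure_moments();
    const fmat& m = net->ps[i]->m; const fmat& v = net->ps[i]->v;
    Rcpp::NumericMatrix rm(m.n_rows, m.n_cols), rv(v.n_rows, v.n_cols);
    for (size_t j = 0; j < m.n_elem; ++j) { rm[j] = m(j); rv[j] = v(j); }
    ms[i] = rm; vs[i] = rv;
  }
  std::ostringstream ss; ss << net->rng;
  return List::create(Rcpp::Named("m") = ms, Rcpp::Named("v") = vs,
                      Rcpp::Named("t") = (double)net->adam_t,
                      Rcpp::Named("rng") = ss.str());
}

// [[Rcpp::export(name = ".unet_set_state")]]
void unet_set_state(SEXP ptr, List state) {
  UNet* net = get_net(ptr);
  List ms = state["m"], vs = state["v"];
  for (size_t i = 0; i < net->ps.size(); ++i) {
    net->ps[i]->ensure_moments();
    Rcpp::NumericMatrix rm = ms[i], rv = vs[i];
    fmat& m = net->ps[i]->m; fmat& v = net->ps[i]->v;
    for (size_t j = 0; j < m.n_elem; ++j) { m(j) = (float)rm[j]; v(j) = (float)rv[j]; }
  }
  net->adam_t = (long long)Rcpp::as<double>(state["t"]);
  std::istringstream ss(Rcpp::as<std::string>(state["rng"]));
  ss >> net->rng;
}
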