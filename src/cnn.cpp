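// Compact single-precision CNN for 128x128 single-channel mask crops.
//
// Fixed topology (conv3 filter count / padding configurable):
//   input 128x128x1
//   conv1 16@3x3 s1 p2 + ReLU        -> 130x130x16
//   maxpool 3x3 s1 p1                -> 130x130x16
//   conv2 32@3x3 s1 p1 + ReLU        -> 130x130x32
//   maxpool 2x2 s2 p0                -> 65x65x32
//   conv3 C3@3x3 s1 pP3 + ReLU       -> S3xS3xC3
//   fc1 100 + ReLU, fc2 100 + ReLU, dropout, fc3 5, softmax
//
// Convolutions run as im2col + sgemm on the BLAS R links against.
// Training: SGD with momentum, L2 penalty, per-epoch shuffle and random
// rotation/reflection augmentation, best-validation weight snapshot.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
using namespace Rcpp;
using namespace arma;

static const int IN = 128;          // input side
static const int S1 = 130;          // conv1 / pool1 / conv2 side
static const int A1 = S1 * S1;      // 16900
static const int S2 = 65;           // pool2 side
static const int A2 = S2 * S2;      // 4225
static const int NPIX = IN * IN;    // 16384
static const int NCLASS = 5;

struct Net {
  int C3, P3, S3, A3dim, D;
  double dropout;
  float input_scale, init_gain;
  fmat W1, W2, W3, Wf1, Wf2, Wf3;
  fvec b1, b2, b3, bf1, bf2, bf3;
  // momentum buffers
  fmat V1, V2, V3, Vf1, Vf2, Vf3;
  fvec v1, v2, v3, vf1, vf2, vf3;
  std::mt19937 rng;

  Net(int c3, int p3, double drop, int seed, double in_scale, double gain)
      : C3(c3), P3(p3), dropout(drop),
        input_scale((float)in_scale), init_gain((float)gain), rng(seed) {
    S3 = S2 + 2 * P3 - 2;
    A3dim = S3 * S3;
    D = A3dim * C3;
    auto he = [&](fmat &m, int rows, int cols, int fan_in) {
      std::normal_distribution<float> g(0.0f,
          init_gain * std::sqrt(2.0f / fan_in));
      m.set_size(rows, cols);
      for (uword i = 0; i < m.n_elem; ++i) m[i] = g(rng);
    };
    he(W1, 16, 9, 9);
    he(W2, 32, 144, 144);
    he(W3, C3, 288, 288);
    he(Wf1, 100, D, D);
    he(Wf2, 100, 100, 100);
    he(Wf3, NCLASS, 100, 100);
    b1.zeros(16); b2.zeros(32); b3.zeros(C3);
    bf1.zeros(100); bf2.zeros(100); bf3.zeros(NCLASS);
    V1.zeros(16, 9); V2.zeros(32, 144); V3.zeros(C3, 288);
    Vf1.zeros(100, D); Vf2.zeros(100, 100); Vf3.zeros(NCLASS, 100);
    v1.zeros(16); v2.zeros(32); v3.zeros(C3);
    vf1.zeros(100); vf2.zeros(100); vf3.zeros(NCLASS);
  }
};

// ---- helpers --------------------------------------------------------------

// im2col for 3x3 stride-1 kernels; input C x (Sin*Sin) column-plane layout,
// output (C*9) x (Sout*Sout), rows ordered (c, ky, kx).
static void im2col3(const float *in, int C, int Sin, int Sout, int pad,
                    float *col) {
  const int K = 3;
  for (int oy = 0; oy < Sout; ++oy)
    for (int ox = 0; ox < Sout; ++ox) {
      float *dst = col + (size_t)(oy * Sout + ox) * (C * K * K);
      for (int c = 0; c < C; ++c) {
        const float *plane = in + (size_t)c * Sin * Sin;
        for (int ky = 0; ky < K; ++ky) {
          int iy = oy - pad + ky;
          for (int kx = 0; kx < K; ++kx) {
            int ix = ox - pad + kx;
            *dst++ = (ix < 0 || iy < 0 || ix >= Sin || iy >= Sin)
                         ? 0.0f
                         : plane[iy * Sin + ix];
          }
        }
      }
    }
}

// col2im: scatter-add gradient columns back to the input planes.
static void col2im3(const float *col, int C, int Sin, int Sout, int pad,
                    float *in) {
  const int K = 3;
  std::memset(in, 0, sizeof(float) * (size_t)C * Sin * Sin);
  for (int oy = 0; oy < Sout; ++oy)
    for (int ox = 0; ox < Sout; ++ox) {
      const float *src = col + (size_t)(oy * Sout + ox) * (C * K * K);
      for (int c = 0; c < C; ++c) {
        float *plane = in + (size_t)c * Sin * Sin;
        for (int ky = 0; ky < K; ++ky) {
          int iy = oy - pad + ky;
          for (int kx = 0; kx < K; ++kx) {
            float v = *src++;
            int ix = ox - pad + kx;
            if (ix >= 0 && iy >= 0 && ix < Sin && iy < Sin)
              plane[iy * Sin + ix] += v;
          }
        }
      }
    }
}

// 3x3 stride-1 pad-1 max pool, per channel plane, with argmax indices.
static void pool3(const float *in, int C, int S, float *out, uint16_t *idx) {
  for (int c = 0; c < C; ++c) {
    const float *p = in + (size_t)c * S * S;
    float *o = out + (size_t)c * S * S;
    uint16_t *ix = idx + (size_t)c * S * S;
    for (int oy = 0; oy < S; ++oy)
      for (int ox = 0; ox < S; ++ox) {
        float best = -1e30f;
        int bi = 0;
        for (int ky = -1; ky <= 1; ++ky) {
          int iy = oy + ky;
          if (iy < 0 || iy >= S) continue;
          for (int kx = -1; kx <= 1; ++kx) {
            int ixx = ox + kx;
            if (ixx < 0 || ixx >= S) continue;
            int ii = iy * S + ixx;
            if (p[ii] > best) { best = p[ii]; bi = ii; }
          }
        }
        o[oy * S + ox] = best;
        ix[oy * S + ox] = (uint16_t)bi;
      }
  }
}

// 2x2 stride-2 max pool (130 -> 65), with argmax indices.
static void pool2(const float *in, int C, int Sin, int Sout, float *out,
                  uint16_t *idx) {
  for (int c = 0; c < C; ++c) {
    const float *p = in + (size_t)c * Sin * Sin;
    float *o = out + (size_t)c * Sout * Sout;
    uint16_t *ix = idx + (size_t)c * Sout * Sout;
    for (int oy = 0; oy < Sout; ++oy)
      for (int ox = 0; ox < Sout; ++ox) {
        float best = -1e30f;
        int bi = 0;
        for (int ky = 0; ky < 2; ++ky)
          for (int kx = 0; kx < 2; ++kx) {
            int ii = (2 * oy + ky) * Sin + (2 * ox + kx);
            if (p[ii] > best) { best = p[ii]; bi = ii; }
          }
        o[oy * Sout + ox] = best;
        ix[oy * Sout + ox] = (uint16_t)bi;
      }
  }
}

// mask-safe rotation about center on a 128x128 float plane, background 0.
// Nearest-neighbor sampling: interpolation would smear intensity into the
// 1-3 px head-tail gap of curled bodies (closing it into a false coil) and
// smooth away the ragged boundaries that define noisy censored crops.
static void rot128(const float *in, float deg, float *out) {
  float th = deg * (float)M_PI / 180.0f, c = std::cos(th), s = std::sin(th);
  float ctr = (IN - 1) / 2.0f;
  for (int y = 0; y < IN; ++y)
    for (int x = 0; x < IN; ++x) {
      float dx = x - ctr, dy = y - ctr;
      float sx = c * dx + s * dy + ctr, sy = -s * dx + c * dy + ctr;
      int xi = (int)std::lround(sx), yi = (int)std::lround(sy);
      out[y * IN + x] = (xi < 0 || yi < 0 || xi >= IN || yi >= IN)
                            ? 0.0f
                            : in[yi * IN + xi];
    }
}

static void load_image(const Rbyte *raw, int b, float scale, float *out) {
  const Rbyte *src = raw + (size_t)b * NPIX;
  for (int i = 0; i < NPIX; ++i) out[i] = src[i] * (scale / 255.0f);
}

// Per-image convolutional forward. Buffers supplied by caller; when
// store != nullptr the activations needed for backprop are kept.
struct ConvStore {
  float *x0, *p1;        // input, pool1 output
  uint8_t *m1, *m2;      // relu masks for conv1, conv2 outputs
  uint16_t *i1, *i2;     // pool argmax indices
  float *p2;             // pool2 output
};

struct ConvTmp {
  std::vector<float> col1, out1, col2, out2, col3, out3;
  ConvTmp(int C3max, int A3max) {
    col1.resize((size_t)9 * A1);
    out1.resize((size_t)16 * A1);
    col2.resize((size_t)144 * A1);
    out2.resize((size_t)32 * A1);
    col3.resize((size_t)288 * A2);
    out3.resize((size_t)C3max * A3max);
  }
};

static void conv_forward(Net &net, const float *x0, ConvTmp &t,
                         ConvStore *st, float *a3out) {
  // conv1
  im2col3(x0, 1, IN, S1, 2, t.col1.data());
  {
    fmat C(t.col1.data(), 9, A1, false, true);
    fmat O(t.out1.data(), 16, A1, false, true);
    O = net.W1 * C;
    O.each_col() += net.b1;
  }
  // relu + mask; pool1 works on channel-plane layout so transpose view:
  // out1 is (16 x A1) with channel as row; convert to plane layout
  static thread_local std::vector<float> plane1, pool1o, plane2, pool2o;
  plane1.resize((size_t)16 * A1);
  pool1o.resize((size_t)16 * A1);
  plane2.resize((size_t)32 * A1);
  pool2o.resize((size_t)32 * A2);
  for (int c = 0; c < 16; ++c)
    for (int j = 0; j < A1; ++j) {
      float v = t.out1[(size_t)j * 16 + c];
      if (v < 0) v = 0;
      if (st) st->m1[(size_t)c * A1 + j] = v > 0;
      plane1[(size_t)c * A1 + j] = v;
    }
  static thread_local std::vector<uint16_t> idx1, idx2;
  idx1.resize((size_t)16 * A1);
  idx2.resize((size_t)32 * A2);
  pool3(plane1.data(), 16, S1, pool1o.data(), idx1.data());
  if (st) {
    std::memcpy(st->p1, pool1o.data(), sizeof(float) * 16 * A1);
    std::memcpy(st->i1, idx1.data(), sizeof(uint16_t) * 16 * A1);
  }
  // conv2
  im2col3(pool1o.data(), 16, S1, S1, 1, t.col2.data());
  {
    fmat C(t.col2.data(), 144, A1, false, true);
    fmat O(t.out2.data(), 32, A1, false, true);
    O = net.W2 * C;
    O.each_col() += net.b2;
  }
  for (int c = 0; c < 32; ++c)
    for (int j = 0; j < A1; ++j) {
      float v = t.out2[(size_t)j * 32 + c];
      if (v < 0) v = 0;
      if (st) st->m2[(size_t)c * A1 + j] = v > 0;
      plane2[(size_t)c * A1 + j] = v;
    }
  pool2(plane2.data(), 32, S1, S2, pool2o.data(), idx2.data());
  if (st) {
    std::memcpy(st->p2, pool2o.data(), sizeof(float) * 32 * A2);
    std::memcpy(st->i2, idx2.data(), sizeof(uint16_t) * 32 * A2);
  }
  // conv3
  im2col3(pool2o.data(), 32, S2, net.S3, net.P3, t.col3.data());
  {
    fmat C(t.col3.data(), 288, net.A3dim, false, true);
    fmat O(t.out3.data(), net.C3, net.A3dim, false, true);
    O = net.W3 * C;
    O.each_col() += net.b3;
  }
  // relu, write channel-plane flattened activation (plane-major)
  for (int c = 0; c < net.C3; ++c)
    for (int j = 0; j < net.A3dim; ++j) {
      float v = t.out3[(size_t)j * net.C3 + c];
      a3out[(size_t)c * net.A3dim + j] = v > 0 ? v : 0;
    }
}

struct Grads {
  fmat W1, W2, W3, Wf1, Wf2, Wf3;
  fvec b1, b2, b3, bf1, bf2, bf3;
  void init(Net &n) {
    W1.zeros(16, 9); W2.zeros(32, 144); W3.zeros(n.C3, 288);
    Wf1.zeros(100, n.D); Wf2.zeros(100, 100); Wf3.zeros(NCLASS, 100);
    b1.zeros(16); b2.zeros(32); b3.zeros(n.C3);
    bf1.zeros(100); bf2.zeros(100); bf3.zeros(NCLASS);
  }
  void zero() {
    W1.zeros(); W2.zeros(); W3.zeros(); Wf1.zeros(); Wf2.zeros(); Wf3.zeros();
    b1.zeros(); b2.zeros(); b3.zeros(); bf1.zeros(); bf2.zeros(); bf3.zeros();
  }
};

// Backward through the conv stack for one image; dA3 is plane-major D vector.
static void conv_backward(Net &net, ConvStore &st, ConvTmp &t,
                          const float *a3, const float *dA3, Grads &g) {
  static thread_local std::vector<float> da3, dcol3, dp2, dplane2, dout2,
      dcol2, dp1, dplane1, dout1;
  da3.resize((size_t)net.C3 * net.A3dim);
  dcol3.resize((size_t)288 * net.A3dim);
  dp2.resize((size_t)32 * A2);
  dplane2.resize((size_t)32 * A1);
  dout2.resize((size_t)32 * A1);
  dcol2.resize((size_t)144 * A1);
  dp1.resize((size_t)16 * A1);
  dplane1.resize((size_t)16 * A1);
  dout1.resize((size_t)16 * A1);

  // relu3 + layout: da3 pixel-major (A3dim cols) for gemm
  for (int c = 0; c < net.C3; ++c)
    for (int j = 0; j < net.A3dim; ++j) {
      size_t pi = (size_t)c * net.A3dim + j;
      da3[(size_t)j * net.C3 + c] = a3[pi] > 0 ? dA3[pi] : 0.0f;
    }
  // regenerate col3 from stored p2
  im2col3(st.p2, 32, S2, net.S3, net.P3, t.col3.data());
  {
    fmat D3(da3.data(), net.C3, net.A3dim, false, true);
    fmat C3m(t.col3.data(), 288, net.A3dim, false, true);
    g.W3 += D3 * C3m.t();
    g.b3 += sum(D3, 1);
    fmat DC(dcol3.data(), 288, net.A3dim, false, true);
    DC = net.W3.t() * D3;
  }
  col2im3(dcol3.data(), 32, S2, net.S3, net.P3, dp2.data());
  // pool2 backward
  std::memset(dplane2.data(), 0, sizeof(float) * 32 * A1);
  for (int c = 0; c < 32; ++c) {
    const float *dsrc = dp2.data() + (size_t)c * A2;
    const uint16_t *ix = st.i2 + (size_t)c * A2;
    float *ddst = dplane2.data() + (size_t)c * A1;
    for (int j = 0; j < A2; ++j) ddst[ix[j]] += dsrc[j];
  }
  // relu2 + layout back to pixel-major
  for (int c = 0; c < 32; ++c)
    for (int j = 0; j < A1; ++j)
      dout2[(size_t)j * 32 + c] =
          st.m2[(size_t)c * A1 + j] ? dplane2[(size_t)c * A1 + j] : 0.0f;
  im2col3(st.p1, 16, S1, S1, 1, t.col2.data());
  {
    fmat D2(dout2.data(), 32, A1, false, true);
    fmat C2(t.col2.data(), 144, A1, false, true);
    g.W2 += D2 * C2.t();
    g.b2 += sum(D2, 1);
    fmat DC(dcol2.data(), 144, A1, false, true);
    DC = net.W2.t() * D2;
  }
  col2im3(dcol2.data(), 16, S1, S1, 1, dp1.data());
  // pool1 backward
  std::memset(dplane1.data(), 0, sizeof(float) * 16 * A1);
  for (int c = 0; c < 16; ++c) {
    const float *dsrc = dp1.data() + (size_t)c * A1;
    const uint16_t *ix = st.i1 + (size_t)c * A1;
    float *ddst = dplane1.data() + (size_t)c * A1;
    for (int j = 0; j < A1; ++j) ddst[ix[j]] += dsrc[j];
  }
  for (int c = 0; c < 16; ++c)
    for (int j = 0; j < A1; ++j)
      dout1[(size_t)j * 16 + c] =
          st.m1[(size_t)c * A1 + j] ? dplane1[(size_t)c * A1 + j] : 0.0f;
  im2col3(st.x0, 1, IN, S1, 2, t.col1.data());
  {
    fmat D1(dout1.data(), 16, A1, false, true);
    fmat C1(t.col1.data(), 9, A1, false, true);
    g.W1 += D1 * C1.t();
    g.b1 += sum(D1, 1);
  }
}

static void sgd_step(fmat &W, fmat &V, fmat &G, float lr, float mom, float wd) {
  V = mom * V - lr * (G + wd * W);
  W += V;
}
static void sgd_step(fvec &W, fvec &V, fvec &G, float lr, float mom, float wd) {
  V = mom * V - lr * (G + wd * W);
  W += V;
}

// forward scores for a set of images (no dropout, no augmentation)
static fmat forward_scores(Net &net, const Rbyte *raw, const IntegerVector &idx) {
  const int n = idx.size();
  ConvTmp tmp(net.C3, net.A3dim);
  std::vector<float> x0(NPIX);
  fmat A3(net.D, n);
  for (int b = 0; b < n; ++b) {
    load_image(raw, idx[b] - 1, net.input_scale, x0.data());
    conv_forward(net, x0.data(), tmp, nullptr, A3.colptr(b));
  }
  fmat F1 = net.Wf1 * A3;
  F1.each_col() += net.bf1;
  F1.transform([](float v) { return v > 0 ? v : 0; });
  fmat F2 = net.Wf2 * F1;
  F2.each_col() += net.bf2;
  F2.transform([](float v) { return v > 0 ? v : 0; });
  fmat Z = net.Wf3 * F2;
  Z.each_col() += net.bf3;
  // stable softmax per column
  for (int b = 0; b < n; ++b) {
    fvec z = Z.col(b);
    z -= z.max();
    fvec e = exp(z);
    Z.col(b) = e / accu(e);
  }
  return Z;
}

// ---- exported API ---------------------------------------------------------

// [[Rcpp::export]]
SEXP cnn_new(int conv3_filters, int conv3_pad, double dropout, int seed,
             double input_scale = 1.0, double init_gain = 1.0) {
  XPtr<Net> p(new Net(conv3_filters, conv3_pad, dropout, seed, input_scale,
                      init_gain), true);
  return p;
}

// [[Rcpp::export]]
bool cnn_ptr_valid(SEXP netp) {
  return R_ExternalPtrAddr(netp) != nullptr;
}

// [[Rcpp::export]]
List cnn_get_weights(SEXP netp) {
  XPtr<Net> net(netp);
  auto wrapf = [](const fmat &m) {
    NumericMatrix out(m.n_rows, m.n_cols);
    for (uword i = 0; i < m.n_elem; ++i) out[i] = m[i];
    return out;
  };
  auto wrapv = [](const fvec &v) {
    NumericVector out(v.n_elem);
    for (uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
    return out;
  };
  return List::create(
      _["W1"] = wrapf(net->W1), _["b1"] = wrapv(net->b1),
      _["W2"] = wrapf(net->W2), _["b2"] = wrapv(net->b2),
      _["W3"] = wrapf(net->W3), _["b3"] = wrapv(net->b3),
      _["Wf1"] = wrapf(net->Wf1), _["bf1"] = wrapv(net->bf1),
      _["Wf2"] = wrapf(net->Wf2), _["bf2"] = wrapv(net->bf2),
      _["Wf3"] = wrapf(net->Wf3), _["bf3"] = wrapv(net->bf3),
      _["conv3_filters"] = net->C3, _["conv3_pad"] = net->P3,
      _["dropout"] = net->dropout);
}

// [[Rcpp::export]]
void cnn_set_weights(SEXP netp, List w) {
  XPtr<Net> net(netp);
  auto setf = [](fmat &m, SEXP s) {
    NumericMatrix in(s);
    if ((int)m.n_rows != in.nrow() || (int)m.n_cols != in.ncol())
      stop("weight shape mismatch");
    for (uword i = 0; i < m.n_elem; ++i) m[i] = (float)in[i];
  };
  auto setv = [](fvec &v, SEXP s) {
    NumericVector in(s);
    if ((int)v.n_elem != in.size()) stop("bias length mismatch");
    for (uword i = 0; i < v.n_elem; ++i) v[i] = (float)in[i];
  };
  setf(net->W1, w["W1"]); setv(net->b1, w["b1"]);
  setf(net->W2, w["W2"]); setv(net->b2, w["b2"]);
  setf(net->W3, w["W3"]); setv(net->b3, w["b3"]);
  setf(net->Wf1, w["Wf1"]); setv(net->bf1, w["bf1"]);
  setf(net->Wf2, w["Wf2"]); setv(net->bf2, w["bf2"]);
  setf(net->Wf3, w["Wf3"]); setv(net->bf3, w["bf3"]);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(SEXP netp, RawVector images, IntegerVector idx) {
  XPtr<Net> net(netp);
  fmat S = forward_scores(*net, RAW(images), idx);
  NumericMatrix out(idx.size(), NCLASS);
  for (int b = 0; b < idx.size(); ++b)
    for (int k = 0; k < NCLASS; ++k) out(b, k) = S(k, b);
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(SEXP netp, RawVector train_images, IntegerVector train_labels,
                   RawVector val_images, IntegerVector val_labels,
                   int max_epochs, int batch_size, double lr, double momentum,
                   double weight_decay, bool augment, int seed, int patience,
                   double val_stop, bool verbose) {
  XPtr<Net> net_p(netp);
  Net &net = *net_p;
  const int ntrain = train_labels.size(), nval = val_labels.size();
  const Rbyte *traw = RAW(train_images), *vraw = RAW(val_images);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<float> uang(0.0f, 360.0f);
  std::uniform_real_distribution<float> u01(0.0f, 1.0f);

  const int B = std::min(batch_size, ntrain);
  ConvTmp tmp(net.C3, net.A3dim);
  Grads g; g.init(net);
  // per-image activation stores for one batch
  std::vector<float> X0((size_t)B * NPIX), P1((size_t)B * 16 * A1),
      P2((size_t)B * 32 * A2);
  std::vector<uint8_t> M1((size_t)B * 16 * A1), M2((size_t)B * 32 * A1);
  std::vector<uint16_t> I1((size_t)B * 16 * A1), I2((size_t)B * 32 * A2);
  fmat A3(net.D, B);
  std::vector<float> xrot(NPIX), xtmp(NPIX);

  std::vector<int> order(ntrain);
  for (int i = 0; i < ntrain; ++i) order[i] = i;

  NumericVector h_loss(max_epochs, NA_REAL), h_tacc(max_epochs, NA_REAL),
      h_vacc(max_epochs, NA_REAL);
  double best_val = -1.0;
  int best_epoch = -1, bad = 0, epochs_run = 0;
  List best_weights;
  std::string stop_reason = "max_epochs";

  for (int ep = 0; ep < max_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int correct = 0, seen = 0;
    for (int start = 0; start < ntrain; start += B) {
      int nb = std::min(B, ntrain - start);
      // forward conv per image, with augmentation
      for (int b = 0; b < nb; ++b) {
        int img = order[start + b];
        load_image(traw, img, net.input_scale, xtmp.data());
        float *x = xtmp.data();
        if (augment) {
          rot128(xtmp.data(), uang(rng), xrot.data());
          x = xrot.data();
          if (u01(rng) < 0.5f) {  // horizontal reflection
            for (int y = 0; y < IN; ++y)
              for (int xx = 0; xx < IN / 2; ++xx)
                std::swap(x[y * IN + xx], x[y * IN + (IN - 1 - xx)]);
          }
          if (u01(rng) < 0.5f) {  // vertical reflection
            for (int y = 0; y < IN / 2; ++y)
              for (int xx = 0; xx < IN; ++xx)
                std::swap(x[y * IN + xx], x[(IN - 1 - y) * IN + xx]);
          }
        }
        std::memcpy(&X0[(size_t)b * NPIX], x, sizeof(float) * NPIX);
        ConvStore st = {&X0[(size_t)b * NPIX], &P1[(size_t)b * 16 * A1],
                        &M1[(size_t)b * 16 * A1], &M2[(size_t)b * 32 * A1],
                        &I1[(size_t)b * 16 * A1], &I2[(size_t)b * 32 * A2],
                        &P2[(size_t)b * 32 * A2]};
        conv_forward(net, st.x0, tmp, &st, A3.colptr(b));
      }
      fmat A3v = A3.cols(0, nb - 1);
      fmat Z1 = net.Wf1 * A3v; Z1.each_col() += net.bf1;
      fmat F1 = Z1; F1.transform([](float v) { return v > 0 ? v : 0; });
      fmat Z2 = net.Wf2 * F1; Z2.each_col() += net.bf2;
      fmat F2 = Z2; F2.transform([](float v) { return v > 0 ? v : 0; });
      // dropout
      fmat drop(100, nb);
      float keep = 1.0f - (float)net.dropout;
      for (uword i = 0; i < drop.n_elem; ++i)
        drop[i] = (u01(rng) < keep) ? 1.0f / keep : 0.0f;
      fmat F2d = F2 % drop;
      fmat Z3 = net.Wf3 * F2d; Z3.each_col() += net.bf3;
      // softmax + CE
      fmat P(NCLASS, nb);
      for (int b = 0; b < nb; ++b) {
        fvec z = Z3.col(b);
        z -= z.max();
        fvec e = exp(z);
        P.col(b) = e / accu(e);
        int y = train_labels[order[start + b]] - 1;
        float py = std::max(P(y, b), 1e-12f);
        loss_sum -= std::log(py);
        uword am = P.col(b).index_max();
        if ((int)am == y) ++correct;
      }
      seen += nb;
      // FC backward
      fmat dZ3 = P;
      for (int b = 0; b < nb; ++b) dZ3(train_labels[order[start + b]] - 1, b) -= 1.0f;
      dZ3 /= (float)nb;
      g.zero();
      g.Wf3 = dZ3 * F2d.t();
      g.bf3 = sum(dZ3, 1);
      fmat dF2 = (net.Wf3.t() * dZ3) % drop;
      dF2.elem(find(Z2 <= 0)).zeros();
      g.Wf2 = dF2 * F1.t();
      g.bf2 = sum(dF2, 1);
      fmat dF1 = net.Wf2.t() * dF2;
      dF1.elem(find(Z1 <= 0)).zeros();
      g.Wf1 = dF1 * A3v.t();
      g.bf1 = sum(dF1, 1);
      fmat dA3 = net.Wf1.t() * dF1;  // D x nb
      dA3 /= 1.0f;                   // gradient already averaged via dZ3
      // conv backward per image (dA3 scaled by 1; conv grads accumulate)
      for (int b = 0; b < nb; ++b) {
        ConvStore st = {&X0[(size_t)b * NPIX], &P1[(size_t)b * 16 * A1],
                        &M1[(size_t)b * 16 * A1], &M2[(size_t)b * 32 * A1],
                        &I1[(size_t)b * 16 * A1], &I2[(size_t)b * 32 * A2],
                        &P2[(size_t)b * 32 * A2]};
        conv_backward(net, st, tmp, A3.colptr(b), dA3.colptr(b), g);
      }
      float flr = (float)lr, fm = (float)momentum, fwd = (float)weight_decay;
      sgd_step(net.W1, net.V1, g.W1, flr, fm, fwd);
      sgd_step(net.b1, net.v1, g.b1, flr, fm, 0.0f);
      sgd_step(net.W2, net.V2, g.W2, flr, fm, fwd);
      sgd_step(net.b2, net.v2, g.b2, flr, fm, 0.0f);
      sgd_step(net.W3, net.V3, g.W3, flr, fm, fwd);
      sgd_step(net.b3, net.v3, g.b3, flr, fm, 0.0f);
      sgd_step(net.Wf1, net.Vf1, g.Wf1, flr, fm, fwd);
      sgd_step(net.bf1, net.vf1, g.bf1, flr, fm, 0.0f);
      sgd_step(net.Wf2, net.Vf2, g.Wf2, flr, fm, fwd);
      sgd_step(net.bf2, net.vf2, g.bf2, flr, fm, 0.0f);
      sgd_step(net.Wf3, net.Vf3, g.Wf3, flr, fm, fwd);
      sgd_step(net.bf3, net.vf3, g.bf3, flr, fm, 0.0f);
      Rcpp::checkUserInterrupt();
    }
    double tl = loss_sum / seen;
    if (!std::isfinite(tl)) {
      return List::create(_["diverged"] = true, _["epochs"] = ep + 1);
    }
    // validation accuracy
    int vc = 0;
    {
      IntegerVector vidx(nval);
      for (int i = 0; i < nval; ++i) vidx[i] = i + 1;
      fmat VS = forward_scores(net, vraw, vidx);
      for (int i = 0; i < nval; ++i)
        if ((int)VS.col(i).index_max() == val_labels[i] - 1) ++vc;
    }
    double vacc = (double)vc / nval, tacc = (double)correct / seen;
    h_loss[ep] = tl; h_tacc[ep] = tacc; h_vacc[ep] = vacc;
    epochs_run = ep + 1;
    if (verbose)
      Rcout << "epoch " << ep + 1 << "  loss " << tl << "  train "
            << tacc << "  val " << vacc << std::endl;
    if (vacc > best_val) {
      best_val = vacc;
      best_epoch = ep + 1;
      best_weights = cnn_get_weights(net_p);
      bad = 0;
    } else if (++bad >= patience) {
      stop_reason = "patience";
      break;
    }
    if (vacc >= val_stop) { stop_reason = "val_stop"; break; }
  }
  if (best_epoch > 0) cnn_set_weights(net_p, best_weights);
  return List::create(
      _["diverged"] = false, _["epochs"] = epochs_run,
      _["train_loss"] = h_loss, _["train_acc"] = h_tacc, _["val_acc"] = h_vacc,
      _["best_epoch"] = best_epoch, _["best_val_acc"] = best_val,
      _["stop_reason"] = stop_reason);
}

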