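// 3D residual CNN kernels: im2col + single-precision BLAS GEMM convolutions,
// manual backward pass, SGD training loop with early stopping on validation
// AUC, and the training-time geometric augmentation. All randomness comes
// from an explicitly seeded std::mt19937 so results are reproducible.
//
// Tensor conventions:
//  - a volume with C channels is an arma::fmat of size (n_voxels x C);
//    voxel index v = x + D0*(y + D1*z), i.e. x fastest, matching R arrays
//    with dim c(D0, D1, D2, C).
//  - conv weights are (27*C_in x F): tap-major, channel-minor ordering with
//    tap t = (dx+1) + 3*(dy+1) + 9*(dz+1), dx/dy/dz in {-1,0,1}.
//  - "SAME" padding with ceil-mode output sizes (ceil(D/stride)); when total
//    padding is odd the extra voxel goes on the high side.
//
// Samples are processed one at a time: the per-sample working set (the
// largest im2col matrix is ~27 MB) stays close to the cache hierarchy,
// which profiling showed beats batch-stacked GEMMs whose intermediates
// spill to main memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <map>
#include <array>
#include <vector>
#include <numeric>
#include <algorithm>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

// ---------------------------------------------------------------------------
// Convolution gather tables
// ---------------------------------------------------------------------------

struct ConvIndex {
  int in_d[3], out_d[3], stride;
  int n_in, n_out;
  std::vector<int> idx;  // 27 * n_out entries; -1 marks zero padding
};

static std::map<std::array<int, 4>, ConvIndex> g_idx_cache;

static const ConvIndex& conv_index(int d0, int d1, int d2, int stride) {
  std::array<int, 4> key = {d0, d1, d2, stride};
  auto it = g_idx_cache.find(key);
  if (it != g_idx_cache.end()) return it->second;
  ConvIndex ci;
  ci.in_d[0] = d0; ci.in_d[1] = d1; ci.in_d[2] = d2;
  ci.stride = stride;
  for (int a = 0; a < 3; a++) ci.out_d[a] = ceil_div(ci.in_d[a], stride);
  ci.n_in = d0 * d1 * d2;
  ci.n_out = ci.out_d[0] * ci.out_d[1] * ci.out_d[2];
  int pad[3];
  for (int a = 0; a < 3; a++) {
    int tot = std::max(0, (ci.out_d[a] - 1) * stride + 3 - ci.in_d[a]);
    pad[a] = tot / 2;  // low-side padding; remainder goes on the high side
  }
  ci.idx.assign(27 * (size_t)ci.n_out, -1);
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int t = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int* dst = ci.idx.data() + (size_t)t * ci.n_out;
        size_t o = 0;
        for (int oz = 0; oz < ci.out_d[2]; oz++) {
          int iz = oz * stride - pad[2] + (dz + 1);
          for (int oy = 0; oy < ci.out_d[1]; oy++) {
            int iy = oy * stride - pad[1] + (dy + 1);
            for (int ox = 0; ox < ci.out_d[0]; ox++) {
              int ix = ox * stride - pad[0] + (dx + 1);
              dst[o++] = (ix >= 0 && ix < d0 && iy >= 0 && iy < d1 &&
                          iz >= 0 && iz < d2)
                             ? (ix + d0 * (iy + (size_t)d1 * iz))
                             : -1;
            }
          }
        }
      }
  auto res = g_idx_cache.emplace(key, std::move(ci));
  return res.first->second;
}

static void im2col(const fmat& X, const ConvIndex& ci, fmat& cols) {
  const int C = X.n_cols;
  cols.set_size(ci.n_out, 27 * C);
  for (int t = 0; t < 27; t++) {
    const int* id = ci.idx.data() + (size_t)t * ci.n_out;
    for (int c = 0; c < C; c++) {
      const float* src = X.colptr(c);
      float* dst = cols.colptr((size_t)t * C + c);
      for (int o = 0; o < ci.n_out; o++) {
        int j = id[o];
        dst[o] = (j < 0) ? 0.0f : src[j];
      }
    }
  }
}

// Y = relu?(cols %*% W + b); cols is cached by the caller for the backward.
static void conv_fwd(const fmat& cols, const fmat& W, const fvec& b, fmat& Y,
                     bool relu) {
  Y = cols * W;
  Y.each_row() += b.t();
  if (relu) Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// Accumulates dW, db; optionally scatter-adds the input gradient into dX.
// `dcols` is a caller-owned scratch buffer reused across samples to avoid
// re-faulting tens of MB of freshly mapped pages on every backward pass.
static void conv_bwd(const ConvIndex& ci, const fmat& cols, const fmat& W,
                     const fmat& dY, fmat* dX, fmat& dW, fvec& db,
                     fmat& dcols) {
  dW += cols.t() * dY;
  db += arma::sum(dY, 0).t();
  if (dX) {
    dcols = dY * W.t();
    const int C = dX->n_cols;
    for (int t = 0; t < 27; t++) {
      const int* id = ci.idx.data() + (size_t)t * ci.n_out;
      for (int c = 0; c < C; c++) {
        const float* s = dcols.colptr((size_t)t * C + c);
        float* d = dX->colptr(c);
        for (int o = 0; o < ci.n_out; o++) {
          int j = id[o];
          if (j >= 0) d[j] += s[o];
        }
      }
    }
  }
}

static inline void relu_bwd_inplace(fmat& dY, const fmat& Ypost) {
  const float* y = Ypost.memptr();
  float* d = dY.memptr();
  const size_t n = dY.n_elem;
  for (size_t i = 0; i < n; i++)
    if (y[i] <= 0.0f) d[i] = 0.0f;
}

// ---------------------------------------------------------------------------
// Network parameters
// ---------------------------------------------------------------------------

// Conv layer order: 1a, 1b, s1, 2a, 2b, s2, 3a, 3b, s3.
static const char* kWNames[9] = {"W1a", "W1b", "Ws1", "W2a", "W2b",
                                 "Ws2", "W3a", "W3b", "Ws3"};
static const char* kBNames[9] = {"b1a", "b1b", "bs1", "b2a", "b2b",
                                 "bs2", "b3a", "b3b", "bs3"};

struct Weights {
  fmat W[9];
  fvec b[9];
  fvec wd;   // dense 64 -> 1
  float bd;
};

static Weights weights_from_list(const List& l) {
  Weights w;
  for (int i = 0; i < 9; i++) {
    w.W[i] = arma::conv_to<fmat>::from(as<arma::mat>(l[kWNames[i]]));
    w.b[i] = arma::conv_to<fvec>::from(as<arma::vec>(l[kBNames[i]]));
  }
  w.wd = arma::conv_to<fvec>::from(as<arma::vec>(l["Wd"]));
  w.bd = (float)as<double>(l["bd"]);
  return w;
}

static List weights_to_list(const Weights& w) {
  List l;
  for (int i = 0; i < 9; i++) {
    l[kWNames[i]] = wrap(arma::conv_to<arma::mat>::from(w.W[i]));
    l[kBNames[i]] = wrap(arma::conv_to<arma::vec>::from(w.b[i]));
  }
  l["Wd"] = wrap(arma::conv_to<arma::vec>::from(w.wd));
  l["bd"] = (double)w.bd;
  return l;
}

struct Grads {
  fmat W[9];
  fvec b[9];
  fvec wd;
  float bd;
  void zero_like(const Weights& w) {
    for (int i = 0; i < 9; i++) {
      W[i].zeros(w.W[i].n_rows, w.W[i].n_cols);
      b[i].zeros(w.b[i].n_elem);
    }
    wd.zeros(w.wd.n_elem);
    bd = 0.0f;
  }
};

// [[Rcpp::export]]
List cpp_init_weights(int in_channels, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  const int F[9] = {16, 16, 1, 32, 32, 1, 64, 64, 1};
  const int Cin[9] = {in_channels, 16, in_channels, 16, 32, 16, 32, 64, 32};
  Weights w;
  for (int i = 0; i < 9; i++) {
    int fan_in = 27 * Cin[i];
    double sd = std::sqrt(2.0 / fan_in);  // He-normal for rectifier layers
    w.W[i].set_size(fan_in, F[i]);
    for (arma::uword j = 0; j < w.W[i].n_elem; j++)
      w.W[i](j) = (float)(sd * nd(rng));
    w.b[i].zeros(F[i]);
  }
  double sd = std::sqrt(1.0 / 64.0);
  w.wd.set_size(64);
  for (int j = 0; j < 64; j++) w.wd(j) = (float)(sd * nd(rng));
  w.bd = 0.0f;
  return weights_to_list(w);
}

// ---------------------------------------------------------------------------
// Forward / backward (one sample at a time)
// ---------------------------------------------------------------------------

struct Cache {
  fmat cols[9];
  fmat A1, B1, R1, A2, B2, R2, A3, B3, R3;
  fvec s1o, s2o, s3o;
  fvec pooled, dropmask;
  float logit, score;
  // backward scratch, reused across samples
  fmat dR3, dB3, dA3, dR2, dB2, dA2, dR1, dB1, dA1;
  fmat dc[9], xin;
};

// One-sample forward. X0 is (n_vox x C) with cubic side `d0`.
// When `train` is true, dropout draws come from `rng`.
static void forward_sample(const Weights& w, const fmat& X0, int d0,
                           bool train, float drop, std::mt19937& rng,
                           Cache& cc) {
  const ConvIndex& i1 = conv_index(d0, d0, d0, 2);
  const int d1 = i1.out_d[0];
  const ConvIndex& i1s = conv_index(d1, d1, d1, 1);
  const ConvIndex& i2 = conv_index(d1, d1, d1, 2);
  const int d2 = i2.out_d[0];
  const ConvIndex& i2s = conv_index(d2, d2, d2, 1);
  const ConvIndex& i3 = conv_index(d2, d2, d2, 2);
  const int d3 = i3.out_d[0];
  const ConvIndex& i3s = conv_index(d3, d3, d3, 1);

  im2col(X0, i1, cc.cols[0]);
  conv_fwd(cc.cols[0], w.W[0], w.b[0], cc.A1, true);
  im2col(cc.A1, i1s, cc.cols[1]);
  conv_fwd(cc.cols[1], w.W[1], w.b[1], cc.B1, true);
  // the shortcut shares the block input's strided im2col columns
  cc.s1o = cc.cols[0] * w.W[2] + w.b[2](0);
  cc.R1 = cc.B1;
  cc.R1.each_col() += cc.s1o;

  im2col(cc.R1, i2, cc.cols[3]);
  conv_fwd(cc.cols[3], w.W[3], w.b[3], cc.A2, true);
  im2col(cc.A2, i2s, cc.cols[4]);
  conv_fwd(cc.cols[4], w.W[4], w.b[4], cc.B2, true);
  cc.s2o = cc.cols[3] * w.W[5] + w.b[5](0);
  cc.R2 = cc.B2;
  cc.R2.each_col() += cc.s2o;

  im2col(cc.R2, i3, cc.cols[6]);
  conv_fwd(cc.cols[6], w.W[6], w.b[6], cc.A3, true);
  im2col(cc.A3, i3s, cc.cols[7]);
  conv_fwd(cc.cols[7], w.W[7], w.b[7], cc.B3, true);
  cc.s3o = cc.cols[6] * w.W[8] + w.b[8](0);
  cc.R3 = cc.B3;
  cc.R3.each_col() += cc.s3o;

  cc.pooled = arma::mean(cc.R3, 0).t();  // global average pooling -> 64
  cc.dropmask.ones(64);
  if (train && drop > 0.0f) {
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    for (int k = 0; k < 64; k++)
      cc.dropmask(k) = (ud(rng) < drop) ? 0.0f : 1.0f / (1.0f - drop);
  }
  fvec pd = cc.pooled % cc.dropmask;
  cc.logit = arma::dot(w.wd, pd) + w.bd;
  if (!std::isfinite(cc.logit))
    stop("non-finite activation at the fully connected output layer");
  cc.score = 1.0f / (1.0f + std::exp(-cc.logit));
}

// Backward for one sample given dLoss/dlogit. Input gradients for the
// first block's input are not needed and are skipped.
static void backward_sample(const Weights& w, Cache& cc, int d0,
                            float dlogit, Grads& g) {
  const ConvIndex& i1 = conv_index(d0, d0, d0, 2);
  const int d1 = i1.out_d[0];
  const ConvIndex& i1s = conv_index(d1, d1, d1, 1);
  const ConvIndex& i2 = conv_index(d1, d1, d1, 2);
  const int d2 = i2.out_d[0];
  const ConvIndex& i2s = conv_index(d2, d2, d2, 1);
  const ConvIndex& i3 = conv_index(d2, d2, d2, 2);
  const int d3 = i3.out_d[0];
  const ConvIndex& i3s = conv_index(d3, d3, d3, 1);
  const int n3 = d3 * d3 * d3;

  fvec pd = cc.pooled % cc.dropmask;
  g.wd += pd * dlogit;
  g.bd += dlogit;
  fvec dp = (w.wd * dlogit) % cc.dropmask / (float)n3;

  cc.dR3.set_size(n3, 64);
  for (int k = 0; k < 64; k++) cc.dR3.col(k).fill(dp(k));

  fvec ds3 = arma::sum(cc.dR3, 1);
  cc.dB3 = cc.dR3;
  relu_bwd_inplace(cc.dB3, cc.B3);
  cc.dA3.zeros(cc.A3.n_rows, cc.A3.n_cols);
  conv_bwd(i3s, cc.cols[7], w.W[7], cc.dB3, &cc.dA3, g.W[7], g.b[7],
           cc.dc[0]);
  relu_bwd_inplace(cc.dA3, cc.A3);
  cc.dR2.zeros(cc.R2.n_rows, cc.R2.n_cols);
  conv_bwd(i3, cc.cols[6], w.W[6], cc.dA3, &cc.dR2, g.W[6], g.b[6],
           cc.dc[1]);
  conv_bwd(i3, cc.cols[6], w.W[8], fmat(ds3), &cc.dR2, g.W[8], g.b[8],
           cc.dc[2]);

  fvec ds2 = arma::sum(cc.dR2, 1);
  cc.dB2 = cc.dR2;
  relu_bwd_inplace(cc.dB2, cc.B2);
  cc.dA2.zeros(cc.A2.n_rows, cc.A2.n_cols);
  conv_bwd(i2s, cc.cols[4], w.W[4], cc.dB2, &cc.dA2, g.W[4], g.b[4],
           cc.dc[3]);
  relu_bwd_inplace(cc.dA2, cc.A2);
  cc.dR1.zeros(cc.R1.n_rows, cc.R1.n_cols);
  conv_bwd(i2, cc.cols[3], w.W[3], cc.dA2, &cc.dR1, g.W[3], g.b[3],
           cc.dc[4]);
  conv_bwd(i2, cc.cols[3], w.W[5], fmat(ds2), &cc.dR1, g.W[5], g.b[5],
           cc.dc[5]);

  fvec ds1 = arma::sum(cc.dR1, 1);
  cc.dB1 = cc.dR1;
  relu_bwd_inplace(cc.dB1, cc.B1);
  cc.dA1.zeros(cc.A1.n_rows, cc.A1.n_cols);
  conv_bwd(i1s, cc.cols[1], w.W[1], cc.dB1, &cc.dA1, g.W[1], g.b[1],
           cc.dc[6]);
  relu_bwd_inplace(cc.dA1, cc.A1);
  conv_bwd(i1, cc.cols[0], w.W[0], cc.dA1, nullptr, g.W[0], g.b[0],
           cc.dc[7]);
  conv_bwd(i1, cc.cols[0], w.W[2], fmat(ds1), nullptr, g.W[2], g.b[2],
           cc.dc[8]);
}

// ---------------------------------------------------------------------------
// Augmentation
// ---------------------------------------------------------------------------

// Random out^3 crop from the context cube, then independent axis flips
// (p = 0.5 each), then a 90-degree-multiple rotation in a random axis pair.
// Draw order: crop origins (x,y,z), flips (x,y,z), axis pair, quarter turns.
static fmat augment_sample(const fmat& X, int D, int out, std::mt19937& rng) {
  const int C = X.n_cols;
  std::uniform_int_distribution<int> dcrop(0, D - out);
  int o0 = dcrop(rng), o1 = dcrop(rng), o2 = dcrop(rng);
  std::uniform_int_distribution<int> dbit(0, 1);
  int f0 = dbit(rng), f1 = dbit(rng), f2 = dbit(rng);
  std::uniform_int_distribution<int> dpair(0, 2);
  int pr = dpair(rng);  // 0: (x,y), 1: (x,z), 2: (y,z)
  std::uniform_int_distribution<int> dk(0, 3);
  int k = dk(rng);

  fmat Y((size_t)out * out * out, C);
  const int n = out;
  for (int c = 0; c < C; c++) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    size_t o = 0;
    for (int z = 0; z < n; z++)
      for (int y = 0; y < n; y++)
        for (int x = 0; x < n; x++) {
          // invert rotation: forward maps (i,j) -> (j, n-1-i) in the pair
          int cx = x, cy = y, cz = z;
          for (int r = 0; r < k; r++) {
            int a, b;
            if (pr == 0)      { a = cx; b = cy; cx = n - 1 - b; cy = a; }
            else if (pr == 1) { a = cx; b = cz; cx = n - 1 - b; cz = a; }
            else              { a = cy; b = cz; cy = n - 1 - b; cz = a; }
          }
          if (f0) cx = n - 1 - cx;
          if (f1) cy = n - 1 - cy;
          if (f2) cz = n - 1 - cz;
          dst[o++] = src[(o0 + cx) +
                         (size_t)D * ((o1 + cy) + (size_t)D * (o2 + cz))];
        }
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_augment(NumericVector x, int seed, int out_size) {
  IntegerVector dims(x.attr("dim"));
  if (dims.size() != 4) stop("expected a (D, D, D, C) array");
  int D = dims[0], C = dims[3];
  if (dims[1] != D || dims[2] != D) stop("context grid must be cubic");
  if (D < out_size) stop("context grid smaller than the requested crop");
  fmat X((size_t)D * D * D, C);
  const double* p = x.begin();
  for (arma::uword i = 0; i < X.n_elem; i++) X(i) = (float)p[i];
  std::mt19937 rng((unsigned)seed);
  fmat Y = augment_sample(X, D, out_size, rng);
  NumericVector out(Y.n_elem);
  for (arma::uword i = 0; i < Y.n_elem; i++) out[i] = (double)Y(i);
  out.attr("dim") = IntegerVector::create(out_size, out_size, out_size, C);
  return out;
}

// ---------------------------------------------------------------------------
// Batch forward (evaluation / feature extraction)
// ---------------------------------------------------------------------------

static std::vector<fmat> split_samples(NumericVector x, int* d_out,
                                       int* c_out) {
  IntegerVector dims(x.attr("dim"));
  if (dims.size() != 5) stop("expected a (D, D, D, C, N) array");
  int D = dims[0], C = dims[3], N = dims[4];
  if (dims[1] != D || dims[2] != D) stop("input grid must be cubic");
  size_t nv = (size_t)D * D * D;
  std::vector<fmat> out(N);
  const double* p = x.begin();
  for (int i = 0; i < N; i++) {
    out[i].set_size(nv, C);
    const double* q = p + (size_t)i * nv * C;
    for (size_t j = 0; j < nv * C; j++) out[i](j) = (float)q[j];
  }
  *d_out = D;
  *c_out = C;
  return out;
}

// [[Rcpp::export]]
List cpp_forward(List weights, NumericVector x, bool training = false,
                 double dropout = 0.0, int seed = 0,
                 bool return_features = false) {
  Weights w = weights_from_list(weights);
  int D, C;
  std::vector<fmat> xs = split_samples(x, &D, &C);
  if ((int)w.W[0].n_rows != 27 * C)
    stop("input has %d channel(s) but the network expects %d", C,
         (int)w.W[0].n_rows / 27);
  int N = xs.size();
  std::mt19937 rng((unsigned)seed);
  NumericVector scores(N), logits(N);
  NumericVector feats;
  NumericMatrix pooled(64, N);
  int d3 = ceil_div(ceil_div(ceil_div(D, 2), 2), 2);
  int n3 = d3 * d3 * d3;
  if (return_features) {
    feats = NumericVector((size_t)n3 * 64 * N);
    feats.attr("dim") = IntegerVector::create(d3, d3, d3, 64, N);
  }
  Cache cc;
  for (int i = 0; i < N; i++) {
    forward_sample(w, xs[i], D, training, (float)dropout, rng, cc);
    scores[i] = cc.score;
    logits[i] = cc.logit;
    for (int k = 0; k < 64; k++) pooled(k, i) = cc.pooled(k);
    if (return_features) {
      double* f = feats.begin() + (size_t)i * n3 * 64;
      for (size_t j = 0; j < (size_t)n3 * 64; j++) f[j] = cc.R3(j);
    }
  }
  List out = List::create(_["scores"] = scores, _["logits"] = logits,
                          _["pooled"] = pooled);
  if (return_features) out["features"] = feats;
  return out;
}

// ---------------------------------------------------------------------------
// Data-dependent bias centering (LSUV-style initialisation)
// ---------------------------------------------------------------------------

// LSUV-style data-dependent initialisation: processed sequentially through
// the network on a reference batch, every convolution's weights are scaled
// to unit pre-activation variance and its bias set for zero pre-activation
// mean; finally the last block is rescaled so the pooled feature vector has
// unit between-sample spread. Without normalisation layers, rectified
// activations otherwise accumulate large means and tiny between-sample
// variance, leaving SGD on a hopelessly ill-conditioned plateau.
// [[Rcpp::export]]
List cpp_center_init(List weights, NumericVector x) {
  Weights w = weights_from_list(weights);
  int D, C;
  std::vector<fmat> xs = split_samples(x, &D, &C);
  if ((int)w.W[0].n_rows != 27 * C)
    stop("input has %d channel(s) but the network expects %d", C,
         (int)w.W[0].n_rows / 27);
  const int M = xs.size();
  const ConvIndex& i1 = conv_index(D, D, D, 2);
  const int d1 = i1.out_d[0];
  const ConvIndex& i1s = conv_index(d1, d1, d1, 1);
  const ConvIndex& i2 = conv_index(d1, d1, d1, 2);
  const int d2 = i2.out_d[0];
  const ConvIndex& i2s = conv_index(d2, d2, d2, 1);
  const ConvIndex& i3 = conv_index(d2, d2, d2, 2);
  const int d3 = i3.out_d[0];
  const ConvIndex& i3s = conv_index(d3, d3, d3, 1);

  // one block step: centre conv a (stride 2), conv b (stride 1) and the
  // shortcut on the pooled statistics of the whole reference batch
  // scale one conv layer's weights to unit pre-activation sd and centre
  // its bias, given the raw pre-activations z over the reference batch
  auto standardise = [&](std::vector<fmat>& z, int wi) {
    const int F = w.W[wi].n_cols;
    arma::frowvec mu(F, arma::fill::zeros), m2(F, arma::fill::zeros);
    double tot = 0;
    for (int m = 0; m < M; m++) {
      mu += arma::sum(z[m], 0);
      m2 += arma::sum(arma::square(z[m]), 0);
      tot += z[m].n_rows;
    }
    mu /= (float)tot;
    // floor the sd so degenerate (near-constant) directions are not blown
    // up by the normalisation
    arma::frowvec sd =
        arma::sqrt(arma::clamp(m2 / (float)tot - arma::square(mu),
                               2.5e-3f, arma::datum::inf));
    for (int k = 0; k < F; k++) {
      w.W[wi].col(k) /= sd(k);
      w.b[wi](k) = -mu(k) / sd(k);
    }
    for (int m = 0; m < M; m++) {
      z[m].each_row() /= sd;
      z[m].each_row() += w.b[wi].t();
    }
  };

  auto centre_block = [&](std::vector<fmat>& in, const ConvIndex& ia,
                          const ConvIndex& ib, int wa, int wb, int ws)
      -> std::vector<fmat> {
    fmat cols;
    std::vector<fmat> za(M), so(M);
    for (int m = 0; m < M; m++) {
      im2col(in[m], ia, cols);
      za[m] = cols * w.W[wa];
      so[m] = cols * w.W[ws];
    }
    standardise(za, wa);
    standardise(so, ws);
    for (int m = 0; m < M; m++)
      za[m].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    std::vector<fmat> zb(M);
    for (int m = 0; m < M; m++) {
      im2col(za[m], ib, cols);
      zb[m] = cols * w.W[wb];
    }
    standardise(zb, wb);
    for (int m = 0; m < M; m++) {
      zb[m].transform([](float v) { return v > 0.0f ? v : 0.0f; });
      zb[m].each_col() += fvec(so[m].col(0));
    }
    return zb;
  };

  std::vector<fmat> r1 = centre_block(xs, i1, i1s, 0, 1, 2);
  std::vector<fmat> r2 = centre_block(r1, i2, i2s, 3, 4, 5);
  std::vector<fmat> r3 = centre_block(r2, i3, i3s, 6, 7, 8);

  // rescale the last block so the pooled features have unit between-sample
  // spread: global average pooling otherwise leaves them orders of
  // magnitude too flat for a logistic head with O(1) weights
  fmat pooled(M, 64);
  for (int m = 0; m < M; m++) pooled.row(m) = arma::mean(r3[m], 0);
  float psd = arma::mean(arma::stddev(pooled, 0, 0).t());
  if (M > 1 && psd > 1e-8f) {
    float c = std::min(1.0f / psd, 100.0f);
    w.W[7] *= c; w.b[7] *= c;   // conv 3b
    w.W[8] *= c; w.b[8] *= c;   // shortcut 3
    pooled *= c;
  }

  // centre the logit via the dense bias
  double mu_z = 0.0;
  for (int m = 0; m < M; m++)
    mu_z += arma::dot(w.wd, pooled.row(m).t());
  w.bd = -(float)(mu_z / M);
  return weights_to_list(w);
}

// ---------------------------------------------------------------------------
// Training loop
// ---------------------------------------------------------------------------

static double auc_midrank(const std::vector<double>& s,
                          const std::vector<int>& y) {
  int n = s.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && s[ord[j]] == s[ord[i]]) j++;
    double r = (i + j + 1) / 2.0;  // midrank of ranks i+1 .. j
    for (int k = i; k < j; k++) rank[ord[k]] = r;
    i = j;
  }
  double sum1 = 0.0, n1 = 0.0;
  for (int k = 0; k < n; k++)
    if (y[k] == 1) { sum1 += rank[k]; n1 += 1.0; }
  double n0 = n - n1;
  if (n1 == 0.0 || n0 == 0.0) stop("AUC undefined: single-class labels");
  return (sum1 - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// [[Rcpp::export]]
List cpp_train_member(List weights, NumericVector x_train,
                      IntegerVector y_train, NumericVector x_val,
                      IntegerVector y_val, List params, int seed) {
  Weights w = weights_from_list(weights);
  int Dtr, Ctr, Dv, Cv;
  std::vector<fmat> xs = split_samples(x_train, &Dtr, &Ctr);
  std::vector<fmat> xv = split_samples(x_val, &Dv, &Cv);
  if (Ctr != Cv) stop("train/validation channel mismatch");
  if ((int)w.W[0].n_rows != 27 * Ctr)
    stop("input has %d channel(s) but the network expects %d", Ctr,
         (int)w.W[0].n_rows / 27);
  const int Ntr = xs.size(), Nv = xv.size();

  const double lr = as<double>(params["learning_rate"]);
  const double momentum = as<double>(params["momentum"]);
  const bool use_adam = params.containsElementNamed("optimizer") &&
                        as<std::string>(params["optimizer"]) == "adam";
  const int batch_size = as<int>(params["batch_size"]);
  const int max_epochs = as<int>(params["max_epochs"]);
  const int patience = as<int>(params["patience_epochs"]);
  const float drop = (float)as<double>(params["dropout_rate"]);
  const bool augment = as<bool>(params["augment"]);
  const double clip_norm = params.containsElementNamed("clip_norm")
                               ? as<double>(params["clip_norm"])
                               : 0.0;  // 0 disables clipping
  const float wdecay = params.containsElementNamed("weight_decay")
                           ? (float)as<double>(params["weight_decay"])
                           : 0.0f;  // decoupled L2 on conv/dense weights

  std::vector<int> ytr(y_train.begin(), y_train.end());
  std::vector<int> yv(y_val.begin(), y_val.end());

  std::mt19937 rng((unsigned)seed);
  Grads g, v, adam_m, adam_v;
  v.zero_like(w);
  if (use_adam) {
    adam_m.zero_like(w);
    adam_v.zero_like(w);
  }
  long adam_t = 0;
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  Cache cc;

  const int crop_off = (Dtr - 50) / 2;

  std::vector<double> hist_loss, hist_auc, hist_gnorm;
  Weights best = w;
  double best_auc = -1.0;
  int best_epoch = 0, since_best = 0, epochs_run = 0;

  std::vector<int> order(Ntr);
  std::iota(order.begin(), order.end(), 0);

  for (int epoch = 1; epoch <= max_epochs; epoch++) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0, epoch_gnorm = 0.0;
    int n_batches = 0;
    int pos = 0;
    while (pos < Ntr) {
      int bn = std::min(batch_size, Ntr - pos);
      g.zero_like(w);
      for (int bi = 0; bi < bn; bi++) {
        int s = order[pos + bi];
        fmat xin;
        if (augment) {
          xin = augment_sample(xs[s], Dtr, 50, rng);
        } else if (Dtr > 50) {
          // deterministic centre crop when the stored grid is larger
          xin.set_size((size_t)50 * 50 * 50, Ctr);
          for (int c = 0; c < Ctr; c++) {
            const float* src = xs[s].colptr(c);
            float* dst = xin.colptr(c);
            size_t o = 0;
            for (int z = 0; z < 50; z++)
              for (int y = 0; y < 50; y++)
                for (int x = 0; x < 50; x++)
                  dst[o++] = src[(crop_off + x) +
                                 (size_t)Dtr * ((crop_off + y) +
                                                (size_t)Dtr * (crop_off + z))];
          }
        } else {
          xin = xs[s];
        }
        forward_sample(w, xin, 50, true, drop, rng, cc);
        float sc = std::min(std::max(cc.score, 1e-7f), 1.0f - 1e-7f);
        float yy = (float)ytr[s];
        epoch_loss += -(yy * std::log(sc) + (1.0f - yy) * std::log(1.0f - sc));
        backward_sample(w, cc, 50, cc.score - yy, g);
      }
      float inv = 1.0f / bn;
      double ss = 0.0;
      for (int i = 0; i < 9; i++)
        ss += arma::dot(g.W[i], g.W[i]) + arma::dot(g.b[i], g.b[i]);
      ss += arma::dot(g.wd, g.wd) + (double)g.bd * g.bd;
      double nrm = std::sqrt(ss) * inv;
      epoch_gnorm += nrm;
      n_batches++;
      if (clip_norm > 0.0 && nrm > clip_norm)
        inv *= (float)(clip_norm / nrm);  // clip the batch-mean gradient
      if (wdecay > 0.0f) {
        float sh = 1.0f - (float)lr * wdecay;
        for (int i = 0; i < 9; i++) w.W[i] *= sh;
        w.wd *= sh;
      }
      if (use_adam) {
        adam_t++;
        float bc1 = 1.0f - std::pow(b1, (float)adam_t);
        float bc2 = 1.0f - std::pow(b2, (float)adam_t);
        float step = (float)lr * std::sqrt(bc2) / bc1;
        auto upd = [&](fmat& wt, fmat& gm, fmat& mm, fmat& vv) {
          mm = b1 * mm + (1.0f - b1) * (gm * inv);
          vv = b2 * vv + (1.0f - b2) * arma::square(gm * inv);
          wt -= step * mm / (arma::sqrt(vv) + eps);
        };
        for (int i = 0; i < 9; i++) {
          upd(w.W[i], g.W[i], adam_m.W[i], adam_v.W[i]);
          fmat bw(w.b[i]), bg(g.b[i]), bm(adam_m.b[i]), bv(adam_v.b[i]);
          upd(bw, bg, bm, bv);
          w.b[i] = bw.col(0); adam_m.b[i] = bm.col(0); adam_v.b[i] = bv.col(0);
        }
        fmat dw(w.wd), dg(g.wd), dm(adam_m.wd), dv(adam_v.wd);
        upd(dw, dg, dm, dv);
        w.wd = dw.col(0); adam_m.wd = dm.col(0); adam_v.wd = dv.col(0);
        adam_m.bd = b1 * adam_m.bd + (1.0f - b1) * (g.bd * inv);
        adam_v.bd = b2 * adam_v.bd + (1.0f - b2) * (g.bd * inv) * (g.bd * inv);
        w.bd -= step * adam_m.bd / (std::sqrt(adam_v.bd) + eps);
      } else {
        for (int i = 0; i < 9; i++) {
          v.W[i] = (float)momentum * v.W[i] + g.W[i] * inv;
          w.W[i] -= (float)lr * v.W[i];
          v.b[i] = (float)momentum * v.b[i] + g.b[i] * inv;
          w.b[i] -= (float)lr * v.b[i];
        }
        v.wd = (float)momentum * v.wd + g.wd * inv;
        w.wd -= (float)lr * v.wd;
        v.bd = (float)momentum * v.bd + g.bd * inv;
        w.bd -= (float)lr * v.bd;
      }
      pos += bn;
    }
    epoch_loss /= Ntr;

    std::vector<double> vs(Nv);
    for (int i = 0; i < Nv; i++) {
      forward_sample(w, xv[i], Dv, false, 0.0f, rng, cc);
      vs[i] = cc.score;
    }
    double auc = auc_midrank(vs, yv);
    hist_loss.push_back(epoch_loss);
    hist_auc.push_back(auc);
    hist_gnorm.push_back(epoch_gnorm / n_batches);
    epochs_run = epoch;

    if (auc > best_auc) {  // strict improvement resets the patience counter
      best_auc = auc;
      best = w;
      best_epoch = epoch;
      since_best = 0;
    } else {
      since_best++;
      if (since_best >= patience) break;
    }
    if (epoch % 5 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["weights"] = weights_to_list(best),
      _["train_loss"] = wrap(hist_loss), _["val_auc"] = wrap(hist_auc),
      _["grad_norm"] = wrap(hist_gnorm),
      _["best_epoch"] = best_epoch, _["epochs_run"] = epochs_run,
      _["best_val_auc"] = best_auc,
      _["stopped_early"] = (epochs_run < max_epochs));
}
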