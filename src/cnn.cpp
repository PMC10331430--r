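// Small residual convolutional network for the original-vs-augmented
// pretext task. Each unit is conv 3x3 (pad 1) -> BatchNorm -> ReLU;
// stages open with maxpool-2 (plus a projection conv when the width
// changes) and contain identity residual blocks
// (conv-BN-ReLU-conv-BN, + skip, ReLU). Global average pooling feeds a
// fully connected projection head with 2 logits.
//
// BatchNorm running statistics are frozen at inference, making every
// embedding a fixed function of its image (batch-size invariant) that
// stays sensitive to out-of-distribution activations — the property the
// KDE anomaly score depends on.
//
// The whole minibatch is processed jointly: activations live in one fcube
// of H x W x (n_images * channels) and every convolution is a single GEMM
// over the batch-concatenated im2col matrix (transposed layout, so the
// im2col writes are contiguous). Single precision throughout; the R driver
// owns initialization and SGD updates, this file computes forward passes
// and exact gradients.
//
// Canonical parameter order (flat list):
//   per conv (stem; per stage: [projection], per block: conv1, conv2):
//     W (Cout x Cin*9), gamma (Cout), beta (Cout)
//   per head FC layer: W (out x in), b (out)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;   // EMA weight of the fresh batch stat

struct Plan {
  int S, stem_c;
  std::vector<int> widths, blocks, head;
  int n_stages() const { return (int)widths.size(); }
  int n_convs() const {
    int c = 1, cin = stem_c;
    for (int s = 0; s < n_stages(); ++s) {
      if (cin != widths[s]) { ++c; cin = widths[s]; }
      c += 2 * blocks[s];
    }
    return c;
  }
};

static Plan parse_plan(const Rcpp::List& config) {
  Plan p;
  p.S = Rcpp::as<int>(config["image_size"]);
  p.stem_c = Rcpp::as<int>(config["stem_channels"]);
  p.widths = Rcpp::as<std::vector<int>>(config["widths"]);
  p.blocks = Rcpp::as<std::vector<int>>(config["blocks"]);
  p.head = Rcpp::as<std::vector<int>>(config["head_dims"]);
  int s = p.S;
  for (size_t i = 0; i < p.widths.size(); ++i) {
    if (s % 2 != 0) Rcpp::stop("image size not divisible by 2 at stage %d", (int)i + 1);
    s /= 2;
  }
  if (p.head.back() != 2) Rcpp::stop("head must end in 2 logits");
  return p;
}

struct Params {
  std::vector<fmat> convW;
  std::vector<fvec> gamma, beta;
  std::vector<fmat> fcW;
  std::vector<fvec> fcb;
};

static Params parse_params(const Rcpp::List& params, const Plan& P) {
  Params q;
  int nc = P.n_convs(), nf = (int)P.head.size();
  if ((int)params.size() != 3 * nc + 2 * nf)
    Rcpp::stop("parameter list length %d does not match plan (%d expected)",
               (int)params.size(), 3 * nc + 2 * nf);
  int k = 0;
  for (int i = 0; i < nc; ++i) {
    q.convW.push_back(Rcpp::as<fmat>(params[k++]));
    q.gamma.push_back(Rcpp::as<fvec>(params[k++]));
    q.beta.push_back(Rcpp::as<fvec>(params[k++]));
  }
  for (int i = 0; i < nf; ++i) {
    q.fcW.push_back(Rcpp::as<fmat>(params[k++]));
    q.fcb.push_back(Rcpp::as<fvec>(params[k++]));
  }
  return q;
}

static inline float relu1(float v) { return v > 0 ? v : 0.0f; }

// Batched im2col for 3x3 kernels, zero padding 1. x holds n images of C
// channels as slices [img*C + c]. Result: (n*H*W) x (C*9), row index
// img*HW + j*H + i, so each (c,dr,dc) feature is one contiguous column.
static fmat im2colT(const fcube& x, int C, int n) {
  int H = x.n_rows, W = x.n_cols;
  size_t HW = (size_t)H * W;
  fmat cols((size_t)n * HW, (size_t)C * 9, fill::zeros);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < C; ++c) {
      const fmat& sl = x.slice(img * C + c);
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int k = c * 9 + (dr + 1) * 3 + (dc + 1);
          float* dst0 = cols.colptr(k) + img * HW;
          int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
          for (int j = 0; j < W; ++j) {
            int js = j + dc;
            if (js < 0 || js >= W) continue;
            const float* src = sl.colptr(js) + dr;
            std::copy(src + i0, src + i1, dst0 + (size_t)j * H + i0);
          }
        }
    }
  return cols;
}

static fcube col2imT(const fmat& dcols, int H, int W, int C, int n) {
  size_t HW = (size_t)H * W;
  fcube dx(H, W, (size_t)n * C, fill::zeros);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < C; ++c) {
      fmat& sl = dx.slice(img * C + c);
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          int k = c * 9 + (dr + 1) * 3 + (dc + 1);
          const float* src0 = dcols.colptr(k) + img * HW;
          int i0 = std::max(0, -dr), i1 = std::min(H, H - dr);
          for (int j = 0; j < W; ++j) {
            int js = j + dc;
            if (js < 0 || js >= W) continue;
            float* dst = sl.colptr(js) + dr;
            const float* src = src0 + (size_t)j * H;
            for (int i = i0; i < i1; ++i) dst[i] += src[i];
          }
        }
    }
  return dx;
}

struct Tape {
  std::vector<fmat> cols;      // per conv: batched im2col of its input
  std::vector<fcube> unit_out; // per conv unit: output after BN (+ReLU?)
  std::vector<fcube> xhat;     // per conv unit: normalized pre-scale values
  std::vector<fvec> sinv;      // per unit: 1/sd per channel (batch stats)
  std::vector<fcube> skip;     // per residual block: block input
  std::vector<fcube> resout;   // per residual block: post add+ReLU
  std::vector<umat> poolarg;
  std::vector<int> poolH, poolW;
  std::vector<fmat> fc_in, fc_act;
  int gapH, gapW;
};

struct BNStats {
  std::vector<fvec> rmean, rvar;  // running statistics per conv unit
};

// conv -> BatchNorm -> optional ReLU, one tape entry per conv unit.
// Training mode normalizes with the current batch's per-channel statistics
// (over images and space) and updates the running averages; eval mode uses
// the frozen running statistics, so inference is a fixed affine transform
// per channel — batch-size invariant and sensitive to out-of-distribution
// activations, which is what the anomaly score relies on.
static fcube unit_fwd(int ci, const Params& q, const Plan& P, const fcube& x,
                      int n, bool relu, bool train, BNStats& bn, Tape& t) {
  int H = x.n_rows, Wd = x.n_cols;
  int Cin = x.n_slices / n, Cout = q.convW[ci].n_rows;
  size_t HW = (size_t)H * Wd;
  fmat colsT = im2colT(x, Cin, n);
  fmat outT = colsT * q.convW[ci].t();    // (n*HW) x Cout
  fcube y(H, Wd, (size_t)n * Cout);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < Cout; ++c) {
      const float* src = outT.colptr(c) + img * HW;
      std::copy(src, src + HW, y.slice(img * Cout + c).memptr());
    }
  fcube xh(H, Wd, (size_t)n * Cout);
  fvec sinv(Cout);
  size_t nel = (size_t)n * HW;
  for (int c = 0; c < Cout; ++c) {
    double mu, var;
    if (train) {
      double sum = 0, sum2 = 0;
      for (int img = 0; img < n; ++img) {
        const fmat& sl = y.slice(img * Cout + c);
        sum += accu(conv_to<mat>::from(sl));
        sum2 += accu(conv_to<mat>::from(square(sl)));
      }
      mu = sum / nel;
      var = std::max(sum2 / nel - mu * mu, 0.0);
      bn.rmean[ci](c) = (1 - BN_MOMENTUM) * bn.rmean[ci](c) +
                        BN_MOMENTUM * (float)mu;
      bn.rvar[ci](c) = (1 - BN_MOMENTUM) * bn.rvar[ci](c) +
                       BN_MOMENTUM * (float)var;
    } else {
      mu = bn.rmean[ci](c);
      var = bn.rvar[ci](c);
    }
    float si = 1.0f / std::sqrt((float)var + BN_EPS);
    sinv(c) = si;
    for (int img = 0; img < n; ++img) {
      int sc = img * Cout + c;
      xh.slice(sc) = (y.slice(sc) - (float)mu) * si;
    }
  }
  fcube out(H, Wd, (size_t)n * Cout);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < Cout; ++c) {
      int sc = img * Cout + c;
      out.slice(sc) = xh.slice(sc) * q.gamma[ci](c) + q.beta[ci](c);
      if (relu) out.slice(sc).transform(relu1);
    }
  t.cols.push_back(std::move(colsT));
  t.xhat.push_back(std::move(xh));
  t.sinv.push_back(std::move(sinv));
  t.unit_out.push_back(out);
  return out;
}

struct Grads {
  std::vector<fmat> convW;
  std::vector<fvec> gamma, beta;
  std::vector<fmat> fcW;
  std::vector<fvec> fcb;
};

// Backward through BN (batch mode) and conv of unit ci. dout is the
// gradient at the unit's output *after* the caller applied any ReLU mask.
// Returns the gradient at the conv unit's input.
static fcube unit_bwd(int ci, const fcube& dout, const Params& q,
                      const Plan& P, Grads& dq, const Tape& t, int Cin,
                      int n) {
  int H = dout.n_rows, W = dout.n_cols;
  int Cout = dout.n_slices / n;
  size_t HW = (size_t)H * W;
  const fcube& xh = t.xhat[ci];
  fcube dy(H, W, (size_t)n * Cout);   // gradient at conv output (pre-BN)
  size_t nel = (size_t)n * HW;
  for (int c = 0; c < Cout; ++c) {
    float gm = q.gamma[ci](c);
    double m1 = 0, m2 = 0;
    for (int img = 0; img < n; ++img) {
      int sc = img * Cout + c;
      m1 += accu(conv_to<mat>::from(dout.slice(sc)));
      m2 += accu(conv_to<mat>::from(dout.slice(sc) % xh.slice(sc)));
    }
    m1 = gm * m1 / nel;
    m2 = gm * m2 / nel;
    float si = t.sinv[ci](c);
    for (int img = 0; img < n; ++img) {
      int sc = img * Cout + c;
      dy.slice(sc) = (dout.slice(sc) * gm - (float)m1 -
                      xh.slice(sc) * (float)m2) * si;
    }
  }
  for (int c = 0; c < Cout; ++c) {
    double dg = 0, db = 0;
    for (int img = 0; img < n; ++img) {
      int sc = img * Cout + c;
      dg += accu(conv_to<mat>::from(dout.slice(sc) % xh.slice(sc)));
      db += accu(conv_to<mat>::from(dout.slice(sc)));
    }
    dq.gamma[ci](c) += (float)dg;
    dq.beta[ci](c) += (float)db;
  }
  fmat dOT((size_t)n * HW, Cout);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < Cout; ++c) {
      const float* src = dy.slice(img * Cout + c).memptr();
      std::copy(src, src + HW, dOT.colptr(c) + img * HW);
    }
  dq.convW[ci] += dOT.t() * t.cols[ci];
  fmat dcolsT = dOT * q.convW[ci];
  return col2imT(dcolsT, H, W, Cin, n);
}

static fcube pool_fwd(const fcube& x, Tape& t) {
  int H = x.n_rows, W = x.n_cols, NS = x.n_slices;
  int H2 = H / 2, W2 = W / 2;
  fcube y(H2, W2, NS);
  umat arg(H2 * W2, NS);
  for (int s = 0; s < NS; ++s) {
    const fmat& sl = x.slice(s);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        float best = -std::numeric_limits<float>::infinity();
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int r = 2 * i + di, c = 2 * j + dj;
            float v = sl(r, c);
            if (v > best) { best = v; bi = r + c * H; }
          }
        y(i, j, s) = best;
        arg(i + j * H2, s) = bi;
      }
  }
  t.poolarg.push_back(arg);
  t.poolH.push_back(H);
  t.poolW.push_back(W);
  return y;
}

static fcube pool_bwd(int pi, const fcube& dy, const Tape& t) {
  int H = t.poolH[pi], W = t.poolW[pi];
  int H2 = dy.n_rows, W2 = dy.n_cols, NS = dy.n_slices;
  fcube dx(H, W, NS, fill::zeros);
  const umat& arg = t.poolarg[pi];
  for (int s = 0; s < NS; ++s)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        unsigned int li = arg(i + j * H2, s);
        dx(li % H, li / H, s) += dy(i, j, s);
      }
  return dx;
}

static bool has_proj(const Plan& P, int s) {
  int cin = (s == 0) ? P.stem_c : P.widths[s - 1];
  return cin != P.widths[s];
}

// Forward pass for a batch of n single-channel images (slices of X).
// Returns logits (2 x n) and embeddings z (D x n); fills the tape.
static void net_forward(const Params& q, const Plan& P, const fcube& X,
                        int n, bool train, BNStats& bn, fmat& logits,
                        fmat& Z, Tape& t) {
  fcube x = X;
  int ci = 0;
  x = unit_fwd(ci, q, P, x, n, true, train, bn, t); ++ci;
  for (int s = 0; s < P.n_stages(); ++s) {
    x = pool_fwd(x, t);
    if (has_proj(P, s)) { x = unit_fwd(ci, q, P, x, n, true, train, bn, t); ++ci; }
    for (int b = 0; b < P.blocks[s]; ++b) {
      t.skip.push_back(x);
      fcube h = unit_fwd(ci, q, P, x, n, true, train, bn, t); ++ci;
      h = unit_fwd(ci, q, P, h, n, false, train, bn, t); ++ci;
      fcube xo = x + h;
      xo.transform(relu1);
      t.resout.push_back(xo);
      x = xo;
    }
  }
  t.gapH = x.n_rows; t.gapW = x.n_cols;
  int D = x.n_slices / n;
  Z.set_size(D, n);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < D; ++c)
      Z(c, img) = accu(x.slice(img * D + c)) / (t.gapH * t.gapW);
  fmat a = Z;
  int L = (int)P.head.size();
  for (int l = 0; l < L; ++l) {
    t.fc_in.push_back(a);
    a = q.fcW[l] * a;
    a.each_col() += q.fcb[l];
    if (l < L - 1) a.transform(relu1);
    t.fc_act.push_back(a);
  }
  logits = a;
}

static void net_backward(const Params& q, const Plan& P, const fmat& dlogits,
                         const Tape& t, int n, Grads& dq) {
  int L = (int)P.head.size();
  fmat da = dlogits;
  for (int l = L - 1; l >= 0; --l) {
    fmat dout = da;
    if (l < L - 1) dout.elem(find(t.fc_act[l] <= 0)).zeros();
    dq.fcW[l] += dout * t.fc_in[l].t();
    dq.fcb[l] += sum(dout, 1);
    da = q.fcW[l].t() * dout;
  }
  int D = da.n_rows;
  fcube dx(t.gapH, t.gapW, (size_t)n * D);
  for (int img = 0; img < n; ++img)
    for (int c = 0; c < D; ++c)
      dx.slice(img * D + c).fill(da(c, img) / (t.gapH * t.gapW));

  int ci = P.n_convs();
  int bi = (int)t.skip.size();
  int pidx = (int)t.poolarg.size();
  for (int s = P.n_stages() - 1; s >= 0; --s) {
    int cin_stage = has_proj(P, s) ? ((s == 0) ? P.stem_c : P.widths[s - 1])
                                   : P.widths[s];
    for (int b = P.blocks[s] - 1; b >= 0; --b) {
      --bi;
      fcube dpre = dx;
      for (uword i = 0; i < dpre.n_elem; ++i)
        if (t.resout[bi](i) <= 0) dpre(i) = 0;
      int c2 = --ci;                       // conv2 unit (no relu)
      fcube dh = unit_bwd(c2, dpre, q, P, dq, t, P.widths[s], n);
      int c1 = --ci;                       // conv1 unit (relu)
      for (uword i = 0; i < dh.n_elem; ++i)
        if (t.unit_out[c1](i) <= 0) dh(i) = 0;
      fcube dxin = unit_bwd(c1, dh, q, P, dq, t, P.widths[s], n);
      dx = dxin + dpre;                    // skip connection
    }
    if (has_proj(P, s)) {
      int cp = --ci;
      for (uword i = 0; i < dx.n_elem; ++i)
        if (t.unit_out[cp](i) <= 0) dx(i) = 0;
      dx = unit_bwd(cp, dx, q, P, dq, t, cin_stage, n);
    }
    dx = pool_bwd(--pidx, dx, t);
  }
  int c0 = --ci;
  for (uword i = 0; i < dx.n_elem; ++i)
    if (t.unit_out[c0](i) <= 0) dx(i) = 0;
  unit_bwd(c0, dx, q, P, dq, t, 1, n);
}

// Stable softmax cross entropy per column; fills dlogits, returns sum loss.
static double ce_batch(const fmat& logits, const std::vector<int>& labels,
                       fmat& dlogits) {
  double loss = 0;
  dlogits.set_size(logits.n_rows, logits.n_cols);
  for (uword j = 0; j < logits.n_cols; ++j) {
    fvec lg = logits.col(j);
    float m = lg.max();
    fvec e = exp(lg - m);
    fvec p = e / accu(e);
    dlogits.col(j) = p;
    dlogits(labels[j], j) -= 1.0f;
    loss += -std::log(std::max((double)p(labels[j]), 1e-38));
  }
  return loss;
}

// Plain R numeric vector (no dim attribute) from an arma float vector.
static Rcpp::NumericVector as_rvec(const fvec& x) {
  Rcpp::NumericVector out(x.n_elem);
  for (uword i = 0; i < x.n_elem; ++i) out[i] = x(i);
  return out;
}

static BNStats parse_stats(const Rcpp::List& stats, const Plan& P) {
  BNStats bn;
  int nc = P.n_convs();
  if ((int)stats.size() != 2 * nc)
    Rcpp::stop("running-stats list length %d does not match plan (%d expected)",
               (int)stats.size(), 2 * nc);
  for (int i = 0; i < nc; ++i) {
    bn.rmean.push_back(Rcpp::as<fvec>(stats[2 * i]));
    bn.rvar.push_back(Rcpp::as<fvec>(stats[2 * i + 1]));
  }
  return bn;
}

static Rcpp::List wrap_stats(const BNStats& bn) {
  Rcpp::List out(2 * bn.rmean.size());
  for (size_t i = 0; i < bn.rmean.size(); ++i) {
    out[2 * i] = as_rvec(bn.rmean[i]);
    out[2 * i + 1] = as_rvec(bn.rvar[i]);
  }
  return out;
}

// Inference-mode forward (frozen running statistics).
// [[Rcpp::export(name = ".cnn_forward_cpp")]]
Rcpp::List cnn_forward_cpp(const Rcpp::List& params, const Rcpp::List& config,
                           const arma::cube& Xd, const Rcpp::List& stats) {
  Plan P = parse_plan(config);
  Params q = parse_params(params, P);
  BNStats bn = parse_stats(stats, P);
  fcube X = conv_to<fcube>::from(Xd);
  int n = X.n_slices;
  int D = P.widths.back();
  mat logits(n, 2), emb(n, D);
  const int chunk = 32;              // bounds im2col memory for large banks
  for (int start = 0; start < n; start += chunk) {
    int m = std::min(chunk, n - start);
    Tape t;
    fmat lg, Z;
    net_forward(q, P, X.slices(start, start + m - 1), m, false, bn, lg, Z, t);
    logits.rows(start, start + m - 1) = conv_to<mat>::from(lg.t());
    emb.rows(start, start + m - 1) = conv_to<mat>::from(Z.t());
  }
  return Rcpp::List::create(Rcpp::Named("logits") = logits,
                            Rcpp::Named("emb") = emb);
}

// Mean over pairs of CE(f(orig), 0) + CE(f(aug), 1), plus its exact
// gradient with respect to every parameter (same canonical order).
// [[Rcpp::export(name = ".cnn_grad_cpp")]]
Rcpp::List cnn_grad_cpp(const Rcpp::List& params, const Rcpp::List& config,
                        const arma::cube& Xorig, const arma::cube& Xaug,
                        const Rcpp::List& stats) {
  Plan P = parse_plan(config);
  Params q = parse_params(params, P);
  BNStats bn = parse_stats(stats, P);
  if (Xorig.n_slices != Xaug.n_slices)
    Rcpp::stop("original/augmented pair counts differ");
  int n = Xorig.n_slices;
  Grads dq;
  for (size_t i = 0; i < q.convW.size(); ++i) {
    dq.convW.push_back(zeros<fmat>(q.convW[i].n_rows, q.convW[i].n_cols));
    dq.gamma.push_back(zeros<fvec>(q.gamma[i].n_elem));
    dq.beta.push_back(zeros<fvec>(q.beta[i].n_elem));
  }
  for (size_t i = 0; i < q.fcW.size(); ++i) {
    dq.fcW.push_back(zeros<fmat>(q.fcW[i].n_rows, q.fcW[i].n_cols));
    dq.fcb.push_back(zeros<fvec>(q.fcb[i].n_elem));
  }
  fcube X = join_slices(conv_to<fcube>::from(Xorig),
                        conv_to<fcube>::from(Xaug));
  std::vector<int> labels(2 * n);
  for (int i = 0; i < n; ++i) { labels[i] = 0; labels[n + i] = 1; }
  Tape t;
  fmat logits, Z, dlogits;
  net_forward(q, P, X, 2 * n, true, bn, logits, Z, t);
  double loss = ce_batch(logits, labels, dlogits);
  net_backward(q, P, dlogits, t, 2 * n, dq);
  loss /= n;                          // mean over pairs (both CE terms)
  float fn = (float)n;
  Rcpp::List grads(3 * q.convW.size() + 2 * q.fcW.size());
  int k = 0;
  for (size_t i = 0; i < q.convW.size(); ++i) {
    grads[k++] = Rcpp::wrap(conv_to<mat>::from(dq.convW[i] / fn));
    grads[k++] = as_rvec(dq.gamma[i] / fn);
    grads[k++] = as_rvec(dq.beta[i] / fn);
  }
  for (size_t i = 0; i < q.fcW.size(); ++i) {
    grads[k++] = Rcpp::wrap(conv_to<mat>::from(dq.fcW[i] / fn));
    grads[k++] = as_rvec(dq.fcb[i] / fn);
  }
  return Rcpp::List::create(Rcpp::Named("grads") = grads,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("stats") = wrap_stats(bn));
}
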