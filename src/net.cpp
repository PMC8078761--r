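// Small residual convolutional network for centerline-angle regression.
// Feature maps are stored as (C x H*W*B) single-precision matrices so every
// convolution reduces to one BLAS sgemm on an im2col buffer; this keeps a
// full training run tractable on one CPU core.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
#include <vector>
#include <memory>

using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.9f;
static const float LRELU_SLOPE = 0.1f;

// column index of pixel (y, x) of sample b in a (C x H*W*B) map
static inline int colidx(int y, int x, int b, int H, int W) {
  return b * H * W + x * H + y;
}

struct Param {
  fmat w, g, m, v, ema;
  void setup(int r, int c) {
    w.set_size(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
    ema.set_size(0, 0);
  }
};

struct Shape { int C, H, W, B; };

// ---- im2col / col2im -------------------------------------------------------

static void im2col(const fmat& X, int C, int H, int W, int B,
                   int k, int stride, int pad, fmat& cols,
                   int Ho, int Wo) {
  cols.set_size(C * k * k, (size_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        size_t oc = (size_t)b * Ho * Wo + (size_t)xo * Ho + yo;
        float* dst = cols.colptr(oc);
        int y0 = yo * stride - pad, x0 = xo * stride - pad;
        for (int kx = 0; kx < k; ++kx) {
          int x = x0 + kx;
          for (int ky = 0; ky < k; ++ky) {
            int y = y0 + ky;
            float* d = dst + (kx * k + ky) * C;
            if (x >= 0 && x < W && y >= 0 && y < H) {
              const float* src = X.colptr(colidx(y, x, b, H, W));
              for (int c = 0; c < C; ++c) d[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) d[c] = 0.0f;
            }
          }
        }
      }
    }
  }
}

static void col2im(const fmat& cols, int C, int H, int W, int B,
                   int k, int stride, int pad, fmat& dX,
                   int Ho, int Wo) {
  dX.zeros(C, (size_t)H * W * B);
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        size_t oc = (size_t)b * Ho * Wo + (size_t)xo * Ho + yo;
        const float* src = cols.colptr(oc);
        int y0 = yo * stride - pad, x0 = xo * stride - pad;
        for (int kx = 0; kx < k; ++kx) {
          int x = x0 + kx;
          if (x < 0 || x >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int y = y0 + ky;
            if (y < 0 || y >= H) continue;
            const float* s = src + (kx * k + ky) * C;
            float* d = dX.colptr(colidx(y, x, b, H, W));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
}

// ---- layers ----------------------------------------------------------------

struct Conv {
  int k, stride, pad, cin, cout;
  Param W_, b_;
  fmat cols;          // cached im2col of input
  Shape in_shape;
  int Ho, Wo;

  void setup(int cin_, int cout_, int k_, int stride_, int pad_,
             std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_; stride = stride_; pad = pad_;
    W_.setup(cout, cin * k * k);
    b_.setup(cout, 1);
    std::normal_distribution<float> gauss(0.0f,
        std::sqrt(2.0f / (cin * k * k)));
    for (arma::uword i = 0; i < W_.w.n_elem; ++i) W_.w[i] = gauss(rng);
    b_.w.zeros();
  }

  fmat forward(const fmat& X, Shape s, Shape& out, bool keep_cache) {
    in_shape = s;
    Ho = (s.H + 2 * pad - k) / stride + 1;
    Wo = (s.W + 2 * pad - k) / stride + 1;
    im2col(X, s.C, s.H, s.W, s.B, k, stride, pad, cols, Ho, Wo);
    fmat Y = W_.w * cols;
    Y.each_col() += b_.w.col(0);
    out = {cout, Ho, Wo, s.B};
    if (!keep_cache) cols.reset();
    return Y;
  }

  fmat backward(const fmat& dY) {
    W_.g += dY * cols.t();
    b_.g += arma::sum(dY, 1);
    fmat dcols = W_.w.t() * dY;
    fmat dX;
    col2im(dcols, in_shape.C, in_shape.H, in_shape.W, in_shape.B,
           k, stride, pad, dX, Ho, Wo);
    cols.reset();
    return dX;
  }
};

struct BatchNorm {
  int C;
  Param gamma, beta;
  fvec run_mean, run_var;
  // caches
  fvec mu, istd;
  fmat xhat;

  void setup(int C_) {
    C = C_;
    gamma.setup(C, 1); gamma.w.ones();
    beta.setup(C, 1);  beta.w.zeros();
    run_mean.zeros(C); run_var.ones(C);
  }

  fmat forward(const fmat& X, bool train, bool keep_cache) {
    fmat Y(C, X.n_cols);
    if (train) {
      mu = arma::mean(X, 1);
      fvec var = arma::var(X, 1 /* normalize by N */, 1);
      istd = 1.0f / arma::sqrt(var + BN_EPS);
      run_mean = BN_MOMENTUM * run_mean + (1.0f - BN_MOMENTUM) * mu;
      run_var  = BN_MOMENTUM * run_var  + (1.0f - BN_MOMENTUM) * var;
      xhat = X;
      xhat.each_col() -= mu;
      xhat.each_col() %= istd;
      Y = xhat;
      Y.each_col() %= gamma.w.col(0);
      Y.each_col() += beta.w.col(0);
      if (!keep_cache) xhat.reset();
    } else {
      fvec is = 1.0f / arma::sqrt(run_var + BN_EPS);
      Y = X;
      Y.each_col() -= run_mean;
      Y.each_col() %= is;
      Y.each_col() %= gamma.w.col(0);
      Y.each_col() += beta.w.col(0);
    }
    return Y;
  }

  fmat backward(const fmat& dY) {
    float n = (float)dY.n_cols;
    fvec dgamma = arma::sum(dY % xhat, 1);
    fvec dbeta  = arma::sum(dY, 1);
    gamma.g += dgamma;
    beta.g  += dbeta;
    // dX = (gamma*istd/n) * (n*dY - dbeta - xhat*dgamma)
    fmat dX = n * dY;
    dX.each_col() -= dbeta;
    fmat t = xhat;
    t.each_col() %= dgamma;
    dX -= t;
    fvec scale = gamma.w.col(0) % istd / n;
    dX.each_col() %= scale;
    xhat.reset();
    return dX;
  }
};

static inline void lrelu_inplace(fmat& X) {
  for (arma::uword i = 0; i < X.n_elem; ++i)
    if (X[i] < 0.0f) X[i] *= LRELU_SLOPE;
}
// backward using the output (sign is preserved by the positive slope)
static inline fmat lrelu_backward(const fmat& dY, const fmat& Yout) {
  fmat dX = dY;
  for (arma::uword i = 0; i < dX.n_elem; ++i)
    if (Yout[i] < 0.0f) dX[i] *= LRELU_SLOPE;
  return dX;
}

struct MaxPool2 {
  Shape in_shape;
  int Ho, Wo;
  arma::umat argmax; // per (C x Ho*Wo*B): linear col index of max in input

  fmat forward(const fmat& X, Shape s, Shape& out, bool keep_cache) {
    in_shape = s;
    Ho = s.H / 2; Wo = s.W / 2;
    fmat Y(s.C, (size_t)Ho * Wo * s.B);
    argmax.set_size(s.C, (size_t)Ho * Wo * s.B);
    for (int b = 0; b < s.B; ++b)
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          size_t oc = (size_t)b * Ho * Wo + (size_t)xo * Ho + yo;
          int cand[4] = {
            colidx(2 * yo,     2 * xo,     b, s.H, s.W),
            colidx(2 * yo + 1, 2 * xo,     b, s.H, s.W),
            colidx(2 * yo,     2 * xo + 1, b, s.H, s.W),
            colidx(2 * yo + 1, 2 * xo + 1, b, s.H, s.W)};
          for (int c = 0; c < s.C; ++c) {
            float best = X(c, cand[0]); int bi = cand[0];
            for (int j = 1; j < 4; ++j) {
              float v = X(c, cand[j]);
              if (v > best) { best = v; bi = cand[j]; }
            }
            Y(c, oc) = best;
            argmax(c, oc) = bi;
          }
        }
    out = {s.C, Ho, Wo, s.B};
    if (!keep_cache) argmax.reset();
    return Y;
  }

  fmat backward(const fmat& dY) {
    fmat dX(in_shape.C, (size_t)in_shape.H * in_shape.W * in_shape.B,
            arma::fill::zeros);
    for (arma::uword j = 0; j < dY.n_cols; ++j)
      for (int c = 0; c < in_shape.C; ++c)
        dX(c, argmax(c, j)) += dY(c, j);
    argmax.reset();
    return dX;
  }
};

// pre-activation residual block: y = conv2(act(bn2(conv1(act(bn1(x)))))) + skip
struct ResBlock {
  int cin, cout, stride;
  bool project;
  BatchNorm bn1, bn2;
  Conv conv1, conv2, proj;
  // caches
  fmat act1, act2, x_in;
  Shape s_in, s_mid, s_out;

  void setup(int cin_, int cout_, int stride_, std::mt19937& rng) {
    cin = cin_; cout = cout_; stride = stride_;
    project = (stride != 1 || cin != cout);
    bn1.setup(cin);
    conv1.setup(cin, cout, 3, stride, 1, rng);
    bn2.setup(cout);
    conv2.setup(cout, cout, 3, 1, 1, rng);
    if (project) proj.setup(cin, cout, 1, stride, 0, rng);
  }

  fmat forward(const fmat& X, Shape s, Shape& out, bool train) {
    s_in = s;
    if (train) x_in = X;
    fmat t = bn1.forward(X, train, train);
    lrelu_inplace(t);
    if (train) act1 = t;
    fmat skip;
    Shape sp;
    if (project) skip = proj.forward(t, s, sp, train);
    fmat y = conv1.forward(t, s, s_mid, train);
    t = bn2.forward(y, train, train);
    lrelu_inplace(t);
    if (train) act2 = t;
    y = conv2.forward(t, s_mid, s_out, train);
    if (project) y += skip;
    else         y += X;
    out = s_out;
    return y;
  }

  fmat backward(const fmat& dY) {
    fmat d2 = conv2.backward(dY);
    d2 = lrelu_backward(d2, act2); act2.reset();
    d2 = bn2.backward(d2);
    fmat d1 = conv1.backward(d2);
    if (project) d1 += proj.backward(dY);
    d1 = lrelu_backward(d1, act1); act1.reset();
    d1 = bn1.backward(d1);
    if (!project) d1 += dY;
    x_in.reset();
    return d1;
  }
};

// ---- network ---------------------------------------------------------------

struct Net {
  int input_side, n_out;
  std::vector<int> stage_filters;
  int blocks_per_stage;
  bool use_pool;
  Conv stem;
  MaxPool2 pool;
  std::vector<ResBlock> blocks;
  BatchNorm bn_final;
  Param Wd, bd;   // dense head
  std::mt19937 rng;
  long adam_t = 0;
  // caches
  fmat final_act, gap_out;
  Shape s_stem, s_pool, s_last;

  Net(int side, std::vector<int> filters, int nblocks, int nout,
      bool pool_after_stem, unsigned int seed)
      : input_side(side), n_out(nout), stage_filters(filters),
        blocks_per_stage(nblocks), use_pool(pool_after_stem), rng(seed) {
    stem.setup(1, filters[0], 7, 2, 3, rng);
    int cin = filters[0];
    for (size_t s = 0; s < filters.size(); ++s) {
      for (int j = 0; j < nblocks; ++j) {
        ResBlock blk;
        int stride = (s > 0 && j == 0) ? 2 : 1;
        blk.setup(cin, filters[s], stride, rng);
        blocks.push_back(std::move(blk));
        cin = filters[s];
      }
    }
    bn_final.setup(cin);
    Wd.setup(nout, cin);
    std::normal_distribution<float> gauss(0.0f, std::sqrt(2.0f / cin));
    for (arma::uword i = 0; i < Wd.w.n_elem; ++i) Wd.w[i] = gauss(rng);
    bd.setup(nout, 1);
    bd.w.zeros();
  }

  std::vector<Param*> params() {
    std::vector<Param*> p;
    p.push_back(&stem.W_); p.push_back(&stem.b_);
    for (auto& b : blocks) {
      p.push_back(&b.bn1.gamma); p.push_back(&b.bn1.beta);
      p.push_back(&b.conv1.W_);  p.push_back(&b.conv1.b_);
      p.push_back(&b.bn2.gamma); p.push_back(&b.bn2.beta);
      p.push_back(&b.conv2.W_);  p.push_back(&b.conv2.b_);
      if (b.project) { p.push_back(&b.proj.W_); p.push_back(&b.proj.b_); }
    }
    p.push_back(&bn_final.gamma); p.push_back(&bn_final.beta);
    p.push_back(&Wd); p.push_back(&bd);
    return p;
  }

  // X: (1 x side*side*B)
  fmat forward(const fmat& X, int B, bool train) {
    Shape s = {1, input_side, input_side, B};
    fmat y = stem.forward(X, s, s_stem, train);
    Shape cur = s_stem;
    if (use_pool) {
      y = pool.forward(y, s_stem, s_pool, train);
      cur = s_pool;
    }
    for (auto& b : blocks) {
      Shape nxt;
      y = b.forward(y, cur, nxt, train);
      cur = nxt;
    }
    s_last = cur;
    y = bn_final.forward(y, train, train);
    lrelu_inplace(y);
    if (train) final_act = y;
    // global average pool -> (C x B)
    int HW = cur.H * cur.W;
    fmat g(cur.C, cur.B);
    for (int b = 0; b < cur.B; ++b) {
      fvec acc(cur.C, arma::fill::zeros);
      for (int j = 0; j < HW; ++j) acc += y.col((size_t)b * HW + j);
      g.col(b) = acc / (float)HW;
    }
    if (train) gap_out = g;
    return Wd.w * g + arma::repmat(bd.w, 1, cur.B); // (n_out x B)
  }

  void backward(const fmat& dOut) {
    int B = s_last.B, HW = s_last.H * s_last.W;
    Wd.g += dOut * gap_out.t();
    bd.g += arma::sum(dOut, 1);
    fmat dg = Wd.w.t() * dOut; // (C x B)
    fmat dy(s_last.C, (size_t)HW * B);
    for (int b = 0; b < B; ++b) {
      fvec col = dg.col(b) / (float)HW;
      for (int j = 0; j < HW; ++j) dy.col((size_t)b * HW + j) = col;
    }
    gap_out.reset();
    dy = lrelu_backward(dy, final_act); final_act.reset();
    dy = bn_final.backward(dy);
    for (int i = (int)blocks.size() - 1; i >= 0; --i)
      dy = blocks[i].backward(dy);
    if (use_pool) dy = pool.backward(dy);
    stem.backward(dy);
  }

  void zero_grad() {
    for (auto* p : params()) p->g.zeros();
  }

  void adam_step(float lr, float ema_decay, float beta1 = 0.9f,
                 float beta2 = 0.999f, float eps = 1e-8f) {
    ++adam_t;
    float c1 = 1.0f - std::pow(beta1, (float)adam_t);
    float c2 = 1.0f - std::pow(beta2, (float)adam_t);
    for (auto* p : params()) {
      p->m = beta1 * p->m + (1.0f - beta1) * p->g;
      p->v = beta2 * p->v + (1.0f - beta2) * (p->g % p->g);
      p->w -= lr * (p->m / c1) / (arma::sqrt(p->v / c2) + eps);
      if (ema_decay > 0.0f) {
        if (p->ema.n_elem == 0) p->ema = p->w;
        else p->ema = ema_decay * p->ema + (1.0f - ema_decay) * p->w;
      }
    }
  }

  // swap current weights with their exponential moving average (Polyak
  // averaging); calling twice restores the live weights
  void swap_ema() {
    for (auto* p : params())
      if (p->ema.n_elem > 0) p->w.swap(p->ema);
  }
};

// ---- symmetric loss --------------------------------------------------------

static inline float wrapf(float a) {
  while (a > (float)M_PI)  a -= 2.0f * (float)M_PI;
  while (a <= -(float)M_PI) a += 2.0f * (float)M_PI;
  return a;
}

// reported loss = mean_b min(d(yhat, a), d(yhat, flip(a)+pi)) with d the
// rms wrapped angle error; the training gradient may instead follow the
// squared distance d^2 (same minimizer and flip choice, smoother descent)
static float symmetric_loss_batch(const fmat& Y, const fmat& A,
                                  fmat* dY, bool squared_grad = false) {
  int N = Y.n_rows, B = Y.n_cols;
  if (dY) dY->zeros(N, B);
  float total = 0.0f;
  std::vector<float> da(N), db(N);
  for (int b = 0; b < B; ++b) {
    float sa = 0.0f, sb = 0.0f;
    for (int i = 0; i < N; ++i) {
      da[i] = wrapf(Y(i, b) - A(i, b));
      db[i] = wrapf(Y(i, b) - (A(N - 1 - i, b) + (float)M_PI));
      sa += da[i] * da[i];
      sb += db[i] * db[i];
    }
    float dda = std::sqrt(sa / N), ddb = std::sqrt(sb / N);
    bool use_a = dda <= ddb;
    float d = use_a ? dda : ddb;
    total += d;
    if (dY && d > 1e-12f) {
      const std::vector<float>& e = use_a ? da : db;
      if (squared_grad) {
        for (int i = 0; i < N; ++i)
          (*dY)(i, b) = 2.0f * e[i] / (N * B);
      } else {
        for (int i = 0; i < N; ++i)
          (*dY)(i, b) = e[i] / (N * d * B);
      }
    }
  }
  return total / B;
}

// ---- R interface -----------------------------------------------------------

static fmat images_to_input(const Rcpp::NumericVector& imgs, int side,
                            int B) {
  // imgs: column-major (side, side, B) array; map to (1 x side*side*B)
  fmat X(1, (size_t)side * side * B);
  const double* p = imgs.begin();
  for (size_t j = 0; j < (size_t)side * side * B; ++j)
    X(0, j) = (float)p[j];
  return X;
}

// [[Rcpp::export]]
SEXP cpp_net_create(int input_side, Rcpp::IntegerVector stage_filters,
                    int blocks_per_stage, int n_out, bool stem_pool,
                    int seed) {
  std::vector<int> f(stage_filters.begin(), stage_filters.end());
  Rcpp::XPtr<Net> ptr(new Net(input_side, f, blocks_per_stage, n_out,
                              stem_pool, (unsigned int)seed), true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_net_forward(SEXP net_ptr, Rcpp::NumericVector images,
                                    int n_images, bool train_mode) {
  Rcpp::XPtr<Net> net(net_ptr);
  fmat X = images_to_input(images, net->input_side, n_images);
  fmat Y = net->forward(X, n_images, train_mode);
  if (train_mode) { // caller only wanted outputs; drop caches
    net->final_act.reset(); net->gap_out.reset();
  }
  Rcpp::NumericMatrix out(Y.n_rows, Y.n_cols);
  for (arma::uword j = 0; j < Y.n_cols; ++j)
    for (arma::uword i = 0; i < Y.n_rows; ++i)
      out(i, j) = Y(i, j);
  return out;
}

// [[Rcpp::export]]
double cpp_net_train_batch(SEXP net_ptr, Rcpp::NumericVector images,
                           Rcpp::NumericMatrix targets, int n_images,
                           double lr, bool squared_grad, double ema_decay) {
  Rcpp::XPtr<Net> net(net_ptr);
  fmat X = images_to_input(images, net->input_side, n_images);
  fmat A(targets.nrow(), targets.ncol());
  for (int j = 0; j < targets.ncol(); ++j)
    for (int i = 0; i < targets.nrow(); ++i)
      A(i, j) = (float)targets(i, j);
  fmat Y = net->forward(X, n_images, true);
  fmat dY;
  float loss = symmetric_loss_batch(Y, A, &dY, squared_grad);
  net->zero_grad();
  net->backward(dY);
  net->adam_step((float)lr, (float)ema_decay);
  return (double)loss;
}

// [[Rcpp::export]]
void cpp_net_swap_ema(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  net->swap_ema();
}

// [[Rcpp::export]]
double cpp_net_eval_loss(SEXP net_ptr, Rcpp::NumericVector images,
                         Rcpp::NumericMatrix targets, int n_images) {
  Rcpp::XPtr<Net> net(net_ptr);
  fmat X = images_to_input(images, net->input_side, n_images);
  fmat A(targets.nrow(), targets.ncol());
  for (int j = 0; j < targets.ncol(); ++j)
    for (int i = 0; i < targets.nrow(); ++i)
      A(i, j) = (float)targets(i, j);
  fmat Y = net->forward(X, n_images, false);
  return (double)symmetric_loss_batch(Y, A, nullptr);
}

// [[Rcpp::export]]
double cpp_net_num_params(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  double n = 0;
  for (auto* p : net->params()) n += p->w.n_elem;
  return n;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_get_state(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::List out;
  auto ps = net->params();
  Rcpp::List weights(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    const fmat& w = ps[i]->w;
    Rcpp::NumericMatrix m(w.n_rows, w.n_cols);
    for (arma::uword j = 0; j < w.n_cols; ++j)
      for (arma::uword r = 0; r < w.n_rows; ++r)
        m(r, j) = w(r, j);
    weights[i] = m;
  }
  // batch-norm running stats
  std::vector<BatchNorm*> bns;
  for (auto& b : net->blocks) { bns.push_back(&b.bn1); bns.push_back(&b.bn2); }
  bns.push_back(&net->bn_final);
  Rcpp::List stats(bns.size());
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericMatrix m(bns[i]->C, 2);
    for (int c = 0; c < bns[i]->C; ++c) {
      m(c, 0) = bns[i]->run_mean(c);
      m(c, 1) = bns[i]->run_var(c);
    }
    stats[i] = m;
  }
  out["weights"] = weights;
  out["bn_stats"] = stats;
  out["adam_t"] = (double)net->adam_t;
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_state(SEXP net_ptr, Rcpp::List state) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::List weights = state["weights"];
  auto ps = net->params();
  if ((size_t)weights.size() != ps.size())
    Rcpp::stop("state does not match network architecture");
  for (size_t i = 0; i < ps.size(); ++i) {
    Rcpp::NumericMatrix m = weights[i];
    if ((arma::uword)m.nrow() != ps[i]->w.n_rows ||
        (arma::uword)m.ncol() != ps[i]->w.n_cols)
      Rcpp::stop("weight %d has wrong shape", (int)i + 1);
    for (int j = 0; j < m.ncol(); ++j)
      for (int r = 0; r < m.nrow(); ++r)
        ps[i]->w(r, j) = (float)m(r, j);
  }
  std::vector<BatchNorm*> bns;
  for (auto& b : net->blocks) { bns.push_back(&b.bn1); bns.push_back(&b.bn2); }
  bns.push_back(&net->bn_final);
  Rcpp::List stats = state["bn_stats"];
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericMatrix m = stats[i];
    for (int c = 0; c < bns[i]->C; ++c) {
      bns[i]->run_mean(c) = (float)m(c, 0);
      bns[i]->run_var(c) = (float)m(c, 1);
    }
  }
  net->adam_t = (long)Rcpp::as<double>(state["adam_t"]);
}

// [[Rcpp::export]]
double cpp_symmetric_loss(Rcpp::NumericVector theta_hat,
                          Rcpp::NumericVector theta_a) {
  int N = theta_hat.size();
  fmat Y(N, 1), A(N, 1);
  for (int i = 0; i < N; ++i) { Y(i, 0) = theta_hat[i]; A(i, 0) = theta_a[i]; }
  return (double)symmetric_loss_batch(Y, A, nullptr);
}
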