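// Training and inference engine for the fixed 9-layer regression CNN:
// dense(1024, sigmoid) -> reshape 32x32x1 -> 6x conv2d(32 filters, 3x3,
// sigmoid, same padding) -> conv2d(1 filter, 3x3, same, linear) ->
// flatten(1024) -> dense(8, sigmoid).
//
// Convolutions are evaluated as GEMMs over im2col buffers in single
// precision; the batch is packed along columns so that one GEMM serves the
// whole minibatch. Feature maps are stored as C x (P*B) matrices with
// column index p + P*b, p = row + SIDE*col of the 32x32 map.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>

using namespace arma;

static const int SIDE = 32;      // spatial side of the reshaped map
static const int P = SIDE * SIDE; // 1024 positions per map

// Deterministic, platform-independent RNG (xorshift64*) for minibatch
// shuffling; std::shuffle/std::*_distribution are implementation-defined.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

static void fisher_yates(std::vector<uword>& idx, XRng& rng) {
  for (uword i = idx.size(); i > 1; --i) {
    uword j = (uword)rng.below(i);
    std::swap(idx[i - 1], idx[j]);
  }
}

struct Net {
  fmat W1;                // 1024 x 1024
  frowvec b1;             // 1024
  std::vector<fmat> Wc;   // per conv layer: C_out x (9*C_in)
  std::vector<fvec> bc;   // per conv layer: C_out
  fmat Wout;              // 1024 x 8
  frowvec bout;           // 8
};

static Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  n.b1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(w["b1"]));
  Rcpp::List Wc = w["conv_W"], bc = w["conv_b"];
  for (int l = 0; l < Wc.size(); ++l) {
    n.Wc.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Wc[l])));
    n.bc.push_back(conv_to<fvec>::from(Rcpp::as<vec>(bc[l])));
  }
  n.Wout = conv_to<fmat>::from(Rcpp::as<mat>(w["Wout"]));
  n.bout = conv_to<frowvec>::from(Rcpp::as<rowvec>(w["bout"]));
  return n;
}

static Rcpp::List net_to_list(const Net& n) {
  Rcpp::List Wc(n.Wc.size()), bc(n.bc.size());
  for (size_t l = 0; l < n.Wc.size(); ++l) {
    Wc[l] = Rcpp::wrap(conv_to<mat>::from(n.Wc[l]));
    bc[l] = Rcpp::wrap(conv_to<vec>::from(n.bc[l]));
  }
  return Rcpp::List::create(
    Rcpp::Named("W1") = Rcpp::wrap(conv_to<mat>::from(n.W1)),
    Rcpp::Named("b1") = Rcpp::wrap(conv_to<rowvec>::from(n.b1)),
    Rcpp::Named("conv_W") = Wc,
    Rcpp::Named("conv_b") = bc,
    Rcpp::Named("Wout") = Rcpp::wrap(conv_to<mat>::from(n.Wout)),
    Rcpp::Named("bout") = Rcpp::wrap(conv_to<rowvec>::from(n.bout)));
}

// Neighbour index of position p for kernel offset k (3x3, same padding),
// or -1 when the neighbour falls outside the map. Precomputed once.
struct NbrTable {
  int q[P][9];
  NbrTable() {
    for (int p = 0; p < P; ++p)
      for (int k = 0; k < 9; ++k) {
        int r = p % SIDE, c = p / SIDE;
        int rr = r + k % 3 - 1, cc = c + k / 3 - 1;
        q[p][k] = (rr < 0 || rr >= SIDE || cc < 0 || cc >= SIDE)
                    ? -1 : rr + SIDE * cc;
      }
  }
};
static const NbrTable NBR;

// A: C x (P*nb) feature maps -> col: (9*C) x (P*nb). Column j = p + P*b
// holds the 3x3 neighbourhood of position p; row block [C*k, C*(k+1)) is
// the channel vector of neighbour k, so each copy is contiguous.
static void im2col(const fmat& A, int nb, fmat& col) {
  const int C = A.n_rows;
  col.set_size(9 * C, P * (uword)nb);
  const size_t bytes = sizeof(float) * C;
  for (int b = 0; b < nb; ++b) {
    const uword off = (uword)P * b;
    for (int p = 0; p < P; ++p) {
      float* dst = col.colptr(off + p);
      for (int k = 0; k < 9; ++k) {
        int q = NBR.q[p][k];
        if (q < 0) std::memset(dst + C * k, 0, bytes);
        else std::memcpy(dst + C * k, A.colptr(off + q), bytes);
      }
    }
  }
}

// Scatter-add transpose of im2col: dcol (9*C x P*nb) -> dA (C x P*nb)
static void col2im(const fmat& dcol, int nb, fmat& dA) {
  const int C = dcol.n_rows / 9;
  dA.zeros(C, P * (uword)nb);
  for (int b = 0; b < nb; ++b) {
    const uword off = (uword)P * b;
    for (int p = 0; p < P; ++p) {
      const float* src = dcol.colptr(off + p);
      for (int k = 0; k < 9; ++k) {
        int q = NBR.q[p][k];
        if (q < 0) continue;
        float* dst = dA.colptr(off + q);
        const float* s = src + C * k;
        for (int c = 0; c < C; ++c) dst[c] += s[c];
      }
    }
  }
}

static inline fmat sigmoidf(const fmat& z) { return 1.0f / (1.0f + exp(-z)); }

// Per-layer reusable buffers (set_size is a no-op when dims are unchanged).
struct Workspace {
  fmat A1;                       // B x 1024 dense-1 activation
  std::vector<fmat> col;         // im2col buffer per conv layer
  std::vector<fmat> A;           // conv activations, A[0] is the reshaped input
  fmat F;                        // B x 1024 flattened
  fmat out;                      // B x 8
  std::vector<fmat> dA;          // conv backward buffers
  fmat dcol;
  Workspace(size_t nconv) : col(nconv), A(nconv + 1), dA(nconv + 1) {}
};

// Forward pass for nb samples; fills ws. Xb: nb x 1024.
static void forward(const Net& net, const fmat& Xb, Workspace& ws) {
  const int nb = Xb.n_rows;
  const size_t L = net.Wc.size();
  ws.A1 = sigmoidf(Xb * net.W1 + repmat(net.b1, nb, 1));
  // pack maps: A[0](0, p + P*b) = A1(b, p)
  ws.A[0] = reshape(fmat(ws.A1.t()), 1, (uword)P * nb);
  for (size_t l = 0; l < L; ++l) {
    im2col(ws.A[l], nb, ws.col[l]);
    fmat Z = net.Wc[l] * ws.col[l];
    Z.each_col() += net.bc[l];
    ws.A[l + 1] = (l + 1 < L) ? sigmoidf(Z) : Z; // last conv is linear
  }
  ws.F = reshape(ws.A[L], P, nb).t();            // nb x 1024
  ws.out = sigmoidf(ws.F * net.Wout + repmat(net.bout, nb, 1));
}

// Weighted loss over a prediction block: w_tau*MSE(cols 1..4) + w_amp*MSE(5..8)
static double wloss(const fmat& pred, const fmat& y, double w_tau, double w_amp) {
  const uword nb = pred.n_rows;
  fmat d = pred - y;
  double mt = accu(square(d.cols(0, 3))) / (4.0 * nb);
  double ma = accu(square(d.cols(4, 7))) / (4.0 * nb);
  return w_tau * mt + w_amp * ma;
}

// Backward pass + SGD-with-momentum update. Returns the batch loss.
static double backward_update(Net& net, Net& vel, const fmat& Xb, const fmat& Yb,
                              Workspace& ws, double lr, double momentum,
                              double w_tau, double w_amp) {
  const int nb = Xb.n_rows;
  const size_t L = net.Wc.size();
  double loss = wloss(ws.out, Yb, w_tau, w_amp);

  fmat dOut = ws.out - Yb;                       // nb x 8
  dOut.cols(0, 3) *= (float)(2.0 * w_tau / (4.0 * nb));
  dOut.cols(4, 7) *= (float)(2.0 * w_amp / (4.0 * nb));
  fmat dZout = dOut % ws.out % (1.0f - ws.out);

  fmat dWout = ws.F.t() * dZout;
  frowvec dbout = sum(dZout, 0);
  fmat dF = dZout * net.Wout.t();                // nb x 1024

  ws.dA[L] = reshape(fmat(dF.t()), 1, (uword)P * nb);

  std::vector<fmat> dWc(L);
  std::vector<fvec> dbc(L);
  for (int l = (int)L - 1; l >= 0; --l) {
    fmat dZ;
    if ((size_t)(l + 1) < L)                     // sigmoid layers
      dZ = ws.dA[l + 1] % ws.A[l + 1] % (1.0f - ws.A[l + 1]);
    else
      dZ = ws.dA[l + 1];                         // linear last conv
    dWc[l] = dZ * ws.col[l].t();
    dbc[l] = sum(dZ, 1);
    ws.dcol = net.Wc[l].t() * dZ;
    col2im(ws.dcol, nb, ws.dA[l]);
  }

  fmat dA1t = reshape(ws.dA[0], P, nb);          // 1024 x nb
  fmat dZ1 = dA1t.t() % ws.A1 % (1.0f - ws.A1);  // nb x 1024
  fmat dW1 = Xb.t() * dZ1;
  frowvec db1 = sum(dZ1, 0);

  const float m = (float)momentum, a = (float)lr;
  vel.W1 = m * vel.W1 - a * dW1;       net.W1 += vel.W1;
  vel.b1 = m * vel.b1 - a * db1;       net.b1 += vel.b1;
  for (size_t l = 0; l < L; ++l) {
    vel.Wc[l] = m * vel.Wc[l] - a * dWc[l];  net.Wc[l] += vel.Wc[l];
    vel.bc[l] = m * vel.bc[l] - a * dbc[l];  net.bc[l] += vel.bc[l];
  }
  vel.Wout = m * vel.Wout - a * dWout; net.Wout += vel.Wout;
  vel.bout = m * vel.bout - a * dbout; net.bout += vel.bout;
  return loss;
}

static Net zeros_like(const Net& n) {
  Net z;
  z.W1 = zeros<fmat>(size(n.W1));
  z.b1 = zeros<frowvec>(n.b1.n_elem);
  for (size_t l = 0; l < n.Wc.size(); ++l) {
    z.Wc.push_back(zeros<fmat>(size(n.Wc[l])));
    z.bc.push_back(zeros<fvec>(n.bc[l].n_elem));
  }
  z.Wout = zeros<fmat>(size(n.Wout));
  z.bout = zeros<frowvec>(n.bout.n_elem);
  return z;
}

// Full-dataset loss in evaluation mode, chunked to bound memory.
static double eval_loss(const Net& net, const fmat& X, const fmat& Y,
                        double w_tau, double w_amp, Workspace& ws, int chunk) {
  const uword n = X.n_rows;
  double acc = 0.0;
  for (uword i0 = 0; i0 < n; i0 += chunk) {
    uword i1 = std::min(i0 + chunk, n) - 1;
    fmat Xb = X.rows(i0, i1);
    forward(net, Xb, ws);
    acc += wloss(ws.out, Y.rows(i0, i1), w_tau, w_amp) * (i1 - i0 + 1);
  }
  return acc / n;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights,
                         const arma::mat& X, const arma::mat& Y,
                         const arma::mat& Xval, const arma::mat& Yval,
                         int epochs, int batch, double lr, double lr_decay,
                         double momentum,
                         double w_tau, double w_amp, int seed,
                         bool keep_best, int verbose_every) {
  Net net = net_from_list(weights);
  Net vel = zeros_like(net);
  const size_t L = net.Wc.size();
  Workspace ws(L), wsv(L);

  fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);
  fmat Xvf = conv_to<fmat>::from(Xval), Yvf = conv_to<fmat>::from(Yval);
  const uword n = Xf.n_rows;

  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  vec tr_hist(epochs, fill::zeros), va_hist(epochs, fill::zeros);
  Net best = net;
  double best_val = datum::inf;
  int best_epoch = 0;

  for (int e = 0; e < epochs; ++e) {
    const double lr_e = lr * std::pow(lr_decay, e);
    fisher_yates(idx, rng);
    double acc = 0.0;
    for (uword i0 = 0; i0 < n; i0 += batch) {
      uword nb = std::min<uword>(batch, n - i0);
      fmat Xb(nb, Xf.n_cols), Yb(nb, 8);
      for (uword j = 0; j < nb; ++j) {
        Xb.row(j) = Xf.row(idx[i0 + j]);
        Yb.row(j) = Yf.row(idx[i0 + j]);
      }
      forward(net, Xb, ws);
      double lb = backward_update(net, vel, Xb, Yb, ws, lr_e, momentum, w_tau, w_amp);
      if (!std::isfinite(lb))
        Rcpp::stop("non-finite training loss at epoch %d (diverged; lower the learning rate)", e + 1);
      acc += lb * nb;
    }
    tr_hist(e) = acc / n;
    va_hist(e) = eval_loss(net, Xvf, Yvf, w_tau, w_amp, wsv, 256);
    if (!std::isfinite(va_hist(e)))
      Rcpp::stop("non-finite validation loss at epoch %d", e + 1);
    if (va_hist(e) < best_val) { best_val = va_hist(e); best = net; best_epoch = e + 1; }
    if (verbose_every > 0 && ((e + 1) % verbose_every == 0 || e == 0))
      Rcpp::Rcout << "epoch " << e + 1 << "/" << epochs
                  << "  train " << tr_hist(e) << "  val " << va_hist(e) << "\n";
    Rcpp::checkUserInterrupt();
  }

  const Net& fin = keep_best ? best : net;
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(fin),
    Rcpp::Named("train_loss") = Rcpp::wrap(tr_hist),
    Rcpp::Named("val_loss") = Rcpp::wrap(va_hist),
    Rcpp::Named("best_epoch") = keep_best ? best_epoch : epochs,
    Rcpp::Named("best_val_loss") = keep_best ? best_val : va_hist(epochs - 1));
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(Rcpp::List weights, const arma::mat& X) {
  Net net = net_from_list(weights);
  Workspace ws(net.Wc.size());
  fmat Xf = conv_to<fmat>::from(X);
  const uword n = Xf.n_rows;
  mat out(n, 8);
  const uword chunk = 256;
  for (uword i0 = 0; i0 < n; i0 += chunk) {
    uword i1 = std::min(i0 + chunk, n) - 1;
    fmat Xb = Xf.rows(i0, i1);
    forward(net, Xb, ws);
    out.rows(i0, i1) = conv_to<mat>::from(ws.out);
  }
  return out;
}

// Across-sample standard deviation of each layer's activations (diagnostic
// for signal propagation through the stack) and of the final output.
// [[Rcpp::export]]
arma::vec cnn_signal_stats_cpp(Rcpp::List weights, const arma::mat& X) {
  Net net = net_from_list(weights);
  Workspace ws(net.Wc.size());
  fmat Xf = conv_to<fmat>::from(X);
  forward(net, Xf, ws);
  const int nb = Xf.n_rows;
  vec out(net.Wc.size() + 3);
  out(0) = stddev(vectorise(conv_to<mat>::from(Xf)));
  out(1) = accu(stddev(conv_to<mat>::from(ws.A1), 0, 0)) / ws.A1.n_cols;
  for (size_t l = 1; l <= net.Wc.size(); ++l) {
    // reshape to (C*P) x nb so stddev is across samples
    const fmat& A = ws.A[l];
    mat Ad = conv_to<mat>::from(A);
    uword C = A.n_rows;
    mat per(C * (uword)P, nb);
    for (int b = 0; b < nb; ++b)
      per.col(b) = vectorise(Ad.cols((uword)P * b, (uword)P * (b + 1) - 1));
    out(l + 1) = mean(stddev(per, 0, 1));
  }
  out(net.Wc.size() + 2) = mean(stddev(conv_to<mat>::from(ws.out), 0, 0));
  return out;
}

// Layer-sequential variance calibration (LSUV-style) on a calibration
// batch: per layer, rescale weights so the centered pre-activation has the
// target standard deviation and recenter the bias, so every sigmoid works
// in its responsive range from the first epoch. Output-layer biases keep
// their prior-logit values (passed in via the current bout).
// [[Rcpp::export]]
Rcpp::List cnn_calibrate_cpp(Rcpp::List weights, const arma::mat& X,
                             double hidden_sd, double out_sd) {
  Net net = net_from_list(weights);
  const size_t L = net.Wc.size();
  Workspace ws(L);
  fmat Xf = conv_to<fmat>::from(X);
  const int nb = Xf.n_rows;

  // dense 1
  {
    fmat Z = Xf * net.W1;                        // nb x 1024, no bias
    frowvec mu = mean(Z, 0);
    float sd = stddev(vectorise(Z.each_row() - mu));
    float s = (sd > 0) ? (float)hidden_sd / sd : 1.0f;
    net.W1 *= s;
    net.b1 = -s * mu;                            // centered
    ws.A1 = sigmoidf(Xf * net.W1 + repmat(net.b1, nb, 1));
    ws.A[0] = reshape(fmat(ws.A1.t()), 1, (uword)P * nb);
  }
  // conv stack
  for (size_t l = 0; l < L; ++l) {
    im2col(ws.A[l], nb, ws.col[l]);
    fmat Z = net.Wc[l] * ws.col[l];              // C_out x (P*nb), no bias
    fvec mu = mean(Z, 1);
    float sd = stddev(vectorise(Z.each_col() - mu));
    float s = (sd > 0) ? (float)hidden_sd / sd : 1.0f;
    net.Wc[l] *= s;
    net.bc[l] = -s * mu;
    Z = net.Wc[l] * ws.col[l];
    Z.each_col() += net.bc[l];
    ws.A[l + 1] = (l + 1 < L) ? sigmoidf(Z) : Z;
  }
  // output dense: scale, then recenter around the prior logits in bout
  {
    ws.F = reshape(ws.A[L], P, nb).t();
    fmat Z = ws.F * net.Wout;                    // nb x 8, no bias
    frowvec mu = mean(Z, 0);
    float sd = stddev(vectorise(Z.each_row() - mu));
    float s = (sd > 0) ? (float)out_sd / sd : 1.0f;
    net.Wout *= s;
    net.bout = net.bout - s * mu;                // bout holds prior logits
  }
  return net_to_list(net);
}
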