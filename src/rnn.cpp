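// Rate-RNN core: Euler-integrated rectified-tanh dynamics, backpropagation
// through time, and the Adam training loop. Trials are padded to a common
// length; all randomness (initial weights, trial pool, batch order) is drawn
// in R so runs are reproducible given the seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat rect_tanh(const mat& x) {
  mat r = tanh(x);
  r.elem(find(x <= 0)).zeros();
  return r;
}

// Forward-simulate a set of trials. U: inputs (n_in x T x K cube).
// Returns node rates (N x T x K) and outputs (n_out x T x K).
// [[Rcpp::export]]
Rcpp::List rnn_forward_cpp(const arma::mat& J, const arma::mat& B,
                           const arma::mat& W, const arma::cube& U,
                           double dt, double tau) {
  const uword N = J.n_rows, T = U.n_cols, K = U.n_slices;
  const double a = dt / tau;
  cube R(N, T, K), Z(W.n_rows, T, K);
  for (uword k = 0; k < K; ++k) {
    vec x(N, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      vec r = vectorise(rect_tanh(x));
      x = (1.0 - a) * x + a * (J * r + B * U.slice(k).col(t));
      vec rt = vectorise(rect_tanh(x));
      R.slice(k).col(t) = rt;
      Z.slice(k).col(t) = W * rt;
    }
  }
  return Rcpp::List::create(Rcpp::Named("rates") = R,
                            Rcpp::Named("outputs") = Z);
}

static inline fmat rect_tanh_f(const fmat& x) {
  fmat r = tanh(x);
  r.elem(find(x <= 0)).zeros();
  return r;
}

struct Grads { fmat gJ, gB, gW; double mse, pen; };

// One batched forward/backward pass in single precision (training only;
// analyses run through the double-precision forward pass above). U, Ztar:
// (n_in|n_out) x T x B cubes already gathered for the batch.
static Grads bptt_batch(const fmat& J, const fmat& B, const fmat& W,
                        const fcube& U, const fcube& Ztar,
                        float a, float alpha) {
  const uword N = J.n_rows, T = U.n_cols, nb = U.n_slices;
  fcube X(N, nb, T), R(N, nb, T);
  fmat x(N, nb, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    fmat r = rect_tanh_f(x);
    // gather input at time t across batch: B * U(:, t, k)
    fmat Ut(U.n_rows, nb);
    for (uword k = 0; k < nb; ++k) Ut.col(k) = U.slice(k).col(t);
    x = (1.0f - a) * x + a * (J * r + B * Ut);
    X.slice(t) = x;
    R.slice(t) = rect_tanh_f(x);
  }
  Grads g;
  g.gJ.zeros(N, N); g.gB.zeros(N, U.n_rows); g.gW.zeros(W.n_rows, N);
  g.mse = 0.0; g.pen = 0.0;
  const float M = float(W.n_rows) * float(T) * float(nb);
  fmat dx_next(N, nb, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const fmat& r_t = R.slice(tt);
    fmat Zt(W.n_rows, nb), Ut(U.n_rows, nb);
    for (uword k = 0; k < nb; ++k) {
      Zt.col(k) = Ztar.slice(k).col(tt);
      Ut.col(k) = U.slice(k).col(tt);
    }
    fmat err = W * r_t - Zt;
    g.mse += accu(square(err));
    g.pen += accu(square(r_t));
    fmat dz = 2.0f * err / M;
    g.gW += dz * r_t.t();
    fmat dr = W.t() * dz + (2.0f * alpha / float(nb)) * r_t
      + a * (J.t() * dx_next);
    fmat dphi = (1.0f - square(r_t));
    dphi.elem(find(X.slice(tt) <= 0)).zeros();
    fmat dx = dphi % dr + (1.0f - a) * dx_next;
    if (tt > 0) g.gJ += a * dx * R.slice(tt - 1).t();
    g.gB += a * dx * Ut.t();
    dx_next = dx;
  }
  g.mse /= M;
  g.pen /= double(nb);
  return g;
}

// Adam training over a fixed trial pool. batch_idx: n_steps x batch matrix
// of 1-based pool indices drawn in R.
// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(arma::mat J0, arma::mat B0, arma::mat W0,
                         const arma::cube& U0, const arma::cube& Ztar0,
                         const arma::imat& batch_idx,
                         double dt, double tau, double alpha,
                         double lr, double clip) {
  const float a = float(dt / tau);
  const uword n_steps = batch_idx.n_rows, nb = batch_idx.n_cols;
  fmat J = conv_to<fmat>::from(J0);
  fmat B = conv_to<fmat>::from(B0);
  fmat W = conv_to<fmat>::from(W0);
  const fcube U = conv_to<fcube>::from(U0);
  const fcube Ztar = conv_to<fcube>::from(Ztar0);
  fmat mJ(size(J), fill::zeros), vJ(size(J), fill::zeros);
  fmat mB(size(B), fill::zeros), vB(size(B), fill::zeros);
  fmat mW(size(W), fill::zeros), vW(size(W), fill::zeros);
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float lrf = float(lr), clipf = float(clip), alphaf = float(alpha);
  vec loss(n_steps), mse_log(n_steps);
  fcube Ub(U.n_rows, U.n_cols, nb), Zb(Ztar.n_rows, Ztar.n_cols, nb);
  for (uword s = 0; s < n_steps; ++s) {
    for (uword k = 0; k < nb; ++k) {
      uword idx = (uword)batch_idx(s, k) - 1;
      Ub.slice(k) = U.slice(idx);
      Zb.slice(k) = Ztar.slice(idx);
    }
    Grads g = bptt_batch(J, B, W, Ub, Zb, a, alphaf);
    loss(s) = g.mse + alpha * g.pen;
    mse_log(s) = g.mse;
    if (!std::isfinite(loss(s)))
      Rcpp::stop("training diverged (non-finite loss) at step %d", (int)s + 1);
    float gn = std::sqrt(accu(square(g.gJ)) + accu(square(g.gB)) +
                         accu(square(g.gW)));
    if (gn > clipf && gn > 0) {
      g.gJ *= clipf / gn; g.gB *= clipf / gn; g.gW *= clipf / gn;
    }
    float c1 = 1.0f - std::pow(b1, float(s + 1));
    float c2 = 1.0f - std::pow(b2, float(s + 1));
    mJ = b1 * mJ + (1 - b1) * g.gJ; vJ = b2 * vJ + (1 - b2) * square(g.gJ);
    J -= lrf * (mJ / c1) / (sqrt(vJ / c2) + eps);
    mB = b1 * mB + (1 - b1) * g.gB; vB = b2 * vB + (1 - b2) * square(g.gB);
    B -= lrf * (mB / c1) / (sqrt(vB / c2) + eps);
    mW = b1 * mW + (1 - b1) * g.gW; vW = b2 * vW + (1 - b2) * square(g.gW);
    W -= lrf * (mW / c1) / (sqrt(vW / c2) + eps);
  }
  return Rcpp::List::create(
    Rcpp::Named("J") = conv_to<mat>::from(J),
    Rcpp::Named("B") = conv_to<mat>::from(B),
    Rcpp::Named("W") = conv_to<mat>::from(W),
    Rcpp::Named("loss") = loss, Rcpp::Named("mse") = mse_log);
}
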