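// Incremental back-propagation trainer for a one-hidden-layer tanh MLP with a
// linear output layer.  Weights are updated after every presented sample
// (gradient descent with momentum); the learning rate adapts per epoch
// (increase on error decrease, decrease + step rejection on error increase);
// training stops early when validation error stops improving.
//
// All randomness (sample shuffling) is drawn from R's RNG so results are
// reproducible under set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

// Fisher-Yates shuffle of 0..n-1 driven by R's RNG.
void shuffle_idx(arma::uvec &idx) {
  const int n = idx.n_elem;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

double mse_of(const mat &X, const mat &Y, const mat &W1, const vec &b1,
              const mat &W2, const vec &b2) {
  // X: D x N (column-major samples), Y: M x N
  mat Hh = arma::tanh(W1 * X + arma::repmat(b1, 1, X.n_cols));
  mat E = Y - (W2 * Hh + arma::repmat(b2, 1, X.n_cols));
  return arma::accu(E % E) / (E.n_rows * E.n_cols);
}

} // namespace

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat &Xt, const arma::mat &Yt,
                   const arma::mat &Xv, const arma::mat &Yv,
                   arma::mat W1, arma::vec b1, arma::mat W2, arma::vec b2,
                   double lr, double momentum,
                   double lr_up, double lr_down, double max_perf_inc,
                   int patience, int max_epochs, int fixed_epochs,
                   int plateau_window, double plateau_tol) {
  // Xt: N x D, Yt: N x M (R layout); transposed internally.
  RNGScope scope;

  const mat X = Xt.t();  // D x N
  const mat Y = Yt.t();  // M x N
  const bool use_val = Xv.n_rows > 0;
  const mat XV = use_val ? mat(Xv.t()) : mat();
  const mat YV = use_val ? mat(Yv.t()) : mat();
  const int N = X.n_cols;

  mat vW1(arma::size(W1), arma::fill::zeros), vW2(arma::size(W2), arma::fill::zeros);
  vec vb1(arma::size(b1), arma::fill::zeros), vb2(arma::size(b2), arma::fill::zeros);

  double prev_mse = mse_of(X, Y, W1, b1, W2, b2);
  double best_val = use_val ? mse_of(XV, YV, W1, b1, W2, b2) : R_PosInf;
  mat bW1 = W1, bW2 = W2;
  vec bb1 = b1, bb2 = b2;
  int best_epoch = 0, wait = 0;

  const int n_epochs = fixed_epochs > 0 ? fixed_epochs : max_epochs;
  std::vector<double> trace;
  trace.reserve(n_epochs);

  arma::uvec idx = arma::regspace<arma::uvec>(0, N - 1);
  int epoch = 0;

  for (epoch = 1; epoch <= n_epochs; ++epoch) {
    // snapshot for possible step rejection
    mat sW1 = W1, sW2 = W2;
    vec sb1 = b1, sb2 = b2;

    shuffle_idx(idx);
    for (int t = 0; t < N; ++t) {
      const int n = idx[t];
      const vec x = X.col(n);
      vec h = arma::tanh(W1 * x + b1);
      vec e = Y.col(n) - (W2 * h + b2);           // M
      vec delta = (W2.t() * e) % (1.0 - h % h);   // H

      vW2 = momentum * vW2 + lr * (e * h.t());
      vb2 = momentum * vb2 + lr * e;
      vW1 = momentum * vW1 + lr * (delta * x.t());
      vb1 = momentum * vb1 + lr * delta;

      W2 += vW2; b2 += vb2;
      W1 += vW1; b1 += vb1;
    }

    if (!W1.is_finite() || !W2.is_finite()) {
      return List::create(_["diverged"] = true, _["epoch"] = epoch);
    }

    double cur = mse_of(X, Y, W1, b1, W2, b2);
    if (cur > prev_mse * max_perf_inc) {
      // reject the step: restore weights, damp the learning rate
      W1 = sW1; W2 = sW2; b1 = sb1; b2 = sb2;
      vW1.zeros(); vW2.zeros(); vb1.zeros(); vb2.zeros();
      lr *= lr_down;
      if (lr < 1e-10) break;
      trace.push_back(prev_mse);
      continue;
    }
    if (cur < prev_mse) lr = std::min(lr * lr_up, 1.0);
    prev_mse = cur;
    trace.push_back(cur);

    if (use_val) {
      double vmse = mse_of(XV, YV, W1, b1, W2, b2);
      if (vmse < best_val - 1e-12) {
        best_val = vmse;
        bW1 = W1; bW2 = W2; bb1 = b1; bb2 = b2;
        best_epoch = epoch;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else if (plateau_window > 0 &&
               (int)trace.size() > plateau_window) {
      // full-data fits stop when the training error stops improving
      double past = trace[trace.size() - 1 - plateau_window];
      if (past - cur < plateau_tol * past) break;
    }
  }

  if (use_val) { W1 = bW1; W2 = bW2; b1 = bb1; b2 = bb2; }

  return List::create(
      _["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
      _["diverged"] = false,
      _["epochs_run"] = std::min(epoch, n_epochs),
      _["best_epoch"] = use_val ? best_epoch : std::min(epoch, n_epochs),
      _["val_mse"] = best_val,
      _["train_trace"] = trace,
      _["final_lr"] = lr);
}
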