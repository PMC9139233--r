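// Fully connected feed-forward classifier backend: ReLU hidden layers,
// softmax output, categorical cross-entropy, Adam. Mini-batch SGD with a
// per-epoch Mersenne-Twister shuffle so runs are reproducible for a fixed
// seed and thread count.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void forward(const std::vector<mat>& W, const std::vector<rowvec>& b,
                    const mat& X, std::vector<mat>& A) {
  // A[0] = input; A[l] = activation after layer l; last layer softmax
  const size_t L = W.size();
  A[0] = X;
  for (size_t l = 0; l < L; ++l) {
    mat Z = A[l] * W[l];
    Z.each_row() += b[l];
    if (l + 1 < L) {
      A[l + 1] = clamp(Z, 0.0, datum::inf);  // ReLU
    } else {
      Z.each_col() -= max(Z, 1);             // stable softmax
      mat E = exp(Z);
      A[l + 1] = E.each_col() / sum(E, 1);
    }
  }
}

static double batch_ce(const mat& P, const uvec& y) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    s -= std::log(std::max(P(i, y[i]), 1e-12));
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(const arma::mat& X, const arma::uvec& y,
                         const arma::mat& Xval, const arma::uvec& yval,
                         Rcpp::List W0, Rcpp::List b0,
                         double lr, double beta1, double beta2, double eps,
                         int batch_size, int max_epochs, double cost_target,
                         int seed) {
  const size_t L = W0.size();
  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  const uword N = X.n_rows;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> perm(N);
  for (uword i = 0; i < N; ++i) perm[i] = i;

  std::vector<double> loss_hist, val_hist;
  std::vector<mat> A(L + 1), D(L);
  long t = 0;  // Adam step counter
  bool reached = false;
  int epoch = 0;
  const bool has_val = Xval.n_rows > 0;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double epoch_loss = 0.0;
    for (uword start = 0; start < N; start += batch_size) {
      uword end = std::min<uword>(start + batch_size, N) - 1;
      uvec idx(end - start + 1);
      for (uword i = start; i <= end; ++i) idx[i - start] = perm[i];
      mat Xb = X.rows(idx);
      uvec yb = y.elem(idx);
      const double nb = static_cast<double>(Xb.n_rows);

      forward(W, b, Xb, A);
      epoch_loss += batch_ce(A[L], yb);

      // delta at output: (P - onehot) / nb
      mat delta = A[L];
      for (uword i = 0; i < yb.n_elem; ++i) delta(i, yb[i]) -= 1.0;
      delta /= nb;

      ++t;
      const double bc1 = 1.0 - std::pow(beta1, (double)t);
      const double bc2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t l = L; l-- > 0;) {
        mat gW = A[l].t() * delta;
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(A[l] > 0.0);  // ReLU gradient
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        W[l] -= lr * (mW[l] / bc1) / (sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        b[l] -= lr * (mb[l] / bc1) / (sqrt(vb[l] / bc2) + eps);
      }
    }
    epoch_loss /= static_cast<double>(N);
    loss_hist.push_back(epoch_loss);
    if (has_val) {
      forward(W, b, Xval, A);
      val_hist.push_back(batch_ce(A[L], yval) /
                         static_cast<double>(Xval.n_rows));
    }
    if (epoch_loss < cost_target) { reached = true; break; }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Wout,
    Rcpp::Named("biases") = bout,
    Rcpp::Named("loss_history") = loss_hist,
    Rcpp::Named("val_history") = val_hist,
    Rcpp::Named("epochs_run") = std::min(epoch, max_epochs),
    Rcpp::Named("target_reached") = reached);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_predict(Rcpp::List Wl, Rcpp::List bl, const arma::mat& X,
                          int batch_size) {
  const size_t L = Wl.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(Wl[l]);
    b[l] = Rcpp::as<rowvec>(bl[l]);
  }
  const uword K = W[L - 1].n_cols;
  mat P(X.n_rows, K);
  std::vector<mat> A(L + 1);
  for (uword start = 0; start < X.n_rows; start += batch_size) {
    uword end = std::min<uword>(start + batch_size, X.n_rows) - 1;
    forward(W, b, X.rows(start, end), A);
    P.rows(start, end) = A[L];
  }
  return P;
}
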