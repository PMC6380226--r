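// Hot inner loops of the neural-field simulator: lateral settling and the
// per-frame Hebbian weight updates with divisive normalization. Everything
// here has a pure-R counterpart in the test suite used as an oracle.
//
// The update kernels modify the weight matrices IN PLACE: they run a few
// hundred thousand times per training run, and allocating a fresh
// multi-megabyte R matrix per frame is page-fault bound (~15x slower than
// the arithmetic itself). Field state lives in environments on the R side,
// and any code that needs a pre-update snapshot copies explicitly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::no_init;

// piecewise-linear sigmoid: 0 below lo, 1 above hi, linear ramp between
static inline double ramp1(double x, double lo, double hi) {
  double v = (x - lo) / (hi - lo);
  return v <= 0.0 ? 0.0 : (v >= 1.0 ? 1.0 : v);
}

// divide each row by its sum; rows summing to <= 0 are left unchanged
// (dead neuron: divisive normalization is skipped)
static inline void divide_rows(double* W, const double* sums, int n, int p) {
  std::vector<double> inv(n);
  for (int i = 0; i < n; ++i) inv[i] = sums[i] > 0.0 ? 1.0 / sums[i] : 1.0;
  for (int j = 0; j < p; ++j) {
    double* col = W + (size_t)j * n;
    for (int i = 0; i < n; ++i) col[i] *= inv[i];
  }
}

// Iterate the lateral settling dynamics for `steps` steps at fixed afferent
// drive S, starting from eta = eta0 (the settled activity of the previous
// frame; zero after a between-sequence reset). W_exc / W_inhb are dense
// n x n matrices, row i = incoming connections of neuron i. Returns
// eta(Ts); weights are read-only here.
// [[Rcpp::export]]
NumericVector cpp_settle(NumericVector S_, NumericVector eta0_,
                         NumericMatrix W_exc_, NumericMatrix W_inhb_,
                         double gamma_exc, double gamma_inhb, int steps,
                         double lo, double hi) {
  const int n = S_.size();
  const arma::vec S(S_.begin(), n, false, true);
  const arma::mat We(W_exc_.begin(), n, n, false, true);
  const arma::mat Wi(W_inhb_.begin(), n, n, false, true);
  NumericVector out_(no_init(n));
  arma::vec eta(out_.begin(), n, false, true);
  eta = arma::vec(eta0_.begin(), n, false, true);
  arma::vec drive(n);
  for (int s = 0; s < steps; ++s) {
    drive = S + gamma_exc * (We * eta) - gamma_inhb * (Wi * eta);
    for (int i = 0; i < n; ++i) eta(i) = ramp1(drive(i), lo, hi);
  }
  return out_;
}

// Afferent Hebbian update + per-neuron (row) divisive normalization,
// in place. W: n x p (row i = neuron i's RF weights), X: n x p input
// patches, dW(i,j) = alpha * eta(i) * X(i,j).
// [[Rcpp::export]]
void cpp_update_aff(NumericMatrix W_, NumericMatrix X_, NumericVector eta_,
                    double alpha) {
  const int n = W_.nrow(), p = W_.ncol();
  double* W = W_.begin();
  const double *X = X_.begin(), *eta = eta_.begin();
  std::vector<double> sums(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const size_t o = (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double v = W[o + i] + alpha * eta[i] * X[o + i];
      W[o + i] = v;
      sums[i] += v;
    }
  }
  divide_rows(W, sums.data(), n, p);
}

// Same update when every neuron shares one full-field receptive field
// (rf == input size): x is the single patch vector of length p. Columns
// with x[j] == 0 (moving stimuli are mostly background) only accumulate
// the normalization sum.
// [[Rcpp::export]]
void cpp_update_aff_shared(NumericMatrix W_, NumericVector x_,
                           NumericVector eta_, double alpha) {
  const int n = W_.nrow(), p = x_.size();
  double* W = W_.begin();
  const double *x = x_.begin(), *eta = eta_.begin();
  std::vector<double> sums(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const size_t o = (size_t)j * n;
    const double axj = alpha * x[j];
    if (axj == 0.0) {
      for (int i = 0; i < n; ++i) sums[i] += W[o + i];
    } else {
      for (int i = 0; i < n; ++i) {
        double v = W[o + i] + axj * eta[i];
        W[o + i] = v;
        sums[i] += v;
      }
    }
  }
  divide_rows(W, sums.data(), n, p);
}

// Lateral Hebbian update on a masked n x n matrix plus row-wise divisive
// normalization, in place. Asymmetric rule: dW(i,k) = alpha * post(i) *
// pre(k) with post = max(0, eta_t - eta_prev) and pre = eta_prev; the
// symmetric control rule passes post = pre = eta_t. mask is the 0/1
// support of the disc/annulus (self-connection excluded).
// [[Rcpp::export]]
void cpp_update_lat(NumericMatrix W_, NumericVector post_,
                    NumericVector pre_, double alpha, NumericMatrix mask_) {
  const int n = W_.nrow();
  double* W = W_.begin();
  const double *mask = mask_.begin();
  const double *post = post_.begin(), *pre = pre_.begin();
  std::vector<double> sums(n, 0.0);
  for (int k = 0; k < n; ++k) {  // column k = presynaptic neuron
    const size_t o = (size_t)k * n;
    const double apre = alpha * pre[k];
    if (apre == 0.0) {
      for (int i = 0; i < n; ++i) sums[i] += W[o + i];
    } else {
      for (int i = 0; i < n; ++i) {
        double v = W[o + i] + (mask[o + i] != 0.0 ? apre * post[i] : 0.0);
        W[o + i] = v;
        sums[i] += v;
      }
    }
  }
  divide_rows(W, sums.data(), n, n);
}

// Afferent drive (scaled inner product of weights and RF patch) through
// the piecewise-linear sigmoid. X: n x p patches; read-only.
// [[Rcpp::export]]
NumericVector cpp_aff_response(NumericMatrix W_, NumericMatrix X_,
                               double gamma_aff, double lo, double hi) {
  const int n = W_.nrow(), p = W_.ncol();
  NumericVector out_(no_init(n));
  const double *W = W_.begin(), *X = X_.begin();
  std::vector<double> acc(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const size_t o = (size_t)j * n;
    for (int i = 0; i < n; ++i) acc[i] += W[o + i] * X[o + i];
  }
  for (int i = 0; i < n; ++i) out_[i] = ramp1(gamma_aff * acc[i], lo, hi);
  return out_;
}
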