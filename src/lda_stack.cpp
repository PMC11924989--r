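// Time-resolved shrinkage-LDA primitives.
//
// The per-timepoint loop (180 discriminants per classifier stack, times
// folds, locations and subjects) is the hot path of the package; it is
// implemented here with Armadillo. The covariance estimate is the
// Ledoit-Wolf analytic shrinkage toward a scaled identity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fit one shrinkage-LDA discriminant. X: trials x channels, y: 1 = high SF.
static void fit_one(const mat& X, const uvec& y, vec& w, double& b) {
  const uvec i1 = find(y == 1), i0 = find(y == 0);
  const rowvec mu1 = mean(X.rows(i1), 0), mu0 = mean(X.rows(i0), 0);
  mat C(X.n_rows, X.n_cols);
  C.rows(i1) = X.rows(i1) - repmat(mu1, i1.n_elem, 1);
  C.rows(i0) = X.rows(i0) - repmat(mu0, i0.n_elem, 1);
  const double n = (double)X.n_rows, p = (double)X.n_cols;
  mat S = C.t() * C / n;
  const double m = trace(S) / p;
  mat target = m * eye(X.n_cols, X.n_cols);
  const double d2 = accu(square(S - target));
  mat sigma;
  if (d2 < datum::eps) {
    sigma = target + 1e-12 * eye(X.n_cols, X.n_cols);
  } else {
    const vec q = sum(square(C), 1);
    const double b2bar =
        (accu(square(q)) - 2.0 * accu((C * S) % C) + n * accu(square(S))) /
        (n * n);
    const double rho = std::min(1.0, std::max(0.0, b2bar / d2));
    sigma = (1.0 - rho) * S + rho * target;
  }
  w = solve(sigma, (mu1 - mu0).t(), solve_opts::likely_sympd);
  b = -dot(w, (mu1 + mu0).t() / 2.0);
}

// Fit a discriminant at every timepoint.
// data: trials x channels x timepoints cube; idx: 0-based training rows;
// y: class indicator aligned with idx. Returns weights (channels x T), bias.
// [[Rcpp::export]]
Rcpp::List lda_fit_stack_cpp(const arma::cube& data, const arma::uvec& idx,
                             const arma::uvec& y) {
  const uword T = data.n_slices, p = data.n_cols;
  mat W(p, T);
  vec bias(T);
  vec w;
  double b;
  for (uword t = 0; t < T; ++t) {
    fit_one(data.slice(t).rows(idx), y, w, b);
    W.col(t) = w;
    bias(t) = b;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("bias") = bias);
}

// Diagonal decision scores: trials x timepoints matrix of w_t' x + b_t.
// [[Rcpp::export]]
arma::mat lda_score_stack_cpp(const arma::cube& data, const arma::uvec& idx,
                              const arma::mat& W, const arma::vec& bias) {
  const uword T = data.n_slices;
  mat out(idx.n_elem, T);
  for (uword t = 0; t < T; ++t) {
    out.col(t) = data.slice(t).rows(idx) * W.col(t) + bias(t);
  }
  return out;
}
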