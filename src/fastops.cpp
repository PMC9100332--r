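// Small hot-path kernels. The in-place variants (_ip) deliberately mutate
// their first argument and must only ever be called on freshly allocated
// matrices owned by the caller (they are internal to the layer code).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix relu_ip(NumericMatrix X) {
  double* p = X.begin();
  const R_xlen_t n = X.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return X;
}

// dY * (act > 0), single pass
// [[Rcpp::export]]
NumericMatrix relu_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& act) {
  NumericMatrix out(dY.nrow(), dY.ncol());
  const double* d = dY.begin();
  const double* a = act.begin();
  double* o = out.begin();
  const R_xlen_t n = dY.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i] > 0 ? d[i] : 0.0;
  return out;
}

// Y(i, j) += b[j], in place
// [[Rcpp::export]]
NumericMatrix addbias_ip(NumericMatrix Y, const NumericVector& b) {
  const int nr = Y.nrow(), nc = Y.ncol();
  double* p = Y.begin();
  for (int j = 0; j < nc; ++j) {
    const double bj = b[j];
    double* col = p + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
  return Y;
}

// Layer norm across columns per row: out = xhat * g + b
// [[Rcpp::export]]
List ln_fwd_cpp(const arma::mat& X, const arma::vec& g, const arma::vec& b,
                double eps = 1e-5) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::vec mu = arma::mean(X, 1);
  arma::mat xhat = X.each_col() - mu;
  arma::vec sd = arma::sqrt(arma::sum(arma::square(xhat), 1) / d + eps);
  xhat.each_col() /= sd;
  arma::mat out(n, d);
  for (arma::uword j = 0; j < d; ++j)
    out.col(j) = xhat.col(j) * g[j] + b[j];
  return List::create(_["out"] = out, _["xhat"] = xhat, _["sd"] = sd);
}

// [[Rcpp::export]]
List ln_bwd_cpp(const arma::mat& dY, const arma::mat& xhat, const arma::vec& sd,
                const arma::vec& g) {
  const arma::uword d = dY.n_cols;
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::sum(dxhat % xhat, 1) / d;
  arma::mat dX = (dxhat.each_col() - m1) - (xhat.each_col() % m2);
  dX.each_col() /= sd;
  arma::rowvec dg = arma::sum(dY % xhat, 0);
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX, _["dg"] = dg.t(), _["db"] = db.t());
}
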