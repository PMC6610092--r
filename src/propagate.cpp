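// Iterative random walk with restarts over a row-stochastic transition
// matrix. The update is p_i = p_{i-1} * W * (1 - c) + c * p_0 with p a row
// vector; convergence is declared when the L1 change between successive
// iterates falls below tol. Small restart probabilities need ~1e5
// iterations, hence the compiled loop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_propagate(const arma::sp_mat& W, const arma::rowvec& p0, double c,
                   double tol, int max_iter, bool keep_trace) {
  arma::rowvec p = p0;
  arma::rowvec pnew;
  double max_sum_dev = std::abs(arma::accu(p) - 1.0);
  std::vector<double> trace;
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    ++it;
    pnew = (1.0 - c) * (p * W) + c * p0;
    double d = arma::accu(arma::abs(pnew - p));
    double sdev = std::abs(arma::accu(pnew) - 1.0);
    if (sdev > max_sum_dev) max_sum_dev = sdev;
    if (keep_trace) trace.push_back(d);
    p = pnew;
    if (d < tol) { converged = true; break; }
  }
  return List::create(_["values"] = NumericVector(p.begin(), p.end()),
                      _["iterations"] = it,
                      _["converged"] = converged,
                      _["max_sum_dev"] = max_sum_dev,
                      _["diff_trace"] = NumericVector(trace.begin(),
                                                      trace.end()));
}

// [[Rcpp::export]]
List cpp_propagate_batch(const arma::sp_mat& W, const arma::mat& P0, double c,
                         double tol, int max_iter) {
  arma::mat P = P0;
  const arma::uword m = P0.n_rows;
  arma::ivec iters(m, arma::fill::zeros);
  arma::uvec done(m, arma::fill::zeros);
  double max_sum_dev = arma::abs(arma::sum(P, 1) - 1.0).max();
  int it = 0;
  while (it < max_iter) {
    ++it;
    arma::mat Pnew = (1.0 - c) * (P * W) + c * P0;
    arma::vec d = arma::sum(arma::abs(Pnew - P), 1);
    double sdev = arma::abs(arma::sum(Pnew, 1) - 1.0).max();
    if (sdev > max_sum_dev) max_sum_dev = sdev;
    P = Pnew;
    bool all_done = true;
    for (arma::uword r = 0; r < m; ++r) {
      if (!done(r)) {
        if (d(r) < tol) { done(r) = 1; iters(r) = it; }
        else all_done = false;
      }
    }
    if (all_done) break;
  }
  for (arma::uword r = 0; r < m; ++r) if (!done(r)) iters(r) = it;
  return List::create(_["values"] = P,
                      _["iterations"] = IntegerVector(iters.begin(),
                                                      iters.end()),
                      _["converged"] = LogicalVector(done.begin(),
                                                     done.end()),
                      _["max_sum_dev"] = max_sum_dev);
}
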