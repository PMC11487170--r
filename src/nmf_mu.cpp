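// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Lee-Seung multiplicative updates for the Frobenius loss ||X - A P||_F.
// A and P arrive pre-initialised (all RNG stays on the R side so runs are
// reproducible from a seed). The eps guard keeps denominators positive;
// entries driven to zero stay zero, preserving non-negativity exactly.
// [[Rcpp::export(name = ".nmf_mu")]]
Rcpp::List nmf_mu(const arma::mat& X, arma::mat A, arma::mat P,
                  int max_iter, double tol) {
  const double eps = 1e-12;
  std::vector<double> trace;
  trace.reserve(64);
  double err_prev = datum::inf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    A = A % (X * P.t()) / (A * (P * P.t()) + eps);
    P = P % (A.t() * X) / ((A.t() * A) * P + eps);
    double err = norm(X - A * P, "fro");
    trace.push_back(err);
    if (std::isfinite(err_prev)) {
      double denom = std::max(err_prev, eps);
      if ((err_prev - err) / denom < tol) { converged = true; break; }
    }
    err_prev = err;
  }
  double err_final = trace.empty() ? norm(X, "fro") : trace.back();
  return Rcpp::List::create(
    Rcpp::Named("A") = A,
    Rcpp::Named("P") = P,
    Rcpp::Named("frobenius_error") = err_final,
    Rcpp::Named("iterations") = (int) trace.size(),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("error_trace") = trace);
}
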