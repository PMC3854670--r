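// Greedy sparse solvers: simultaneous orthogonal matching pursuit (SOMP).
// A is n x N (atoms in columns), Y is n x s. At each step the atom with the
// largest q-norm of correlations against the current residual is added to the
// row support, the coefficients on the support are refit by least squares,
// and the residual is recomputed. OMP is the s = 1 special case.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".somp_cpp")]]
List somp_cpp(const arma::mat& A, const arma::mat& Y, int K0, double tol,
              double q) {
  const arma::uword N = A.n_cols, s = Y.n_cols;
  arma::mat R = Y;                       // residual, R0 = Y
  std::vector<arma::uword> support;
  std::vector<double> trace;
  arma::mat Xs;                          // |support| x s coefficients
  double rnorm = arma::norm(R, "fro");

  if (K0 > (int)N)
    Rcpp::stop("K0 (%d) exceeds the number of atoms (%d)", K0, (int)N);

  int iter = 0;
  while ((int)support.size() < K0 && rnorm > tol) {
    // correlations of every atom with the residual; row k of A^T R
    arma::mat C = A.t() * R;             // N x s
    arma::vec score(N);
    if (q == 2.0) {
      score = arma::sqrt(arma::sum(arma::square(C), 1));
    } else {
      score = arma::pow(arma::sum(arma::pow(arma::abs(C), q), 1), 1.0 / q);
    }
    for (arma::uword j : support) score(j) = -1.0;  // never reselect
    // deterministic tie-break: lowest index wins
    arma::uword w = 0;
    double best = score(0);
    for (arma::uword k = 1; k < N; ++k)
      if (score(k) > best) { best = score(k); w = k; }
    support.push_back(w);

    arma::uvec omega(support.size());
    for (arma::uword j = 0; j < support.size(); ++j) omega(j) = support[j];
    arma::mat Ao = A.cols(omega);
    // pseudo-inverse update via least squares
    bool ok = arma::solve(Xs, Ao, Y);
    if (!ok) Xs = arma::pinv(Ao) * Y;
    R = Y - Ao * Xs;
    rnorm = arma::norm(R, "fro");
    trace.push_back(rnorm);
    ++iter;
  }

  arma::mat X(N, s, arma::fill::zeros);
  for (arma::uword j = 0; j < support.size(); ++j)
    X.row(support[j]) = Xs.row(j);

  IntegerVector sup(support.size());
  for (size_t j = 0; j < support.size(); ++j) sup[j] = (int)support[j] + 1;

  return List::create(_["coefficients"] = X,
                      _["support"] = sup,
                      _["residual_norm"] = rnorm,
                      _["iterations"] = iter,
                      _["residual_trace"] = NumericVector(trace.begin(), trace.end()));
}
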