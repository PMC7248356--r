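// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Adjoint gradient of the MSE cost through the steady-state fixed point.
// Given the solved excitation vector q, assembles the linearised map
// J[i,k] = d q_i / d q_k, solves the adjoint system (I - J)^T lam = e and
// returns the full (unmasked) gradient matrices
//   G+[a,b] = lam_b q_a / D_b - q_a lam_a / (D_a (1 - d_a))
//   G-[a,b] = -lam_b q_b q_a / D_b - q_a lam_a / (D_a (1 - d_a))
// with the row-rate term zeroed for sink rows.
// [[Rcpp::export(name = ".gnet_gradient_core_cpp")]]
List gnet_gradient_core_cpp(const arma::mat& w_plus, const arma::mat& w_minus,
                            const arma::vec& r, const arma::vec& d,
                            const arma::vec& lambda_minus,
                            const arma::vec& q, const arma::vec& e,
                            const arma::uvec& is_sink) {
  const arma::uword n = q.n_elem;
  arma::vec D = r + lambda_minus + w_minus.t() * q;
  arma::mat J = (w_plus.t() - arma::diagmat(q) * w_minus.t());
  J.each_col() /= D;
  arma::mat A = arma::eye(n, n) - J;
  arma::vec lam = arma::solve(A.t(), e);

  arma::vec u = lam / D;
  arma::vec c_r(n);
  for (arma::uword i = 0; i < n; ++i)
    c_r[i] = is_sink[i] ? 0.0 : q[i] * lam[i] / (D[i] * (1.0 - d[i]));

  arma::mat g_plus = q * u.t();
  g_plus.each_col() -= c_r;
  arma::mat g_minus = -(q * (u % q).t());
  g_minus.each_col() -= c_r;
  return List::create(_["g_plus"] = g_plus, _["g_minus"] = g_minus);
}
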