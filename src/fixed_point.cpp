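#include <Rcpp.h>
using namespace Rcpp;

// Damped successive substitution for the G-network excitation fixed point
//   q_i = (Lambda_i + sum_j q_j w+(j,i)) / (r_i + lambda_i + sum_j q_j w-(j,i))
// q is clipped into [0, 1] during iteration; the residual is the unrelaxed
// update norm max|T(q) - q|. Hot path of the steady-state solver and the
// training loop.
// [[Rcpp::export(name = ".gnet_fixed_point_cpp")]]
List gnet_fixed_point_cpp(NumericMatrix w_plus, NumericMatrix w_minus,
                          NumericVector r, NumericVector Lambda,
                          NumericVector lambda_minus, NumericVector q0,
                          double tol, int max_iter, double damping) {
  const int n = r.size();
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> num(n), den(n);
  double res = R_PosInf;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double s_p = 0.0, s_m = 0.0;
      for (int j = 0; j < n; ++j) {
        s_p += q[j] * w_plus(j, i);
        s_m += q[j] * w_minus(j, i);
      }
      num[i] = Lambda[i] + s_p;
      den[i] = r[i] + lambda_minus[i] + s_m;
    }
    res = 0.0;
    for (int i = 0; i < n; ++i) {
      double t = den[i] > 0.0 ? num[i] / den[i] : 0.0;
      if (t < 0.0) t = 0.0;
      if (t > 1.0) t = 1.0;
      double d = std::fabs(t - q[i]);
      if (d > res) res = d;
      num[i] = t;   // reuse num as T(q)
    }
    if (res < tol) {
      for (int i = 0; i < n; ++i) q[i] = num[i];
      converged = true;
      break;
    }
    for (int i = 0; i < n; ++i) q[i] += damping * (num[i] - q[i]);
  }
  return List::create(_["q"] = NumericVector(q.begin(), q.end()),
                      _["converged"] = converged,
                      _["n_iterations"] = std::min(it, max_iter),
                      _["residual"] = res);
}
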