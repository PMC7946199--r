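// Spectral ADMM iteration of 2D variational mode decomposition.
//
// Everything happens in the frequency domain: the forward/inverse FFTs are
// done once on the R side. Each iteration performs, per mode k, the Wiener
// update restricted to the analytic half-plane, then recenters w_k on the
// power-spectrum centroid of the updated mode, and finally a dual ascent
// step on the reconstruction constraint.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List vmd_core_cpp(const arma::cx_mat& fhat, const arma::mat& FX,
                        const arma::mat& FY, arma::mat omega, const arma::vec& alpha,
                        double tau, double tol, int max_iter, bool dc_mode) {
  const int K = omega.n_rows;
  const uword N = fhat.n_elem;
  std::vector<cx_mat> U(K, cx_mat(fhat.n_rows, fhat.n_cols, fill::zeros));
  cx_mat lambda(fhat.n_rows, fhat.n_cols, fill::zeros);
  cx_mat sum_u(fhat.n_rows, fhat.n_cols, fill::zeros);
  std::vector<double> trace;
  bool diverged = false;
  int iters = 0;
  int grow_run = 0;  // consecutive iterations with 10x growth over 20 steps

  const std::complex<double>* fp = fhat.memptr();
  const double* fx = FX.memptr();
  const double* fy = FY.memptr();

  for (int it = 0; it < max_iter; ++it) {
    double crit = 0.0;
    for (int k = 0; k < K; ++k) {
      const double wx = omega(k, 0), wy = omega(k, 1);
      const double alk = alpha(k);
      std::complex<double>* uk = U[k].memptr();
      std::complex<double>* su = sum_u.memptr();
      const std::complex<double>* lp = lambda.memptr();
      double num = 0.0, den = 0.0, px = 0.0, py = 0.0, ptot = 0.0;
      for (uword i = 0; i < N; ++i) {
        const std::complex<double> old = uk[i];
        const std::complex<double> rest = su[i] - old;
        // all modes share the fixed half-plane fx >= 0: real modes are
        // fully determined by it, and a common domain makes the modes
        // compete for every coefficient (per-mode tilted half-planes let a
        // second mode duplicate low-frequency content from the conjugate
        // mirror region without any competition)
        const bool inmask = fx[i] >= 0.0;
        std::complex<double> nu(0.0, 0.0);
        if (inmask) {
          const double dx = fx[i] - wx, dy = fy[i] - wy;
          nu = (fp[i] - rest + 0.5 * lp[i]) /
               (1.0 + 2.0 * alk * (dx * dx + dy * dy));
        }
        uk[i] = nu;
        su[i] = rest + nu;
        num += std::norm(nu - old);
        den += std::norm(old);
        const double p = std::norm(nu);
        px += fx[i] * p;
        py += fy[i] * p;
        ptot += p;
      }
      crit += num / std::max(den, 1e-10);
      // centroid update; the DC-pinned first mode keeps omega = (0,0)
      if (!(dc_mode && k == 0) && ptot > 0.0) {
        omega(k, 0) = px / ptot;
        omega(k, 1) = py / ptot;
      }
    }
    if (tau != 0.0) lambda += tau * (fhat - sum_u);
    trace.push_back(crit);
    iters = it + 1;
    if (crit < tol) break;
    // divergence = sustained unbounded growth: 10x above the value 20
    // iterations earlier on several consecutive iterations AND far above
    // the best value seen (plateau oscillation and single spikes from
    // center-frequency jumps are not divergence)
    const double best = *std::min_element(trace.begin(), trace.end());
    if (it >= 20 && crit > 10.0 * trace[it - 20] && crit > 1e3 * best)
      ++grow_run;
    else
      grow_run = 0;
    if (grow_run >= 5) { diverged = true; break; }
  }

  Rcpp::List uhats(K);
  for (int k = 0; k < K; ++k) uhats[k] = U[k];
  return Rcpp::List::create(
      Rcpp::Named("u_hats") = uhats, Rcpp::Named("omegas") = omega,
      Rcpp::Named("n_iter") = iters, Rcpp::Named("trace") = trace,
      Rcpp::Named("diverged") = diverged);
}
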