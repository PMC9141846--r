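// Joint RK4 integrator for the anti-Hebbian self-poising system
//   x' = M x
//   M' = alpha (I - x x^T)
// The two timescales (activity ~1, plasticity ~1/alpha) force ~1e6 small
// dense steps for alpha = 1e-3, which is why this lives in compiled code.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List ah_integrate_cpp(const arma::vec& x0, const arma::mat& M0,
                            double alpha, double dt, int nsteps,
                            int record_every) {
  const int n = x0.n_elem;
  vec x = x0;
  mat M = M0;
  const mat I = eye(n, n);

  const int nrec = nsteps / record_every + 1;
  // real/imag parts kept separate (Rcomplex interop)
  mat eig_re(n, nrec), eig_im(n, nrec);
  mat xs(n, nrec);
  vec times(nrec), trM(nrec), xnorm2(nrec);

  int rec = 0;
  auto record = [&](int step) {
    times(rec) = step * dt;
    cx_vec ev = eig_gen(M);
    eig_re.col(rec) = real(ev);
    eig_im.col(rec) = imag(ev);
    xs.col(rec) = x;
    trM(rec) = trace(M);
    xnorm2(rec) = dot(x, x);
    ++rec;
  };
  record(0);

  vec k1x(n), k2x(n), k3x(n), k4x(n), xt(n);
  mat k1M(n, n), k2M(n, n), k3M(n, n), k4M(n, n);

  for (int s = 1; s <= nsteps; ++s) {
    k1x = M * x;
    k1M = alpha * (I - x * x.t());

    xt = x + 0.5 * dt * k1x;
    k2x = (M + 0.5 * dt * k1M) * xt;
    k2M = alpha * (I - xt * xt.t());

    xt = x + 0.5 * dt * k2x;
    k3x = (M + 0.5 * dt * k2M) * xt;
    k3M = alpha * (I - xt * xt.t());

    xt = x + dt * k3x;
    k4x = (M + dt * k3M) * xt;
    k4M = alpha * (I - xt * xt.t());

    x += (dt / 6.0) * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    M += (dt / 6.0) * (k1M + 2.0 * k2M + 2.0 * k3M + k4M);

    if (s % record_every == 0) {
      if (!x.is_finite() || !M.is_finite())
        Rcpp::stop("integration blow-up at t = %f", s * dt);
      record(s);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("times") = times.head(rec),
      Rcpp::Named("eig_re") = eig_re.head_cols(rec),
      Rcpp::Named("eig_im") = eig_im.head_cols(rec),
      Rcpp::Named("x") = xs.head_cols(rec),
      Rcpp::Named("trM") = trM.head(rec),
      Rcpp::Named("xnorm2") = xnorm2.head(rec),
      Rcpp::Named("x_final") = x,
      Rcpp::Named("M_final") = M);
}
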