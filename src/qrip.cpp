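#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Frisch-Newton primal-dual interior point solver for the quantile
// regression linear program, generalised to a per-observation quantile
// level.  Solves
//
//   min_b  sum_i rho_{tau_i}(y_i - x_i' b),   rho_t(u) = u (t - 1{u<0})
//
// through the bounded-variable dual
//
//   max_a  y'a   s.t.  X'a = X'(1 - tau),  0 <= a <= 1,
//
// with Mehrotra predictor-corrector steps.  The multiplier on the equality
// constraint at the optimum is the coefficient vector b.  L1 penalties and
// composite (shared-slope) fits are handled upstream by augmenting rows,
// which is why tau is a vector here.
//
// [[Rcpp::export]]
Rcpp::List qr_fit_ip(const arma::mat& X, const arma::vec& y,
                     const arma::vec& tau,
                     double tol = 1e-10, int maxit = 100,
                     double step_factor = 0.99995) {
  const uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n || tau.n_elem != n)
    Rcpp::stop("dimension mismatch in qr_fit_ip");

  vec a = 1.0 - tau;              // dual variables, feasible by construction
  vec s = tau;                    // slacks: a + s = 1
  vec b;
  bool ok = solve(b, X.t() * X + 1e-10 * eye(p, p), X.t() * y,
                  solve_opts::likely_sympd);
  if (!ok) b = pinv(X) * y;

  vec res = y - X * b;
  const double eps0 = 1e-6 * (1.0 + stddev(res));
  vec q = clamp(res, 0.0, datum::inf) + eps0;   // q - r = y - X b keeps the
  vec r = clamp(-res, 0.0, datum::inf) + eps0;  // dual constraint feasible

  int it = 0;
  double gap = dot(r, a) + dot(q, s);
  for (it = 0; it < maxit && gap > tol * (1.0 + n); ++it) {
    vec d = 1.0 / (q / s + r / a);
    // affine (predictor) direction: mu = 0
    vec u_aff = q - r;
    mat XD = X.each_col() % d;
    mat M = X.t() * XD;
    M.diag() += 1e-12 * (1.0 + trace(M) / p);  // guards late-stage collapse
    vec dw_aff;
    if (!solve(dw_aff, M, XD.t() * u_aff, solve_opts::likely_sympd))
      dw_aff = pinv(M) * (XD.t() * u_aff);
    vec da_aff = d % (u_aff - X * dw_aff);
    vec dr_aff = -r - (r / a) % da_aff;
    vec dq_aff = -q + (q / s) % da_aff;

    auto steplen = [&](const vec& v, const vec& dv) {
      double al = 1.0;
      for (uword i = 0; i < v.n_elem; ++i)
        if (dv(i) < 0) al = std::min(al, -v(i) / dv(i));
      return al;
    };
    double ap = std::min(steplen(a, da_aff), steplen(s, -da_aff));
    double ad = std::min(steplen(r, dr_aff), steplen(q, dq_aff));
    ap = std::min(1.0, step_factor * ap);
    ad = std::min(1.0, step_factor * ad);

    double gap_aff = dot(r + ad * dr_aff, a + ap * da_aff) +
                     dot(q + ad * dq_aff, s - ap * da_aff);
    double mu = gap_aff / gap;
    mu = mu * mu * mu * gap / (2.0 * n);

    // corrector with second-order complementarity terms
    vec u = (mu - a % r - da_aff % dr_aff) / a -
            (mu - s % q + da_aff % dq_aff) / s;
    vec dw;
    if (!solve(dw, M, XD.t() * u, solve_opts::likely_sympd))
      dw = pinv(M) * (XD.t() * u);
    vec da = d % (u - X * dw);
    vec dr = (mu - a % r - da_aff % dr_aff) / a - (r / a) % da;
    vec dq = (mu - s % q + da_aff % dq_aff) / s + (q / s) % da;

    ap = std::min(steplen(a, da), steplen(s, -da));
    ad = std::min(steplen(r, dr), steplen(q, dq));
    ap = std::min(1.0, step_factor * ap);
    ad = std::min(1.0, step_factor * ad);

    a += ap * da;  s -= ap * da;
    r += ad * dr;  q += ad * dq;
    b += ad * dw;
    gap = dot(r, a) + dot(q, s);
  }

  res = y - X * b;
  vec pos = clamp(res, 0.0, datum::inf), neg = clamp(-res, 0.0, datum::inf);
  double obj = dot(tau, pos) + dot(1.0 - tau, neg);
  return Rcpp::List::create(Rcpp::Named("coefficients") = b,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("gap") = gap);
}
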