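#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Primal-dual interior-point solver for the check-loss problem
//
//   min_b  sum_i rho_tau(y_i - x_i' b),
//
// posed as the LP  min tau*1'u + (1-tau)*1'v  s.t.  Xb + u - v = y, u,v >= 0.
// KKT conditions (d the dual of the equality constraint):
//   X'd = 0,  z = tau - d >= 0,  w = (1-tau) + d >= 0,
//   u.z = 0,  v.w = 0,  Xb + u - v = y.
// Starting from b = OLS, d = 0 keeps the linear residuals exactly zero, so
// Newton steps only have to drive complementarity; Mehrotra's
// predictor-corrector is used with a single factorization per iteration.
// At the optimum d_i = tau for positive residuals and tau - 1 for negative
// ones (values in between on the basic observations): d is exactly the
// regression rank-score vector used by the rank-score association test.
static bool rq_ip(const mat& X, const vec& y, const double tau,
                  const double tol, const int maxit,
                  vec& b, vec& d, double& obj, int& iters) {
  const int n = X.n_rows;
  const double big = 0.9995;

  mat XtX = X.t() * X;
  bool ok = solve(b, XtX, X.t() * y, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) b = pinv(X) * y;
  vec r = y - X * b;
  const double eps0 = std::max(0.1, 0.1 * mean(abs(r)));
  vec u = clamp(r, 0.0, datum::inf) + eps0;
  vec v = u - r;                       // r^- + eps0, stays > 0
  d = zeros<vec>(n);
  vec z(n), w(n);
  z.fill(tau);
  w.fill(1.0 - tau);

  const double scale0 = 1.0 + sum(abs(y)) / n;
  bool converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    const double gap = dot(u, z) + dot(v, w);
    if (gap < tol * n * scale0) { converged = true; break; }

    vec q = u / z + v / w;             // diagonal of Q
    vec qi = 1.0 / q;
    mat A = X.t() * (X.each_col() % qi);

    // affine (predictor) direction: complementarity target 0
    vec rhs_n = u - v;                 // = -r3/z + r4/w with r3 = -u.z, r4 = -v.w
    vec db;
    ok = solve(db, A, X.t() * (rhs_n % qi), solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) db = pinv(A) * (X.t() * (rhs_n % qi));
    vec dd = (rhs_n - X * db) % qi;
    vec du = -u + (u / z) % dd;
    vec dv = -v - (v / w) % dd;

    double ap = 1.0, ad = 1.0;
    for (int i = 0; i < n; ++i) {
      if (du[i] < 0) ap = std::min(ap, -big * u[i] / du[i]);
      if (dv[i] < 0) ap = std::min(ap, -big * v[i] / dv[i]);
      if (dd[i] > 0) ad = std::min(ad,  big * z[i] / dd[i]);   // z step is -dd
      if (dd[i] < 0) ad = std::min(ad, -big * w[i] / dd[i]);   // w step is +dd
    }
    const double gap_aff = dot(u + ap * du, z - ad * dd) + dot(v + ap * dv, w + ad * dd);
    double sigma = std::pow(gap_aff / gap, 3.0);
    sigma = std::min(std::max(sigma, 1e-8), 0.999);
    const double mu = sigma * gap / (2.0 * n);

    // corrector: reuse the factorization pattern (A unchanged)
    vec r3 = mu - u % z - du % (-dd);
    vec r4 = mu - v % w - dv % dd;
    rhs_n = -(r3 / z) + (r4 / w);
    ok = solve(db, A, X.t() * (rhs_n % qi), solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) db = pinv(A) * (X.t() * (rhs_n % qi));
    dd = (rhs_n - X * db) % qi;
    du = r3 / z + (u / z) % dd;
    dv = r4 / w - (v / w) % dd;

    ap = 1.0; ad = 1.0;
    for (int i = 0; i < n; ++i) {
      if (du[i] < 0) ap = std::min(ap, -big * u[i] / du[i]);
      if (dv[i] < 0) ap = std::min(ap, -big * v[i] / dv[i]);
      if (dd[i] > 0) ad = std::min(ad,  big * z[i] / dd[i]);
      if (dd[i] < 0) ad = std::min(ad, -big * w[i] / dd[i]);
    }
    b += ap * db;
    u += ap * du;
    v += ap * dv;
    d += ad * dd;
    z = tau - d;
    w = (1.0 - tau) + d;
  }
  iters = it;
  r = y - X * b;
  obj = 0.0;
  for (int i = 0; i < n; ++i)
    obj += (r[i] >= 0) ? tau * r[i] : (tau - 1.0) * r[i];
  return converged;
}

// [[Rcpp::export]]
Rcpp::List cpp_rq_fit(const arma::mat& X, const arma::vec& y, const double tau,
                      const double tol = 1e-10, const int maxit = 200) {
  vec b, d;
  double obj;
  int iters;
  bool conv = rq_ip(X, y, tau, tol, maxit, b, d, obj, iters);
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = b,
    Rcpp::Named("dual") = d,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = conv);
}

// Per-marker full-model quantile fits for a scan: design [Xr, m_j] for each
// column m_j of M; returns the marker coefficient and LP objective per marker.
// [[Rcpp::export]]
Rcpp::List cpp_rq_scan(const arma::mat& Xr, const arma::mat& M, const arma::vec& y,
                       const double tau, const double tol = 1e-10,
                       const int maxit = 200) {
  const int m = M.n_cols, p = Xr.n_cols;
  vec eff(m), objv(m);
  ivec convv(m);
  mat X(Xr.n_rows, p + 1);
  X.cols(0, p - 1) = Xr;
  for (int j = 0; j < m; ++j) {
    X.col(p) = M.col(j);
    vec b, d;
    double obj;
    int iters;
    bool conv = rq_ip(X, y, tau, tol, maxit, b, d, obj, iters);
    eff[j] = b[p];
    objv[j] = obj;
    convv[j] = conv ? 1 : 0;
  }
  return Rcpp::List::create(
    Rcpp::Named("effect") = eff,
    Rcpp::Named("objective") = objv,
    Rcpp::Named("converged") = convv);
}
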