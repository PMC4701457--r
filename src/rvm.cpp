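#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Invert the posterior precision H = diag(a) + beta * Phi'Phi restricted to the
// active set.  inv_sympd can fail when alphas span many orders of magnitude;
// retry once with a relative ridge jitter before giving up.
static bool safe_inv_sympd(mat& out, const mat& H) {
  if (inv_sympd(out, H)) return true;
  double scale = trace(H) / H.n_rows;
  if (!(scale > 0)) scale = 1.0;
  for (double rel = 1e-12; rel <= 1e-4; rel *= 100) {
    mat Hj = H;
    Hj.diag() += rel * scale;
    if (inv_sympd(out, Hj)) return true;
  }
  return false;
}

// Log marginal likelihood of the current (alpha, beta) state:
//   log p(y) = -0.5 * ( n log 2pi + log|C| + y' C^{-1} y ),
//   C = I/beta + Phi_A diag(1/alpha_A) Phi_A'.
// Only evaluated on request (test fixtures are small).
static double log_evidence(const mat& PhiA, const vec& y,
                           const vec& a, double beta) {
  const uword n = y.n_elem;
  mat C = PhiA * diagmat(1.0 / a) * PhiA.t();
  C.diag() += 1.0 / beta;
  double ld, sign;
  if (!log_det(ld, sign, C) || sign <= 0) return datum::nan;
  vec Ci_y = solve(C, y, solve_opts::likely_sympd);
  return -0.5 * (n * std::log(2.0 * datum::pi) + ld + dot(y, Ci_y));
}

// Type-II maximum-likelihood re-estimation for the relevance vector machine
// (regression).  Phi is the full design [bias | kernel columns]; y is assumed
// already centered by the caller.  Iterates
//   Sigma = (A + beta Phi'Phi)^{-1},  mu = beta Sigma Phi'y,
//   gamma_i = 1 - alpha_i Sigma_ii,  alpha_i <- gamma_i / mu_i^2,
//   1/beta <- ||y - Phi mu||^2 / (n - sum gamma),
// pruning basis i once alpha_i exceeds prune_alpha.  max_iter = 0 performs a
// single posterior solve at the supplied hyperparameters (no re-estimation).
// [[Rcpp::export(.rvm_em)]]
Rcpp::List rvm_em(const arma::mat& Phi, const arma::vec& y,
                  const arma::vec& alpha0, double beta0, double beta_max,
                  int max_iter, double tol, double prune_alpha,
                  bool track_evidence) {
  const uword n = Phi.n_rows;
  const uword m0 = Phi.n_cols;

  mat PtP = Phi.t() * Phi;
  vec Pty = Phi.t() * y;

  uvec active = find(alpha0 <= prune_alpha);
  vec a = alpha0(active);
  double beta = beta0;

  vec mu, sig_diag;
  bool converged = (max_iter == 0);
  bool degenerate = false;
  int it = 0;
  std::vector<double> ev;

  // noise-precision ceiling; guards the degenerate interpolation fixed
  // point of the type-II updates on full-rank kernels
  const double beta_cap = std::isfinite(beta_max) ? beta_max : 1e12;

  for (it = 0; it < max_iter; ++it) {
    if (active.n_elem == 0) break;
    mat H = beta * PtP(active, active);
    H.diag() += a;
    mat Sigma;
    if (!safe_inv_sympd(Sigma, H))
      Rcpp::stop("posterior precision matrix is numerically singular");
    mu = beta * (Sigma * Pty(active));
    vec sdiag = Sigma.diag();
    // gamma in [0, 1] analytically; clamp away round-off excursions that
    // would turn a precision negative
    vec gamma = clamp(1.0 - a % sdiag, 1e-12, 1.0);

    vec mu2 = square(mu);
    vec a_new(a.n_elem);
    for (uword j = 0; j < a.n_elem; ++j)
      a_new(j) = (mu2(j) > 0) ? gamma(j) / mu2(j) : datum::inf;

    vec resid = y - Phi.cols(active) * mu;
    double rss = dot(resid, resid);
    double denom = static_cast<double>(n) - accu(gamma);
    if (denom <= 0) { denom = 1e-10; degenerate = true; }
    double beta_new = (rss > 0) ? denom / rss : beta_cap;
    if (beta_new > beta_cap) beta_new = beta_cap;

    // convergence measured on bases that survive this update
    double dmax = 0.0;
    for (uword j = 0; j < a.n_elem; ++j) {
      if (a_new(j) <= prune_alpha) {
        double d = std::fabs(std::log(a_new(j)) - std::log(a(j)));
        if (d > dmax) dmax = d;
      }
    }
    bool any_pruned = any(a_new > prune_alpha);

    uvec keep = find(a_new <= prune_alpha);
    active = active(keep);
    a = a_new(keep);
    beta = beta_new;

    if (track_evidence && active.n_elem > 0)
      ev.push_back(log_evidence(Phi.cols(active), y, a, beta));

    if (!any_pruned && dmax < tol) { converged = true; ++it; break; }
  }

  // final posterior solve so the returned state is consistent with (a, beta)
  if (active.n_elem > 0) {
    mat H = beta * PtP(active, active);
    H.diag() += a;
    mat Sigma;
    if (!safe_inv_sympd(Sigma, H))
      Rcpp::stop("posterior precision matrix is numerically singular");
    mu = beta * (Sigma * Pty(active));
    sig_diag = Sigma.diag();
  } else {
    mu.reset();
    sig_diag.reset();
  }

  return Rcpp::List::create(
    Rcpp::Named("active")    = active + 1,   // 1-based (1 = bias column)
    Rcpp::Named("alpha")     = a,
    Rcpp::Named("mu")        = mu,
    Rcpp::Named("sigma_diag")= sig_diag,
    Rcpp::Named("beta")      = beta,
    Rcpp::Named("n_iter")    = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("degenerate")= degenerate,
    Rcpp::Named("evidence")  = ev);
}
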