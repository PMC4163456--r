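// Newton/IRLS core for L2-penalized logistic regression.
//
// Objective: -sum_i [y_i log p_i + (1-y_i) log(1-p_i)] + lambda * ||gamma||^2
// where eta = b0 + Z gamma and the intercept b0 is unpenalized. Callers pass
// Z already column-standardized and (for wide problems) reduced to the
// training row space by SVD, so dimensions stay O(n).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double penalized_nll(const vec& eta, const vec& y, double lambda,
                            const vec& gamma) {
  // log(1 + exp(eta)) - y*eta, computed stably
  vec soft = eta;
  soft.transform([](double e) {
    return e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  });
  return accu(soft - y % eta) + lambda * dot(gamma, gamma);
}

// Newton with step halving; theta = [b0, gamma]. Returns iterations used,
// sets converged.
static int irls(const mat& Z, const vec& y, double lambda, vec& theta,
                int maxit, double tol, bool& converged) {
  const uword n = Z.n_rows, r = Z.n_cols;
  converged = false;
  vec eta = theta(0) + Z * theta.subvec(1, r);
  double obj = penalized_nll(eta, y, lambda, theta.subvec(1, r));
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    vec p = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(p % (1.0 - p), 1e-10, datum::inf);
    vec resid = y - p;
    vec g(r + 1);
    g(0) = accu(resid);
    g.subvec(1, r) = Z.t() * resid - 2.0 * lambda * theta.subvec(1, r);
    mat H(r + 1, r + 1);
    H(0, 0) = accu(w);
    rowvec zw = w.t() * Z;
    H(0, span(1, r)) = zw;
    H(span(1, r), 0) = zw.t();
    mat ZtWZ = Z.t() * (Z.each_col() % w);
    ZtWZ.diag() += 2.0 * lambda;
    H(span(1, r), span(1, r)) = ZtWZ;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      H.diag() += 1e-8;
      if (!solve(step, H, g)) break;
    }
    // backtracking on the penalized objective
    double alpha = 1.0;
    vec theta_new, eta_new;
    double obj_new = obj;
    for (int h = 0; h < 30; ++h) {
      theta_new = theta + alpha * step;
      eta_new = theta_new(0) + Z * theta_new.subvec(1, r);
      obj_new = penalized_nll(eta_new, y, lambda, theta_new.subvec(1, r));
      if (obj_new <= obj + 1e-12 * std::abs(obj)) break;
      alpha *= 0.5;
    }
    double delta = abs(theta_new - theta).max();
    theta = theta_new;
    eta = eta_new;
    obj = obj_new;
    if (delta < tol) { converged = true; ++it; break; }
  }
  return it;
}

// [[Rcpp::export(name = ".ridge_logistic_core")]]
Rcpp::List ridge_logistic_core(const arma::mat& Z, const arma::vec& y,
                               double lambda, arma::vec theta_init,
                               int maxit = 100, double tol = 1e-8) {
  bool converged = false;
  vec theta = theta_init;
  int it = irls(Z, y, lambda, theta, maxit, tol, converged);
  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("n_iter") = it);
}

// Leave-one-out predictive log-likelihood for each lambda on (Z, y).
// Full-data fits warm-start along the lambda path; each LOO fit warm-starts
// from the full-data solution at its lambda.
// [[Rcpp::export(name = ".ridge_loo_loglik_core")]]
arma::vec ridge_loo_loglik_core(const arma::mat& Z, const arma::vec& y,
                                const arma::vec& lambdas, int maxit = 100,
                                double tol = 1e-8) {
  const uword n = Z.n_rows, r = Z.n_cols, L = lambdas.n_elem;
  vec out(L, fill::zeros);
  bool conv;
  vec theta_full(r + 1, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    double lambda = lambdas(l);
    irls(Z, y, lambda, theta_full, maxit, tol, conv);
    double ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      uvec keep = regspace<uvec>(0, n - 1);
      keep.shed_row(i);
      mat Zi = Z.rows(keep);
      vec yi = y.elem(keep);
      vec theta = theta_full;
      irls(Zi, yi, lambda, theta, maxit, tol, conv);
      double eta = theta(0) + dot(Z.row(i), theta.subvec(1, r));
      double p = 1.0 / (1.0 + std::exp(-eta));
      p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
      ll += y(i) > 0.5 ? std::log(p) : std::log(1.0 - p);
    }
    out(l) = ll;
  }
  return out;
}
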