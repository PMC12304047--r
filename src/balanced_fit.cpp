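// Profiled (RE)ML criterion for the balanced two-level growth model.
//
// All subjects share one time grid, so a dataset enters the likelihood only
// through per-arm mean vectors and the pooled within-arm SSCP matrix. With
// the marginal covariance written as sigma^2 (I + Z G Z'), the Woodbury
// identity reduces every evaluation to 2x2 and 4x4 arithmetic, and sigma^2
// is profiled out analytically. G = Sigma_u / sigma^2 is parameterized by
// its log-Cholesky factor, so the optimizer works unconstrained.
//
// Layouts (flat double vectors):
//   cst: [n, N0, N1, reml, M(4), D0(16), D1(16), C0(8), C1(8)]  (56)
//   dat: [w0(2), w1(2), v0(4), v1(4), q0, q1, trSw, SZZ(4)]     (19)
// Matrices are column-major; C_g = X_g' Z (4x2), D_g = X_g' X_g,
// M = Z'Z, w_g = Z' ybar_g, v_g = X_g' ybar_g, SZZ = Z' Sw Z.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BIG = 1e10;

struct Parts {
  mat H;        // scaled Fisher information, 4x4
  vec rhs;      // scaled score, 4
  vec beta;     // GLS fixed effects
  double Q;     // scaled residual quadratic form
  double logdetK;
  bool ok;
};

static Parts assemble(const arma::vec& par, const double* dat,
                      const double* cst) {
  Parts out;
  out.ok = false;

  const double n  = cst[0];
  const double N0 = cst[1];
  const double N1 = cst[2];
  const mat M(const_cast<double*>(cst + 4), 2, 2, false);
  const mat D0(const_cast<double*>(cst + 8), 4, 4, false);
  const mat D1(const_cast<double*>(cst + 24), 4, 4, false);
  const mat C0(const_cast<double*>(cst + 40), 4, 2, false);
  const mat C1(const_cast<double*>(cst + 48), 4, 2, false);

  const vec w0(const_cast<double*>(dat + 0), 2, false);
  const vec w1(const_cast<double*>(dat + 2), 2, false);
  const vec v0(const_cast<double*>(dat + 4), 4, false);
  const vec v1(const_cast<double*>(dat + 8), 4, false);
  const double q0 = dat[12], q1 = dat[13], trSw = dat[14];
  const mat SZZ(const_cast<double*>(dat + 15), 2, 2, false);

  if (!par.is_finite()) return out;
  mat L(2, 2, fill::zeros);
  L(0, 0) = std::exp(par(0));
  L(1, 0) = par(1);
  L(1, 1) = std::exp(par(2));
  if (!L.is_finite()) return out;
  mat G = L * L.t();

  mat K = eye(2, 2) + M * G;
  double detK = K(0, 0) * K(1, 1) - K(0, 1) * K(1, 0);
  if (!std::isfinite(detK) || detK <= 0) return out;
  mat W = G * inv(K);
  W = 0.5 * (W + W.t());  // symmetric up to roundoff

  mat A0 = D0 - C0 * W * C0.t();
  mat A1 = D1 - C1 * W * C1.t();
  vec b0 = v0 - C0 * (W * w0);
  vec b1 = v1 - C1 * (W * w1);
  double c0 = q0 - dot(w0, W * w0);
  double c1 = q1 - dot(w1, W * w1);
  double tr_term = trSw - trace(W * SZZ);

  out.H = N0 * A0 + N1 * A1;
  out.rhs = N0 * b0 + N1 * b1;
  vec beta;
  if (!solve(beta, out.H, out.rhs, solve_opts::no_approx)) return out;
  out.beta = beta;
  out.Q = tr_term + N0 * c0 + N1 * c1 - dot(beta, out.rhs);
  out.logdetK = std::log(detK);
  (void)n;
  out.ok = out.Q > 0 && std::isfinite(out.Q);
  return out;
}

// [[Rcpp::export]]
double crit_balanced(const arma::vec& par, const arma::vec& dat,
                     const arma::vec& cst) {
  Parts p = assemble(par, dat.memptr(), cst.memptr());
  if (!p.ok) return BIG;
  const double n = cst[0], N0 = cst[1], N1 = cst[2], reml = cst[3];
  const double N = N0 + N1, Nn = N * n;
  double crit;
  if (reml > 0.5) {
    const double df = Nn - 4.0;
    double s2 = p.Q / df;
    double val, sign;
    log_det(val, sign, p.H);
    if (sign <= 0) return BIG;
    crit = df * std::log(s2) + N * p.logdetK + val;
  } else {
    double s2 = p.Q / Nn;
    crit = Nn * std::log(s2) + N * p.logdetK;
  }
  return std::isfinite(crit) ? crit : BIG;
}

// [[Rcpp::export]]
Rcpp::List extract_balanced(const arma::vec& par, const arma::vec& dat,
                            const arma::vec& cst) {
  Parts p = assemble(par, dat.memptr(), cst.memptr());
  if (!p.ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
  const double n = cst[0], N0 = cst[1], N1 = cst[2], reml = cst[3];
  const double N = N0 + N1, Nn = N * n;
  double s2 = reml > 0.5 ? p.Q / (Nn - 4.0) : p.Q / Nn;
  mat Hinv;
  if (!inv(Hinv, p.H)) return Rcpp::List::create(Rcpp::Named("ok") = false);
  mat L(2, 2, fill::zeros);
  L(0, 0) = std::exp(par(0));
  L(1, 0) = par(1);
  L(1, 1) = std::exp(par(2));
  mat Su = s2 * (L * L.t());
  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("beta") = p.beta,
    Rcpp::Named("se2_beta2") = s2 * Hinv(3, 3),
    Rcpp::Named("vcov_beta") = s2 * Hinv,
    Rcpp::Named("sigma2_e") = s2,
    Rcpp::Named("Sigma_u") = Su);
}
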