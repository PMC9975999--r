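// Full-information maximum likelihood for the trivariate twin Cholesky model.
//
// The parameter vector theta is laid out as
//   mu (3) | vech(L_A) (6) | [vech(L_C) (6) if ACE] | vech(L_E) (6)
// with vech in column-major lower-triangular order:
//   (1,1),(2,1),(3,1),(2,2),(3,2),(3,3).
//
// Families are pre-grouped in R by (zygosity, missingness pattern); each group
// carries a data matrix X (families x observed variables), the 1-based indices
// of the observed entries of the stacked (twin1, twin2) 6-vector, and the
// genetic sharing coefficient alpha (1 for MZ, 0.5 for DZ).
//
// Analytic gradients: with P = Sigma_obs^-1, W = sum_f r_f r_f', and
// G = n P - P W P, d(-2lnL)/dtheta = tr(G dSigma_obs) plus the mean terms;
// for Sigma built from block structure [[S, aA + C], [aA + C, S]] with
// S = A + C + E and A = L_A L_A', the trace collapses to 2 (M L)[i,j] for
// M the appropriately alpha-weighted sum of blocks of G embedded at the
// observed indices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

static mat lower_from_vech(const vec& v) {
  mat L(3, 3, fill::zeros);
  L(0, 0) = v(0); L(1, 0) = v(1); L(2, 0) = v(2);
  L(1, 1) = v(3); L(2, 1) = v(4); L(2, 2) = v(5);
  return L;
}

static vec vech_lower(const mat& M) {
  vec v(6);
  v(0) = M(0, 0); v(1) = M(1, 0); v(2) = M(2, 0);
  v(3) = M(1, 1); v(4) = M(2, 1); v(5) = M(2, 2);
  return v;
}

// [[Rcpp::export]]
Rcpp::List fiml_eval_cpp(const arma::vec& theta, bool has_c,
                         const Rcpp::List& groups, bool want_grad) {
  const int n_par = theta.n_elem;
  vec mu = theta.subvec(0, 2);
  mat LA = lower_from_vech(theta.subvec(3, 8));
  mat LC(3, 3, fill::zeros);
  int e_off = 9;
  if (has_c) { LC = lower_from_vech(theta.subvec(9, 14)); e_off = 15; }
  mat LE = lower_from_vech(theta.subvec(e_off, e_off + 5));

  mat A = LA * LA.t();
  mat C = LC * LC.t();
  mat E = LE * LE.t();
  mat S = A + C + E;
  vec mu6 = join_cols(mu, mu);

  double value = 0.0;
  mat MA(3, 3, fill::zeros), MC(3, 3, fill::zeros), ME(3, 3, fill::zeros);
  vec gmu(3, fill::zeros);
  bool bad = false;

  for (int g = 0; g < groups.size(); ++g) {
    Rcpp::List grp = groups[g];
    mat X = Rcpp::as<mat>(grp["X"]);
    uvec idx = Rcpp::as<uvec>(grp["idx"]) - 1;
    double alpha = Rcpp::as<double>(grp["alpha"]);
    const int n = X.n_rows, m = X.n_cols;

    mat cross = alpha * A + C;
    mat Sig6 = join_rows(join_cols(S, cross), join_cols(cross, S));
    mat Sig = Sig6.submat(idx, idx);
    vec mo = mu6.elem(idx);

    mat R;
    if (!chol(R, Sig)) { bad = true; break; }
    double logdet = 2.0 * accu(log(R.diag()));
    mat Rinv = inv(trimatu(R));
    mat P = Rinv * Rinv.t();

    mat Xc = X;
    Xc.each_row() -= mo.t();
    mat V = Xc * P;
    value += n * (m * LOG2PI + logdet) + accu(V % Xc);

    if (want_grad) {
      mat W = Xc.t() * Xc;
      mat G = n * P - P * W * P;
      mat G6(6, 6, fill::zeros);
      G6.submat(idx, idx) = G;
      mat Gsum = G6.submat(0, 0, 2, 2) + G6.submat(3, 3, 5, 5);
      mat Gcross = G6.submat(0, 3, 2, 5) + G6.submat(3, 0, 5, 2);
      MA += Gsum + alpha * Gcross;
      MC += Gsum + Gcross;
      ME += Gsum;
      vec t6(6, fill::zeros);
      t6.elem(idx) = P * sum(Xc, 0).t();
      for (int k = 0; k < 3; ++k) gmu(k) += -2.0 * (t6(k) + t6(k + 3));
    }
  }

  if (bad || !std::isfinite(value)) {
    // large finite penalty so the optimizer can back away
    return Rcpp::List::create(
      Rcpp::Named("value") = 1e12,
      Rcpp::Named("gradient") = Rcpp::NumericVector(n_par),
      Rcpp::Named("ok") = false);
  }

  vec grad(n_par, fill::zeros);
  if (want_grad) {
    grad.subvec(0, 2) = gmu;
    grad.subvec(3, 8) = vech_lower(2.0 * MA * LA);
    if (has_c) grad.subvec(9, 14) = vech_lower(2.0 * MC * LC);
    grad.subvec(e_off, e_off + 5) = vech_lower(2.0 * ME * LE);
  }
  return Rcpp::List::create(
    Rcpp::Named("value") = value,
    Rcpp::Named("gradient") = Rcpp::NumericVector(grad.begin(), grad.end()),
    Rcpp::Named("ok") = true);
}
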