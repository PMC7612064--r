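// Marginal Gaussian likelihood for the stacked two-equation mediation model.
//
// Per participant g the stacked response vector (M-equation rows, then
// Y-equation rows) is multivariate normal with mean X_g beta and covariance
//   V_g = Z_g G Z_g' + R_g
// where G is the random-effect covariance (intercepts + random slopes) and
// R_g is diagonal (per-row residual variance) unless a cross-equation
// residual covariance is requested, in which case paired rows share an
// off-diagonal element.
//
// When R is diagonal the solves use the Woodbury identity so the per-group
// cost is O(n_g q^2) with q = ncol(Z) (typically 4), which keeps repeated
// evaluation cheap inside the optimiser and in simulation studies.

// [[Rcpp::depends(RcppArmadillo)]]
// Degenerate covariance proposals are caught explicitly (chol failure ->
// ok = false); Armadillo's own rcond console warnings for the near-boundary
// triangular inverses are noise, so runtime warnings are disabled.
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
Rcpp::List msem_nll_engine(const arma::vec& y,
                           const arma::mat& X,
                           const arma::mat& Z,
                           const arma::ivec& grp_start,
                           const arma::ivec& grp_end,
                           const arma::mat& G,
                           const arma::vec& resid_var,
                           const arma::ivec& pair_row,
                           const double resid_cov,
                           const bool profile,
                           const arma::vec& beta_in,
                           const bool want_scores) {
  const uword N = y.n_elem;
  const uword p = X.n_cols;
  const uword q = Z.n_cols;
  const uword ngrp = grp_start.n_elem;

  mat cG;
  if (!chol(cG, G)) {
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "G_not_pd");
  }
  const double logdetG = 2.0 * accu(log(cG.diag()));
  mat Ginv = inv(trimatu(cG));
  Ginv = Ginv * Ginv.t();

  mat A(p, p, fill::zeros);      // sum X' V^-1 X
  vec bvec(p, fill::zeros);      // sum X' V^-1 y  (or r when beta given)
  double yy = 0.0;               // sum y' V^-1 y (or r' V^-1 r)
  double logdet = 0.0;
  mat scores;
  if (want_scores) scores.zeros(p, ngrp);

  const bool use_dense = (resid_cov != 0.0);
  vec resp = y;
  if (!profile) resp = y - X * beta_in;

  for (uword g = 0; g < ngrp; ++g) {
    const uword s = (uword)grp_start(g);
    const uword e = (uword)grp_end(g);
    const uword n = e - s + 1;
    mat Xg = X.rows(s, e);
    mat Zg = Z.rows(s, e);
    vec yg = resp.subvec(s, e);
    vec rg = resid_var.subvec(s, e);

    mat XtViX_g(p, p);
    vec XtViy_g(p);
    double ytViy_g;

    if (!use_dense) {
      vec Ri = 1.0 / rg;
      mat XRi = Xg.each_col() % Ri;          // R^-1 X
      vec yRi = yg % Ri;
      mat ZtRiX = Zg.t() * XRi;              // q x p
      vec ZtRiy = Zg.t() * yRi;              // q
      mat M = Ginv + Zg.t() * (Zg.each_col() % Ri);
      mat cM;
      if (!chol(cM, M)) {
        return Rcpp::List::create(Rcpp::Named("ok") = false,
                                  Rcpp::Named("reason") = "inner_not_pd");
      }
      logdet += accu(log(rg)) + logdetG + 2.0 * accu(log(cM.diag()));
      // solve via triangular factors
      mat U = solve(trimatl(cM.t()), join_rows(ZtRiX, ZtRiy));
      mat Ux = U.cols(0, p - 1);
      vec uy = U.col(p);
      XtViX_g = Xg.t() * XRi - Ux.t() * Ux;
      XtViy_g = Xg.t() * yRi - Ux.t() * uy;
      ytViy_g = dot(yg, yRi) - dot(uy, uy);
    } else {
      mat R(n, n, fill::zeros);
      R.diag() = rg;
      for (uword i = 0; i < n; ++i) {
        sword pr = pair_row(s + i);
        if (pr >= 0) {
          uword j = (uword)pr - s;
          R(i, j) = resid_cov;
          R(j, i) = resid_cov;
        }
      }
      mat V = Zg * G * Zg.t() + R;
      mat cV;
      if (!chol(cV, V)) {
        return Rcpp::List::create(Rcpp::Named("ok") = false,
                                  Rcpp::Named("reason") = "V_not_pd");
      }
      logdet += 2.0 * accu(log(cV.diag()));
      mat W = solve(trimatl(cV.t()), join_rows(Xg, yg));
      mat Wx = W.cols(0, p - 1);
      vec wy = W.col(p);
      XtViX_g = Wx.t() * Wx;
      XtViy_g = Wx.t() * wy;
      ytViy_g = dot(wy, wy);
    }

    A += XtViX_g;
    bvec += XtViy_g;
    yy += ytViy_g;
    if (want_scores) scores.col(g) = XtViy_g;
  }

  double nll, rss;
  vec beta_hat;
  if (profile) {
    mat cA;
    if (!chol(cA, A)) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("reason") = "XtViX_singular");
    }
    beta_hat = solve(trimatu(cA), solve(trimatl(cA.t()), bvec));
    rss = yy - dot(bvec, beta_hat);
  } else {
    beta_hat = beta_in;
    rss = yy;  // resp already residualised
  }
  nll = 0.5 * ((double)N * LOG2PI + logdet + rss);

  return Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("nll") = nll,
      Rcpp::Named("beta") = beta_hat,
      Rcpp::Named("XtViX") = A,
      Rcpp::Named("logdet") = logdet,
      Rcpp::Named("quadform") = rss,
      Rcpp::Named("scores") = scores);
}
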