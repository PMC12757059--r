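// Mean-field anchor-point projections for manifold capacity analysis.
// For each Gaussian sample t (in the D+1 coordinates of one manifold:
// D manifold axes plus the center direction), solve
//     min_v ||v - t||^2  s.t.  v . s_j >= kappa  for all manifold points s_j
// via cyclic coordinate descent on the nonnegative dual
//     min_{l >= 0} 1/2 l' A A' l + l' (A t - kappa).
// The anchor point is the KKT-weighted convex combination of the support
// points; when no constraint is active the touching point argmin_j t.s_j
// stands in for the anchor (it contributes zero to the capacity term).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List anchor_qp(const arma::mat& S, const arma::mat& Tm, double kappa,
               int max_pass = 500, double tol = 1e-10) {
  const int m = S.n_rows, d = S.n_cols, nt = Tm.n_rows;
  arma::mat H = S * S.t();                 // m x m Gram matrix
  arma::vec Hdiag = H.diag();
  arma::vec Fout(nt), lam_sum(nt);
  arma::mat anchors(nt, d);
  arma::ivec interior(nt);

  for (int k = 0; k < nt; ++k) {
    arma::vec t = Tm.row(k).t();
    arma::vec q = S * t;                   // A t
    // feasibility check: all constraints already satisfied?
    if (q.min() >= kappa - 1e-12) {
      arma::uword j = q.index_min();       // touching point
      anchors.row(k) = S.row(j);
      Fout[k] = 0.0;
      lam_sum[k] = 0.0;
      interior[k] = 1;
      continue;
    }
    arma::vec lam(m, arma::fill::zeros), g = q;   // g = H lam + A t
    for (int pass = 0; pass < max_pass; ++pass) {
      double delta = 0.0;
      for (int j = 0; j < m; ++j) {
        if (Hdiag[j] <= 0) continue;
        double lj = lam[j] - (g[j] - kappa) / Hdiag[j];
        if (lj < 0) lj = 0;
        double dl = lj - lam[j];
        if (dl != 0.0) {
          g += dl * H.col(j);
          lam[j] = lj;
          delta = std::max(delta, std::abs(dl));
        }
      }
      if (delta < tol) break;
    }
    arma::vec corr = S.t() * lam;          // v - t = A' lam
    Fout[k] = arma::dot(corr, corr);
    double ls = arma::sum(lam);
    lam_sum[k] = ls;
    if (ls > 0) {
      anchors.row(k) = (lam.t() * S) / ls; // convex combination of supports
    } else {
      arma::uword j = q.index_min();
      anchors.row(k) = S.row(j);
    }
    interior[k] = 0;
  }
  return List::create(_["F"] = Fout, _["anchors"] = anchors,
                      _["lam_sum"] = lam_sum,
                      _["interior"] = IntegerVector(interior.begin(),
                                                    interior.end()));
}
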