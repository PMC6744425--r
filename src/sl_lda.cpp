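// Searchlight LDA cross-validation core.
//
// For every neighborhood (a set of voxel columns) and every cross-validation
// fold, fits a shrinkage-regularized two-class linear discriminant on the
// training samples and counts correct held-out predictions. Shrinkage target
// is (tr(S)/p) * I; intensity is either fixed or the Ledoit-Wolf analytic
// estimate (shrinkage < 0 requests Ledoit-Wolf), matching the R-level
// fit_lda() exactly so the two paths can be cross-checked.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double lw_lambda(const arma::mat& xc) {
  const double n = xc.n_rows, p = xc.n_cols;
  arma::mat s_n = xc.t() * xc / n;
  double m = arma::trace(s_n) / p;
  arma::mat dev = s_n;
  dev.diag() -= m;
  double d2 = arma::accu(dev % dev) / p;
  if (d2 <= 0.0) return 0.0;
  arma::vec rn2 = arma::sum(arma::square(xc), 1);
  double mean_rn4 = arma::mean(arma::square(rn2));
  double b2 = (mean_rn4 - arma::accu(s_n % s_n)) / (n * p);
  if (b2 < 0.0) b2 = 0.0;
  double lam = b2 / d2;
  return lam > 1.0 ? 1.0 : lam;
}

// [[Rcpp::export]]
NumericVector sl_crossval_accuracy(const arma::mat& X,
                                   const arma::ivec& y,
                                   const arma::ivec& fold,
                                   const List& neighborhoods,
                                   const double shrinkage) {
  const int n_nb = neighborhoods.size();
  NumericVector out(n_nb, NA_REAL);
  arma::ivec ufold = arma::unique(fold);

  for (int nb = 0; nb < n_nb; ++nb) {
    arma::uvec cols = as<arma::uvec>(neighborhoods[nb]) - 1;  // 1-based in R
    int n_correct = 0, n_test = 0;
    bool ok = true;

    for (arma::uword fi = 0; fi < ufold.n_elem && ok; ++fi) {
      int f = ufold(fi);
      arma::uvec tr = arma::find(fold != f);
      arma::uvec te = arma::find(fold == f);
      arma::mat Xt = X.submat(tr, cols);
      arma::ivec yt = y(tr);
      arma::uvec i0 = arma::find(yt == 0), i1 = arma::find(yt == 1);
      if (i0.n_elem == 0 || i1.n_elem == 0) { ok = false; break; }

      arma::rowvec mu0 = arma::mean(Xt.rows(i0), 0);
      arma::rowvec mu1 = arma::mean(Xt.rows(i1), 0);
      arma::mat xc = Xt;
      for (arma::uword i = 0; i < i0.n_elem; ++i) xc.row(i0(i)) -= mu0;
      for (arma::uword i = 0; i < i1.n_elem; ++i) xc.row(i1(i)) -= mu1;
      double df = std::max((int)Xt.n_rows - 2, 1);
      arma::mat s_pooled = xc.t() * xc / df;
      double lam = shrinkage < 0 ? lw_lambda(xc) : shrinkage;
      double m = arma::trace(s_pooled) / s_pooled.n_cols;
      arma::mat sigma = (1.0 - lam) * s_pooled;
      sigma.diag() += lam * m;

      arma::vec w;
      bool solved = arma::solve(w, sigma, (mu1 - mu0).t(),
                                arma::solve_opts::likely_sympd);
      if (!solved || !w.is_finite()) { ok = false; break; }
      double b = -arma::dot(w, ((mu0 + mu1) / 2.0).t());

      arma::mat Xe = X.submat(te, cols);
      arma::vec score = Xe * w + b;
      for (arma::uword i = 0; i < te.n_elem; ++i) {
        int pred = score(i) > 0 ? 1 : 0;
        if (pred == y(te(i))) ++n_correct;
        ++n_test;
      }
    }
    if (ok && n_test > 0) out[nb] = (double)n_correct / n_test;
  }
  return out;
}
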