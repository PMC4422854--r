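// Exhaustive best-subset search for log-OLS biomass models.
//
// Works on centered cross-products so each candidate subset costs one small
// linear solve: for subset S, slopes b solve Sxx[S,S] b = Sxy[S] and
// SSE = Syy - b'Sxy[S]. VIFs come from the inverse of the predictor
// correlation submatrix. Subsets are enumerated by size (1..max_terms) and
// lexicographically within size; strict improvement keeps the first
// minimum-BIC subset, so ties resolve to the smaller subset, then to the
// lexicographically earlier one.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool next_combination(uvec& idx, unsigned int p) {
  int k = idx.n_elem;
  for (int i = k - 1; i >= 0; --i) {
    if (idx[i] < p - (k - i)) {
      ++idx[i];
      for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::List best_subset_cpp(const arma::mat& Sxx, const arma::vec& Sxy,
                           double Syy, const arma::mat& R, int n,
                           int max_terms, double vif_limit) {
  const unsigned int p = Sxx.n_rows;
  double best_bic = datum::inf;
  uvec best_idx;
  bool found = false;
  long n_admissible = 0;
  const double logn = std::log((double) n);

  for (int k = 1; k <= max_terms && (unsigned) k <= p; ++k) {
    uvec idx = regspace<uvec>(0, k - 1);
    do {
      // collinearity screen: VIF_j = diag of inverse correlation submatrix
      if (k > 1) {
        mat Rinv;
        if (!inv_sympd(Rinv, R.submat(idx, idx))) continue;
        if (Rinv.diag().max() >= vif_limit) continue;
      }
      vec b;
      if (!solve(b, Sxx.submat(idx, idx), Sxy.elem(idx),
                 solve_opts::no_approx)) continue;
      double sse = Syy - dot(b, Sxy.elem(idx));
      if (sse < 0) sse = 0;  // guard against rounding on near-perfect fits
      ++n_admissible;
      double bic = n * std::log(sse / n) + (k + 1) * logn;
      if (bic < best_bic) {
        best_bic = bic;
        best_idx = idx;
        found = true;
      }
    } while (next_combination(idx, p));
  }

  if (!found) {
    return Rcpp::List::create(Rcpp::Named("indices") = Rcpp::IntegerVector(0),
                              Rcpp::Named("bic") = NA_REAL,
                              Rcpp::Named("n_admissible") = (double) n_admissible);
  }
  return Rcpp::List::create(
      Rcpp::Named("indices") = Rcpp::IntegerVector(best_idx.begin(),
                                                   best_idx.end()),
      Rcpp::Named("bic") = best_bic,
      Rcpp::Named("n_admissible") = (double) n_admissible);
}
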