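// Best-subset search on sufficient statistics (X'X, X'y, y'y), computed on
// mean-centred data so the intercept is implicit.  Exact mode enumerates all
// size-k subsets; hybrid mode is forward selection refined by sequential
// replacement, for problems too large to enumerate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double subset_rss(const arma::mat& XtX, const arma::vec& Xty,
                         double yty, const arma::uvec& idx) {
  arma::vec b;
  bool ok = arma::solve(b, XtX.submat(idx, idx), Xty.elem(idx),
                        arma::solve_opts::no_approx);
  if (!ok) return arma::datum::inf;
  double rss = yty - arma::dot(b, Xty.elem(idx));
  return rss < 0.0 ? 0.0 : rss;
}

// [[Rcpp::export]]
Rcpp::List best_subsets_exact_cpp(const arma::mat& XtX, const arma::vec& Xty,
                                  double yty, int kmax) {
  const int p = XtX.n_rows;
  Rcpp::List out(kmax);
  std::vector<unsigned int> comb(kmax);
  for (int k = 1; k <= kmax; ++k) {
    for (int i = 0; i < k; ++i) comb[i] = i;
    double best = arma::datum::inf;
    arma::uvec best_idx;
    arma::uvec idx(k);
    while (true) {
      for (int i = 0; i < k; ++i) idx[i] = comb[i];
      double rss = subset_rss(XtX, Xty, yty, idx);
      if (rss < best) { best = rss; best_idx = idx; }
      // next lexicographic combination
      int i = k - 1;
      while (i >= 0 && comb[i] == (unsigned int)(p - k + i)) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
    out[k - 1] = Rcpp::List::create(
        Rcpp::Named("cols") = arma::conv_to<std::vector<int>>::from(best_idx + 1),
        Rcpp::Named("rss") = best);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List best_subsets_hybrid_cpp(const arma::mat& XtX, const arma::vec& Xty,
                                   double yty, int kmax) {
  const int p = XtX.n_rows;
  Rcpp::List out(kmax);
  std::vector<unsigned int> sel;  // forward-selected set, grown in place

  for (int k = 1; k <= kmax; ++k) {
    // forward step: add the variable minimising RSS
    double best = arma::datum::inf;
    int best_j = -1;
    arma::uvec idx(k);
    for (int i = 0; i < k - 1; ++i) idx[i] = sel[i];
    for (int j = 0; j < p; ++j) {
      if (std::find(sel.begin(), sel.end(), (unsigned int)j) != sel.end())
        continue;
      idx[k - 1] = j;
      double rss = subset_rss(XtX, Xty, yty, idx);
      if (rss < best) { best = rss; best_j = j; }
    }
    if (best_j < 0) Rcpp::stop("no admissible variable at size %d", k);
    sel.push_back(best_j);

    // sequential replacement: swap in/out pairs until no improvement
    std::vector<unsigned int> cur(sel);
    double cur_rss = best;
    bool improved = true;
    while (improved) {
      improved = false;
      for (int pos = 0; pos < k; ++pos) {
        for (int j = 0; j < p; ++j) {
          if (std::find(cur.begin(), cur.end(), (unsigned int)j) != cur.end())
            continue;
          arma::uvec trial(k);
          for (int i = 0; i < k; ++i)
            trial[i] = (i == pos) ? (unsigned int)j : cur[i];
          double rss = subset_rss(XtX, Xty, yty, trial);
          if (rss < cur_rss - 1e-12) {
            cur_rss = rss;
            cur[pos] = j;
            improved = true;
          }
        }
      }
    }
    // keep the refined set as the forward base for the next size
    sel = cur;
    std::vector<int> cols(cur.begin(), cur.end());
    for (auto& c : cols) ++c;
    std::sort(cols.begin(), cols.end());
    out[k - 1] = Rcpp::List::create(Rcpp::Named("cols") = cols,
                                    Rcpp::Named("rss") = cur_rss);
  }
  return out;
}
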