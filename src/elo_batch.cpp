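#include <Rcpp.h>
using namespace Rcpp;

// Final Elo scores for many orderings of the same contest list.
// winner/loser: 1-based individual indices per contest; orders: one column
// per randomization, each a permutation of contest indices. Transfer is
// k * (1 - p_win) with logistic expectation, or a fixed k.
// [[Rcpp::export]]
NumericMatrix elo_batch_finals(IntegerVector winner, IntegerVector loser,
                               IntegerMatrix orders, int n_ind,
                               double init_score, double k, double scale,
                               bool fixed_transfer) {
  const int n_ev = winner.size();
  const int n_rand = orders.ncol();
  if (orders.nrow() != n_ev) stop("orders must have one row per contest");
  NumericMatrix finals(n_rand, n_ind);
  std::vector<double> s(n_ind);
  for (int r = 0; r < n_rand; ++r) {
    std::fill(s.begin(), s.end(), init_score);
    for (int e = 0; e < n_ev; ++e) {
      const int idx = orders(e, r) - 1;
      const int w = winner[idx] - 1;
      const int l = loser[idx] - 1;
      double transfer = k;
      if (!fixed_transfer) {
        const double p = 1.0 / (1.0 + std::exp(-(s[w] - s[l]) / scale));
        transfer = k * (1.0 - p);
      }
      s[w] += transfer;
      s[l] -= transfer;
    }
    for (int i = 0; i < n_ind; ++i) finals(r, i) = s[i];
  }
  return finals;
}
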