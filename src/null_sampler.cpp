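#include <Rcpp.h>
using namespace Rcpp;

// Sample B null match scores for one profile.
//
// Each draw: k ~ Binomial(n, alpha) matches; k distinct positions are chosen
// uniformly at random among the n mutated positions (partial Fisher-Yates,
// undone after each draw so the index array never needs re-initialising);
// the null score is the case-count sum at the chosen positions over the
// total case count. Uses R's RNG so set.seed() governs reproducibility.
//
// [[Rcpp::export]]
NumericVector cpp_null_scores(IntegerVector counts, double alpha, int B) {
  int n = counts.size();
  if (n < 1) stop("profile has no positions");
  if (alpha < 0.0 || alpha > 1.0) stop("alpha outside [0,1]");
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += counts[i];
  if (total < 1.0) stop("profile has no cases");

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> swaps(n);

  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    int k = (int) R::rbinom((double) n, alpha);
    double s = 0.0;
    for (int j = 0; j < k; ++j) {
      int r = j + (int) (unif_rand() * (n - j));
      if (r >= n) r = n - 1;  // guard against unif_rand() == 1.0
      std::swap(idx[j], idx[r]);
      swaps[j] = r;
      s += counts[idx[j]];
    }
    // undo the partial shuffle
    for (int j = k - 1; j >= 0; --j) std::swap(idx[j], idx[swaps[j]]);
    out[b] = s / total;
  }
  return out;
}

// Count exceedances (draws >= observed, with a small tolerance for the
// rational score values) without materialising the draws in R.
//
// [[Rcpp::export]]
int cpp_count_exceedances(NumericVector draws, double observed) {
  int cnt = 0;
  double thr = observed - 1e-9;
  for (int i = 0; i < draws.size(); ++i)
    if (draws[i] >= thr) ++cnt;
  return cnt;
}
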