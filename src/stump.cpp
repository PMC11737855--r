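#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Best weighted decision stump over the columns of X.
// y is coded -1/+1, w sums to 1. A stump predicts
// polarity * (x > threshold ? +1 : -1). Returns the column (1-based),
// threshold (midpoint between distinct adjacent values), polarity and
// weighted error of the best stump; ties resolved toward the earliest
// column / smallest threshold.
// [[Rcpp::export(name = ".best_stump")]]
List best_stump(NumericMatrix X, NumericVector w, IntegerVector y) {
  const int n = X.nrow(), p = X.ncol();
  double tot_pos = 0.0, tot_neg = 0.0;
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0) tot_pos += w[i]; else tot_neg += w[i];
  }
  double best_err = 2.0, best_thr = 0.0;
  int best_col = -1, best_pol = 1;
  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column col = X(_, j);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    double s_pos = 0.0, s_neg = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      int i = idx[k];
      if (y[i] > 0) s_pos += w[i]; else s_neg += w[i];
      if (col[idx[k]] == col[idx[k + 1]]) continue;  // not a valid split
      // polarity +1: right side predicted +1
      double err1 = s_pos + (tot_neg - s_neg);
      double err = err1, pol = 1;
      if (1.0 - err1 < err) { err = 1.0 - err1; pol = -1; }
      if (err < best_err - 1e-15) {
        best_err = err;
        best_col = j;
        best_pol = (int)pol;
        best_thr = 0.5 * (col[idx[k]] + col[idx[k + 1]]);
      }
    }
  }
  return List::create(_["col"] = best_col + 1, _["threshold"] = best_thr,
                      _["polarity"] = best_pol, _["err"] = best_err);
}
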