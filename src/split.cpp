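#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exhaustive axis-aligned split search for the CART fitter.
//
// Candidates are the midpoints between consecutive distinct sorted values of
// each feature; the objective is the weight-averaged Gini impurity of the two
// children. Ties are broken by scan order: lowest feature index first, then
// smallest threshold (features and thresholds are visited in ascending order
// and only strict improvements are kept). Samples equal to the threshold go
// left (<= convention).
//
// idx holds the 0-based row indices of the node's samples; y is 0-based
// class codes; w per-sample weights; min_leaf is a raw-count constraint on
// both children.
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, NumericVector w,
                    IntegerVector idx, int nclass, int min_leaf) {
  const int n = idx.size();
  const int p = X.ncol();
  std::vector<double> tot(nclass, 0.0);
  double W = 0.0;
  for (int i = 0; i < n; ++i) {
    tot[y[idx[i]]] += w[idx[i]];
    W += w[idx[i]];
  }
  double sumsq = 0.0;
  for (int c = 0; c < nclass; ++c) sumsq += tot[c] * tot[c];
  const double parent_gini = 1.0 - sumsq / (W * W);

  int best_f = -1;
  double best_thr = 0.0, best_score = parent_gini - 1e-12;

  std::vector<int> ord(n);
  std::vector<double> v(n);
  std::vector<double> left(nclass);

  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) ord[i] = idx[i];
    NumericMatrix::Column col = X(_, f);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) v[i] = col[ord[i]];
    std::fill(left.begin(), left.end(), 0.0);
    double WL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const int yi = y[ord[i]];
      left[yi] += w[ord[i]];
      WL += w[ord[i]];
      if (v[i + 1] <= v[i]) continue;             // not a distinct boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double WR = W - WL;
      double sl = 0.0, sr = 0.0;
      for (int c = 0; c < nclass; ++c) {
        sl += left[c] * left[c];
        const double rc = tot[c] - left[c];
        sr += rc * rc;
      }
      const double score =
        (WL * (1.0 - sl / (WL * WL)) + WR * (1.0 - sr / (WR * WR))) / W;
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (v[i] + v[i + 1]);
      }
    }
  }
  return List::create(_["feature"] = best_f + 1,  // 0 = no split
                      _["threshold"] = best_thr,
                      _["score"] = best_score,
                      _["parent_gini"] = parent_gini);
}
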