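#include <Rcpp.h>
using namespace Rcpp;

// One Lloyd run from given initial centroids. Assignment step, update
// step, repeat until assignments stop changing or maxIter. Empty
// clusters are re-seeded to the point farthest from its current
// centroid (deterministic).
// [[Rcpp::export(name = ".lloyd_run")]]
List lloyd_run(NumericMatrix X, NumericMatrix init, int maxIter = 200) {
  const int n = X.nrow(), d = X.ncol(), k = init.nrow();
  NumericMatrix cen(clone(init));
  IntegerVector assign(n, -1);
  std::vector<double> dist2(n);

  for (int iter = 0; iter < maxIter; ++iter) {
    bool changed = false;
    // assignment
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          double t = X(i, c) - cen(j, c);
          s += t * t;
        }
        if (s < best) { best = s; bj = j; }
      }
      dist2[i] = best;
      if (assign[i] != bj) { assign[i] = bj; changed = true; }
    }
    // empty-cluster repair: move to the globally farthest point
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; ++i) cnt[assign[i]]++;
    bool repaired = false;
    for (int j = 0; j < k; ++j) {
      if (cnt[j] == 0) {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (cnt[assign[i]] > 1 && dist2[i] > fd) { fd = dist2[i]; far = i; }
        cnt[assign[far]]--;
        assign[far] = j;
        cnt[j] = 1;
        dist2[far] = 0.0;
        for (int c = 0; c < d; ++c) cen(j, c) = X(far, c);
        repaired = true;
      }
    }
    if (!changed && !repaired) break;
    // update
    NumericMatrix nc(k, d);
    std::vector<int> m(k, 0);
    for (int i = 0; i < n; ++i) {
      m[assign[i]]++;
      for (int c = 0; c < d; ++c) nc(assign[i], c) += X(i, c);
    }
    for (int j = 0; j < k; ++j)
      if (m[j] > 0)
        for (int c = 0; c < d; ++c) cen(j, c) = nc(j, c) / m[j];
  }
  // final SSD
  double ssd = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = X(i, c) - cen(j, c);
        s += t * t;
      }
      if (s < best) { best = s; bj = j; }
    }
    assign[i] = bj;
    ssd += best;
  }
  return List::create(_["assignments"] = assign + 1,
                      _["centroids"] = cen,
                      _["ssd"] = ssd);
}
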