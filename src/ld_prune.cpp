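#include <Rcpp.h>
using namespace Rcpp;

// Greedy windowed LD pruning on allele dosages (0/1/2, NA = missing).
// Within each window (a span of `window` SNPs, or `window` kb when
// kb_unit), any kept pair with squared Pearson correlation > r2max has its
// LATER site removed. Windows advance by `step` sites. Pairwise-complete
// observations; undefined correlations (zero variance) never prune.
// [[Rcpp::export]]
LogicalVector ld_prune_cpp(IntegerMatrix geno, NumericVector pos,
                           int window, bool kb_unit, int step, double r2max) {
  const int m = geno.nrow();
  const int n = geno.ncol();
  LogicalVector kept(m, true);
  if (m == 0) return kept;
  if (step < 1) step = 1;

  for (int ws = 0; ws < m; ws += step) {
    int we;  // exclusive end of window
    if (kb_unit) {
      double lim = pos[ws] + 1000.0 * window;
      we = ws + 1;
      while (we < m && pos[we] <= lim) ++we;
    } else {
      we = ws + window;
      if (we > m) we = m;
    }
    for (int i = ws; i < we; ++i) {
      if (!kept[i]) continue;
      for (int j = i + 1; j < we; ++j) {
        if (!kept[j]) continue;
        // pairwise-complete correlation of dosage columns i, j
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        int k = 0;
        for (int s = 0; s < n; ++s) {
          int x = geno(i, s), y = geno(j, s);
          if (x == NA_INTEGER || y == NA_INTEGER) continue;
          ++k;
          sx += x; sy += y;
          sxx += (double)x * x; syy += (double)y * y; sxy += (double)x * y;
        }
        if (k < 2) continue;
        double vx = sxx - sx * sx / k;
        double vy = syy - sy * sy / k;
        double cxy = sxy - sx * sy / k;
        if (vx <= 0 || vy <= 0) continue;
        double r2 = (cxy * cxy) / (vx * vy);
        if (r2 > r2max) kept[j] = false;
      }
    }
    if (!kb_unit && ws + window >= m) break;
  }
  return kept;
}
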