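#include <Rcpp.h>
using namespace Rcpp;

// Match-count matrix M for two encoded sequences (0-based integer codes).
// M(a, b) = number of agreeing positions in the alignment of the two
// prefixes ending at a and b (length min(a, b) + 1), with the zero
// border left implicit. Recurrence:
//   M(a, b) = M(a - 1, b - 1) + [x[a] == y[b]]
// Full-matrix mode; used for testing and for the matrix output surface.
// [[Rcpp::export]]
IntegerMatrix lmer_match_matrix_cpp(IntegerVector x, IntegerVector y) {
  const int n = x.size();
  IntegerMatrix M(n, n);
  for (int b = 0; b < n; ++b) {
    for (int a = 0; a < n; ++a) {
      const int prev = (a > 0 && b > 0) ? M(a - 1, b - 1) : 0;
      M(a, b) = prev + (x[a] == y[b] ? 1 : 0);
    }
  }
  return M;
}

// Histogram of Hamming distances over all (n-l+1)^2 window pairs.
// Walks each diagonal of the conceptual match matrix keeping a running
// cumulative match count, so the window distance at alignment offset i is
//   l - (cum[i+1] - cum[i+1-l])
// Only O(n) working storage per diagonal; total work O(n^2).
// [[Rcpp::export]]
IntegerVector lmer_dist_histogram_cpp(IntegerVector x, IntegerVector y, int l) {
  const int n = x.size();
  IntegerVector hist(l + 1);
  std::vector<int> cums(n + 1);
  for (int o = -(n - 1); o <= n - 1; ++o) {
    const int a0 = o < 0 ? -o : 0;
    const int b0 = o < 0 ? 0 : o;
    const int len = n - (o < 0 ? -o : o);
    if (len < l) continue;
    cums[0] = 0;
    for (int i = 0; i < len; ++i) {
      cums[i + 1] = cums[i] + (x[a0 + i] == y[b0 + i] ? 1 : 0);
      if (i + 1 >= l) hist[l - (cums[i + 1] - cums[i + 1 - l])]++;
    }
  }
  return hist;
}

// Full (n-l+1) x (n-l+1) window-distance matrix; entry (u, v) (0-based
// window starts) is the Hamming distance between x[u..u+l-1] and
// y[v..v+l-1]. Same diagonal scheme as the histogram.
// [[Rcpp::export]]
IntegerMatrix lmer_dist_matrix_cpp(IntegerVector x, IntegerVector y, int l) {
  const int n = x.size();
  const int m = n - l + 1;
  IntegerMatrix D(m, m);
  std::vector<int> cums(n + 1);
  for (int o = -(n - 1); o <= n - 1; ++o) {
    const int a0 = o < 0 ? -o : 0;
    const int b0 = o < 0 ? 0 : o;
    const int len = n - (o < 0 ? -o : o);
    if (len < l) continue;
    cums[0] = 0;
    for (int i = 0; i < len; ++i) {
      cums[i + 1] = cums[i] + (x[a0 + i] == y[b0 + i] ? 1 : 0);
      if (i + 1 >= l) {
        const int u = a0 + i - l + 1;
        const int v = b0 + i - l + 1;
        D(u, v) = l - (cums[i + 1] - cums[i + 1 - l]);
      }
    }
  }
  return D;
}

// Window-distance histograms for a batch of sequence pairs. enc is n x t
// (one column per encoded sequence); ii/jj are 0-based column indices of
// the pairs. Returns an npairs x (l+1) matrix of histogram counts.
// [[Rcpp::export]]
NumericMatrix pair_histograms_cpp(IntegerMatrix enc, IntegerVector ii,
                                  IntegerVector jj, int l) {
  const int n = enc.nrow();
  const int np = ii.size();
  NumericMatrix H(np, l + 1);
  std::vector<int> cums(n + 1);
  for (int p = 0; p < np; ++p) {
    const int* x = &enc(0, ii[p]);
    const int* y = &enc(0, jj[p]);
    for (int o = -(n - 1); o <= n - 1; ++o) {
      const int a0 = o < 0 ? -o : 0;
      const int b0 = o < 0 ? 0 : o;
      const int len = n - (o < 0 ? -o : o);
      if (len < l) continue;
      cums[0] = 0;
      for (int i = 0; i < len; ++i) {
        cums[i + 1] = cums[i] + (x[a0 + i] == y[b0 + i] ? 1 : 0);
        if (i + 1 >= l) H(p, l - (cums[i + 1] - cums[i + 1 - l]))++;
      }
    }
  }
  return H;
}
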