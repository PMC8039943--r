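#include <Rcpp.h>
using namespace Rcpp;

// Pooled permutation null for the modified jackstraw.
//
// Z: row-standardized gene matrix (genes x samples, mean 0, unit variance
//    with denominator m - 1); s: standardized score vector. For each of B
//    iterations and each gene, the score is shuffled (Fisher-Yates on R's
//    RNG) against the fixed gene row and |sum(z * s_perm)| / (m - 1) is
//    recorded: identical to permuting the gene's values by the inverse
//    permutation. Returns the sorted pooled null (length B * G).
// [[Rcpp::export]]
NumericVector jackstraw_null_stats(NumericMatrix Z, NumericVector s, int B) {
  const int G = Z.nrow(), m = Z.ncol();
  std::vector<double> sp(s.begin(), s.end());
  R_xlen_t total = (R_xlen_t)B * G;
  NumericVector out(total);
  RNGScope scope;
  R_xlen_t k = 0;
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < G; ++g) {
      for (int i = m - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(sp[i], sp[j]);
      }
      double acc = 0.0;
      for (int i = 0; i < m; ++i) acc += Z(g, i) * sp[i];
      out[k++] = std::fabs(acc) / (m - 1);
    }
  }
  std::sort(out.begin(), out.end());
  return out;
}
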