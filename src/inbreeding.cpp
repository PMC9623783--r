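#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo traversal of the
// L'DL decomposition of the numerator relationship matrix.
// sire/dam are 1-based positions in a parents-before-offspring ordering,
// 0 meaning unknown.  Animals with an unknown parent get F = 0 (unknown
// parents are treated as unrelated, non-inbred population members).
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  // d[j] = Mendelian sampling variance fraction of animal j (1-based)
  std::vector<double> d(n + 1, 0.0);
  std::vector<double> L(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    if (s > i || dd > i)
      stop("pedigree not sorted parents-before-offspring at position %d", i + 1);
    double Fs = (s > 0) ? F[s - 1] : -1.0;  // unknown parent contributes -1
    double Fd = (dd > 0) ? F[dd - 1] : -1.0;
    d[i + 1] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 || dd == 0) { F[i] = 0.0; continue; }
    // a_ii = sum_j L_j^2 d_j over ancestors j of i (including i itself)
    L[i + 1] = 1.0;
    double aii = 0.0;
    for (int j = i + 1; j >= 1; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * d[j];
      int js = sire[j - 1], jd = dam[j - 1];
      if (js > 0) L[js] += 0.5 * lj;
      if (jd > 0) L[jd] += 0.5 * lj;
      L[j] = 0.0;  // reset as we go; all remaining nonzeros have smaller index
    }
    F[i] = aii - 1.0;
  }
  return F;
}
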