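#include <Rcpp.h>
using namespace Rcpp;

// Gather the nine zero-padded 3x3-offset copies of a feature-map matrix
// (npix x channels) into the im2col layout used by the conv layers:
// (npix x 9*channels), columns ordered offset-fastest within each channel,
// matching the row order of matrix(W, 9 * cin, cout). Indices in idx9 are
// 1-based; any index beyond nrow(x) reads the shared zero row.
// [[Rcpp::export(name = ".im2col_gather")]]
NumericMatrix im2col_gather(NumericMatrix x, IntegerVector idx9) {
  const int n = x.nrow(), c = x.ncol();
  const int reps = idx9.size() / n;
  // Rf_allocMatrix skips the zero fill NumericMatrix(n, m) would do;
  // every element is written below.
  NumericMatrix out(Rf_allocMatrix(REALSXP, n, reps * c));
  const double* xp = REAL(x);
  double* op = REAL(out);
  const int* ip = INTEGER(idx9);
  for (int cc = 0; cc < c; ++cc) {
    const double* col = xp + (size_t)cc * n;
    for (int k = 0; k < reps; ++k) {
      double* ocol = op + (size_t)(cc * reps + k) * n;
      const int* id = ip + (size_t)k * n;
      for (int i = 0; i < n; ++i) {
        const int j = id[i] - 1;
        ocol[i] = (j < n) ? col[j] : 0.0;
      }
    }
  }
  return out;
}
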