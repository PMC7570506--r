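#include <Rcpp.h>
using namespace Rcpp;

// Gather the im2col expansion of a batch of flattened patches.
// X: n x n_in, one flattened patch per row (column-major voxel order).
// rel: Fin * P voxel indices (1-based), feature index fastest within each
// output position. Returns (n * P) x Fin with sample index fastest in the
// rows, matching dim(Z) <- c(n, P, Fin) reshapes on the R side.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerVector& rel,
                         const int fin, const int p) {
  const int n = X.nrow();
  NumericMatrix out(n * p, fin);
  const double* x = REAL(X);
  double* o = REAL(out);
  const int* r = INTEGER(rel);
  for (int f = 0; f < fin; ++f) {
    for (int q = 0; q < p; ++q) {
      const double* src = x + (static_cast<size_t>(r[q * fin + f] - 1)) * n;
      double* dst = o + (static_cast<size_t>(f) * p + q) * n;
      std::copy(src, src + n, dst);
    }
  }
  return out;
}
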