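#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Similarity scores |c1 . c2'| / (||c1|| ||c2||) for a batch of neuron
// relabelings of the second matrix. perms is n_perm x n, 0-based; the
// upper-triangle norm of C2 is invariant under joint row/column
// permutation, so only the scalar product needs the permuted indexing.
// [[Rcpp::export]]
NumericVector perm_similarity_core(NumericMatrix C1, NumericMatrix C2,
                                   IntegerMatrix perms) {
  const int n = C1.nrow();
  if (C2.nrow() != n || perms.ncol() != n)
    stop("dimension mismatch between matrices and permutations");
  double n1 = 0.0, n2 = 0.0;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      n1 += C1(i, j) * C1(i, j);
      n2 += C2(i, j) * C2(i, j);
    }
  }
  const double denom = std::sqrt(n1) * std::sqrt(n2);
  if (denom == 0.0) stop("zero upper-triangle vector: similarity undefined");

  const int n_perm = perms.nrow();
  NumericVector out(n_perm);
  std::vector<int> p(n);
  const double *c2 = C2.begin();
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < n; ++i) p[i] = perms(k, i);
    double s = 0.0;
    for (int j = 1; j < n; ++j) {
      const double *col = &C1(0, j);
      const int pj = p[j];
      for (int i = 0; i < j; ++i) {
        s += col[i] * c2[(size_t)pj * n + p[i]];
      }
    }
    out[k] = std::fabs(s) / denom;
  }
  return out;
}
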