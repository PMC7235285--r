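// In-place finishing passes for pairwise distance matrices: enforce exact
// symmetry (average the two triangles), clamp small negative rounding
// artifacts to zero, zero the diagonal, and optionally take the square root
// (euclidean, which arrives as squared distances). Avoids the multiple full
// n x n copies that t(), pmax() and diag<- would allocate.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Turn a Gram matrix G = X X' and the squared row norms into the euclidean
// distance matrix, in place: d_ij = sqrt(max(0, sq_i + sq_j - 2 G_ij)).
// [[Rcpp::export]]
NumericMatrix cpp_finish_euclidean(NumericMatrix G, NumericVector sq) {
  int n = G.nrow();
  double* x = REAL(G);
  const double* s = REAL(sq);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      double v = s[i] + s[j] - x[(size_t)i * n + j] - x[(size_t)j * n + i];
      if (v < 0) v = 0;
      v = std::sqrt(v);
      x[(size_t)i * n + j] = v;
      x[(size_t)j * n + i] = v;
    }
    x[(size_t)i * n + i] = 0.0;
  }
  return G;
}

// [[Rcpp::export]]
NumericMatrix cpp_finish_dist(NumericMatrix M, bool take_sqrt) {
  int n = M.nrow();
  double* x = REAL(M);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      double v = (x[(size_t)i * n + j] + x[(size_t)j * n + i]) / 2.0;
      if (v < 0) v = 0;
      if (take_sqrt) v = std::sqrt(v);
      x[(size_t)i * n + j] = v;
      x[(size_t)j * n + i] = v;
    }
    x[(size_t)i * n + i] = 0.0;
  }
  return M;
}
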