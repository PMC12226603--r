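#include <Rcpp.h>
using namespace Rcpp;

// 2D cross-correlation with zero padding, "same" output size.
// Anchor (a1, a2) is the 0-based kernel element aligned with the output pixel:
//   y[i,j] = sum_{u,v} x[i+u-a1, j+v-a2] * k[u,v]
// Out-of-range x entries are treated as zero.
// [[Rcpp::export]]
NumericMatrix corr2_same(const NumericMatrix& x, const NumericMatrix& k,
                         int a1, int a2) {
  const int n = x.nrow(), m = x.ncol(), p = k.nrow(), q = k.ncol();
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    for (int v = 0; v < q; ++v) {
      const int jj0 = j + v - a2;
      if (jj0 < 0 || jj0 >= m) continue;
      for (int u = 0; u < p; ++u) {
        const double kv = k(u, v);
        if (kv == 0.0) continue;
        const int lo = std::max(0, a1 - u);
        const int hi = std::min(n - 1, n - 1 + a1 - u);
        for (int i = lo; i <= hi; ++i)
          y(i, j) += x(i + u - a1, jj0) * kv;
      }
    }
  }
  return y;
}

// Adjoint of corr2_same in its image argument:
//   z[i,j] = sum_{u,v} g[i-u+a1, j-v+a2] * k[u,v]
// so that <corr2_same(x,k), g> == <x, corr2_same_adj(g,k)>.
// [[Rcpp::export]]
NumericMatrix corr2_same_adj(const NumericMatrix& g, const NumericMatrix& k,
                             int a1, int a2) {
  const int n = g.nrow(), m = g.ncol(), p = k.nrow(), q = k.ncol();
  NumericMatrix z(n, m);
  for (int j = 0; j < m; ++j) {
    for (int v = 0; v < q; ++v) {
      const int jj0 = j - v + a2;
      if (jj0 < 0 || jj0 >= m) continue;
      for (int u = 0; u < p; ++u) {
        const double kv = k(u, v);
        if (kv == 0.0) continue;
        const int lo = std::max(0, u - a1);
        const int hi = std::min(n - 1, n - 1 + u - a1);
        for (int i = lo; i <= hi; ++i)
          z(i, j) += g(i - u + a1, jj0) * kv;
      }
    }
  }
  return z;
}

// Gradient of corr2_same(x, k) with respect to k, given the output cotangent g:
//   dk[u,v] = sum_{i,j} g[i,j] * x[i+u-a1, j+v-a2]
// [[Rcpp::export]]
NumericMatrix corr2_same_kgrad(const NumericMatrix& x, const NumericMatrix& g,
                               int p, int q, int a1, int a2) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix dk(p, q);
  for (int v = 0; v < q; ++v) {
    for (int u = 0; u < p; ++u) {
      double acc = 0.0;
      const int ilo = std::max(0, a1 - u), ihi = std::min(n - 1, n - 1 + a1 - u);
      const int jlo = std::max(0, a2 - v), jhi = std::min(m - 1, m - 1 + a2 - v);
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i)
          acc += g(i, j) * x(i + u - a1, j + v - a2);
      dk(u, v) = acc;
    }
  }
  return dk;
}

// Gradient of corr2_same_adj(t, k) with respect to k, given the output cotangent g:
//   dk[u,v] = sum_{i,j} g[i,j] * t[i-u+a1, j-v+a2]
// [[Rcpp::export]]
NumericMatrix corr2_same_adj_kgrad(const NumericMatrix& t, const NumericMatrix& g,
                                   int p, int q, int a1, int a2) {
  const int n = t.nrow(), m = t.ncol();
  NumericMatrix dk(p, q);
  for (int v = 0; v < q; ++v) {
    for (int u = 0; u < p; ++u) {
      double acc = 0.0;
      const int ilo = std::max(0, u - a1), ihi = std::min(n - 1, n - 1 + u - a1);
      const int jlo = std::max(0, v - a2), jhi = std::min(m - 1, m - 1 + v - a2);
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i)
          acc += g(i, j) * t(i - u + a1, j - v + a2);
      dk(u, v) = acc;
    }
  }
  return dk;
}
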