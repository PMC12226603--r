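#include <Rcpp.h>
using namespace Rcpp;

// Fused field-of-experts layer kernels: all priors of one unrolled layer are
// processed in a single call (convolution, piecewise-linear penalty transform
// on equispaced knots, spatial weighting, transposed convolution), for both
// the forward evaluation and its reverse-mode gradients.

static inline double pwl_val(const double* y, int nk, double lo, double step, double v) {
  double u = (v - lo) / step;
  if (u <= 0.0) return y[0];
  if (u >= nk - 1) return y[nk - 1];
  int i = (int)u;
  double a = u - i;
  return (1.0 - a) * y[i] + a * y[i + 1];
}

static inline double pwl_der(const double* y, int nk, double lo, double step, double v) {
  double u = (v - lo) / step;
  if (u < 0.0 || u > nk - 1) return 0.0;
  int i = (int)u;
  if (i >= nk - 1) i = nk - 2;
  return (y[i + 1] - y[i]) / step;
}

static inline void pwl_acc(double* dy, int nk, double lo, double step, double v, double g) {
  double u = (v - lo) / step;
  if (u <= 0.0) { dy[0] += g; return; }
  if (u >= nk - 1) { dy[nk - 1] += g; return; }
  int i = (int)u;
  double a = u - i;
  dy[i] += (1.0 - a) * g;
  dy[i + 1] += a * g;
}

// [[Rcpp::export]]
NumericVector pwl_eval_eq(const NumericVector& y, double lo, double step,
                          const NumericVector& v) {
  const int nk = y.size(), n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pwl_val(REAL(y), nk, lo, step, v[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector pwl_slope_eq(const NumericVector& y, double lo, double step,
                           const NumericVector& v) {
  const int nk = y.size(), n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pwl_der(REAL(y), nk, lo, step, v[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector pwl_ygrad_eq(int nk, double lo, double step,
                           const NumericVector& v, const NumericVector& g) {
  const int n = v.size();
  NumericVector dy(nk);
  for (int i = 0; i < n; ++i) pwl_acc(REAL(dy), nk, lo, step, v[i], g[i]);
  return dy;
}

static inline void corr_acc(const double* x, int n, int m, const double* k,
                            int p, int q, int a1, int a2, double* y) {
  // y += corr(x, k), "same", zero padding
  for (int j = 0; j < m; ++j)
    for (int v = 0; v < q; ++v) {
      int jj = j + v - a2;
      if (jj < 0 || jj >= m) continue;
      for (int u = 0; u < p; ++u) {
        double kv = k[u + p * v];
        if (kv == 0.0) continue;
        int lo = a1 - u > 0 ? a1 - u : 0;
        int hi = n - 1 + a1 - u < n - 1 ? n - 1 + a1 - u : n - 1;
        for (int i = lo; i <= hi; ++i)
          y[i + n * j] += x[(i + u - a1) + n * jj] * kv;
      }
    }
}

static inline void corr_adj_acc(const double* g, int n, int m, const double* k,
                                int p, int q, int a1, int a2, double* z) {
  // z += corr_adj(g, k)
  for (int j = 0; j < m; ++j)
    for (int v = 0; v < q; ++v) {
      int jj = j - v + a2;
      if (jj < 0 || jj >= m) continue;
      for (int u = 0; u < p; ++u) {
        double kv = k[u + p * v];
        if (kv == 0.0) continue;
        int lo = u - a1 > 0 ? u - a1 : 0;
        int hi = n - 1 + u - a1 < n - 1 ? n - 1 + u - a1 : n - 1;
        for (int i = lo; i <= hi; ++i)
          z[i + n * j] += g[(i - u + a1) + n * jj] * kv;
      }
    }
}

static inline void kgrad_acc(const double* x, const double* g, int n, int m,
                             int p, int q, int a1, int a2, double* dk) {
  // dk += kernel gradient of corr(x, .) with cotangent g
  for (int v = 0; v < q; ++v)
    for (int u = 0; u < p; ++u) {
      double acc = 0.0;
      int ilo = a1 - u > 0 ? a1 - u : 0, ihi = n - 1 + a1 - u < n - 1 ? n - 1 + a1 - u : n - 1;
      int jlo = a2 - v > 0 ? a2 - v : 0, jhi = m - 1 + a2 - v < m - 1 ? m - 1 + a2 - v : m - 1;
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i)
          acc += g[i + n * j] * x[(i + u - a1) + n * (j + v - a2)];
      dk[u + p * v] += acc;
    }
}

static inline void adj_kgrad_acc(const double* t, const double* g, int n, int m,
                                 int p, int q, int a1, int a2, double* dk) {
  // dk += kernel gradient of corr_adj(t, .) with cotangent g
  for (int v = 0; v < q; ++v)
    for (int u = 0; u < p; ++u) {
      double acc = 0.0;
      int ilo = u - a1 > 0 ? u - a1 : 0, ihi = n - 1 + u - a1 < n - 1 ? n - 1 + u - a1 : n - 1;
      int jlo = v - a2 > 0 ? v - a2 : 0, jhi = m - 1 + v - a2 < m - 1 ? m - 1 + v - a2 : m - 1;
      for (int j = jlo; j <= jhi; ++j)
        for (int i = ilo; i <= ihi; ++i)
          acc += g[i + n * j] * t[(i - u + a1) + n * (j - v + a2)];
      dk[u + p * v] += acc;
    }
}

// Forward pass of the regularizer of one layer:
//   g_reg = sum_j corr_adj(w_j * phi_j(corr(x, r2_j) / phi_scale_j), r1_j)
// phi ordinates are columns of phi_y on equispaced knots [lo, lo+step*(nk-1)].
// When cache = true the per-prior responses f, transformed responses pp and
// weighted responses tt are returned for the backward pass.
// [[Rcpp::export]]
List foe_apply(const NumericMatrix& x, const NumericVector& r1,
               const NumericVector& r2, const NumericVector& w,
               const NumericMatrix& phi_y, double lo, double step,
               const NumericVector& phi_scale, int o1, int o2, int n_k,
               int a1, int a2, bool cache) {
  const int n = x.nrow(), m = x.ncol();
  const int nk = phi_y.nrow();
  NumericMatrix g_reg(n, m);
  NumericVector f_all(cache ? n * m * n_k : 0), p_all(cache ? n * m * n_k : 0),
                t_all(cache ? n * m * n_k : 0), fmax(n_k);
  std::vector<double> f(n * m), tt(n * m);
  for (int j = 0; j < n_k; ++j) {
    std::fill(f.begin(), f.end(), 0.0);
    corr_acc(REAL(x), n, m, REAL(r2) + (size_t)j * o1 * o2, o1, o2, a1, a2, f.data());
    double fm = 0.0;
    const double isc = 1.0 / phi_scale[j];
    const double* yj = &phi_y(0, 0) + (size_t)j * nk;
    const double* wj = REAL(w) + (size_t)j * n * m;
    for (int i = 0; i < n * m; ++i) {
      double fa = std::abs(f[i]);
      if (fa > fm) fm = fa;
      double pv = phi_scale[j] * pwl_val(yj, nk, lo, step, f[i] * isc);
      tt[i] = wj[i] * pv;
      if (cache) {
        f_all[(size_t)j * n * m + i] = f[i];
        p_all[(size_t)j * n * m + i] = pv;
        t_all[(size_t)j * n * m + i] = tt[i];
      }
    }
    fmax[j] = fm;
    corr_adj_acc(tt.data(), n, m, REAL(r1) + (size_t)j * o1 * o2, o1, o2, a1, a2, REAL(g_reg));
  }
  List out = List::create(_["g_reg"] = g_reg, _["fmax"] = fmax);
  if (cache) {
    out["f"] = f_all; out["p"] = p_all; out["t"] = t_all;
  }
  return out;
}

// Reverse-mode gradients of the regularizer path of one layer, given the
// cotangent ghat on g_reg. Returns dr1, dr2, dw, dphi_y and the contribution
// to the cotangent on x.
// [[Rcpp::export]]
List foe_backward(const NumericMatrix& ghat, const NumericMatrix& x_in,
                  const NumericVector& r1, const NumericVector& r2,
                  const NumericVector& w, const NumericMatrix& phi_y,
                  double lo, double step, const NumericVector& phi_scale,
                  const NumericVector& f_all, const NumericVector& p_all,
                  const NumericVector& t_all, int o1, int o2, int n_k,
                  int a1, int a2) {
  const int n = ghat.nrow(), m = ghat.ncol();
  const int nk = phi_y.nrow();
  NumericVector dr1(o1 * o2 * n_k), dr2(o1 * o2 * n_k), dw(n * m * n_k);
  NumericMatrix dphi(nk, n_k), dx(n, m);
  std::vector<double> that(n * m), df(n * m), fn(n * m);
  for (int j = 0; j < n_k; ++j) {
    const size_t off = (size_t)j * n * m;
    const size_t koff = (size_t)j * o1 * o2;
    // dr1: kernel gradient of the synthesis-side transposed convolution
    adj_kgrad_acc(REAL(t_all) + off, REAL(ghat), n, m, o1, o2, a1, a2, REAL(dr1) + koff);
    // cotangent on the weighted response t_j
    std::fill(that.begin(), that.end(), 0.0);
    corr_acc(REAL(ghat), n, m, REAL(r1) + koff, o1, o2, a1, a2, that.data());
    const double isc = 1.0 / phi_scale[j];
    const double* yj = &phi_y(0, 0) + (size_t)j * nk;
    const double* wj = REAL(w) + off;
    double* dyj = &dphi(0, 0) + (size_t)j * nk;
    for (int i = 0; i < n * m; ++i) {
      double fni = f_all[off + i] * isc;
      fn[i] = fni;
      REAL(dw)[off + i] = p_all[off + i] * that[i];
      double dp = wj[i] * that[i];
      pwl_acc(dyj, nk, lo, step, fni, dp * phi_scale[j]);
      df[i] = pwl_der(yj, nk, lo, step, fni) * dp;
    }
    kgrad_acc(REAL(x_in), df.data(), n, m, o1, o2, a1, a2, REAL(dr2) + koff);
    corr_adj_acc(df.data(), n, m, REAL(r2) + koff, o1, o2, a1, a2, REAL(dx));
  }
  return List::create(_["dr1"] = dr1, _["dr2"] = dr2, _["dw"] = dw,
                      _["dphi"] = dphi, _["dx"] = dx);
}

// Plain CSC sparse matrix-vector product (dgCMatrix slots), avoiding S4
// dispatch overhead in the unrolled network's inner loop.
// [[Rcpp::export]]
NumericVector spmv_csc(const IntegerVector& p, const IntegerVector& i,
                       const NumericVector& x, const NumericVector& v,
                       int n_row) {
  NumericVector out(n_row);
  const int nc = v.size();
  for (int j = 0; j < nc; ++j) {
    const double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) out[i[k]] += x[k] * vj;
  }
  return out;
}
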