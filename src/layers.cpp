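#include <Rcpp.h>
using namespace Rcpp;

// Single-pass elementwise / row-wise primitives for the transformer.
// These are memory-bandwidth bound; doing them in one pass avoids the
// chain of temporaries R vector arithmetic would allocate.

// Y = M + b (bias per column), one allocation
// [[Rcpp::export(name = ".addb_cpp")]]
NumericMatrix addb_cpp(const NumericMatrix& M, const NumericVector& b) {
  const int n = M.nrow(), p = M.ncol();
  NumericMatrix Y(n, p);
  for (int j = 0; j < p; ++j) {
    const double bj = b[j];
    const double* src = &M(0, j);
    double* dst = &Y(0, j);
    for (int i = 0; i < n; ++i) dst[i] = src[i] + bj;
  }
  return Y;
}

// GELU (tanh parameterization); returns the activation and the cached
// tanh value used by the backward pass
// [[Rcpp::export(name = ".gelu_fwd_cpp")]]
List gelu_fwd_cpp(const NumericMatrix& X) {
  const double c1 = std::sqrt(2.0 / M_PI), c2 = 0.044715;
  const R_xlen_t n = X.size();
  NumericMatrix Y(X.nrow(), X.ncol()), Tn(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* y = Y.begin();
  double* t = Tn.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double ti = std::tanh(c1 * xi * (1.0 + c2 * xi * xi));
    t[i] = ti;
    y[i] = 0.5 * xi * (1.0 + ti);
  }
  return List::create(_["Y"] = Y, _["Tn"] = Tn);
}

// dX = dY * gelu'(X) given the cached tanh values
// [[Rcpp::export(name = ".gelu_bwd_cpp")]]
NumericMatrix gelu_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                           const NumericMatrix& Tn) {
  const double c1 = std::sqrt(2.0 / M_PI), c2 = 0.044715;
  const R_xlen_t n = X.size();
  NumericMatrix dX(X.nrow(), X.ncol());
  const double* x = X.begin();
  const double* t = Tn.begin();
  const double* dy = dY.begin();
  double* dx = dX.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i], ti = t[i];
    const double du = c1 * (1.0 + 3.0 * c2 * xi * xi);
    dx[i] = dy[i] * (0.5 * (1.0 + ti) + 0.5 * xi * (1.0 - ti * ti) * du);
  }
  return dX;
}

// row-wise LayerNorm forward: Y = ((x - mean) / sqrt(var + eps)) * g + b
// [[Rcpp::export(name = ".ln_fwd_cpp")]]
List ln_fwd_cpp(const NumericMatrix& X, const NumericVector& g,
                const NumericVector& b, double eps) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix Y(n, p), xhat(n, p);
  NumericVector inv(n);
  std::vector<double> mu(n, 0.0), s2(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* src = &X(0, j);
    for (int i = 0; i < n; ++i) mu[i] += src[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= p;
  for (int j = 0; j < p; ++j) {
    const double* src = &X(0, j);
    for (int i = 0; i < n; ++i) {
      const double c = src[i] - mu[i];
      s2[i] += c * c;
    }
  }
  for (int i = 0; i < n; ++i) inv[i] = 1.0 / std::sqrt(s2[i] / p + eps);
  for (int j = 0; j < p; ++j) {
    const double* src = &X(0, j);
    double* xh = &xhat(0, j);
    double* y = &Y(0, j);
    const double gj = g[j], bj = b[j];
    for (int i = 0; i < n; ++i) {
      xh[i] = (src[i] - mu[i]) * inv[i];
      y[i] = xh[i] * gj + bj;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["inv"] = inv);
}

// row-wise LayerNorm backward
// [[Rcpp::export(name = ".ln_bwd_cpp")]]
List ln_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& inv, const NumericVector& g) {
  const int n = dY.nrow(), p = dY.ncol();
  NumericMatrix dX(n, p);
  NumericVector dg(p), db(p);
  std::vector<double> m1(n, 0.0), m2(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* dy = &dY(0, j);
    const double* xh = &xhat(0, j);
    const double gj = g[j];
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dxh = dy[i] * gj;
      m1[i] += dxh;
      m2[i] += dxh * xh[i];
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dg[j] = sg;
    db[j] = sb;
  }
  for (int i = 0; i < n; ++i) {
    m1[i] /= p;
    m2[i] /= p;
  }
  for (int j = 0; j < p; ++j) {
    const double* dy = &dY(0, j);
    const double* xh = &xhat(0, j);
    double* dx = &dX(0, j);
    const double gj = g[j];
    for (int i = 0; i < n; ++i)
      dx[i] = inv[i] * (dy[i] * gj - m1[i] - xh[i] * m2[i]);
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}
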