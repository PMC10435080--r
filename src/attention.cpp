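// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Factorized multi-headed self-attention kernels.
//
// Tokens are stored as an N x G matrix with row index
//   r = s + n_s (t - 1) + n_s n_t (b - 1)
// (spatial index fastest, then temporal patch, then sample) and head-major
// column blocks of width d = G / heads. Spatial attention groups share a
// temporal index (contiguous row blocks); temporal attention groups share
// a spatial index (rows strided by n_s). Gathering the groups here avoids
// any reshaping on the R side.
//
// Attention matrices are returned as an n x n x S cube with slice index
//   slice = g + n_groups ((b - 1) + B (h - 1))
// where g runs over temporal patches (spatial attention) or spatial
// indices (temporal attention); they feed both the backward pass and
// attention rollout.

static inline void gather(const arma::mat& M, arma::mat& buf,
                          const int r0, const int stride, const int n,
                          const int c0, const int d) {
  for (int j = 0; j < d; ++j) {
    const double* src = M.colptr(c0 + j) + r0;
    double* dst = buf.colptr(j);
    for (int i = 0; i < n; ++i) dst[i] = src[i * stride];
  }
}

static inline void scatter_add(arma::mat& M, const arma::mat& buf,
                               const int r0, const int stride, const int n,
                               const int c0, const int d) {
  for (int j = 0; j < d; ++j) {
    double* dst = M.colptr(c0 + j) + r0;
    const double* src = buf.colptr(j);
    for (int i = 0; i < n; ++i) dst[i * stride] += src[i];
  }
}

// [[Rcpp::export(name = ".attn_fwd_cpp")]]
List attn_fwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  int n_s, int n_t, int B, int heads, bool spatial,
                  double scale) {
  const int G = Q.n_cols, d = G / heads;
  const int n = spatial ? n_s : n_t;        // tokens per group
  const int n_groups = spatial ? n_t : n_s; // groups per sample
  const int stride = spatial ? 1 : n_s;
  arma::mat O(Q.n_rows, G, arma::fill::none);
  arma::cube A(n, n, (size_t)n_groups * B * heads, arma::fill::none);
  arma::mat Qb(n, d), Kb(n, d), Vb(n, d), Sc(n, n);
  for (int h = 0; h < heads; ++h) {
    const int c0 = h * d;
    for (int b = 0; b < B; ++b) {
      for (int g = 0; g < n_groups; ++g) {
        const int r0 = spatial ? n_s * (g + n_t * b)
                               : g + n_s * n_t * b;
        gather(Q, Qb, r0, stride, n, c0, d);
        gather(K, Kb, r0, stride, n, c0, d);
        gather(V, Vb, r0, stride, n, c0, d);
        Sc = Qb * Kb.t() * scale;
        Sc.each_col() -= arma::max(Sc, 1);
        Sc = arma::exp(Sc);
        Sc.each_col() /= arma::sum(Sc, 1);
        A.slice(g + (size_t)n_groups * (b + B * h)) = Sc;
        Qb = Sc * Vb;  // reuse buffer for the output block
        for (int j = 0; j < d; ++j) {
          double* dst = O.colptr(c0 + j) + r0;
          const double* src = Qb.colptr(j);
          for (int i = 0; i < n; ++i) dst[i * stride] = src[i];
        }
      }
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(name = ".attn_bwd_cpp")]]
List attn_bwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const arma::cube& A, const arma::mat& dO,
                  int n_s, int n_t, int B, int heads, bool spatial,
                  double scale) {
  const int G = Q.n_cols, d = G / heads;
  const int n = spatial ? n_s : n_t;
  const int n_groups = spatial ? n_t : n_s;
  const int stride = spatial ? 1 : n_s;
  arma::mat dQ(Q.n_rows, G, arma::fill::zeros);
  arma::mat dK(Q.n_rows, G, arma::fill::zeros);
  arma::mat dV(Q.n_rows, G, arma::fill::zeros);
  arma::mat Qb(n, d), Kb(n, d), Vb(n, d), dOb(n, d), buf(n, d);
  arma::mat dA(n, n), dS(n, n);
  for (int h = 0; h < heads; ++h) {
    const int c0 = h * d;
    for (int b = 0; b < B; ++b) {
      for (int g = 0; g < n_groups; ++g) {
        const int r0 = spatial ? n_s * (g + n_t * b)
                               : g + n_s * n_t * b;
        const arma::mat& As = A.slice(g + (size_t)n_groups * (b + B * h));
        gather(Q, Qb, r0, stride, n, c0, d);
        gather(K, Kb, r0, stride, n, c0, d);
        gather(V, Vb, r0, stride, n, c0, d);
        gather(dO, dOb, r0, stride, n, c0, d);
        dA = dOb * Vb.t();
        buf = As.t() * dOb;                       // dV block
        scatter_add(dV, buf, r0, stride, n, c0, d);
        dS = dA % As;
        dS = dS - As.each_col() % arma::sum(dS, 1);
        buf = dS * Kb * scale;                    // dQ block
        scatter_add(dQ, buf, r0, stride, n, c0, d);
        buf = dS.t() * Qb * scale;                // dK block
        scatter_add(dK, buf, r0, stride, n, c0, d);
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
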