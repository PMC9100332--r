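// Multi-head scaled dot-product self-attention over a batch of equal-length
// sequences. Q, K, V are (n_seq * len) x d matrices, rows sequence-major
// (rows 1..len belong to sequence 1, and so on). Heads partition the columns.
//
// The per-(sequence, head) blocks are tiny (len x dh, e.g. 46 x 8), so BLAS
// call overhead dominates a naive implementation. Blocks are instead copied
// into contiguous row-major scratch buffers and multiplied with manual
// dot-product loops; softmax matrices are returned as a cube
// (len x len x n_seq*n_heads) for reuse by the backward pass.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void load_block(const double* M, arma::uword nrow, arma::uword r0,
                              arma::uword c0, int len, int dh, double* buf) {
  // buf[i*dh + k] = M[(c0+k)*nrow + r0 + i]
  for (int k = 0; k < dh; ++k) {
    const double* col = M + (c0 + k) * nrow + r0;
    for (int i = 0; i < len; ++i) buf[i * dh + k] = col[i];
  }
}

static inline void store_block(double* M, arma::uword nrow, arma::uword r0,
                               arma::uword c0, int len, int dh, const double* buf) {
  for (int k = 0; k < dh; ++k) {
    double* col = M + (c0 + k) * nrow + r0;
    for (int i = 0; i < len; ++i) col[i] = buf[i * dh + k];
  }
}

static inline double dot_dh(const double* a, const double* b, int dh) {
  double s = 0;
  for (int k = 0; k < dh; ++k) s += a[k] * b[k];
  return s;
}

// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                      int n_seq, int len, int n_heads) {
  const int d = Q.n_cols;
  if (d % n_heads != 0) stop("d_model not divisible by n_heads");
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const arma::uword N = Q.n_rows;
  arma::mat out(N, d);
  arma::cube P(len, len, (arma::uword)n_seq * n_heads);
  std::vector<double> Qb(len * dh), Kb(len * dh), Vb(len * dh), Ob(len * dh),
      S(len * len);
  for (int s = 0; s < n_seq; ++s) {
    const arma::uword r0 = (arma::uword)s * len;
    for (int h = 0; h < n_heads; ++h) {
      const arma::uword c0 = (arma::uword)h * dh;
      load_block(Q.memptr(), N, r0, c0, len, dh, Qb.data());
      load_block(K.memptr(), N, r0, c0, len, dh, Kb.data());
      load_block(V.memptr(), N, r0, c0, len, dh, Vb.data());
      // scores + row softmax (S kept row-major: S[i*len + j])
      for (int i = 0; i < len; ++i) {
        double* Si = S.data() + (R_xlen_t)i * len;
        double mx = -INFINITY;
        for (int j = 0; j < len; ++j) {
          Si[j] = scale * dot_dh(Qb.data() + i * dh, Kb.data() + j * dh, dh);
          if (Si[j] > mx) mx = Si[j];
        }
        double sum = 0;
        for (int j = 0; j < len; ++j) { Si[j] = std::exp(Si[j] - mx); sum += Si[j]; }
        const double inv = 1.0 / sum;
        for (int j = 0; j < len; ++j) Si[j] *= inv;
        // output row i = sum_j S[i][j] * V[j]
        double* Oi = Ob.data() + i * dh;
        for (int k = 0; k < dh; ++k) Oi[k] = 0;
        for (int j = 0; j < len; ++j) {
          const double w = Si[j];
          const double* Vj = Vb.data() + j * dh;
          for (int k = 0; k < dh; ++k) Oi[k] += w * Vj[k];
        }
      }
      // save softmax (cube slice is column-major len x len)
      double* Ps = P.slice_memptr((arma::uword)s * n_heads + h);
      for (int i = 0; i < len; ++i)
        for (int j = 0; j < len; ++j) Ps[(R_xlen_t)j * len + i] = S[(R_xlen_t)i * len + j];
      store_block(out.memptr(), N, r0, c0, len, dh, Ob.data());
    }
  }
  return List::create(_["out"] = out, _["P"] = P);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& dOut, const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::cube& P,
                       int n_seq, int len, int n_heads) {
  const int d = Q.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const arma::uword N = Q.n_rows;
  arma::mat dQ(N, d), dK(N, d), dV(N, d);
  std::vector<double> Qb(len * dh), Kb(len * dh), Vb(len * dh), dOb(len * dh),
      dQb(len * dh), dKb(len * dh), dVb(len * dh), Pb(len * len), dS(len * len);
  for (int s = 0; s < n_seq; ++s) {
    const arma::uword r0 = (arma::uword)s * len;
    for (int h = 0; h < n_heads; ++h) {
      const arma::uword c0 = (arma::uword)h * dh;
      load_block(Q.memptr(), N, r0, c0, len, dh, Qb.data());
      load_block(K.memptr(), N, r0, c0, len, dh, Kb.data());
      load_block(V.memptr(), N, r0, c0, len, dh, Vb.data());
      load_block(dOut.memptr(), N, r0, c0, len, dh, dOb.data());
      // Pb row-major from cube slice (column-major)
      const double* Ps = P.slice_memptr((arma::uword)s * n_heads + h);
      for (int i = 0; i < len; ++i)
        for (int j = 0; j < len; ++j) Pb[(R_xlen_t)i * len + j] = Ps[(R_xlen_t)j * len + i];
      std::fill(dVb.begin(), dVb.end(), 0.0);
      for (int i = 0; i < len; ++i) {
        const double* Pi = Pb.data() + (R_xlen_t)i * len;
        double* dSi = dS.data() + (R_xlen_t)i * len;
        const double* dOi = dOb.data() + i * dh;
        // dP row i, and accumulate dV += P^T dO
        double rs = 0;
        for (int j = 0; j < len; ++j) {
          const double dp = dot_dh(dOi, Vb.data() + j * dh, dh);
          dSi[j] = dp;                     // temporarily dP
          rs += dp * Pi[j];
          double* dVj = dVb.data() + j * dh;
          const double pij = Pi[j];
          for (int k = 0; k < dh; ++k) dVj[k] += pij * dOi[k];
        }
        // softmax backward, then dQ row i = scale * dS_i K
        double* dQi = dQb.data() + i * dh;
        for (int k = 0; k < dh; ++k) dQi[k] = 0;
        for (int j = 0; j < len; ++j) {
          dSi[j] = Pi[j] * (dSi[j] - rs);
          const double w = dSi[j];
          const double* Kj = Kb.data() + j * dh;
          for (int k = 0; k < dh; ++k) dQi[k] += w * Kj[k];
        }
        for (int k = 0; k < dh; ++k) dQi[k] *= scale;
      }
      // dK_j = scale * sum_i dS(i,j) Q_i
      std::fill(dKb.begin(), dKb.end(), 0.0);
      for (int i = 0; i < len; ++i) {
        const double* dSi = dS.data() + (R_xlen_t)i * len;
        const double* Qi = Qb.data() + i * dh;
        for (int j = 0; j < len; ++j) {
          const double w = scale * dSi[j];
          double* dKj = dKb.data() + j * dh;
          for (int k = 0; k < dh; ++k) dKj[k] += w * Qi[k];
        }
      }
      store_block(dQ.memptr(), N, r0, c0, len, dh, dQb.data());
      store_block(dK.memptr(), N, r0, c0, len, dh, dKb.data());
      store_block(dV.memptr(), N, r0, c0, len, dh, dVb.data());
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
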