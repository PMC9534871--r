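// Grouped 1D convolution kernels ("same" padding, arbitrary stride) for the
// residual-network classifier. Tensors arrive as arma::cube with dimensions
// (channels, length, batch), matching the R-side layout; channels are the
// fastest-varying dimension, so group-channel blocks are contiguous and can
// be moved with memcpy.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for one group: rows are (channel-within-group, kernel-offset) pairs
// with channel fastest, columns are (output position, sample) with position
// fastest.
static mat im2col_group(const cube& X, int c0, int cpg, int k, int stride,
                        int pl, int L_out) {
  const int C_in = X.n_rows;
  const int L = X.n_cols;
  const int N = X.n_slices;
  mat P(cpg * k, (size_t)L_out * N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xs = X.slice_colptr(n, 0);
    for (int t = 0; t < L_out; ++t) {
      double* pcol = P.colptr((size_t)n * L_out + t);
      const int base = t * stride - pl;  // input index of kernel offset 0
      for (int j = 0; j < k; ++j) {
        const int l = base + j;
        if (l < 0 || l >= L) continue;
        std::memcpy(pcol + (size_t)j * cpg, xs + (size_t)l * C_in + c0,
                    cpg * sizeof(double));
      }
    }
  }
  return P;
}

// reshape W rows of one group into a (cpg_out, cpg_in*k) GEMM operand with
// channel-within-group fastest along each row
static mat weight_group(const cube& W, int g, int cpg_out) {
  const int cpg_in = W.n_cols;
  const int k = W.n_slices;
  mat Wg(cpg_out, cpg_in * k);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < cpg_in; ++c)
      for (int oc = 0; oc < cpg_out; ++oc)
        Wg(oc, (size_t)j * cpg_in + c) = W(g * cpg_out + oc, c, j);
  return Wg;
}

// [[Rcpp::export]]
arma::cube conv1d_fw_cpp(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b, int stride, int groups,
                         int pl, int L_out) {
  const int C_in = X.n_rows;
  const int N = X.n_slices;
  const int C_out = W.n_rows;
  const int cpg_in = W.n_cols;
  const int k = W.n_slices;
  const int cpg_out = C_out / groups;
  cube Y(C_out, L_out, N);
  for (int g = 0; g < groups; ++g) {
    mat P = im2col_group(X, g * (C_in / groups), cpg_in, k, stride, pl, L_out);
    mat Yg = weight_group(W, g, cpg_out) * P;  // (cpg_out, L_out*N)
    Yg.each_col() += b.subvec(g * cpg_out, (g + 1) * cpg_out - 1);
    for (int n = 0; n < N; ++n) {
      double* ys = Y.slice_colptr(n, 0);
      for (int t = 0; t < L_out; ++t) {
        std::memcpy(ys + (size_t)t * C_out + g * cpg_out,
                    Yg.colptr((size_t)n * L_out + t),
                    cpg_out * sizeof(double));
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bw_cpp(const arma::cube& dY, const arma::cube& X,
                         const arma::cube& W, int stride, int groups,
                         int pl) {
  const int C_in = X.n_rows;
  const int L = X.n_cols;
  const int N = X.n_slices;
  const int C_out = W.n_rows;
  const int cpg_in = W.n_cols;
  const int k = W.n_slices;
  const int cpg_out = C_out / groups;
  const int L_out = dY.n_cols;
  cube dX(C_in, L, N, fill::zeros);
  cube dW(C_out, cpg_in, k, fill::zeros);
  vec db(C_out, fill::zeros);
  for (int g = 0; g < groups; ++g) {
    const int c0 = g * (C_in / groups);
    mat P = im2col_group(X, c0, cpg_in, k, stride, pl, L_out);
    mat dYg(cpg_out, (size_t)L_out * N);
    for (int n = 0; n < N; ++n) {
      const double* ds = dY.slice_colptr(n, 0);
      for (int t = 0; t < L_out; ++t) {
        std::memcpy(dYg.colptr((size_t)n * L_out + t),
                    ds + (size_t)t * C_out + g * cpg_out,
                    cpg_out * sizeof(double));
      }
    }
    db.subvec(g * cpg_out, (g + 1) * cpg_out - 1) = sum(dYg, 1);
    mat dWg = dYg * P.t();  // (cpg_out, cpg_in*k)
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < cpg_in; ++c)
        for (int oc = 0; oc < cpg_out; ++oc)
          dW(g * cpg_out + oc, c, j) = dWg(oc, (size_t)j * cpg_in + c);
    mat dP = weight_group(W, g, cpg_out).t() * dYg;  // (cpg_in*k, L_out*N)
    for (int n = 0; n < N; ++n) {
      double* dxs = dX.slice_colptr(n, 0);
      for (int t = 0; t < L_out; ++t) {
        const double* pcol = dP.colptr((size_t)n * L_out + t);
        const int base = t * stride - pl;
        for (int j = 0; j < k; ++j) {
          const int l = base + j;
          if (l < 0 || l >= L) continue;
          double* dst = dxs + (size_t)l * C_in + c0;
          const double* src = pcol + (size_t)j * cpg_in;
          for (int c = 0; c < cpg_in; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
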