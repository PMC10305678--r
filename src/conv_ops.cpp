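// Hot numeric kernels of the fusion network: length-3 "same" 1D
// convolution (forward and backward) and length-2 max-pooling on the
// (L*B) x C activation layout, where rows l + (b-1)*L hold position l of
// sample b. Weights are (3*Cin) x Cout with row blocks ordered
// [tap -1; tap 0; tap +1].
//
// The convolution runs as full-matrix BLAS products of the contiguous
// activation matrix; the length shift is applied to the product instead of
// the input (one strided in-place add), and the few rows that leak across
// sample boundaries are corrected explicitly. No im2col buffer is ever
// materialized and no per-sample submatrix products are issued.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// forward: ReLU(conv(A, W) + bias); returns the post-activation matrix
// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& A, const arma::mat& W,
                    const arma::vec& bias, const int L) {
  const int cin = A.n_cols;
  const int B = A.n_rows / L;
  const int n = A.n_rows;
  const arma::mat W1 = W.rows(0, cin - 1);
  const arma::mat Wm = W.rows(cin, 2 * cin - 1);
  const arma::mat W3 = W.rows(2 * cin, 3 * cin - 1);
  arma::mat Z = A * Wm;
  if (L > 1) {
    const arma::mat Z1 = A * W1; // tap -1: Z[l] += Z1[l-1] within a sample
    const arma::mat Z3 = A * W3; // tap +1: Z[l] += Z3[l+1]
    for (int c = 0; c < (int)Z.n_cols; ++c) {
      double* z = Z.colptr(c);
      const double* z1 = Z1.colptr(c);
      const double* z3 = Z3.colptr(c);
      for (int b = 0; b < B; ++b) {
        const int s = b * L;
        for (int l = 1; l < L; ++l) z[s + l] += z1[s + l - 1];
        for (int l = 0; l < L - 1; ++l) z[s + l] += z3[s + l + 1];
      }
    }
  }
  for (int c = 0; c < (int)Z.n_cols; ++c) {
    double* z = Z.colptr(c);
    const double bc = bias[c];
    for (int r = 0; r < n; ++r) {
      const double v = z[r] + bc;
      z[r] = v > 0.0 ? v : 0.0;
    }
  }
  return Z;
}

// backward through ReLU + conv: `act` is the cached post-activation,
// `dout` the gradient at the stage output
// [[Rcpp::export]]
List conv3_bwd(const arma::mat& A, const arma::mat& W, const arma::mat& act,
               const arma::mat& dout, const int L) {
  const int cin = A.n_cols;
  const int cout = W.n_cols;
  const int B = A.n_rows / L;
  arma::mat dz = dout;
  { // ReLU mask from the cached post-activation
    const double* a = act.memptr();
    double* d = dz.memptr();
    const arma::uword n = dz.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      if (a[i] <= 0.0) d[i] = 0.0;
    }
  }
  // dz3 = [dzup | dz | dzdown] with dzup[l] = dz[l+1], dzdown[l] = dz[l-1]
  // (shifts within sample blocks, zero padded), built in place
  const int n = dz.n_rows;
  arma::mat dz3(n, 3 * cout);
  for (int c = 0; c < cout; ++c) {
    const double* in = dz.colptr(c);
    double* up = dz3.colptr(c);
    double* mid = dz3.colptr(cout + c);
    double* down = dz3.colptr(2 * cout + c);
    std::memcpy(up, in + 1, (n - 1) * sizeof(double));
    up[n - 1] = 0.0;
    std::memcpy(mid, in, n * sizeof(double));
    std::memcpy(down + 1, in, (n - 1) * sizeof(double));
    down[0] = 0.0;
    for (int b = 0; b < B; ++b) {
      up[b * L + L - 1] = 0.0;
      down[b * L] = 0.0;
    }
  }
  arma::mat dWflat = A.t() * dz3; // cin x 3cout
  arma::mat dW(3 * cin, cout);
  dW.rows(0, cin - 1) = dWflat.cols(0, cout - 1);
  dW.rows(cin, 2 * cin - 1) = dWflat.cols(cout, 2 * cout - 1);
  dW.rows(2 * cin, 3 * cin - 1) = dWflat.cols(2 * cout, 3 * cout - 1);
  // dA[l] = dz[l+1] W1^T + dz[l] Wm^T + dz[l-1] W3^T
  arma::mat WT(3 * cout, cin);
  WT.rows(0, cout - 1) = W.rows(0, cin - 1).t();
  WT.rows(cout, 2 * cout - 1) = W.rows(cin, 2 * cin - 1).t();
  WT.rows(2 * cout, 3 * cout - 1) = W.rows(2 * cin, 3 * cin - 1).t();
  arma::mat dA = dz3 * WT;
  arma::vec db = arma::vec(arma::sum(dz, 0).t());
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// length-2 max pool (stride 2, trailing element dropped when L is odd);
// returns the pooled matrix and the winner mask for backward
// [[Rcpp::export]]
List maxpool2_fwd(const arma::mat& A, const int L) {
  const int C = A.n_cols;
  const int B = A.n_rows / L;
  const int M = L / 2;
  arma::mat out(M * B, C);
  IntegerMatrix take1(M * B, C);
  int* tk = INTEGER(take1);
  for (int c = 0; c < C; ++c) {
    const double* col = A.colptr(c);
    double* oc = out.colptr(c);
    int* tc = tk + (size_t)c * M * B;
    for (int b = 0; b < B; ++b) {
      const double* cb = col + b * L;
      double* ob = oc + b * M;
      int* tb = tc + b * M;
      for (int m = 0; m < M; ++m) {
        const double a1 = cb[2 * m], a2 = cb[2 * m + 1];
        const bool first = a1 >= a2;
        ob[m] = first ? a1 : a2;
        tb[m] = first ? 1 : 0;
      }
    }
  }
  return List::create(_["out"] = out, _["take1"] = take1);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd(const IntegerMatrix& take1, const arma::mat& dout,
                       const int L) {
  const int C = dout.n_cols;
  const int M = L / 2;
  const int B = take1.nrow() / M;
  arma::mat dA(L * B, C);
  const int* tk = INTEGER(take1);
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.colptr(c);
    const int* tc = tk + (size_t)c * M * B;
    double* ac = dA.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* db = dc + b * M;
      const int* tb = tc + b * M;
      double* ab = ac + b * L;
      for (int m = 0; m < M; ++m) {
        const double d = db[m];
        ab[2 * m] = tb[m] ? d : 0.0;
        ab[2 * m + 1] = tb[m] ? 0.0 : d;
      }
      if (L % 2 == 1) ab[L - 1] = 0.0;
    }
  }
  return dA;
}
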