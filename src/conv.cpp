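// Hot path of the 1-D (self-ONN) convolutions. A "same" stride-1
// cross-correlation over a stacked batch is computed as K shifted BLAS
// dgemm accumulations — no im2col intermediate is ever materialized, which
// keeps the training loop memory-bandwidth friendly.
//
// Feature maps are stacked (B*L) x C column-major matrices with
// sample-major rows. Kernels are passed flattened as (Cin*K) x Cout
// matrices with the input channel fastest, so the tap-k slice is the
// contiguous-row block starting at row k*Cin (unit row stride, as dgemm
// requires).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// y = sum_k shift_k(x) %*% W[k]  ("same" zero padding)
// [[Rcpp::export(rng = false)]]
NumericMatrix conv_fwd_blas(const NumericMatrix& x, const NumericMatrix& Wflat,
                            int B, int L, int K) {
  const int Cin = x.ncol();
  const int Co = Wflat.ncol();
  const int BL = B * L;
  const int ldw = Cin * K;
  NumericMatrix Y(BL, Co);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int o = k - (K - 1) / 2;
    const int lo = o < 0 ? -o : 0;
    const int hi = o > 0 ? L - o : L;
    const int M = hi - lo;
    if (M <= 0) continue;
    for (int b = 0; b < B; ++b) {
      F77_CALL(dgemm)("N", "N", &M, &Co, &Cin, &one,
                      x.begin() + (size_t)b * L + lo + o, &BL,
                      Wflat.begin() + (size_t)k * Cin, &ldw, &one,
                      Y.begin() + (size_t)b * L + lo, &BL
                      FCONE FCONE);
    }
  }
  return Y;
}

// Gradients of conv_fwd_blas: dx = sum_k unshift_k(dY %*% t(W[k])) and
// dW[k] = t(shift_k(x)) %*% dY, both accumulated with dgemm.
// [[Rcpp::export(rng = false)]]
List conv_bwd_blas(const NumericMatrix& x, const NumericMatrix& dY,
                   const NumericMatrix& Wflat, int B, int L, int K) {
  const int Cin = x.ncol();
  const int Co = Wflat.ncol();
  const int BL = B * L;
  const int ldw = Cin * K;
  NumericMatrix dx(BL, Cin);
  NumericMatrix dW(ldw, Co);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int o = k - (K - 1) / 2;
    const int lo = o < 0 ? -o : 0;
    const int hi = o > 0 ? L - o : L;
    const int M = hi - lo;
    if (M <= 0) continue;
    for (int b = 0; b < B; ++b) {
      // dx[lo+o : hi+o, ] += dY[lo : hi, ] %*% t(W[k])
      F77_CALL(dgemm)("N", "T", &M, &Cin, &Co, &one,
                      dY.begin() + (size_t)b * L + lo, &BL,
                      Wflat.begin() + (size_t)k * Cin, &ldw, &one,
                      dx.begin() + (size_t)b * L + lo + o, &BL
                      FCONE FCONE);
      // dW[k] += t(x[lo+o : hi+o, ]) %*% dY[lo : hi, ]
      F77_CALL(dgemm)("T", "N", &Cin, &Co, &M, &one,
                      x.begin() + (size_t)b * L + lo + o, &BL,
                      dY.begin() + (size_t)b * L + lo, &BL, &one,
                      dW.begin() + (size_t)k * Cin, &ldw
                      FCONE FCONE);
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW);
}

// Zero-insertion upsampling (transpose-convolution stride) and its adjoint.
// [[Rcpp::export(rng = false)]]
NumericMatrix stuff_rows(const NumericMatrix& x, int B, int L, int s) {
  const int C = x.ncol();
  const int Lo = s * L;
  NumericMatrix out((size_t)B * Lo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * B * L;
    double* oc = out.begin() + (size_t)c * B * Lo;
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < L; ++t) {
        oc[(size_t)b * Lo + (size_t)t * s] = xc[(size_t)b * L + t];
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix unstuff_rows(const NumericMatrix& y, int B, int L, int s) {
  const int C = y.ncol();
  const int Lo = s * L;
  NumericMatrix out((size_t)B * L, C);
  for (int c = 0; c < C; ++c) {
    const double* yc = y.begin() + (size_t)c * B * Lo;
    double* oc = out.begin() + (size_t)c * B * L;
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < L; ++t) {
        oc[(size_t)b * L + t] = yc[(size_t)b * Lo + (size_t)t * s];
      }
    }
  }
  return out;
}
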