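#ifndef CARDIOPOINT_TINYMAT_H
#define CARDIOPOINT_TINYMAT_H

#include <vector>
#include <cstring>
#include <cmath>
#include <R_ext/BLAS.h>

// Minimal column-major dense matrix used by the network kernels; the three
// multiply flavours delegate to the host BLAS dgemm (deterministic for a
// fixed thread count), everything else is scalar C++.
struct TMat {
  int nr = 0, nc = 0;
  std::vector<double> d;
  TMat() = default;
  TMat(int r, int c) : nr(r), nc(c), d((size_t)r * c, 0.0) {}
  inline double* col(int j) { return d.data() + (size_t)j * nr; }
  inline const double* col(int j) const { return d.data() + (size_t)j * nr; }
  inline double& at(int i, int j) { return d[(size_t)j * nr + i]; }
  inline double at(int i, int j) const { return d[(size_t)j * nr + i]; }
  void zero() { std::memset(d.data(), 0, d.size() * sizeof(double)); }
  void resize(int r, int c) { nr = r; nc = c; d.assign((size_t)r * c, 0.0); }
};

inline void blas_gemm(const char* ta, const char* tb, int m, int n, int k,
                      const double* A, int lda, const double* B, int ldb,
                      double beta, double* C, int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc
                  FCONE FCONE);
}

// C (+)= A %*% B ; A: n x k, B: k x m
inline void gemm_nn(const TMat& A, const TMat& B, TMat& C, bool accumulate = false) {
  blas_gemm("N", "N", A.nr, B.nc, A.nc, A.d.data(), A.nr, B.d.data(), B.nr,
            accumulate ? 1.0 : 0.0, C.d.data(), C.nr);
}

// C (+)= A %*% t(B) ; A: n x k, B: m x k
inline void gemm_nt(const TMat& A, const TMat& B, TMat& C, bool accumulate = false) {
  blas_gemm("N", "T", A.nr, B.nr, A.nc, A.d.data(), A.nr, B.d.data(), B.nr,
            accumulate ? 1.0 : 0.0, C.d.data(), C.nr);
}

// C (+)= t(A) %*% B ; A: k x n, B: k x m
inline void gemm_tn(const TMat& A, const TMat& B, TMat& C, bool accumulate = false) {
  blas_gemm("T", "N", A.nc, B.nc, A.nr, A.d.data(), A.nr, B.d.data(), B.nr,
            accumulate ? 1.0 : 0.0, C.d.data(), C.nr);
}

inline void add_bias(TMat& A, const std::vector<double>& b) {
  for (int j = 0; j < A.nc; ++j) {
    double* aj = A.col(j);
    const double bv = b[j];
    for (int i = 0; i < A.nr; ++i) aj[i] += bv;
  }
}

inline void relu_(TMat& A) {
  for (auto& v : A.d) if (v < 0.0) v = 0.0;
}

// dX masked by activation output (post-ReLU values in Y): dX = dY * (Y > 0)
inline void relu_bwd(const TMat& Y, TMat& dY) {
  const size_t n = Y.d.size();
  for (size_t i = 0; i < n; ++i) if (Y.d[i] <= 0.0) dY.d[i] = 0.0;
}

#endif
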