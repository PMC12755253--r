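// Gather/scatter helpers for zero-padded 3x3 convolutions.
//
// srcs/dsts hold, per kernel offset k, the 1-based in-bounds source and
// destination columns of the shifted feature matrix (precomputed once per
// grid geometry).

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".im2colCpp")]]
NumericMatrix im2colCpp(NumericMatrix X, List srcs, List dsts) {
  const int C = X.nrow();
  const R_xlen_t T = X.ncol();
  NumericMatrix cols(9 * C, T);
  const double* xp = REAL(X);
  double* cp = REAL(cols);
  const R_xlen_t CR = 9 * static_cast<R_xlen_t>(C);
  for (int k = 0; k < 9; ++k) {
    IntegerVector src = srcs[k], dst = dsts[k];
    const int* sp = INTEGER(src);
    const int* dp = INTEGER(dst);
    const R_xlen_t n = src.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double* xc = xp + static_cast<R_xlen_t>(C) * (sp[i] - 1);
      double* cc = cp + CR * (dp[i] - 1) + static_cast<R_xlen_t>(k) * C;
      std::memcpy(cc, xc, sizeof(double) * C);
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".col2imCpp")]]
NumericMatrix col2imCpp(NumericMatrix dcols, List srcs, List dsts, int C) {
  const R_xlen_t T = dcols.ncol();
  NumericMatrix dX(C, T);
  const double* cp = REAL(dcols);
  double* xp = REAL(dX);
  const R_xlen_t CR = dcols.nrow();
  for (int k = 0; k < 9; ++k) {
    IntegerVector src = srcs[k], dst = dsts[k];
    const int* sp = INTEGER(src);
    const int* dp = INTEGER(dst);
    const R_xlen_t n = src.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double* cc = cp + CR * (dp[i] - 1) + static_cast<R_xlen_t>(k) * C;
      double* xc = xp + static_cast<R_xlen_t>(C) * (sp[i] - 1);
      for (int c = 0; c < C; ++c) xc[c] += cc[c];
    }
  }
  return dX;
}

// [[Rcpp::export(name = ".dwConvForwardCpp")]]
NumericMatrix dwConvForwardCpp(NumericMatrix X, NumericMatrix K,
                               NumericVector b, List srcs, List dsts) {
  const int C = X.nrow();
  const R_xlen_t T = X.ncol();
  if (K.nrow() != C || K.ncol() != 9 || b.size() != C)
    stop("depthwise conv: kernel shape mismatch");
  NumericMatrix Y(C, T);
  const double* xp = REAL(X);
  const double* kp = REAL(K);
  const double* bp = REAL(b);
  double* yp = REAL(Y);
  for (R_xlen_t t = 0; t < T; ++t) {
    double* yt = yp + static_cast<R_xlen_t>(C) * t;
    for (int c = 0; c < C; ++c) yt[c] = bp[c];
  }
  for (int k = 0; k < 9; ++k) {
    IntegerVector src = srcs[k], dst = dsts[k];
    const int* sp = INTEGER(src);
    const int* dp = INTEGER(dst);
    const R_xlen_t n = src.size();
    const double* kk = kp + static_cast<R_xlen_t>(C) * k;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double* xc = xp + static_cast<R_xlen_t>(C) * (sp[i] - 1);
      double* yc = yp + static_cast<R_xlen_t>(C) * (dp[i] - 1);
      for (int c = 0; c < C; ++c) yc[c] += kk[c] * xc[c];
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".dwConvBackwardCpp")]]
List dwConvBackwardCpp(NumericMatrix dY, NumericMatrix X, NumericMatrix K,
                       List srcs, List dsts) {
  const int C = X.nrow();
  const R_xlen_t T = X.ncol();
  NumericMatrix dX(C, T), dK(C, 9);
  NumericVector db(C);
  const double* dyp = REAL(dY);
  const double* xp = REAL(X);
  const double* kp = REAL(K);
  double* dxp = REAL(dX);
  double* dkp = REAL(dK);
  double* dbp = REAL(db);
  for (R_xlen_t t = 0; t < T; ++t) {
    const double* dyt = dyp + static_cast<R_xlen_t>(C) * t;
    for (int c = 0; c < C; ++c) dbp[c] += dyt[c];
  }
  for (int k = 0; k < 9; ++k) {
    IntegerVector src = srcs[k], dst = dsts[k];
    const int* sp = INTEGER(src);
    const int* dp = INTEGER(dst);
    const R_xlen_t n = src.size();
    const double* kk = kp + static_cast<R_xlen_t>(C) * k;
    double* dkk = dkp + static_cast<R_xlen_t>(C) * k;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double* xc = xp + static_cast<R_xlen_t>(C) * (sp[i] - 1);
      const double* dyc = dyp + static_cast<R_xlen_t>(C) * (dp[i] - 1);
      double* dxc = dxp + static_cast<R_xlen_t>(C) * (sp[i] - 1);
      for (int c = 0; c < C; ++c) {
        dkk[c] += dyc[c] * xc[c];
        dxc[c] += kk[c] * dyc[c];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK, _["db"] = db);
}
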