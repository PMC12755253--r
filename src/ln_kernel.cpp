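// Layer normalization over channels (rows), one token per column.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".lnForwardCpp")]]
List lnForwardCpp(NumericMatrix X, NumericVector g, NumericVector b,
                  double eps) {
  const int C = X.nrow();
  const R_xlen_t T = X.ncol();
  if (g.size() != C || b.size() != C) stop("layer norm: affine size mismatch");
  NumericMatrix y(C, T), xhat(C, T);
  NumericVector invstd(T);
  const double* xp = REAL(X);
  const double* gp = REAL(g);
  const double* bp = REAL(b);
  double* yp = REAL(y);
  double* hp = REAL(xhat);
  double* ip = REAL(invstd);
  for (R_xlen_t t = 0; t < T; ++t) {
    const double* xt = xp + C * t;
    double* yt = yp + C * t;
    double* ht = hp + C * t;
    double mu = 0.0;
    for (int c = 0; c < C; ++c) mu += xt[c];
    mu /= C;
    double v = 0.0;
    for (int c = 0; c < C; ++c) {
      const double d = xt[c] - mu;
      v += d * d;
    }
    const double is = 1.0 / std::sqrt(v / C + eps);
    ip[t] = is;
    for (int c = 0; c < C; ++c) {
      ht[c] = (xt[c] - mu) * is;
      yt[c] = gp[c] * ht[c] + bp[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".lnBackwardCpp")]]
List lnBackwardCpp(NumericMatrix dY, NumericMatrix xhat, NumericVector invstd,
                   NumericVector g) {
  const int C = dY.nrow();
  const R_xlen_t T = dY.ncol();
  NumericMatrix dX(C, T);
  NumericVector dg(C), db(C);
  const double* dyp = REAL(dY);
  const double* hp = REAL(xhat);
  const double* ip = REAL(invstd);
  const double* gp = REAL(g);
  double* dxp = REAL(dX);
  double* dgp = REAL(dg);
  double* dbp = REAL(db);
  for (R_xlen_t t = 0; t < T; ++t) {
    const double* dyt = dyp + C * t;
    const double* ht = hp + C * t;
    double* dxt = dxp + C * t;
    double m1 = 0.0, m2 = 0.0;
    for (int c = 0; c < C; ++c) {
      const double dxh = dyt[c] * gp[c];
      m1 += dxh;
      m2 += dxh * ht[c];
      dgp[c] += dyt[c] * ht[c];
      dbp[c] += dyt[c];
    }
    m1 /= C;
    m2 /= C;
    const double is = ip[t];
    for (int c = 0; c < C; ++c)
      dxt[c] = (dyt[c] * gp[c] - m1 - ht[c] * m2) * is;
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}
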