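// Selective state-space scan over 2D token grids.
//
// Diagonal continuous-time system per head, zero-order-hold discretized:
//   abar = exp(delta * A),  phi = (exp(delta * A) - 1) / A
//   h_t  = abar_t * h_{t-1} + phi_t * B_t * u_t
//   y_t  = C_t . h_t + D * u_t
// with A = diag(-exp(a_raw)) < 0 so |abar| < 1 for delta > 0.
//
// The traversal order is passed as a vector of 1-based token columns; the
// kernel gathers inputs and scatters outputs through it, so callers keep
// features in grid order and no explicit serialization is needed. Inputs
// may be batched (order columns stacked per image, independent state).
//
// A 2-term Taylor expansion of phi is used when |delta * A| < 1e-6 to avoid
// catastrophic cancellation; the backward pass differentiates the same
// branch so gradients stay consistent with the forward computation.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const double PHI_TAYLOR_THRESH = 1e-6;

// [[Rcpp::export(name = ".scanForwardCpp")]]
List scanForwardCpp(NumericMatrix u, NumericVector delta, NumericVector A,
                    NumericMatrix Bsel, NumericMatrix Csel, NumericVector Dvec,
                    IntegerVector order, int batch, bool keepState) {
  const int Ch = u.nrow();
  const R_xlen_t T = u.ncol();           // batch * L
  const int N = A.size();
  if (delta.size() != T || Bsel.ncol() != T || Csel.ncol() != T ||
      Bsel.nrow() != N || Csel.nrow() != N || Dvec.size() != Ch ||
      order.size() != T || T % batch != 0)
    stop("selective scan: inconsistent input shapes");
  const R_xlen_t L = T / batch;

  NumericMatrix y(no_init_matrix(Ch, T));
  NumericMatrix abar(no_init_matrix(N, T)), phi(no_init_matrix(N, T));
  NumericVector hstore;
  if (keepState)
    hstore = NumericVector(no_init(static_cast<R_xlen_t>(N) * Ch * T));
  double* hs = keepState ? REAL(hstore) : nullptr;
  const double* up = REAL(u);
  const double* dp = REAL(delta);
  const double* Ap = REAL(A);
  const double* Bp = REAL(Bsel);
  const double* Cp = REAL(Csel);
  const double* Dp = REAL(Dvec);
  const int* op = INTEGER(order);
  double* yp = REAL(y);
  double* abp = REAL(abar);
  double* php = REAL(phi);
  std::vector<double> h(static_cast<size_t>(N) * Ch);
  std::vector<double> s(N);

  for (int b = 0; b < batch; ++b) {
    std::fill(h.begin(), h.end(), 0.0);
    for (R_xlen_t p = b * L; p < (b + 1) * L; ++p) {
      const R_xlen_t t = op[p] - 1;       // token column in grid order
      const double dt = dp[t];
      double* abt = abp + static_cast<R_xlen_t>(N) * p;  // by position
      double* pht = php + static_cast<R_xlen_t>(N) * p;
      const double* Bt = Bp + static_cast<R_xlen_t>(N) * t;
      const double* Ct = Cp + static_cast<R_xlen_t>(N) * t;
      for (int n = 0; n < N; ++n) {
        const double x = dt * Ap[n];
        const double a = std::exp(x);
        abt[n] = a;
        pht[n] = (std::fabs(x) < PHI_TAYLOR_THRESH)
                     ? dt * (1.0 + 0.5 * x)
                     : (a - 1.0) / Ap[n];
        s[n] = pht[n] * Bt[n];
      }
      const double* ut = up + static_cast<R_xlen_t>(Ch) * t;
      double* yt = yp + static_cast<R_xlen_t>(Ch) * t;
      for (int c = 0; c < Ch; ++c) {
        double* hc = h.data() + static_cast<size_t>(c) * N;
        const double uc = ut[c];
        double acc = 0.0;
        for (int n = 0; n < N; ++n) {
          hc[n] = abt[n] * hc[n] + s[n] * uc;
          acc += Ct[n] * hc[n];
        }
        yt[c] = acc + Dp[c] * uc;
      }
      if (keepState)
        std::memcpy(hs + static_cast<R_xlen_t>(N) * Ch * p, h.data(),
                    sizeof(double) * N * Ch);
    }
  }
  if (keepState)
    return List::create(_["y"] = y, _["h"] = hstore,
                        _["abar"] = abar, _["phi"] = phi);
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".scanBackwardCpp")]]
List scanBackwardCpp(NumericMatrix g, NumericMatrix u, NumericVector delta,
                     NumericVector A, NumericMatrix Bsel, NumericMatrix Csel,
                     NumericVector Dvec, NumericVector hstore,
                     NumericMatrix abar, NumericMatrix phi,
                     IntegerVector order, int batch) {
  const int Ch = u.nrow();
  const R_xlen_t T = u.ncol();
  const int N = A.size();
  const R_xlen_t L = T / batch;

  NumericMatrix du(no_init_matrix(Ch, T));
  NumericMatrix dB(no_init_matrix(N, T)), dC(no_init_matrix(N, T));
  NumericVector ddelta(no_init(T)), dA(N), dD(Ch);
  const double* gp = REAL(g);
  const double* up = REAL(u);
  const double* dp = REAL(delta);
  const double* Ap = REAL(A);
  const double* Bp = REAL(Bsel);
  const double* Cp = REAL(Csel);
  const double* Dp = REAL(Dvec);
  const double* hs = REAL(hstore);
  const double* abp = REAL(abar);
  const double* php = REAL(phi);
  const int* op = INTEGER(order);
  double* dup = REAL(du);
  double* dBp = REAL(dB);
  double* dCp = REAL(dC);
  double* ddp = REAL(ddelta);
  double* dAp = REAL(dA);
  double* dDp = REAL(dD);
  std::vector<double> lam(static_cast<size_t>(N) * Ch);  // dL/dh at position
  std::vector<double> dal(N), dph(N), sB(N);

  for (int b = 0; b < batch; ++b) {
    std::fill(lam.begin(), lam.end(), 0.0);
    for (R_xlen_t p = (b + 1) * L - 1; p >= b * L; --p) {
      const R_xlen_t t = op[p] - 1;
      const double dt = dp[t];
      const double* abt = abp + static_cast<R_xlen_t>(N) * p;
      const double* pht = php + static_cast<R_xlen_t>(N) * p;
      const double* Bt = Bp + static_cast<R_xlen_t>(N) * t;
      const double* Ct = Cp + static_cast<R_xlen_t>(N) * t;
      const double* gt = gp + static_cast<R_xlen_t>(Ch) * t;
      const double* ut = up + static_cast<R_xlen_t>(Ch) * t;
      const double* ht = hs + static_cast<R_xlen_t>(N) * Ch * p;
      const double* hprev =
          (p > b * L) ? hs + static_cast<R_xlen_t>(N) * Ch * (p - 1) : nullptr;
      double* dut = dup + static_cast<R_xlen_t>(Ch) * t;
      double* dBt = dBp + static_cast<R_xlen_t>(N) * t;
      double* dCt = dCp + static_cast<R_xlen_t>(N) * t;
      std::fill(dal.begin(), dal.end(), 0.0);
      std::fill(dph.begin(), dph.end(), 0.0);
      for (int n = 0; n < N; ++n) {
        sB[n] = pht[n] * Bt[n];
        dBt[n] = 0.0;
        dCt[n] = 0.0;
      }
      for (int c = 0; c < Ch; ++c) {
        const double gc = gt[c];
        const double uc = ut[c];
        dDp[c] += gc * uc;
        double duc = gc * Dp[c];
        double* lc = lam.data() + static_cast<size_t>(c) * N;
        const double* hc = ht + static_cast<size_t>(c) * N;
        const double* hp = hprev ? hprev + static_cast<size_t>(c) * N
                                 : nullptr;
        for (int n = 0; n < N; ++n) {
          const double l = gc * Ct[n] + lc[n];  // dL/dh at this position
          dCt[n] += gc * hc[n];
          dal[n] += hp ? l * hp[n] : 0.0;       // dL/dabar
          duc += l * sB[n];
          dBt[n] += l * pht[n] * uc;
          dph[n] += l * Bt[n] * uc;             // dL/dphi
          lc[n] = l * abt[n];                   // propagate back one step
        }
        dut[c] = duc;
      }
      double ddt = 0.0;
      for (int n = 0; n < N; ++n) {
        const double x = dt * Ap[n];
        if (std::fabs(x) < PHI_TAYLOR_THRESH) {
          // phi = dt * (1 + x/2): dphi/ddt = 1 + x, dphi/dA = dt^2 / 2
          ddt += dal[n] * Ap[n] * abt[n] + dph[n] * (1.0 + x);
          dAp[n] += dal[n] * dt * abt[n] + dph[n] * 0.5 * dt * dt;
        } else {
          ddt += (dal[n] * Ap[n] + dph[n]) * abt[n];
          dAp[n] += dal[n] * dt * abt[n] +
                    dph[n] * (dt * abt[n] * Ap[n] - (abt[n] - 1.0)) /
                        (Ap[n] * Ap[n]);
        }
      }
      ddp[t] = ddt;
    }
  }
  return List::create(_["du"] = du, _["ddelta"] = ddelta, _["dA"] = dA,
                      _["dB"] = dB, _["dC"] = dC, _["dD"] = dD);
}
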