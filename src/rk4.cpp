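#include <Rcpp.h>
using namespace Rcpp;

// Hill activation term x^n / (1 + x^n), with x clamped at 0 so fractional
// exponents never see a negative base from RK4 trial states.
static inline double hill_term(double x, double n) {
  if (x <= 0.0) return 0.0;
  double xn;
  if (n == 2.0) xn = x * x;
  else if (n == 1.0) xn = x;
  else xn = std::pow(x, n);
  return xn / (1.0 + xn);
}

static inline double fdrift(double x, double c, double r, double n, bool hill) {
  double xs = x < 0.0 ? 0.0 : x;
  double v = c - r * xs;
  if (hill) v += hill_term(xs, n);
  return v;
}

// 4-point (Catmull-Rom style) midpoint interpolation between samples k and
// k+1; falls back to the linear average at the grid ends. Keeps the
// half-step forcing accurate to O(dt^4) so RK4 retains its order for
// smooth drives.
static inline double mid_interp(const NumericVector& v, R_xlen_t k) {
  R_xlen_t N = v.size();
  if (k == 0 || k + 2 >= N)
    return 0.5 * (v[k] + v[k + 1]);
  return (-v[k - 1] + 9.0 * v[k] + 9.0 * v[k + 1] - v[k + 2]) / 16.0;
}

// Classical RK4 on T dx/dt = c_tot(t) - r(t) x + x^n/(1+x^n).
//
// cvec and rvec live on the uniform time grid (length N); within a step the
// forcing is interpolated at the half-step (cubic, linear at the ends)
// while the noise sample eta[k] is held constant (stochastic-Euler
// splitting). c_tot = c + eta is floored at 0 before entering the drift,
// and the state is floored at 0 after each step.
// [[Rcpp::export]]
NumericVector rk4_core(NumericVector cvec, NumericVector eta, NumericVector rvec,
                       double n, double T, double dt, double x0, bool hill) {
  R_xlen_t N = cvec.size();
  if (rvec.size() != N) stop("r schedule must match the time grid");
  bool has_eta = eta.size() > 0;
  if (has_eta && eta.size() != N) stop("noise path must match the time grid");
  NumericVector x(N);
  if (N == 0) return x;
  x[0] = x0 < 0.0 ? 0.0 : x0;
  const double invT = 1.0 / T;
  for (R_xlen_t k = 0; k + 1 < N; ++k) {
    double e = has_eta ? eta[k] : 0.0;
    double ca = cvec[k] + e;
    double cb = mid_interp(cvec, k) + e;
    double cc = cvec[k + 1] + e;
    if (ca < 0.0) ca = 0.0;
    if (cb < 0.0) cb = 0.0;
    if (cc < 0.0) cc = 0.0;
    double ra = rvec[k];
    double rb = mid_interp(rvec, k);
    double rc = rvec[k + 1];
    double xk = x[k];
    double k1 = fdrift(xk, ca, ra, n, hill) * invT;
    double k2 = fdrift(xk + 0.5 * dt * k1, cb, rb, n, hill) * invT;
    double k3 = fdrift(xk + 0.5 * dt * k2, cb, rb, n, hill) * invT;
    double k4 = fdrift(xk + dt * k3, cc, rc, n, hill) * invT;
    double xn = xk + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    x[k + 1] = xn < 0.0 ? 0.0 : xn;
  }
  return x;
}
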