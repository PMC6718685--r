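#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Piecewise-linear activation: -1 / gain*x / +1 with threshold 1/gain.
static inline double act(double x, double gain) {
  const double th = 1.0 / gain;
  if (x < -th) return -1.0;
  if (x >  th) return  1.0;
  return gain * x;
}

// One deterministic step of the full map F(z) + K u(z).
static inline double map_step(double z, double a, double b, double k,
                              double K, double zd, double sigma) {
  double F = act(z, a) - k * act(z, b);
  if (K != 0.0) {
    const double dz = z - zd;
    F += K * (-dz * std::exp(-dz * dz / (2.0 * sigma * sigma)));
  }
  return F;
}

// Iterate z(t+1) = F(z(t)) + K u(z(t)) + S(t) + D xi(t) and return the T
// states retained after the transient.  The drive phase uses the absolute
// iteration index starting at t = 0, so the retained window is
// t = transient .. transient + T - 1.  Gaussian noise comes from R's RNG
// (seed it with set.seed() before calling).
// [[Rcpp::export]]
NumericVector sim_core(double z0, int T, int transient,
                       double a, double b, double k,
                       double K, double zd, double sigma,
                       double A, double Omega, double D) {
  NumericVector out(T);
  const double twopi = 2.0 * M_PI;
  double z = z0;
  const int N = T + transient;
  for (int t = 0; t < N; ++t) {
    if (t >= transient) out[t - transient] = z;
    const double S  = (A != 0.0) ? A * std::sin(twopi * Omega * (double)t) : 0.0;
    const double xi = (D != 0.0) ? norm_rand() : 0.0;
    z = map_step(z, a, b, k, K, zd, sigma) + S + D * xi;
    if (!std::isfinite(z)) stop("non-finite state at iteration %d", t);
  }
  return out;
}

// Lyapunov exponent by repeated perturbation along one orbit: at M restart
// points spaced tau apart, clone the state, offset it by d0, evolve both
// copies tau steps under the identical drive and noise realization, and
// average ln(d(tau)/d0)/tau.  A separation that collapses to exactly zero
// (possible on the saturated flat branches, where the local slope is zero)
// is floored at d0 * machine-epsilon; the number of floored terms is
// returned so callers can warn.
// [[Rcpp::export]]
List lyap_core(double z0, int transient, int M, int tau, double d0,
               double a, double b, double k,
               double K, double zd, double sigma,
               double A, double Omega, double D) {
  const double twopi = 2.0 * M_PI;
  double z = z0;
  long t_abs = 0;
  for (int t = 0; t < transient; ++t) {
    const double S  = (A != 0.0) ? A * std::sin(twopi * Omega * (double)t_abs) : 0.0;
    const double xi = (D != 0.0) ? norm_rand() : 0.0;
    z = map_step(z, a, b, k, K, zd, sigma) + S + D * xi;
    ++t_abs;
  }
  const double floor_d = d0 * std::numeric_limits<double>::epsilon();
  double sum = 0.0;
  int n_floored = 0;
  for (int m = 0; m < M; ++m) {
    double zp = z + d0;
    for (int s = 0; s < tau; ++s) {
      const double S  = (A != 0.0) ? A * std::sin(twopi * Omega * (double)t_abs) : 0.0;
      const double xi = (D != 0.0) ? norm_rand() : 0.0;
      z  = map_step(z,  a, b, k, K, zd, sigma) + S + D * xi;
      zp = map_step(zp, a, b, k, K, zd, sigma) + S + D * xi;
      ++t_abs;
    }
    double d = std::fabs(z - zp);
    if (d < floor_d) { d = floor_d; ++n_floored; }
    sum += std::log(d / d0);
  }
  return List::create(_["lambda"] = sum / ((double)tau * (double)M),
                      _["n_floored"] = n_floored);
}

// Normalized delayed cross-correlation C(tau) = C_SZ(tau)/sqrt(C_SS*C_ZZ).
// Means and variances are taken over the full series; the lagged product is
// averaged over the overlapping window t = 0 .. n - tau - 1.
// [[Rcpp::export]]
NumericVector ccf_core(NumericVector S, NumericVector Z, IntegerVector tau) {
  const int n = S.size();
  double mS = 0.0, mZ = 0.0;
  for (int i = 0; i < n; ++i) { mS += S[i]; mZ += Z[i]; }
  mS /= n; mZ /= n;
  double vS = 0.0, vZ = 0.0;
  for (int i = 0; i < n; ++i) {
    vS += (S[i] - mS) * (S[i] - mS);
    vZ += (Z[i] - mZ) * (Z[i] - mZ);
  }
  vS /= n; vZ /= n;
  const double denom = std::sqrt(vS * vZ);
  std::vector<double> Sc(n), Zc(n);
  for (int i = 0; i < n; ++i) { Sc[i] = S[i] - mS; Zc[i] = Z[i] - mZ; }
  const int m = tau.size();
  NumericVector C(m);
  for (int j = 0; j < m; ++j) {
    const int tj = tau[j];
    if (tj < 0 || tj >= n) stop("delay out of range");
    const int cnt = n - tj;
    const double *a = Sc.data() + tj, *b = Zc.data();
    double s = 0.0;
    for (int i = 0; i < cnt; ++i) s += a[i] * b[i];
    C[j] = (s / cnt) / denom;
  }
  return C;
}
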