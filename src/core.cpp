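#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Delay-coupled two-population neural-mass network, fixed-step Euler with a
// full stored EPSP history acting as the delay buffer.  Delay history before
// t = 0 is the (held) initial state.  Noise is a bounded uniform forcing on
// the current derivatives, redrawn each step from R's RNG so that runs are
// reproducible under set.seed().
//
// State per region: y_e, y_i (PSPs), z_e, z_i (currents).
//   y'  = z
//   z_e' = A a R^2 sigma_e((C/N) sum_m C_nm y_e,m(t - tau_nm) - Cei y_i)
//          - 2 a R z_e - a^2 R^2 y_e + eta_e
//   z_i' = B b R^2 sigma_i(Cie y_e) - 2 b R z_i - b^2 R^2 y_i + eta_i
// [[Rcpp::export(name = ".nm_simulate_cpp")]]
List nm_simulate_cpp(NumericMatrix cnm, IntegerMatrix delaySteps,
                     double C, bool scaleByN,
                     double Fe, double Fi, double a, double b,
                     double A, double B, double r, double v0,
                     double Cie, double Cei, double Rsc,
                     double noiseAmp, double dt,
                     int nSteps, int nTransient, bool keepYi) {
  const int N = cnm.nrow();
  const int T = nSteps + nTransient;           // integration steps
  if (N < 2) stop("need at least 2 regions");
  if (nSteps < 1) stop("nSteps must be >= 1");

  // adjacency lists: incoming edges per target region
  std::vector<std::vector<int> >    src(N);
  std::vector<std::vector<double> > wgt(N);
  std::vector<std::vector<int> >    del(N);
  for (int n = 0; n < N; ++n)
    for (int m = 0; m < N; ++m)
      if (m != n && cnm(n, m) != 0.0) {
        src[n].push_back(m);
        wgt[n].push_back(cnm(n, m));
        del[n].push_back(delaySteps(n, m));
      }

  const double aR = a * Rsc, bR = b * Rsc;
  const double aR2 = aR * aR, bR2 = bR * bR;
  const double gainE = A * a * Rsc * Rsc, gainI = B * b * Rsc * Rsc;
  const double cScale = scaleByN ? C / (double)N : C;

  // full EPSP history (t = 0 .. T); column t holds state at time t*dt
  NumericMatrix yeHist(N, T + 1);
  NumericMatrix yiOut(keepYi ? N : 1, keepYi ? (nSteps + 1) : 1);
  std::vector<double> ye(N, 0.0), yi(N, 0.0), ze(N, 0.0), zi(N, 0.0);
  std::vector<double> yeNew(N), yiNew(N);

  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    for (int n = 0; n < N; ++n) {
      double cpl = 0.0;
      const int nedge = (int)src[n].size();
      for (int e = 0; e < nedge; ++e) {
        int tlag = t - del[n][e];
        double yDel = (tlag >= 0) ? yeHist(src[n][e], tlag) : 0.0;
        cpl += wgt[n][e] * yDel;
      }
      double ve = cScale * cpl - Cei * yi[n];
      double vi = Cie * ye[n];
      double Pe = gainE * Fe / (1.0 + std::exp(r * (v0 - ve)));
      double Pi = gainI * Fi / (1.0 + std::exp(r * (v0 - vi)));
      double etaE = 0.0, etaI = 0.0;
      if (noiseAmp > 0.0) {
        etaE = noiseAmp * (2.0 * unif_rand() - 1.0);
        etaI = noiseAmp * (2.0 * unif_rand() - 1.0);
      }
      double dze = Pe - 2.0 * aR * ze[n] - aR2 * ye[n] + etaE;
      double dzi = Pi - 2.0 * bR * zi[n] - bR2 * yi[n] + etaI;
      yeNew[n] = ye[n] + dt * ze[n];
      yiNew[n] = yi[n] + dt * zi[n];
      ze[n] += dt * dze;
      zi[n] += dt * dzi;
    }
    for (int n = 0; n < N; ++n) {
      ye[n] = yeNew[n];
      yi[n] = yiNew[n];
      if (!R_finite(ye[n]) || !R_finite(yi[n]))
        stop("non-finite state at t = %.3f s (region %d)", (t + 1) * dt, n + 1);
      yeHist(n, t + 1) = ye[n];
      if (keepYi && t + 1 >= nTransient)
        yiOut(n, t + 1 - nTransient) = yi[n];
    }
    if ((t & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  // post-transient EPSP: columns nTransient .. T of the history
  NumericMatrix yeOut(N, nSteps + 1);
  for (int t = 0; t <= nSteps; ++t)
    for (int n = 0; n < N; ++n)
      yeOut(n, t) = yeHist(n, nTransient + t);

  if (keepYi) return List::create(_["ye"] = yeOut, _["yi"] = yiOut);
  return List::create(_["ye"] = yeOut);
}

// Balloon-Windkessel hemodynamics, RK4 at the neural time step with linear
// interpolation of the input inside each step.
//   s' = x - kappa s - gamma (f - 1)
//   f' = s
//   tMTT v' = f - v^(1/alpha)
//   tMTT q' = f (1 - (1 - E0)^(1/f)) / E0 - v^(1/alpha) q / v
// BOLD observation: V0 (k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)).
struct BWP {
  double kappa, gamma, tMTT, E0, ialpha, k1, k2, k3, V0;
};

static inline void bw_deriv(double x, const double *st, double *d, const BWP &p) {
  double s = st[0], f = st[1], v = st[2], q = st[3];
  double via = std::pow(v, p.ialpha);
  d[0] = x - p.kappa * s - p.gamma * (f - 1.0);
  d[1] = s;
  d[2] = (f - via) / p.tMTT;
  d[3] = (f * (1.0 - std::pow(1.0 - p.E0, 1.0 / f)) / p.E0 - via * q / v) / p.tMTT;
}

// x: regions x (nSteps+1) input at dt; returns BOLD sampled at times k*tr
// (nearest integration step, no cumulative drift) and optionally the full
// state trajectories for diagnostics.
// [[Rcpp::export(name = ".bw_integrate_cpp")]]
List bw_integrate_cpp(NumericMatrix x, double dt,
                      double TE, double tMTT, double E0, double V0,
                      double theta0, double epsilon, double r0, double alpha,
                      double kappa, double gamma,
                      double tr, bool returnStates) {
  const int N = x.nrow();
  const int T = x.ncol() - 1;                   // number of integration steps
  if (T < 1) stop("input too short");
  if (tr < dt) stop("tr must be >= dt");
  for (int i = 0; i < N * (T + 1); ++i)
    if (!R_finite(x[i])) stop("non-finite neural input");

  BWP p;
  p.kappa = kappa; p.gamma = gamma; p.tMTT = tMTT; p.E0 = E0;
  p.ialpha = 1.0 / alpha; p.V0 = V0;
  p.k1 = 4.3 * theta0 * E0 * TE;
  p.k2 = epsilon * r0 * E0 * TE;
  p.k3 = 1.0 - epsilon;

  const int nOut = (int)std::floor(T * dt / tr + 1e-9);
  std::vector<int> outStep(nOut);
  for (int k = 0; k < nOut; ++k)
    outStep[k] = (int)std::floor((k + 1) * tr / dt + 0.5);
  NumericMatrix bold(N, nOut);
  NumericMatrix states;
  if (returnStates) states = NumericMatrix(4 * N, T + 1);

  for (int n = 0; n < N; ++n) {
    double st[4] = {0.0, 1.0, 1.0, 1.0};
    if (returnStates)
      for (int k = 0; k < 4; ++k) states(4 * n + k, 0) = st[k];
    int outIdx = 0;
    for (int t = 0; t < T; ++t) {
      double x0 = x(n, t), x1 = x(n, t + 1), xm = 0.5 * (x0 + x1);
      double k1d[4], k2d[4], k3d[4], k4d[4], tmp[4];
      bw_deriv(x0, st, k1d, p);
      for (int k = 0; k < 4; ++k) tmp[k] = st[k] + 0.5 * dt * k1d[k];
      bw_deriv(xm, tmp, k2d, p);
      for (int k = 0; k < 4; ++k) tmp[k] = st[k] + 0.5 * dt * k2d[k];
      bw_deriv(xm, tmp, k3d, p);
      for (int k = 0; k < 4; ++k) tmp[k] = st[k] + dt * k3d[k];
      bw_deriv(x1, tmp, k4d, p);
      for (int k = 0; k < 4; ++k)
        st[k] += dt / 6.0 * (k1d[k] + 2.0 * k2d[k] + 2.0 * k3d[k] + k4d[k]);
      if (st[2] <= 0.0 || st[3] <= 0.0 || !R_finite(st[2]) || !R_finite(st[3]))
        stop("balloon state non-positive at t = %.3f s (region %d)",
             (t + 1) * dt, n + 1);
      if (returnStates)
        for (int k = 0; k < 4; ++k) states(4 * n + k, t + 1) = st[k];
      if (outIdx < nOut && t + 1 == outStep[outIdx]) {
        double v = st[2], q = st[3];
        bold(n, outIdx++) =
          p.V0 * (p.k1 * (1.0 - q) + p.k2 * (1.0 - q / v) + p.k3 * (1.0 - v));
      }
    }
    Rcpp::checkUserInterrupt();
  }

  if (returnStates) return List::create(_["bold"] = bold, _["states"] = states);
  return List::create(_["bold"] = bold);
}
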