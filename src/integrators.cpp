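#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Square-wave block input: -c * (2*floor(f*t) - floor(2*f*t)), f = 1/T.
// Equals 0 on [0, T/2) and c on [T/2, T), repeating with period T.
static inline double square_wave(double t, double c, double period) {
  double ft = t / period;
  return -c * (2.0 * std::floor(ft) - std::floor(2.0 * ft));
}

// Derivative of the coupled FitzHugh-Nagumo network.
//   eps * du_k/dt = u_k - u_k^3/3 - w_k + I0 - sigma * sum_l g_kl u_l + I_k(t)
//        dw_k/dt = u_k + a - b w_k
// Coupling and external input act on the activator component only.
static void fhn_deriv(const std::vector<double>& u, const std::vector<double>& w,
                      double t, const double* G, int N,
                      double a, double b, double inv_eps, double sigma, double I0,
                      double c, double period, const std::vector<char>& is_target,
                      bool input_on,
                      std::vector<double>& du, std::vector<double>& dw) {
  std::fill(du.begin(), du.end(), 0.0);
  // coupling: du accumulates sum_l g_kl * u_l (column-major walk)
  double* __restrict__ acc = du.data();
  for (int l = 0; l < N; ++l) {
    const double ul = u[l];
    const double* __restrict__ col = G + (size_t)l * N;
    for (int k = 0; k < N; ++k) acc[k] += col[k] * ul;
  }
  const double I_t = input_on ? square_wave(t, c, period) : 0.0;
  for (int k = 0; k < N; ++k) {
    const double uk = u[k], wk = w[k];
    double drive = uk - uk * uk * uk / 3.0 - wk + I0 - sigma * du[k];
    if (input_on && is_target[k]) drive += I_t;
    du[k] = inv_eps * drive;
    dw[k] = uk + a - b * wk;
  }
}

// [[Rcpp::export]]
List fhn_integrate_cpp(NumericMatrix G, double a, double b, double eps,
                       double sigma, double I0,
                       double c, double period, IntegerVector targets0,
                       bool input_on,
                       double duration, double dt,
                       NumericVector u0, NumericVector w0, double guard) {
  const int N = G.nrow();
  const int nsteps = (int)std::lround(duration / dt);
  NumericMatrix U(N, nsteps + 1), W(N, nsteps + 1);
  NumericVector times(nsteps + 1);

  std::vector<char> is_target(N, 0);
  for (int i = 0; i < targets0.size(); ++i) is_target[targets0[i]] = 1;

  std::vector<double> u(u0.begin(), u0.end()), w(w0.begin(), w0.end());
  std::vector<double> k1u(N), k1w(N), k2u(N), k2w(N), k3u(N), k3w(N), k4u(N), k4w(N);
  std::vector<double> tu(N), tw(N);
  const double inv_eps = 1.0 / eps;
  const double* Gp = REAL(G);

  for (int k = 0; k < N; ++k) { U(k, 0) = u[k]; W(k, 0) = w[k]; }
  times[0] = 0.0;

  for (int i = 0; i < nsteps; ++i) {
    const double t = i * dt;
    fhn_deriv(u, w, t, Gp, N, a, b, inv_eps, sigma, I0, c, period, is_target, input_on, k1u, k1w);
    for (int k = 0; k < N; ++k) { tu[k] = u[k] + 0.5 * dt * k1u[k]; tw[k] = w[k] + 0.5 * dt * k1w[k]; }
    fhn_deriv(tu, tw, t + 0.5 * dt, Gp, N, a, b, inv_eps, sigma, I0, c, period, is_target, input_on, k2u, k2w);
    for (int k = 0; k < N; ++k) { tu[k] = u[k] + 0.5 * dt * k2u[k]; tw[k] = w[k] + 0.5 * dt * k2w[k]; }
    fhn_deriv(tu, tw, t + 0.5 * dt, Gp, N, a, b, inv_eps, sigma, I0, c, period, is_target, input_on, k3u, k3w);
    for (int k = 0; k < N; ++k) { tu[k] = u[k] + dt * k3u[k]; tw[k] = w[k] + dt * k3w[k]; }
    fhn_deriv(tu, tw, t + dt, Gp, N, a, b, inv_eps, sigma, I0, c, period, is_target, input_on, k4u, k4w);
    for (int k = 0; k < N; ++k) {
      u[k] += dt / 6.0 * (k1u[k] + 2.0 * k2u[k] + 2.0 * k3u[k] + k4u[k]);
      w[k] += dt / 6.0 * (k1w[k] + 2.0 * k2w[k] + 2.0 * k3w[k] + k4w[k]);
    }
    const double tnext = (i + 1) * dt;
    for (int k = 0; k < N; ++k) {
      if (!std::isfinite(u[k]) || !std::isfinite(w[k]) ||
          std::fabs(u[k]) > guard || std::fabs(w[k]) > guard)
        stop("FHN trajectory diverged at node %d, time %.4f (|state| > guard or non-finite)",
             k + 1, tnext);
      U(k, i + 1) = u[k];
      W(k, i + 1) = w[k];
    }
    times[i + 1] = tnext;
  }
  return List::create(_["times"] = times, _["u"] = U, _["w"] = W);
}

// Balloon-Windkessel hemodynamic ODE, one node:
//   s' = eps_b * uhat - s/tau_s - (f - 1)/tau_f
//   f' = s
//   v' = (f - v^expo) / tau0          (f_out(v) = v^expo)
//   q' = (E(f)/E0 - v^expo * q / v) / tau0,  E(f) = 1 - (1 - E0)^(1/f)
struct HemoPar {
  double tau0, E0, expo, tau_s, tau_f, eps_b;
  double log1mE0;   // log(1 - E0), cached for the extraction formula
};

static inline void hemo_deriv(double s, double f, double v, double q,
                              double uh, const HemoPar& p,
                              double& ds, double& df, double& dv, double& dq) {
  ds = p.eps_b * uh - s / p.tau_s - (f - 1.0) / p.tau_f;
  df = s;
  const double fout = std::pow(v, p.expo);
  dv = (f - fout) / p.tau0;
  const double E = 1.0 - std::exp(p.log1mE0 / f);   // 1 - (1-E0)^(1/f)
  dq = (E / p.E0 - fout * q / v) / p.tau0;
}

// [[Rcpp::export]]
NumericMatrix hemo_integrate_cpp(NumericMatrix uhat, double dt,
                                 double tau0, double E0, double V0, double expo,
                                 double tau_s, double tau_f, double eps_b,
                                 double k1, double k2, double k3) {
  const int N = uhat.nrow();
  const int ncol = uhat.ncol();   // nsteps + 1 neural grid points
  NumericMatrix Y(N, ncol);
  HemoPar p{tau0, E0, expo, tau_s, tau_f, eps_b, std::log(1.0 - E0)};

  for (int n = 0; n < N; ++n) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    Y(n, 0) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    for (int i = 0; i + 1 < ncol; ++i) {
      const double u0 = uhat(n, i), u1 = uhat(n, i + 1);
      const double um = 0.5 * (u0 + u1);   // linear interpolation at the midpoint
      double k1s, k1f, k1v, k1q, k2s, k2f, k2v, k2q;
      double k3s, k3f, k3v, k3q, k4s, k4f, k4v, k4q;
      hemo_deriv(s, f, v, q, u0, p, k1s, k1f, k1v, k1q);
      hemo_deriv(s + 0.5 * dt * k1s, f + 0.5 * dt * k1f,
                 v + 0.5 * dt * k1v, q + 0.5 * dt * k1q, um, p, k2s, k2f, k2v, k2q);
      hemo_deriv(s + 0.5 * dt * k2s, f + 0.5 * dt * k2f,
                 v + 0.5 * dt * k2v, q + 0.5 * dt * k2q, um, p, k3s, k3f, k3v, k3q);
      hemo_deriv(s + dt * k3s, f + dt * k3f,
                 v + dt * k3v, q + dt * k3q, u1, p, k4s, k4f, k4v, k4q);
      s += dt / 6.0 * (k1s + 2.0 * k2s + 2.0 * k3s + k4s);
      f += dt / 6.0 * (k1f + 2.0 * k2f + 2.0 * k3f + k4f);
      v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      q += dt / 6.0 * (k1q + 2.0 * k2q + 2.0 * k3q + k4q);
      if (!std::isfinite(s) || !std::isfinite(f) || !std::isfinite(v) || !std::isfinite(q) ||
          f <= 0.0 || v <= 0.0 || q <= 0.0)
        stop("Balloon-Windkessel state lost positivity at node %d, time %.4f; try a smaller dt",
             n + 1, (i + 1) * dt);
      Y(n, i + 1) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return Y;
}
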