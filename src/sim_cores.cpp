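#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sigmoidal input-output firing-rate function H(x) = (a x - b) /
// (1 - exp(-d (a x - b))), continuous at a x = b with limit 1/d.
static inline double hrate(double x, double a, double b, double d) {
  double u = a * x - b;
  double du = d * u;
  if (std::fabs(du) < 1e-8) {
    // series of u / (1 - exp(-d u)) around du = 0
    return 1.0 / d + u / 2.0 + d * u * u / 12.0;
  }
  return u / (-std::expm1(-du));
}

// [[Rcpp::export]]
double cpp_firing_rate(double x, double a, double b, double d) {
  return hrate(x, a, b, d);
}

static inline double clamp01(double v) {
  if (v < 0.0) return 0.0;
  if (v > 1.0) return 1.0;
  return v;
}

// Euler-Maruyama integration of the reduced Wong-Wang model on a weighted
// network:
//   dS_i = [-S_i/tau_s + gamma_s (1 - S_i) H(x_i)] dt + D sqrt(dt) xi_i
//   x_i  = w J S_i + G J sum_j A_ij S_j(t - delay_ij) + I0_i
// delay_steps holds per-pair delays in integration steps (all zeros =
// instantaneous coupling); a ring buffer carries the history, initialized
// at S0. One N(0,1) draw per region per step, region-major order, from R's
// global RNG. States are clamped to [0, 1] after each step.
// Returns the (nsteps+1) x n state trace. Errors on non-finite states.
// [[Rcpp::export]]
NumericMatrix cpp_ww_sim(const NumericMatrix& A, double w, double J,
                         double G, const NumericVector& I0, double tau_s,
                         double gamma_s, double D, double a, double b,
                         double d, double dt, int nsteps,
                         const NumericVector& S0,
                         const IntegerMatrix& delay_steps) {
  const int n = A.nrow();
  int maxd = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > maxd) maxd = delay_steps(i, j);
  const int H = maxd + 1;
  const double sqdt = std::sqrt(dt);

  NumericMatrix out(nsteps + 1, n);
  std::vector<double> hist((size_t)H * n);
  for (int h = 0; h < H; ++h)
    for (int j = 0; j < n; ++j) hist[(size_t)h * n + j] = S0[j];
  std::vector<double> S(n), Snew(n);
  for (int j = 0; j < n; ++j) { S[j] = S0[j]; out(0, j) = S0[j]; }

  for (int t = 0; t < nsteps; ++t) {
    const int cur = t % H;
    for (int i = 0; i < n; ++i) {
      double coup = 0.0;
      if (H == 1) {
        for (int j = 0; j < n; ++j) coup += A(i, j) * S[j];
      } else {
        for (int j = 0; j < n; ++j) {
          double aij = A(i, j);
          if (aij != 0.0) {
            int idx = (cur - delay_steps(i, j) % H + H) % H;
            coup += aij * hist[(size_t)idx * n + j];
          }
        }
      }
      double x = w * J * S[i] + G * J * coup + I0[i];
      double drift = -S[i] / tau_s + gamma_s * (1.0 - S[i]) * hrate(x, a, b, d);
      double v = S[i] + dt * drift + D * sqdt * norm_rand();
      if (!std::isfinite(v))
        stop("non-finite state at step %d, region %d", t + 1, i + 1);
      Snew[i] = clamp01(v);
    }
    const int nxt = (t + 1) % H;
    for (int j = 0; j < n; ++j) {
      S[j] = Snew[j];
      hist[(size_t)nxt * n + j] = S[j];
      out(t + 1, j) = S[j];
    }
  }
  return out;
}

// Sweep engine: for each w in wgrid, integrate the Wong-Wang model and
// return the per-region time average of S after discarding ntrans steps.
// Returns an n x length(wgrid) matrix. No delays (the sweep is defined for
// the instantaneous model; delayed sweeps go through cpp_ww_sim from R).
// [[Rcpp::export]]
NumericMatrix cpp_ww_sweep(const NumericMatrix& A, const NumericVector& wgrid,
                           double J, double G, const NumericVector& I0,
                           double tau_s, double gamma_s, double D, double a,
                           double b, double d, double dt, int nsteps,
                           int ntrans, const NumericVector& S0) {
  const int n = A.nrow();
  const int nw = wgrid.size();
  const double sqdt = std::sqrt(dt);
  NumericMatrix sbar(n, nw);
  std::vector<double> S(n), Snew(n), acc(n);

  for (int k = 0; k < nw; ++k) {
    const double w = wgrid[k];
    for (int j = 0; j < n; ++j) { S[j] = S0[j]; acc[j] = 0.0; }
    long navg = 0;
    for (int t = 0; t < nsteps; ++t) {
      for (int i = 0; i < n; ++i) {
        double coup = 0.0;
        for (int j = 0; j < n; ++j) coup += A(i, j) * S[j];
        double x = w * J * S[i] + G * J * coup + I0[i];
        double drift = -S[i] / tau_s +
                       gamma_s * (1.0 - S[i]) * hrate(x, a, b, d);
        double v = S[i] + dt * drift + D * sqdt * norm_rand();
        if (!std::isfinite(v))
          stop("non-finite state at step %d, region %d (w = %g)",
               t + 1, i + 1, w);
        Snew[i] = clamp01(v);
      }
      for (int j = 0; j < n; ++j) S[j] = Snew[j];
      if (t >= ntrans) {
        for (int j = 0; j < n; ++j) acc[j] += S[j];
        ++navg;
      }
    }
    for (int j = 0; j < n; ++j) sbar(j, k) = acc[j] / (double)navg;
  }
  return sbar;
}

static inline double sigm(double x, double a, double mu) {
  return 1.0 / (1.0 + std::exp(-a * (x - mu)));
}

// Euler-Maruyama integration of the Wilson-Cowan model:
//   dSE_i = (1/tauE) [-SE_i + (1-SE_i) HE(xE_i)] dt + (DE/tauE) sqrt(dt) xi
//   xE_i  = wEE SE_i - wEI SI_i + G sum_j A_ij SE_j + GE PE
//   xI_i  = wIE SE_i - wII SI_i
// Noise sits inside the 1/tau bracket, as the model is written. Two draws
// per region per step (E then I), region-major order. States clamped to
// [0, 1]. Returns list(SE, SI) of (nsteps+1) x n traces.
// [[Rcpp::export]]
List cpp_wc_sim(const NumericMatrix& A, double wEE, double wEI, double wIE,
                double wII, double G, double GE, double PE, double tauE,
                double tauI, double DE, double DI, double aE, double aI,
                double muE, double muI, double dt, int nsteps,
                double SE0, double SI0) {
  const int n = A.nrow();
  const double sqdt = std::sqrt(dt);
  NumericMatrix outE(nsteps + 1, n), outI(nsteps + 1, n);
  std::vector<double> SE(n, SE0), SI(n, SI0), SEn(n), SIn(n);
  for (int j = 0; j < n; ++j) { outE(0, j) = SE0; outI(0, j) = SI0; }

  for (int t = 0; t < nsteps; ++t) {
    for (int i = 0; i < n; ++i) {
      double coup = 0.0;
      for (int j = 0; j < n; ++j) coup += A(i, j) * SE[j];
      double xE = wEE * SE[i] - wEI * SI[i] + G * coup + GE * PE;
      double xI = wIE * SE[i] - wII * SI[i];
      double vE = SE[i] +
        (dt / tauE) * (-SE[i] + (1.0 - SE[i]) * sigm(xE, aE, muE)) +
        (DE / tauE) * sqdt * norm_rand();
      double vI = SI[i] +
        (dt / tauI) * (-SI[i] + (1.0 - SI[i]) * sigm(xI, aI, muI)) +
        (DI / tauI) * sqdt * norm_rand();
      if (!std::isfinite(vE) || !std::isfinite(vI))
        stop("non-finite state at step %d, region %d", t + 1, i + 1);
      SEn[i] = clamp01(vE);
      SIn[i] = clamp01(vI);
    }
    for (int j = 0; j < n; ++j) {
      SE[j] = SEn[j]; SI[j] = SIn[j];
      outE(t + 1, j) = SE[j]; outI(t + 1, j) = SI[j];
    }
  }
  return List::create(_["SE"] = outE, _["SI"] = outI);
}

// Sweep engine for the Wilson-Cowan model over a wEE grid; returns the
// n x length(grid) matrix of time-averaged SE after ntrans steps.
// [[Rcpp::export]]
NumericMatrix cpp_wc_sweep(const NumericMatrix& A, const NumericVector& grid,
                           double wEI, double wIE, double wII, double G,
                           double GE, double PE, double tauE, double tauI,
                           double DE, double DI, double aE, double aI,
                           double muE, double muI, double dt, int nsteps,
                           int ntrans, double SE0, double SI0) {
  const int n = A.nrow();
  const int nw = grid.size();
  const double sqdt = std::sqrt(dt);
  NumericMatrix sbar(n, nw);
  std::vector<double> SE(n), SI(n), SEn(n), SIn(n), acc(n);

  for (int k = 0; k < nw; ++k) {
    const double wEE = grid[k];
    for (int j = 0; j < n; ++j) { SE[j] = SE0; SI[j] = SI0; acc[j] = 0.0; }
    long navg = 0;
    for (int t = 0; t < nsteps; ++t) {
      for (int i = 0; i < n; ++i) {
        double coup = 0.0;
        for (int j = 0; j < n; ++j) coup += A(i, j) * SE[j];
        double xE = wEE * SE[i] - wEI * SI[i] + G * coup + GE * PE;
        double xI = wIE * SE[i] - wII * SI[i];
        double vE = SE[i] +
          (dt / tauE) * (-SE[i] + (1.0 - SE[i]) * sigm(xE, aE, muE)) +
          (DE / tauE) * sqdt * norm_rand();
        double vI = SI[i] +
          (dt / tauI) * (-SI[i] + (1.0 - SI[i]) * sigm(xI, aI, muI)) +
          (DI / tauI) * sqdt * norm_rand();
        if (!std::isfinite(vE) || !std::isfinite(vI))
          stop("non-finite state at step %d, region %d (wEE = %g)",
               t + 1, i + 1, wEE);
        SEn[i] = clamp01(vE);
        SIn[i] = clamp01(vI);
      }
      for (int j = 0; j < n; ++j) { SE[j] = SEn[j]; SI[j] = SIn[j]; }
      if (t >= ntrans) {
        for (int j = 0; j < n; ++j) acc[j] += SE[j];
        ++navg;
      }
    }
    for (int j = 0; j < n; ++j) sbar(j, k) = acc[j] / (double)navg;
  }
  return sbar;
}

// Balloon-Windkessel haemodynamics driven by a neural trace (rows = time
// at step dt). Euler integration of vasodilatory signal z, inflow f, volume
// v, deoxyhemoglobin q from rest (z=0, f=v=q=1); the BOLD signal is the
// algebraic readout Y = V0 [k1 (1-q) + k2 (1-q/v) + k3 (1-v)].
// Returns the (T x n) BOLD trace on the neural time grid.
// [[Rcpp::export]]
NumericMatrix cpp_bw_sim(const NumericMatrix& S, double dt, double kappa,
                         double gamma, double tau, double alpha, double rho,
                         double V0, double k1, double k2, double k3) {
  const int T = S.nrow();
  const int n = S.ncol();
  const double ialpha = 1.0 / alpha;
  NumericMatrix Y(T, n);
  for (int j = 0; j < n; ++j) {
    double z = 0.0, f = 1.0, v = 1.0, q = 1.0;
    Y(0, j) = 0.0;
    for (int t = 1; t < T; ++t) {
      double dz = S(t - 1, j) - kappa * z - gamma * (f - 1.0);
      double df = z;
      double dv = (f - std::pow(v, ialpha)) / tau;
      double dq = ((f / rho) * (1.0 - std::pow(1.0 - rho, 1.0 / f)) -
                   q * std::pow(v, ialpha - 1.0)) / tau;
      z += dt * dz;
      f += dt * df;
      v += dt * dv;
      q += dt * dq;
      if (f <= 0.0 || v <= 0.0 || !std::isfinite(z) || !std::isfinite(q))
        stop("haemodynamic blow-up at step %d, region %d", t, j + 1);
      Y(t, j) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return Y;
}

// Networked drift-diffusion trials on a Laplacian:
//   dy_i = [beta_i + lambda y_i - sum_j L_ij y_j] dt + D sqrt(dt) xi_i
// from y = 0. A region's decision is its FIRST grid point at or beyond
// +/- theta; if clamp_absorbed, the region is then held at the boundary
// value (still entering neighbours' coupling), otherwise it keeps
// diffusing while only the first hit is recorded.
// Returns hit_sign (ntrials x n; +1 correct, -1 incorrect, 0 undecided)
// and hit_step (ntrials x n; 1-based step of first hit, 0 if undecided).
// [[Rcpp::export]]
List cpp_ddm_trials(const NumericMatrix& L, const NumericVector& beta,
                    double lambda, double D, double theta, double dt,
                    int nsteps, int ntrials, bool clamp_absorbed) {
  const int n = L.nrow();
  const double sqdt = std::sqrt(dt);
  IntegerMatrix hit_sign(ntrials, n), hit_step(ntrials, n);
  std::vector<double> y(n), yn(n);
  std::vector<int> sgn(n), stp(n);

  for (int tr = 0; tr < ntrials; ++tr) {
    for (int j = 0; j < n; ++j) { y[j] = 0.0; sgn[j] = 0; stp[j] = 0; }
    int undecided = n;
    for (int t = 1; t <= nsteps; ++t) {
      for (int i = 0; i < n; ++i) {
        if (clamp_absorbed && sgn[i] != 0) {
          norm_rand();  // keep the draw order identical across variants
          yn[i] = y[i];
          continue;
        }
        double coup = 0.0;
        for (int j = 0; j < n; ++j) coup += L(i, j) * y[j];
        double v = y[i] + dt * (beta[i] + lambda * y[i] - coup) +
                   D * sqdt * norm_rand();
        if (!std::isfinite(v))
          stop("non-finite evidence at step %d, region %d", t, i + 1);
        yn[i] = v;
      }
      for (int i = 0; i < n; ++i) {
        if (sgn[i] == 0 && std::fabs(yn[i]) >= theta) {
          sgn[i] = yn[i] >= theta ? 1 : -1;
          stp[i] = t;
          --undecided;
          if (clamp_absorbed) yn[i] = sgn[i] > 0 ? theta : -theta;
        }
        y[i] = yn[i];
      }
      if (undecided == 0 && clamp_absorbed) break;
    }
    for (int i = 0; i < n; ++i) {
      hit_sign(tr, i) = sgn[i];
      hit_step(tr, i) = stp[i];
    }
  }
  return List::create(_["hit_sign"] = hit_sign, _["hit_step"] = hit_step);
}
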