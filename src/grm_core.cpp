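// Numerical core for the four NFkB-driven transcription models.
//
// The driving input NFkB(t) is a scaled fold-change trajectory tabulated on a
// 1-second grid; delayed input terms NFkB(t - tau) are table lookups with
// t - tau rounded to the nearest grid second.  Delayed state terms (A(t - tau),
// TF(t - tau_TF)) are read from the integration's own stored node history.
//
// Integrators:
//   * simple / IFFL: classical RK4 with fixed step (the free rate constants
//     are bounded by 2e-3 s^-1, so the systems are non-stiff and the step is
//     accuracy-, not stability-, limited).
//   * 3-state cycle / v4 promoter states: TR-BDF2 (L-stable, 2nd order) with
//     an analytic 3x3 Newton solve; the promoter transition rate k2 may be as
//     large as ~69 s^-1, which makes explicit integration infeasible.
//   * TF and mRNA equations of the cycle models are linear in their own state
//     and are advanced with exact exponential (integrating-factor) updates
//     driven by the piecewise-linear node history of their inputs.
//
// All schemes preserve the linear invariant C + O + A = 1 up to the Newton
// residual tolerance, and leave exact steady states invariant.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double SENTINEL = 1e6;

// model ids
enum { MODEL_SIMPLE = 1, MODEL_IFFL = 2, MODEL_CYCLE3 = 3, MODEL_V4 = 4 };

// parameter vector layouts (filled by the R wrappers):
// simple: [ksyn, kdeg, KD, h, tau]
// iffl:   [ksyn, kdeg, KD1, KD2, h, tau, kdegTF, KDTF, hTF, tauTF]
// cycle3: [ksyn, kdeg, k1, k2, km1, km2, km3, KD1, KD2, KD3, tau]
// v4:     [ksyn, kdeg, k1, k2, km1, km2, km3, KD1, KD2, KD3, KDTF2,
//          h, tau, kdegTF, KDTF, hTF, tauTF]

struct Grid {
  const double* v;
  int n;
  long t0; // time (s) of first grid value
  double at(double t) const {
    long idx = std::lround(t) - t0;
    if (idx < 0) idx = 0;
    if (idx >= n) idx = n - 1;
    return v[idx];
  }
};

static inline double powh(double x, double h) {
  if (x <= 0.0) return 0.0;
  if (h == 1.0) return x;
  if (h == 2.0) return x * x;
  return std::pow(x, h);
}

// Hill activation (K x)^h / ((K x)^h + 1)
static inline double hillKx(double x, double K, double h) {
  double z = powh(K * x, h);
  return z / (z + 1.0);
}

// ---------------------------------------------------------------------------
// steady states under constant input n0
// ---------------------------------------------------------------------------

// promoter-cycle steady state: bisection on A in [0, 1]
static void cycleSteady(double a, double b, double km1, double km2, double km3,
                        double KD3, double& C, double& O, double& A) {
  if (a <= 0.0 || b <= 0.0) { C = 1.0; O = 0.0; A = 0.0; return; }
  auto gfun = [&](double A_) { return km3 * KD3 * A_ / (KD3 * A_ + 1.0); };
  auto Ofun = [&](double A_) { return (km2 * A_ + gfun(A_)) / b; };
  auto F = [&](double A_) {
    double O_ = Ofun(A_);
    return a * (1.0 - O_ - A_) - km1 * O_ - gfun(A_);
  };
  double lo = 0.0, hi = 1.0;
  for (int i = 0; i < 100; ++i) {
    double mid = 0.5 * (lo + hi);
    if (F(mid) > 0.0) lo = mid; else hi = mid;
  }
  A = 0.5 * (lo + hi);
  O = Ofun(A);
  C = 1.0 - O - A;
  if (C < 0.0) C = 0.0;
}

// full steady state; returns state vector in the model's layout
// simple: [m]; iffl: [TF, m]; cycle3: [C, O, A, m]; v4: [C, O, A, TF, m]
static std::vector<double> steadyStateVec(int model, const double* p, double n0) {
  std::vector<double> y;
  switch (model) {
  case MODEL_SIMPLE: {
    double ksyn = p[0], kdeg = p[1], KD = p[2], h = p[3];
    y.push_back(ksyn * hillKx(n0, KD, h) / kdeg);
    break;
  }
  case MODEL_IFFL: {
    double ksyn = p[0], kdeg = p[1], KD1 = p[2], KD2 = p[3], h = p[4];
    double kdegTF = p[6], KDTF = p[7], hTF = p[8];
    double TFss = hillKx(n0, KDTF, hTF) / kdegTF;
    double x1 = powh(KD1 * n0, h), x2 = powh(KD2 * TFss, h);
    y.push_back(TFss);
    y.push_back(ksyn * x1 / (x1 + x2 + 1.0) / kdeg);
    break;
  }
  case MODEL_CYCLE3: {
    double ksyn = p[0], kdeg = p[1], k1 = p[2], k2 = p[3];
    double km1 = p[4], km2 = p[5], km3 = p[6];
    double KD1 = p[7], KD2 = p[8], KD3 = p[9];
    double a = k1 * hillKx(n0, KD1, 1.0), b = k2 * hillKx(n0, KD2, 1.0);
    double C, O, A;
    cycleSteady(a, b, km1, km2, km3, KD3, C, O, A);
    y.push_back(C); y.push_back(O); y.push_back(A);
    y.push_back(ksyn * A / kdeg);
    break;
  }
  case MODEL_V4: {
    double ksyn = p[0], kdeg = p[1], k1 = p[2], k2 = p[3];
    double km1 = p[4], km2 = p[5], km3 = p[6];
    double KD1 = p[7], KD2 = p[8], KD3 = p[9], KDTF2 = p[10];
    double h = p[11], kdegTF = p[13], KDTF = p[14], hTF = p[15];
    double a = k1 * hillKx(n0, KD1, 1.0), b = k2 * hillKx(n0, KD2, 1.0);
    double C, O, A;
    cycleSteady(a, b, km1, km2, km3, KD3, C, O, A);
    double TFss = hillKx(n0, KDTF, hTF) / kdegTF;
    double x1 = powh(A, h), x2 = powh(KDTF2 * TFss, h);
    y.push_back(C); y.push_back(O); y.push_back(A);
    y.push_back(TFss);
    y.push_back(ksyn * x1 / (x1 + x2 + 1.0) / kdeg);
    break;
  }
  default:
    stop("unknown model id");
  }
  return y;
}

// ---------------------------------------------------------------------------
// exact exponential update for  y' = s(t) - k y  with s piecewise linear
// ---------------------------------------------------------------------------
static inline double expUpdate(double y, double s0, double s1, double k, double dt) {
  double kdt = k * dt;
  double E = std::exp(-kdt);
  double w0 = -std::expm1(-kdt) / k;      // (1 - E)/k
  double w1;                               // (dt - (1-E)/k)/k
  if (kdt < 1e-4) {
    w1 = dt * dt * 0.5 * (1.0 - kdt / 3.0);
  } else {
    w1 = (dt - w0) / k;
  }
  return y * E + s0 * w0 + (s1 - s0) / dt * w1;
}

// ---------------------------------------------------------------------------
// simulation result on uniform nodes
// ---------------------------------------------------------------------------
struct SimNodes {
  bool ok = false;
  double simStart = 0.0, dt = 1.0;
  int N = 0;                        // number of steps; N + 1 nodes
  std::vector<double> y0;           // initial (steady) state
  std::vector<double> m, tf, C, O, A;
};

// linear interpolation in a node history; t <= simStart returns y0v
static inline double nodeAt(const std::vector<double>& h, double y0v,
                            double t, double simStart, double dt, int N) {
  if (t <= simStart) return y0v;
  double x = (t - simStart) / dt;
  if (x >= N) return h[N];
  int i = (int)x;
  double fr = x - i;
  return h[i] * (1.0 - fr) + h[i + 1] * fr;
}

// 3x3 linear solve with partial pivoting; returns false if singular
static bool solve3(double Mmat[3][3], double rhs[3], double out[3]) {
  int piv[3] = {0, 1, 2};
  for (int c = 0; c < 3; ++c) {
    int best = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(Mmat[piv[r]][c]) > std::fabs(Mmat[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    double d = Mmat[piv[c]][c];
    if (std::fabs(d) < 1e-300) return false;
    for (int r = c + 1; r < 3; ++r) {
      double f = Mmat[piv[r]][c] / d;
      for (int cc = c; cc < 3; ++cc) Mmat[piv[r]][cc] -= f * Mmat[piv[c]][cc];
      rhs[piv[r]] -= f * rhs[piv[c]];
    }
  }
  for (int c = 2; c >= 0; --c) {
    double s = rhs[piv[c]];
    for (int cc = c + 1; cc < 3; ++cc) s -= Mmat[piv[c]][cc] * out[cc];
    out[c] = s / Mmat[piv[c]][c];
  }
  return true;
}

struct CycleParams {
  double k1, k2, km1, km2, km3, KD1, KD2, KD3;
};

static inline void cycleF(const CycleParams& cp, double u, const double y[3],
                          double f[3]) {
  double a = cp.k1 * hillKx(u, cp.KD1, 1.0);
  double b = cp.k2 * hillKx(u, cp.KD2, 1.0);
  double g = cp.km3 * cp.KD3 * y[2] / (cp.KD3 * y[2] + 1.0);
  f[0] = -a * y[0] + cp.km1 * y[1] + g;
  f[1] = a * y[0] - (b + cp.km1) * y[1] + cp.km2 * y[2];
  f[2] = b * y[1] - cp.km2 * y[2] - g;
}

// Newton solve of y - c*dt*f(t*, y) = r
static bool cycleStage(const CycleParams& cp, double u, double cdt,
                       const double r[3], double y[3]) {
  for (int iter = 0; iter < 25; ++iter) {
    double f[3];
    cycleF(cp, u, y, f);
    double G[3];
    double norm = 0.0;
    for (int i = 0; i < 3; ++i) {
      G[i] = y[i] - cdt * f[i] - r[i];
      norm = std::max(norm, std::fabs(G[i]));
    }
    if (norm < 1e-13) return true;
    double a = cp.k1 * hillKx(u, cp.KD1, 1.0);
    double b = cp.k2 * hillKx(u, cp.KD2, 1.0);
    double den = cp.KD3 * y[2] + 1.0;
    double gp = cp.km3 * cp.KD3 / (den * den);
    double J[3][3] = {
      {-a, cp.km1, gp},
      {a, -(b + cp.km1), cp.km2},
      {0.0, b, -cp.km2 - gp}
    };
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        M[i][j] = (i == j ? 1.0 : 0.0) - cdt * J[i][j];
    double rhs[3] = {-G[0], -G[1], -G[2]};
    double dy[3];
    if (!solve3(M, rhs, dy)) return false;
    for (int i = 0; i < 3; ++i) y[i] += dy[i];
    if (!std::isfinite(y[0]) || !std::isfinite(y[1]) || !std::isfinite(y[2]))
      return false;
  }
  return false;
}

// repair tiny negative promoter fractions without breaking conservation
static bool repairStates(double y[3]) {
  for (int i = 0; i < 3; ++i) {
    if (y[i] < 0.0) {
      if (y[i] < -1e-6) return false;
      int jmax = 0;
      for (int j = 1; j < 3; ++j) if (y[j] > y[jmax]) jmax = j;
      y[jmax] += y[i];
      y[i] = 0.0;
    }
  }
  return true;
}

// core simulation; tStart/tEnd/dt must satisfy: (0 - tStart) and (tEnd - 0)
// are integer multiples of dt
static SimNodes simCore(int model, const double* p, const Grid& grid,
                        double tStart, double tEnd, double dt, double n0) {
  SimNodes out;
  out.dt = dt;

  // the pre-stimulus window holds the t = 0 input value, so the steady-state
  // solution is constant there; skip ahead to 0 when the grid confirms this
  double simStart = tStart;
  {
    double u0 = grid.at(0.0);
    bool constant = true;
    for (long t = (long)tStart; t <= 0; ++t) {
      if (grid.at((double)t) != u0) { constant = false; break; }
    }
    if (constant) simStart = 0.0;
  }
  out.simStart = simStart;

  int N = (int)std::lround((tEnd - simStart) / dt);
  out.N = N;
  out.y0 = steadyStateVec(model, p, n0);
  for (double v : out.y0) if (!std::isfinite(v)) return out;

  switch (model) {
  case MODEL_SIMPLE: {
    double ksyn = p[0], kdeg = p[1], KD = p[2], h = p[3], tau = p[4];
    out.m.assign(N + 1, 0.0);
    out.m[0] = out.y0[0];
    double m = out.m[0];
    for (int i = 0; i < N; ++i) {
      double t = simStart + i * dt;
      double s0 = ksyn * hillKx(grid.at(t - tau), KD, h);
      double sh = ksyn * hillKx(grid.at(t + 0.5 * dt - tau), KD, h);
      double s1 = ksyn * hillKx(grid.at(t + dt - tau), KD, h);
      double k1v = s0 - kdeg * m;
      double k2v = sh - kdeg * (m + 0.5 * dt * k1v);
      double k3v = sh - kdeg * (m + 0.5 * dt * k2v);
      double k4v = s1 - kdeg * (m + dt * k3v);
      m += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      out.m[i + 1] = m;
    }
    out.ok = true;
    break;
  }
  case MODEL_IFFL: {
    double ksyn = p[0], kdeg = p[1], KD1 = p[2], KD2 = p[3], h = p[4];
    double tau = p[5], kdegTF = p[6], KDTF = p[7], hTF = p[8], tauTF = p[9];
    out.tf.assign(N + 1, 0.0);
    out.m.assign(N + 1, 0.0);
    out.tf[0] = out.y0[0];
    out.m[0] = out.y0[1];
    double TF = out.tf[0], m = out.m[0];
    double TF0 = out.tf[0];
    for (int i = 0; i < N; ++i) {
      double t = simStart + i * dt;
      // stage helper: derivatives at offset dt_off with state (TFv, mv)
      auto deriv = [&](double toff, double TFv, double mv, double& dTF,
                       double& dm) {
        double tt = t + toff;
        double sTF = hillKx(grid.at(tt - tau), KDTF, hTF);
        dTF = sTF - kdegTF * TFv;
        double TFlag = nodeAt(out.tf, TF0, tt - tauTF, simStart, dt, i);
        double x1 = powh(KD1 * grid.at(tt - tau), h);
        double x2 = powh(KD2 * TFlag, h);
        dm = ksyn * x1 / (x1 + x2 + 1.0) - kdeg * mv;
      };
      double dTF1, dm1, dTF2, dm2, dTF3, dm3, dTF4, dm4;
      deriv(0.0, TF, m, dTF1, dm1);
      deriv(0.5 * dt, TF + 0.5 * dt * dTF1, m + 0.5 * dt * dm1, dTF2, dm2);
      deriv(0.5 * dt, TF + 0.5 * dt * dTF2, m + 0.5 * dt * dm2, dTF3, dm3);
      deriv(dt, TF + dt * dTF3, m + dt * dm3, dTF4, dm4);
      TF += dt / 6.0 * (dTF1 + 2.0 * dTF2 + 2.0 * dTF3 + dTF4);
      m += dt / 6.0 * (dm1 + 2.0 * dm2 + 2.0 * dm3 + dm4);
      out.tf[i + 1] = TF;
      out.m[i + 1] = m;
    }
    out.ok = true;
    break;
  }
  case MODEL_CYCLE3:
  case MODEL_V4: {
    bool isV4 = (model == MODEL_V4);
    double ksyn = p[0], kdeg = p[1];
    CycleParams cp;
    cp.k1 = p[2]; cp.k2 = p[3]; cp.km1 = p[4]; cp.km2 = p[5]; cp.km3 = p[6];
    cp.KD1 = p[7]; cp.KD2 = p[8]; cp.KD3 = p[9];
    double KDTF2 = 0.0, h = 1.0, tau = 0.0, kdegTF = 0.0, KDTF = 0.0,
      hTF = 1.0, tauTF = 0.0;
    if (isV4) {
      KDTF2 = p[10]; h = p[11]; tau = p[12];
      kdegTF = p[13]; KDTF = p[14]; hTF = p[15]; tauTF = p[16];
    } else {
      tau = p[10];
    }
    out.C.assign(N + 1, 0.0);
    out.O.assign(N + 1, 0.0);
    out.A.assign(N + 1, 0.0);
    out.m.assign(N + 1, 0.0);
    if (isV4) out.tf.assign(N + 1, 0.0);

    double y[3] = {out.y0[0], out.y0[1], out.y0[2]};
    out.C[0] = y[0]; out.O[0] = y[1]; out.A[0] = y[2];
    double TF = 0.0;
    if (isV4) { TF = out.y0[3]; out.tf[0] = TF; }

    const double gam = 2.0 - std::sqrt(2.0);
    const double c2 = (1.0 - gam) / (2.0 - gam);
    const double bd1 = 1.0 / (gam * (2.0 - gam));
    const double bd0 = (1.0 - gam) * (1.0 - gam) / (gam * (2.0 - gam));

    bool failed = false;
    for (int i = 0; i < N && !failed; ++i) {
      double t = simStart + i * dt;
      // the promoter states are driven by NFkB(t) in the 3-state cycle model
      // and by NFkB(t - tau) in model v4 (the asymmetry is intentional)
      double lagIn = isV4 ? tau : 0.0;
      double u0 = grid.at(t - lagIn);
      double ug = grid.at(t + gam * dt - lagIn);
      double u1 = grid.at(t + dt - lagIn);
      double f0[3];
      cycleF(cp, u0, y, f0);
      // trapezoidal stage to t + gam*dt (explicit Euler predictor)
      double r1[3], y1[3];
      for (int j = 0; j < 3; ++j) {
        r1[j] = y[j] + 0.5 * gam * dt * f0[j];
        y1[j] = y[j] + gam * dt * f0[j];
      }
      if (!cycleStage(cp, ug, 0.5 * gam * dt, r1, y1)) { failed = true; break; }
      // BDF2 stage to t + dt (extrapolated predictor)
      double r2[3], y2[3];
      for (int j = 0; j < 3; ++j) {
        r2[j] = bd1 * y1[j] - bd0 * y[j];
        y2[j] = r2[j];
      }
      if (!cycleStage(cp, u1, c2 * dt, r2, y2)) { failed = true; break; }
      if (!repairStates(y2)) { failed = true; break; }
      for (int j = 0; j < 3; ++j) y[j] = y2[j];
      out.C[i + 1] = y[0]; out.O[i + 1] = y[1]; out.A[i + 1] = y[2];
      if (isV4) {
        // Eq for TF in the combined model uses undelayed NFkB(t)
        double s0 = hillKx(grid.at(t), KDTF, hTF);
        double s1 = hillKx(grid.at(t + dt), KDTF, hTF);
        TF = expUpdate(TF, s0, s1, kdegTF, dt);
        out.tf[i + 1] = TF;
      }
    }
    if (failed) return out;

    // mRNA pass: synthesis from the stored A (and TF) history
    double A0 = out.y0[2];
    double TF0v = isV4 ? out.y0[3] : 0.0;
    auto synthAt = [&](double t) {
      double Alag = nodeAt(out.A, A0, t - tau, simStart, dt, N);
      if (!isV4) return ksyn * Alag;
      double TFlag = nodeAt(out.tf, TF0v, t - tauTF, simStart, dt, N);
      double x1 = powh(Alag, h), x2 = powh(KDTF2 * TFlag, h);
      return ksyn * x1 / (x1 + x2 + 1.0);
    };
    double m = out.y0.back();
    out.m[0] = m;
    double sPrev = synthAt(simStart);
    for (int i = 0; i < N; ++i) {
      double sNext = synthAt(simStart + (i + 1) * dt);
      m = expUpdate(m, sPrev, sNext, kdeg, dt);
      out.m[i + 1] = m;
      sPrev = sNext;
    }
    out.ok = true;
    break;
  }
  default:
    stop("unknown model id");
  }
  return out;
}

static int stateDim(int model) {
  switch (model) {
  case MODEL_SIMPLE: return 1;
  case MODEL_IFFL: return 2;
  case MODEL_CYCLE3: return 4;
  case MODEL_V4: return 5;
  }
  return 0;
}

// [[Rcpp::export(name = ".cppSteadyState")]]
NumericVector cppSteadyState(int model, NumericVector p, double n0) {
  std::vector<double> y = steadyStateVec(model, REAL(p), n0);
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export(name = ".cppSimulate")]]
List cppSimulate(int model, NumericVector p, NumericVector gridV, double gridT0,
                 double tStart, double tEnd, double dt, NumericVector evalS,
                 double n0) {
  Grid grid{REAL(gridV), (int)gridV.size(), (long)std::lround(gridT0)};
  if (!std::isfinite(n0)) n0 = grid.at(0.0);
  SimNodes s = simCore(model, REAL(p), grid, tStart, tEnd, dt, n0);
  int ne = evalS.size();
  NumericVector m(ne), tf(ne), C(ne), O(ne), A(ne);
  if (s.ok) {
    for (int i = 0; i < ne; ++i) {
      double t = evalS[i];
      m[i] = nodeAt(s.m, s.y0.back(), t, s.simStart, s.dt, s.N);
      if (model == MODEL_IFFL)
        tf[i] = nodeAt(s.tf, s.y0[0], t, s.simStart, s.dt, s.N);
      if (model == MODEL_V4)
        tf[i] = nodeAt(s.tf, s.y0[3], t, s.simStart, s.dt, s.N);
      if (model == MODEL_CYCLE3 || model == MODEL_V4) {
        C[i] = nodeAt(s.C, s.y0[0], t, s.simStart, s.dt, s.N);
        O[i] = nodeAt(s.O, s.y0[1], t, s.simStart, s.dt, s.N);
        A[i] = nodeAt(s.A, s.y0[2], t, s.simStart, s.dt, s.N);
      }
    }
  }
  return List::create(
    _["ok"] = s.ok, _["mrna"] = m,
    _["tf"] = (model == MODEL_IFFL || model == MODEL_V4) ? (SEXP)tf : R_NilValue,
    _["C"] = (model >= MODEL_CYCLE3) ? (SEXP)C : R_NilValue,
    _["O"] = (model >= MODEL_CYCLE3) ? (SEXP)O : R_NilValue,
    _["A"] = (model >= MODEL_CYCLE3) ? (SEXP)A : R_NilValue,
    _["y0"] = NumericVector(s.y0.begin(), s.y0.end()),
    _["stateDim"] = stateDim(model));
}

// objective: nRMSD between jointly max-normalized simulated and measured
// fold changes in the target condition, plus the steady-state drift penalty
// |m_hat(0) - m_hat(tStart)| on the same normalized scale
// [[Rcpp::export(name = ".cppObjective")]]
double cppObjective(int model, NumericVector p,
                    NumericVector gridCV, double gridCT0,
                    NumericVector gridSV, double gridST0,
                    NumericVector dataNormC, NumericVector dataNormS,
                    NumericVector evalS, int target,
                    double tStart, double tEnd, double dt, bool penalty) {
  Grid gc{REAL(gridCV), (int)gridCV.size(), (long)std::lround(gridCT0)};
  Grid gs{REAL(gridSV), (int)gridSV.size(), (long)std::lround(gridST0)};
  SimNodes sc = simCore(model, REAL(p), gc, tStart, tEnd, dt, gc.at(0.0));
  if (!sc.ok) return SENTINEL;
  SimNodes ss = simCore(model, REAL(p), gs, tStart, tEnd, dt, gs.at(0.0));
  if (!ss.ok) return SENTINEL;

  int ne = evalS.size();
  std::vector<double> fcC(ne), fcS(ne);
  double mC0 = nodeAt(sc.m, sc.y0.back(), 0.0, sc.simStart, sc.dt, sc.N);
  double mS0 = nodeAt(ss.m, ss.y0.back(), 0.0, ss.simStart, ss.dt, ss.N);
  if (!(mC0 > 0.0) || !(mS0 > 0.0)) return SENTINEL;
  double mn = R_PosInf, mx = R_NegInf;
  for (int i = 0; i < ne; ++i) {
    fcC[i] = nodeAt(sc.m, sc.y0.back(), evalS[i], sc.simStart, sc.dt, sc.N) / mC0;
    fcS[i] = nodeAt(ss.m, ss.y0.back(), evalS[i], ss.simStart, ss.dt, ss.N) / mS0;
    if (!std::isfinite(fcC[i]) || !std::isfinite(fcS[i])) return SENTINEL;
    mn = std::min(mn, std::min(fcC[i], fcS[i]));
    mx = std::max(mx, std::max(fcC[i], fcS[i]));
  }
  double rg = mx - mn;
  if (!(rg > 0.0)) return SENTINEL;

  const std::vector<double>& fcT = (target == 0) ? fcC : fcS;
  const double* dat = (target == 0) ? REAL(dataNormC) : REAL(dataNormS);
  double sum = 0.0;
  for (int i = 0; i < ne; ++i) {
    double d = (fcT[i] - mn) / rg - dat[i];
    sum += d * d;
  }
  double obj = std::sqrt(sum / ne);

  if (penalty) {
    const SimNodes& st = (target == 0) ? sc : ss;
    double m0t = (target == 0) ? mC0 : mS0;
    double mStart = nodeAt(st.m, st.y0.back(), tStart, st.simStart, st.dt, st.N);
    obj += std::fabs(1.0 - mStart / m0t) / rg;
  }
  if (!std::isfinite(obj)) return SENTINEL;
  return obj;
}
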