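// Two-feedback-loop biochemical oscillator: 5-state ODE right-hand side and
// an adaptive Dormand-Prince RK5(4) integrator with dense (Hermite) output on
// a fixed grid. Compiled because every viability test of the oscillator costs
// one full integration and explorations need 1e4-1e5 of them.
//
// States: R, Rp (mass action), Xp, Yp, Zp (Michaelis-Menten, totals = 1).
// The positive loop acts through p([Zp]) = k2 + k11*[Zp] (activation of R
// phosphorylation), the negative loop through n([Yp]) = k3 + k12*[Yp]
// (degradation of Rp). Loop perturbation modes support essentiality
// classification: 0 = intact, 1 = removed (feedback rate constant set to 0),
// 2 = frozen (feedback function replaced by a supplied constant).

#include <Rcpp.h>
#include <cmath>

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

namespace {

struct OscSys {
  double k[13];  // 1-based: k[1]..k[12] are the linear-scale rates
  int pos_mode, neg_mode;
  double p_const, n_const;

  inline void rhs(const double* y, double* dy) const {
    const double R = y[0], Rp = y[1], Xp = y[2], Yp = y[3], Zp = y[4];
    double p;
    if (pos_mode == 1) p = k[2];
    else if (pos_mode == 2) p = p_const;
    else p = k[2] + k[11] * Zp;
    double n;
    if (neg_mode == 1) n = k[3];
    else if (neg_mode == 2) n = n_const;
    else n = k[3] + k[12] * Yp;

    dy[0] = k[1] - p * R;
    dy[1] = p * R - n * Rp;
    dy[2] = k[4] * Rp * (1.0 - Xp) / (k[10] + 1.0 - Xp) -
            k[5] * Xp / (k[10] + Xp);
    dy[3] = k[6] * Xp * (1.0 - Yp) / (k[10] + 1.0 - Yp) -
            k[7] * Yp / (k[10] + Yp);
    dy[4] = k[8] * Rp * (1.0 - Zp) / (k[10] + 1.0 - Zp) -
            k[9] * Zp / (k[10] + Zp);
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

}  // namespace

namespace {

// analytic Jacobian of the 5-state system (autonomous)
void osc_jac(const OscSys& sys, const double* y, double J[5][5]) {
  const double R = y[0], Rp = y[1], Xp = y[2], Yp = y[3], Zp = y[4];
  const double* k = sys.k;
  double p, dp_dZ;
  if (sys.pos_mode == 1) { p = k[2]; dp_dZ = 0.0; }
  else if (sys.pos_mode == 2) { p = sys.p_const; dp_dZ = 0.0; }
  else { p = k[2] + k[11] * Zp; dp_dZ = k[11]; }
  double n, dn_dY;
  if (sys.neg_mode == 1) { n = k[3]; dn_dY = 0.0; }
  else if (sys.neg_mode == 2) { n = sys.n_const; dn_dY = 0.0; }
  else { n = k[3] + k[12] * Yp; dn_dY = k[12]; }

  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) J[i][j] = 0.0;

  J[0][0] = -p;
  J[0][4] = -dp_dZ * R;
  J[1][0] = p;
  J[1][1] = -n;
  J[1][3] = -dn_dY * Rp;
  J[1][4] = dp_dZ * R;

  double dX1 = k[10] + 1.0 - Xp, dX2 = k[10] + Xp;
  J[2][1] = k[4] * (1.0 - Xp) / dX1;
  J[2][2] = -k[4] * Rp * k[10] / (dX1 * dX1) - k[5] * k[10] / (dX2 * dX2);

  double dY1 = k[10] + 1.0 - Yp, dY2 = k[10] + Yp;
  J[3][2] = k[6] * (1.0 - Yp) / dY1;
  J[3][3] = -k[6] * Xp * k[10] / (dY1 * dY1) - k[7] * k[10] / (dY2 * dY2);

  double dZ1 = k[10] + 1.0 - Zp, dZ2 = k[10] + Zp;
  J[4][1] = k[8] * (1.0 - Zp) / dZ1;
  J[4][4] = -k[8] * Rp * k[10] / (dZ1 * dZ1) - k[9] * k[10] / (dZ2 * dZ2);
}

// LU factorization with partial pivoting of a 5x5 matrix
bool lu5(double A[5][5], int piv[5]) {
  for (int i = 0; i < 5; ++i) piv[i] = i;
  for (int c = 0; c < 5; ++c) {
    int pr = c;
    double mx = std::fabs(A[c][c]);
    for (int r = c + 1; r < 5; ++r)
      if (std::fabs(A[r][c]) > mx) { mx = std::fabs(A[r][c]); pr = r; }
    if (mx == 0.0) return false;
    if (pr != c) {
      for (int j = 0; j < 5; ++j) std::swap(A[c][j], A[pr][j]);
      std::swap(piv[c], piv[pr]);
    }
    for (int r = c + 1; r < 5; ++r) {
      A[r][c] /= A[c][c];
      for (int j = c + 1; j < 5; ++j) A[r][j] -= A[r][c] * A[c][j];
    }
  }
  return true;
}

void lu5_solve(const double A[5][5], const int piv[5], const double b[5],
               double x[5]) {
  double y[5];
  for (int i = 0; i < 5; ++i) y[i] = b[piv[i]];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < i; ++j) y[i] -= A[i][j] * y[j];
  for (int i = 4; i >= 0; --i) {
    for (int j = i + 1; j < 5; ++j) y[i] -= A[i][j] * y[j];
    y[i] /= A[i][i];
  }
  for (int i = 0; i < 5; ++i) x[i] = y[i];
}

struct Sdirk {
  // Alexander's 3-stage, order-3, L-stable, stiffly accurate SDIRK
  double gam, a21, b1, b2;
  const OscSys* sys;
  double W[5][5];
  int piv[5];

  Sdirk(const OscSys* s) : sys(s) {
    gam = 0.435866521508459;
    a21 = (1.0 - gam) / 2.0;
    b1 = -1.5 * gam * gam + 4.0 * gam - 0.25;
    b2 = 1.5 * gam * gam - 5.0 * gam + 1.25;
  }

  bool factor(const double* y, double h) {
    double J[5][5];
    osc_jac(*sys, y, J);
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j)
        W[i][j] = (i == j ? 1.0 : 0.0) - h * gam * J[i][j];
    return lu5(W, piv);
  }

  // solve one stage: Y = rhs + h*gam*f(Y), Newton with the frozen W
  bool stage(const double* rhs, double h, double* Y, double* fY,
             double atol, double rtol) {
    for (int it = 0; it < 12; ++it) {
      sys->rhs(Y, fY);
      double G[5], dY[5];
      for (int i = 0; i < 5; ++i) G[i] = rhs[i] + h * gam * fY[i] - Y[i];
      lu5_solve(W, piv, G, dY);
      double nrm = 0.0;
      for (int i = 0; i < 5; ++i) {
        double sc = atol + rtol * std::fabs(Y[i]);
        double r = dY[i] / sc;
        nrm += r * r;
        Y[i] += dY[i];
      }
      if (!std::isfinite(nrm)) return false;
      if (std::sqrt(nrm / 5.0) < 0.05) {
        sys->rhs(Y, fY);
        return true;
      }
    }
    return false;
  }

  // one SDIRK step of size h from y (W must be factored for this h)
  bool step(const double* y, double h, double* ynew, double atol,
            double rtol) {
    double Y1[5], Y2[5], Y3[5], f1[5], f2[5], f3[5], rhs[5];
    for (int i = 0; i < 5; ++i) { rhs[i] = y[i]; Y1[i] = y[i]; }
    if (!stage(rhs, h, Y1, f1, atol, rtol)) return false;
    for (int i = 0; i < 5; ++i) {
      rhs[i] = y[i] + h * a21 * f1[i];
      Y2[i] = Y1[i];
    }
    if (!stage(rhs, h, Y2, f2, atol, rtol)) return false;
    for (int i = 0; i < 5; ++i) {
      rhs[i] = y[i] + h * (b1 * f1[i] + b2 * f2[i]);
      Y3[i] = Y2[i];
    }
    if (!stage(rhs, h, Y3, f3, atol, rtol)) return false;
    for (int i = 0; i < 5; ++i) ynew[i] = Y3[i];  // stiffly accurate
    return true;
  }
};

}  // namespace

// L-stable SDIRK3 with step-doubling error control; used as the fallback
// when the explicit integrator stalls on stiff parameter combinations.
// [[Rcpp::export(name = ".osc_integrate_sdirk_cpp")]]
Rcpp::List osc_integrate_sdirk_cpp(NumericVector ktilde, double t_end,
                                   double t_record, double dt_out,
                                   double rtol, double atol, int max_steps,
                                   int pos_mode, double p_const, int neg_mode,
                                   double n_const, NumericVector y0) {
  const int D = 5;
  OscSys sys;
  for (int i = 0; i < 12; ++i) sys.k[i + 1] = ktilde[i];
  sys.pos_mode = pos_mode;
  sys.neg_mode = neg_mode;
  sys.p_const = p_const;
  sys.n_const = n_const;
  Sdirk integ(&sys);

  const int n_out =
      static_cast<int>(std::floor((t_end - t_record) / dt_out + 1e-9)) + 1;
  NumericVector t_out(n_out);
  NumericMatrix y_out(n_out, D);
  for (int i = 0; i < n_out; ++i) t_out[i] = t_record + i * dt_out;
  int next_out = 0;

  double y[D], y_big[D], y_half[D], y2[D], f0[D], f2[D];
  for (int i = 0; i < D; ++i) y[i] = y0[i];
  double t = 0.0, h = 1e-3;
  const double hmin = 1e-12, hmax = 0.5;
  bool success = true;
  int step = 0;

  for (; step < max_steps && t < t_end; ++step) {
    if (t + h > t_end) h = t_end - t;
    bool ok = integ.factor(y, h) &&
              integ.step(y, h, y_big, atol, rtol);
    if (ok) {
      ok = integ.factor(y, h / 2) &&
           integ.step(y, h / 2, y_half, atol, rtol) &&
           integ.step(y_half, h / 2, y2, atol, rtol);
    }
    if (!ok) {
      h /= 4;
      if (h < hmin) { success = false; break; }
      continue;
    }
    double errnorm = 0.0;
    for (int i = 0; i < D; ++i) {
      double e = (y2[i] - y_big[i]) / 7.0;  // order 3: 2^3 - 1
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y2[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / D);
    if (!std::isfinite(errnorm)) { success = false; break; }

    if (errnorm <= 1.0) {
      double tnew = t + h;
      sys.rhs(y, f0);
      sys.rhs(y2, f2);
      while (next_out < n_out && t_out[next_out] <= tnew + 1e-12) {
        double s = (t_out[next_out] - t) / h;
        double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
        double h10 = s * (1 - s) * (1 - s);
        double h01 = s * s * (3 - 2 * s);
        double h11 = s * s * (s - 1);
        for (int i = 0; i < D; ++i)
          y_out(next_out, i) =
              h00 * y[i] + h10 * h * f0[i] + h01 * y2[i] + h11 * h * f2[i];
        ++next_out;
      }
      t = tnew;
      for (int i = 0; i < D; ++i) y[i] = y2[i];
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.25);
      h *= std::min(4.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.25);
      h *= std::max(0.1, fac);
      if (h < hmin) { success = false; break; }
    }
  }
  if (t < t_end - 1e-9) success = false;

  return Rcpp::List::create(
      Rcpp::Named("t") = t_out, Rcpp::Named("y") = y_out,
      Rcpp::Named("success") = success, Rcpp::Named("steps") = step,
      Rcpp::Named("filled") = next_out);
}

// [[Rcpp::export(name = ".osc_integrate_cpp")]]
Rcpp::List osc_integrate_cpp(NumericVector ktilde, double t_end,
                             double t_record, double dt_out, double rtol,
                             double atol, int max_steps, int pos_mode,
                             double p_const, int neg_mode, double n_const,
                             NumericVector y0) {
  const int D = 5;
  OscSys sys;
  for (int i = 0; i < 12; ++i) sys.k[i + 1] = ktilde[i];
  sys.pos_mode = pos_mode;
  sys.neg_mode = neg_mode;
  sys.p_const = p_const;
  sys.n_const = n_const;

  const int n_out = static_cast<int>(std::floor((t_end - t_record) / dt_out + 1e-9)) + 1;
  NumericVector t_out(n_out);
  NumericMatrix y_out(n_out, D);
  for (int i = 0; i < n_out; ++i) t_out[i] = t_record + i * dt_out;
  int next_out = 0;

  double y[D], ynew[D], k1v[D], k2v[D], k3v[D], k4v[D], k5v[D], k6v[D],
      k7v[D], ytmp[D], yerr[D];
  for (int i = 0; i < D; ++i) y[i] = y0[i];

  double t = 0.0, h = 1e-4;
  const double hmin = 1e-12, hmax = 1.0;
  bool success = true;
  sys.rhs(y, k1v);  // FSAL

  int step = 0;
  for (; step < max_steps && t < t_end; ++step) {
    if (t + h > t_end) h = t_end - t;

    for (int i = 0; i < D; ++i) ytmp[i] = y[i] + h * a21 * k1v[i];
    sys.rhs(ytmp, k2v);
    for (int i = 0; i < D; ++i)
      ytmp[i] = y[i] + h * (a31 * k1v[i] + a32 * k2v[i]);
    sys.rhs(ytmp, k3v);
    for (int i = 0; i < D; ++i)
      ytmp[i] = y[i] + h * (a41 * k1v[i] + a42 * k2v[i] + a43 * k3v[i]);
    sys.rhs(ytmp, k4v);
    for (int i = 0; i < D; ++i)
      ytmp[i] = y[i] + h * (a51 * k1v[i] + a52 * k2v[i] + a53 * k3v[i] +
                            a54 * k4v[i]);
    sys.rhs(ytmp, k5v);
    for (int i = 0; i < D; ++i)
      ytmp[i] = y[i] + h * (a61 * k1v[i] + a62 * k2v[i] + a63 * k3v[i] +
                            a64 * k4v[i] + a65 * k5v[i]);
    sys.rhs(ytmp, k6v);
    for (int i = 0; i < D; ++i)
      ynew[i] = y[i] + h * (b1 * k1v[i] + b3 * k3v[i] + b4 * k4v[i] +
                            b5 * k5v[i] + b6 * k6v[i]);
    sys.rhs(ynew, k7v);
    for (int i = 0; i < D; ++i)
      yerr[i] = h * (e1 * k1v[i] + e3 * k3v[i] + e4 * k4v[i] + e5 * k5v[i] +
                     e6 * k6v[i] + e7 * k7v[i]);

    double errnorm = 0.0;
    for (int i = 0; i < D; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = yerr[i] / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / D);
    if (!std::isfinite(errnorm)) { success = false; break; }

    if (errnorm <= 1.0) {
      // accepted: dense output via cubic Hermite on [t, t+h]
      double tnew = t + h;
      while (next_out < n_out && t_out[next_out] <= tnew + 1e-12) {
        double s = (t_out[next_out] - t) / h;
        double h00 = (1 + 2 * s) * (1 - s) * (1 - s);
        double h10 = s * (1 - s) * (1 - s);
        double h01 = s * s * (3 - 2 * s);
        double h11 = s * s * (s - 1);
        for (int i = 0; i < D; ++i)
          y_out(next_out, i) = h00 * y[i] + h10 * h * k1v[i] + h01 * ynew[i] +
                               h11 * h * k7v[i];
        ++next_out;
      }
      t = tnew;
      for (int i = 0; i < D; ++i) { y[i] = ynew[i]; k1v[i] = k7v[i]; }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
      if (h > hmax) h = hmax;
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.1, fac);
    }
    if (h < hmin) { success = false; break; }
  }
  if (t < t_end - 1e-9) success = false;

  return Rcpp::List::create(
      Rcpp::Named("t") = t_out, Rcpp::Named("y") = y_out,
      Rcpp::Named("success") = success, Rcpp::Named("steps") = step,
      Rcpp::Named("filled") = next_out);
}
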