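#ifndef PORECV_FULLPATH_H
#define PORECV_FULLPATH_H

#include <cmath>
#include <algorithm>
#include <vector>

// Role codes shared with R: 0 = head, 1 = tail, 2 = terminal_tail, 3 = water.

namespace porecv {

struct CVParams {
  double rcyl;     // cylinder radius (nm)
  double cv_eq;    // equilibrium soft count in the cylinder
  double cv0;      // switching threshold
  double alpha;    // switching rate
  double r_unit;   // pore radius unit (nm)
  double beta;     // soft-minimum sharpness (nm)
  int    nexp;     // rational membership exponents (n, m)
  int    mexp;
  double dfloor;   // distance floor inside the soft minimum (nm)
};

struct CVResult {
  double value, cv_cyl, cv_radius, d, r_soft, s1, s2;
};

// branch-based minimum image (fast path for wrapped coordinates, where
// |dx| < L always holds), with an exact rounding fallback for stray inputs
inline double min_image(double dx, double L) {
  if (dx > 0.5 * L) {
    dx -= L;
    if (dx > 0.5 * L) dx -= L * std::round(dx / L);
  } else if (dx < -0.5 * L) {
    dx += L;
    if (dx < -0.5 * L) dx -= L * std::round(dx / L);
  }
  return dx;
}

// smoothly decaying rational membership w(rho) with w(0) = 1 and
// w(rcyl) = n/m; for m = 2n the form reduces exactly to 1/(1 + x^n)
inline void rational_membership(double rho, double rcyl, int n, int m,
                                double &w, double &dwdrho) {
  double x = rho / rcyl;
  if (m == 2 * n) {
    double xn = std::pow(x, n);
    double denom = 1.0 + xn;
    w = 1.0 / denom;
    double dxn = (x > 0.0) ? n * std::pow(x, n - 1) : 0.0;
    dwdrho = -dxn / (denom * denom) / rcyl;
  } else {
    double xn = std::pow(x, n), xm = std::pow(x, m);
    if (std::fabs(1.0 - xm) < 1e-9) {
      w = double(n) / m;                       // l'Hopital limit at x = 1
      dwdrho = n * double(n - m) / (2.0 * m) / rcyl;
    } else {
      w = (1.0 - xn) / (1.0 - xm);
      double dnum = (x > 0.0) ? -n * std::pow(x, n - 1) : 0.0;
      double dden = (x > 0.0) ? -m * std::pow(x, m - 1) : 0.0;
      dwdrho = (dnum * (1.0 - xm) - dden * (1.0 - xn)) /
               ((1.0 - xm) * (1.0 - xm)) / rcyl;
    }
  }
}

// numerically stable logistic switching pair; s1 decreasing, s1 + s2 = 1
inline void switching(double x, double cv0, double alpha,
                      double &s1, double &s2) {
  double a = alpha * (x - cv0);
  if (a > 0.0) {
    double e = std::exp(-a);
    s1 = e / (1.0 + e);
  } else {
    s1 = 1.0 / (1.0 + std::exp(a));
  }
  s2 = 1.0 - s1;
}

// Joint Full-Path CV over tail-role beads. px/py point at the x and y
// coordinates (stride 1); gx/gy (may be null) receive d(value)/d(x_i),
// d(value)/d(y_i); the z-gradient is identically zero because the cylinder
// spans the box and distances are in-plane. Water and head beads get zero
// gradient. Returns every component. n_sel_out reports the tail selection
// size (caller errors when 0).
inline CVResult fullpath_eval(const double *px, const double *py, int n,
                              const int *roles, double Lx, double Ly,
                              double cx, double cy, const CVParams &p,
                              double *gx, double *gy, int *n_sel_out) {
  CVResult out;
  int n_sel = 0;
  double d = 0.0;
  double emax = -1e300;
  // first pass: distances, membership sum, soft-min exponent maximum;
  // scratch buffers persist across calls (hot path of biased dynamics)
  static thread_local std::vector<double> rho, dx, dy, wd, ddist;
  rho.assign(n, 0.0); dx.assign(n, 0.0); dy.assign(n, 0.0);
  wd.assign(n, 0.0); ddist.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (roles[i] != 1 && roles[i] != 2) { rho[i] = -1.0; continue; }
    ++n_sel;
    double ddx = min_image(px[i] - cx, Lx);
    double ddy = min_image(py[i] - cy, Ly);
    double r = std::sqrt(ddx * ddx + ddy * ddy);
    rho[i] = r; dx[i] = ddx; dy[i] = ddy;
    double w, dw;
    rational_membership(r, p.rcyl, p.nexp, p.mexp, w, dw);
    d += w; wd[i] = dw;
    double dist = std::max(r, p.dfloor);
    ddist[i] = dist;
    emax = std::max(emax, p.beta / dist);
  }
  *n_sel_out = n_sel;
  if (n_sel == 0) { out = CVResult{0, 0, 0, 0, 0, 0, 0}; return out; }

  double S = 0.0;
  for (int i = 0; i < n; ++i)
    if (rho[i] >= 0.0) S += std::exp(p.beta / ddist[i] - emax);
  double L = emax + std::log(S);
  double r_soft = p.beta / L;

  double cv_cyl = 1.0 - d / p.cv_eq;
  double cv_radius = r_soft / p.r_unit;
  double s1, s2;
  switching(cv_radius, p.cv0, p.alpha, s1, s2);
  double value = s1 * cv_cyl + s2 * cv_radius;

  if (gx && gy) {
    double ds1dx = -p.alpha * s1 * s2;         // d s1 / d cv_radius
    double coef_cyl = s1;                      // multiplies grad cv_cyl
    double coef_rad = s2 + (cv_cyl - cv_radius) * ds1dx;
    for (int i = 0; i < n; ++i) {
      if (rho[i] < 0.0) { gx[i] = 0.0; gy[i] = 0.0; continue; }
      double gxx = 0.0, gyy = 0.0;
      if (rho[i] > 1e-9) {
        double ux = dx[i] / rho[i], uy = dy[i] / rho[i];
        // cylinder-count part: d cv_cyl/d rho = -w'(rho)/cv_eq
        double gc = -wd[i] / p.cv_eq;
        // soft-min part: d r_soft/d d_i = p_i (r_soft/d_i)^2, zero if floored
        double gr = 0.0;
        if (rho[i] > p.dfloor) {
          double pi_w = std::exp(p.beta / ddist[i] - emax) / S;
          gr = pi_w * (r_soft / ddist[i]) * (r_soft / ddist[i]) / p.r_unit;
        }
        double dvdrho = coef_cyl * gc + coef_rad * gr;
        gxx = dvdrho * ux; gyy = dvdrho * uy;
      }
      gx[i] = gxx; gy[i] = gyy;
    }
  }
  out.value = value; out.cv_cyl = cv_cyl; out.cv_radius = cv_radius;
  out.d = d; out.r_soft = r_soft; out.s1 = s1; out.s2 = s2;
  return out;
}

} // namespace porecv

#endif
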