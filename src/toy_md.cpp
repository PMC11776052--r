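#include <Rcpp.h>
#include <random>
#include <map>
#include <string>
#include "fullpath.h"

using namespace Rcpp;

// Implicit-solvent bead-lipid model (Cooke-style): WCA repulsion between all
// lipid beads, a broadened cos^2 tail-tail attraction, FENE bonds along each
// lipid, and a harmonic head-to-terminal straightening spring. Water beads
// are decorative markers for observables and carry no interactions here.

namespace {

struct FF {
  double sigma, head_factor, bond_k, bond_rinf, bend_k;
  double eps_attr, w_attr, eps_rep, overlap_floor;
};

FF ff_from_list(const List &l) {
  FF f;
  f.sigma = as<double>(l["bead_diameter"]);
  f.head_factor = as<double>(l["head_diameter_factor"]);
  f.bond_k = as<double>(l["bond_stiffness"]);
  f.bond_rinf = as<double>(l["bond_length"]);
  f.bend_k = as<double>(l["bend_stiffness"]);
  f.eps_attr = as<double>(l["tail_attraction_eps"]);
  f.w_attr = as<double>(l["tail_attraction_range"]);
  f.eps_rep = as<double>(l["repulsion_eps"]);
  f.overlap_floor = as<double>(l["overlap_floor"]);
  return f;
}

struct Topology {
  std::vector<int> b1, b2;    // FENE bonds
  std::vector<int> a1, a2;    // head..terminal straightening pairs
};

Topology build_topology(const IntegerVector &lipid_ids) {
  Topology t;
  std::map<int, std::vector<int>> lip;
  for (int i = 0; i < lipid_ids.size(); ++i)
    if (lipid_ids[i] != NA_INTEGER) lip[lipid_ids[i]].push_back(i);
  for (auto &kv : lip) {
    const std::vector<int> &idx = kv.second;
    for (size_t j = 0; j + 1 < idx.size(); ++j) {
      t.b1.push_back(idx[j]); t.b2.push_back(idx[j + 1]);
    }
    if (idx.size() >= 3) {
      t.a1.push_back(idx.front()); t.a2.push_back(idx.back());
    }
  }
  return t;
}

inline double mi(double d, double L) { return porecv::min_image(d, L); }

// Verlet pair list over non-water particles within `rlist`
struct NeighborList {
  std::vector<int> pi, pj;
  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const IntegerVector &roles,
             double Lx, double Ly, double Lz, double rlist) {
    pi.clear(); pj.clear();
    int n = x.size();
    double r2l = rlist * rlist;
    for (int i = 0; i < n; ++i) {
      if (roles[i] == 3) continue;
      for (int j = i + 1; j < n; ++j) {
        if (roles[j] == 3) continue;
        double dx = mi(x[i] - x[j], Lx);
        double dy = mi(y[i] - y[j], Ly);
        double dz = mi(z[i] - z[j], Lz);
        if (dx * dx + dy * dy + dz * dz < r2l) { pi.push_back(i); pj.push_back(j); }
      }
    }
  }
};

// Pair + bonded energy and forces. term_on[0..3] = repulsion, attraction,
// bonds, bends. Positions may be scaled along y via `sy` (used for the
// piston finite difference); forces are only accumulated when fx != null.
// When `nl` is given, only its pairs are visited (they must cover the
// interaction cutoff).
double ff_energy_forces(const std::vector<double> &x,
                        const std::vector<double> &y,
                        const std::vector<double> &z,
                        const IntegerVector &roles, const Topology &top,
                        double Lx, double Ly, double Lz, const FF &f,
                        const bool term_on[4], double term_e[4],
                        std::vector<double> *fx, std::vector<double> *fy,
                        std::vector<double> *fz, double sy = 1.0,
                        const NeighborList *nl = nullptr) {
  int n = x.size();
  for (int k = 0; k < 4; ++k) term_e[k] = 0.0;
  const double RC126 = 1.1224620483093730;     // 2^(1/6)
  double rc_att = RC126 * f.sigma;
  double cut_att = rc_att + f.w_attr;
  double cut2 = cut_att * cut_att;
  double Lys = Ly * sy;
  std::vector<double> sig(n);
  std::vector<char> tailf(n);
  for (int i = 0; i < n; ++i) {
    sig[i] = (roles[i] == 0) ? f.sigma * f.head_factor : f.sigma;
    tailf[i] = (roles[i] == 1 || roles[i] == 2);
  }
  std::vector<int> act;
  if (!nl) {
    act.reserve(n);
    for (int i = 0; i < n; ++i) if (roles[i] != 3) act.push_back(i);
  }
  size_t n_pairs = nl ? nl->pi.size()
                      : (act.size() ? act.size() * (act.size() - 1) / 2 : 0);
  size_t a = 0, b = 1;
  for (size_t p = 0; p < n_pairs; ++p) {
    int i, j;
    if (nl) { i = nl->pi[p]; j = nl->pj[p]; }
    else {
      i = act[a]; j = act[b];
      if (++b >= act.size()) { ++a; b = a + 1; }
    }
    double dx = mi(x[i] - x[j], Lx);
    double dy = mi((y[i] - y[j]) * sy, Lys);
    double dz = mi(z[i] - z[j], Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) continue;
    double sij = 0.5 * (sig[i] + sig[j]);
    if (r2 < f.overlap_floor * f.overlap_floor * sij * sij)
      stop("particle overlap below the hard floor (r = %f nm)", std::sqrt(r2));
    double dvdr = 0.0;
    double r = 0.0;
    if (term_on[0]) {
      double rc2 = RC126 * RC126 * sij * sij;
      if (r2 < rc2) {
        double inv = sij * sij / r2;
        double s6 = inv * inv * inv, s12 = s6 * s6;
        term_e[0] += 4.0 * f.eps_rep * (s12 - s6) + f.eps_rep;
        r = std::sqrt(r2);
        dvdr += 4.0 * f.eps_rep * (-12.0 * s12 + 6.0 * s6) / r;
      }
    }
    if (term_on[1] && tailf[i] && tailf[j]) {
      if (r == 0.0) r = std::sqrt(r2);
      if (r < rc_att) {
        term_e[1] += -f.eps_attr;
      } else if (r < cut_att) {
        // smooth quartic shoulder -eps (1 - u^2)^2: depth eps at the
        // plateau edge, zero value and slope at the cutoff, C1 at both
        // ends (same contract and nearly the same shape as a cos^2
        // shoulder, at a fraction of the cost)
        double u = (r - rc_att) / f.w_attr;
        double q = 1.0 - u * u;
        term_e[1] += -f.eps_attr * q * q;
        dvdr += 4.0 * f.eps_attr * u * q / f.w_attr;
      }
    }
    if (dvdr != 0.0 && fx) {
      double fac = -dvdr / r;
      (*fx)[i] += fac * dx; (*fx)[j] -= fac * dx;
      (*fy)[i] += fac * dy * sy; (*fy)[j] -= fac * dy * sy;
      (*fz)[i] += fac * dz; (*fz)[j] -= fac * dz;
    }
  }
  if (term_on[2]) {
    for (size_t b = 0; b < top.b1.size(); ++b) {
      int i = top.b1[b], j = top.b2[b];
      double dx = mi(x[i] - x[j], Lx);
      double dy = mi((y[i] - y[j]) * sy, Lys);
      double dz = mi(z[i] - z[j], Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double q = r / f.bond_rinf;
      if (q >= 0.98) stop("bond overstretched (r = %f nm); integration blew up", r);
      term_e[2] += -0.5 * f.bond_k * f.bond_rinf * f.bond_rinf *
                   std::log(1.0 - q * q);
      double dvdr = f.bond_k * r / (1.0 - q * q);
      if (fx) {
        double fac = -dvdr / r;
        (*fx)[i] += fac * dx; (*fx)[j] -= fac * dx;
        (*fy)[i] += fac * dy * sy; (*fy)[j] -= fac * dy * sy;
        (*fz)[i] += fac * dz; (*fz)[j] -= fac * dz;
      }
    }
  }
  if (term_on[3]) {
    double rest = 4.0 * f.sigma;
    for (size_t b = 0; b < top.a1.size(); ++b) {
      int i = top.a1[b], j = top.a2[b];
      double dx = mi(x[i] - x[j], Lx);
      double dy = mi((y[i] - y[j]) * sy, Lys);
      double dz = mi(z[i] - z[j], Lz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      term_e[3] += 0.5 * f.bend_k * (r - rest) * (r - rest);
      double dvdr = f.bend_k * (r - rest);
      if (fx && r > 1e-12) {
        double fac = -dvdr / r;
        (*fx)[i] += fac * dx; (*fx)[j] -= fac * dx;
        (*fy)[i] += fac * dy * sy; (*fy)[j] -= fac * dy * sy;
        (*fz)[i] += fac * dz; (*fz)[j] -= fac * dz;
      }
    }
  }
  return term_e[0] + term_e[1] + term_e[2] + term_e[3];
}

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector roles,
                       IntegerVector lipid_ids, NumericVector box,
                       List ff, LogicalVector terms) {
  FF f = ff_from_list(ff);
  Topology top = build_topology(lipid_ids);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  bool term_on[4];
  for (int k = 0; k < 4; ++k) term_on[k] = terms[k];
  double term_e[4];
  double e = ff_energy_forces(x, y, z, roles, top, box[0], box[1], box[2], f,
                              term_on, term_e, &fx, &fy, &fz);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(
      _["energy"] = e,
      _["terms"] = NumericVector::create(
          _["repulsion"] = term_e[0], _["attraction"] = term_e[1],
          _["bonds"] = term_e[2], _["bends"] = term_e[3]),
      _["forces"] = F);
}

namespace {

struct FullpathBias {
  bool active = false;
  double kappa = 0.0, c_from = 0.0, c_to = 0.0;
  porecv::CVParams p;
};

struct PistonBias {
  bool active = false;
  double kappa = 0.0, center = 0.0, mobility = 0.0;
  int interval = 10;
};

struct FlatBottomBias {
  bool active = false;
  int axis = 0;
  double k_fb = 1000.0, half_width = 2.5;
};

struct TetherBias {
  bool active = false;
  std::vector<int> idx;
  double k = 0.0;
  double ref[3] = {0, 0, 0};
};

} // namespace

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, IntegerVector roles,
                      IntegerVector lipid_ids, NumericVector box,
                      List ff, List settings, List biases) {
  const double kB = 0.00831446;
  FF f = ff_from_list(ff);
  Topology top = build_topology(lipid_ids);
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double T = as<double>(settings["temperature"]);
  double dt = as<double>(settings["timestep"]);
  double gamma = as<double>(settings["friction"]);
  double mass = as<double>(settings["mass"]);
  long n_steps = as<double>(settings["n_steps"]);
  int rec = as<int>(settings["record_interval"]);
  unsigned long seed = (unsigned long)as<double>(settings["seed"]);

  FullpathBias fp;
  PistonBias piston;
  FlatBottomBias fb;
  TetherBias tether;
  for (int b = 0; b < biases.size(); ++b) {
    List bl = biases[b];
    std::string kind = as<std::string>(bl["kind"]);
    if (kind == "fullpath") {
      fp.active = true;
      fp.kappa = as<double>(bl["kappa"]);
      fp.c_from = as<double>(bl["center_from"]);
      fp.c_to = as<double>(bl["center_to"]);
      List pp = bl["params"];
      fp.p.rcyl = as<double>(pp["r_cyl"]); fp.p.cv_eq = as<double>(pp["cv_eq"]);
      fp.p.cv0 = as<double>(pp["cv0"]); fp.p.alpha = as<double>(pp["alpha"]);
      fp.p.r_unit = as<double>(pp["r_unit"]);
      fp.p.beta = as<double>(pp["softmin_beta"]);
      IntegerVector be = pp["boundary_exponents"];
      fp.p.nexp = be[0]; fp.p.mexp = be[1];
      fp.p.dfloor = as<double>(pp["dist_floor"]);
    } else if (kind == "piston") {
      piston.active = true;
      piston.kappa = as<double>(bl["kappa"]);
      piston.center = as<double>(bl["center"]);
      piston.mobility = as<double>(bl["mobility"]);
      piston.interval = as<int>(bl["interval"]);
    } else if (kind == "flat_bottom") {
      fb.active = true;
      fb.axis = as<int>(bl["axis"]) - 1;
      fb.k_fb = as<double>(bl["k_fb"]);
      fb.half_width = as<double>(bl["half_width"]);
    } else if (kind == "tether") {
      tether.active = true;
      tether.k = as<double>(bl["k"]);
      IntegerVector ii = bl["index"];
      for (int q = 0; q < ii.size(); ++q) tether.idx.push_back(ii[q] - 1);
      NumericVector rr = bl["ref"];
      for (int q = 0; q < 3; ++q) tether.ref[q] = rr[q];
    } else {
      stop("unknown bias kind: %s", kind.c_str());
    }
  }

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fxv(n), fyv(n), fzv(n), gx(n), gy(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double vsig = std::sqrt(kB * T / mass);
  for (int i = 0; i < n; ++i) {
    vx[i] = vsig * gauss(rng); vy[i] = vsig * gauss(rng); vz[i] = vsig * gauss(rng);
  }

  bool term_on[4] = {true, true, true, true};
  double term_e[4];
  porecv::CVResult cvres{0, 0, 0, 0, 0, 0, 0};

  // Verlet list with skin; rebuilt when any particle has moved more than
  // half the skin since the last build (includes piston rescaling moves)
  const double RC126 = 1.1224620483093730;
  const double skin = 0.4;
  double rlist = RC126 * f.sigma + f.w_attr + skin;
  NeighborList nlist;
  std::vector<double> refx(n), refy(n), refz(n);
  auto rebuild_list = [&]() {
    nlist.build(x, y, z, roles, Lx, Ly, Lz, rlist);
    refx = x; refy = y; refz = z;
  };
  auto ensure_list = [&]() {
    double lim2 = (skin / 2) * (skin / 2);
    for (int i = 0; i < n; ++i) {
      double dx = mi(x[i] - refx[i], Lx);
      double dy = mi(y[i] - refy[i], Ly);
      double dz = mi(z[i] - refz[i], Lz);
      if (dx * dx + dy * dy + dz * dz > lim2) { rebuild_list(); return; }
    }
  };
  rebuild_list();

  // center of the cylinder for the Full-Path bias: instantaneous lipid
  // center of geometry in xy (treated as a fixed reference for gradients)
  auto lipid_cog = [&](int axis) {
    double s = 0.0; int m = 0;
    for (int i = 0; i < n; ++i)
      if (roles[i] != 3) {
        s += (axis == 0 ? x[i] : (axis == 1 ? y[i] : z[i])); ++m;
      }
    return m ? s / m : 0.0;
  };

  auto compute_forces = [&](long step) {
    std::fill(fxv.begin(), fxv.end(), 0.0);
    std::fill(fyv.begin(), fyv.end(), 0.0);
    std::fill(fzv.begin(), fzv.end(), 0.0);
    ensure_list();
    ff_energy_forces(x, y, z, roles, top, Lx, Ly, Lz, f, term_on, term_e,
                     &fxv, &fyv, &fzv, 1.0, &nlist);
    if (fp.active) {
      // cylinder axis fixed at the box xy-center (systems are built centered
      // and the bias localizes the pore there)
      double cx = 0.5 * Lx, cy = 0.5 * Ly;
      int n_sel = 0;
      cvres = porecv::fullpath_eval(x.data(), y.data(), n, roles.begin(),
                                    Lx, Ly, cx, cy, fp.p, gx.data(), gy.data(),
                                    &n_sel);
      double frac = n_steps > 0 ? double(step) / double(n_steps) : 0.0;
      double c = fp.c_from + (fp.c_to - fp.c_from) * frac;
      double pref = -fp.kappa * (cvres.value - c);
      for (int i = 0; i < n; ++i) {
        fxv[i] += pref * gx[i]; fyv[i] += pref * gy[i];
      }
    }
    if (fb.active) {
      double com = lipid_cog(fb.axis);
      for (int i = 0; i < n; ++i) {
        if (roles[i] != 0) continue;
        double c = (fb.axis == 0 ? x[i] : (fb.axis == 1 ? y[i] : z[i]));
        double d = c - com;
        double ad = std::fabs(d);
        if (ad > fb.half_width) {
          double fmag = -fb.k_fb * (ad - fb.half_width) * (d > 0 ? 1.0 : -1.0);
          if (fb.axis == 0) fxv[i] += fmag;
          else if (fb.axis == 1) fyv[i] += fmag;
          else fzv[i] += fmag;
        }
      }
    }
    if (tether.active) {
      for (int i : tether.idx) {
        fxv[i] += -tether.k * (x[i] - tether.ref[0]);
        fyv[i] += -tether.k * (y[i] - tether.ref[1]);
        fzv[i] += -tether.k * (z[i] - tether.ref[2]);
      }
    }
  };

  auto wrap_all = [&]() {
    for (int i = 0; i < n; ++i) {
      x[i] -= Lx * std::floor(x[i] / Lx);
      y[i] -= Ly * std::floor(y[i] / Ly);
      z[i] -= Lz * std::floor(z[i] / Lz);
    }
  };

  long n_rec = (rec > 0) ? (n_steps / rec) : 0;
  bool rec_cv = fp.active, rec_piston = piston.active;
  int ncol = 1 + (rec_cv ? 6 : 0) + (rec_piston ? 1 : 0);
  NumericMatrix series(n_rec, ncol);
  List frames(n_rec);
  NumericMatrix frame_boxes(n_rec, 3);

  double c1 = std::exp(-gamma * dt);
  double noise = std::sqrt((1.0 - c1 * c1) * kB * T / mass);

  compute_forces(0);
  long irec = 0;
  for (long step = 1; step <= n_steps; ++step) {
    double hdtm = 0.5 * dt / mass;
    for (int i = 0; i < n; ++i) {     // B
      vx[i] += hdtm * fxv[i]; vy[i] += hdtm * fyv[i]; vz[i] += hdtm * fzv[i];
    }
    for (int i = 0; i < n; ++i) {     // A
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    for (int i = 0; i < n; ++i) {     // O
      vx[i] = c1 * vx[i] + noise * gauss(rng);
      vy[i] = c1 * vy[i] + noise * gauss(rng);
      vz[i] = c1 * vz[i] + noise * gauss(rng);
    }
    for (int i = 0; i < n; ++i) {     // A
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    wrap_all();
    compute_forces(step);             // B
    for (int i = 0; i < n; ++i) {
      vx[i] += hdtm * fxv[i]; vy[i] += hdtm * fyv[i]; vz[i] += hdtm * fzv[i];
    }

    if (piston.active && step % piston.interval == 0) {
      // overdamped piston on the rim-axis (y) edge with affine rescaling;
      // -dU/dLy from a central finite difference of the potential
      double h = 1e-4;
      double ep, em;
      double te[4];
      ensure_list();
      ep = ff_energy_forces(x, y, z, roles, top, Lx, Ly, Lz, f, term_on, te,
                            nullptr, nullptr, nullptr, 1.0 + h, &nlist);
      em = ff_energy_forces(x, y, z, roles, top, Lx, Ly, Lz, f, term_on, te,
                            nullptr, nullptr, nullptr, 1.0 - h, &nlist);
      double dUdL = (ep - em) / (2.0 * h * Ly);
      double Fgen = -dUdL - piston.kappa * (Ly - piston.center);
      double dtp = piston.interval * dt;
      double dL = piston.mobility * dtp * Fgen +
                  std::sqrt(2.0 * kB * T * piston.mobility * dtp) * gauss(rng);
      double smax = 0.005;            // cap a single piston move at 0.5%
      dL = std::max(-smax * Ly, std::min(smax * Ly, dL));
      double sc = (Ly + dL) / Ly;
      for (int i = 0; i < n; ++i) y[i] *= sc;
      Ly *= sc;
    }

    if (rec > 0 && step % rec == 0 && irec < n_rec) {
      if (!std::isfinite(x[0]) || !std::isfinite(fxv[0]))
        stop("non-finite coordinates at step %ld; integration blew up", step);
      int col = 0;
      series(irec, col++) = step * dt;
      if (rec_cv) {
        series(irec, col++) = cvres.value;
        series(irec, col++) = cvres.cv_cyl;
        series(irec, col++) = cvres.cv_radius;
        series(irec, col++) = cvres.s1;
        series(irec, col++) = cvres.s2;
        double frac = double(step) / double(n_steps);
        series(irec, col++) = fp.c_from + (fp.c_to - fp.c_from) * frac;
      }
      if (rec_piston) series(irec, col++) = Ly;
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i]; }
      frames[irec] = fr;
      frame_boxes(irec, 0) = Lx; frame_boxes(irec, 1) = Ly; frame_boxes(irec, 2) = Lz;
      ++irec;
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinates at end of run; integration blew up");

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = z[i]; }
  CharacterVector cn(ncol);
  int col = 0;
  cn[col++] = "time";
  if (rec_cv) {
    cn[col++] = "cv"; cn[col++] = "cv_cyl"; cn[col++] = "cv_radius";
    cn[col++] = "s1"; cn[col++] = "s2"; cn[col++] = "bias_center";
  }
  if (rec_piston) cn[col++] = "box_rim";
  colnames(series) = cn;
  return List::create(
      _["positions"] = fin,
      _["box"] = NumericVector::create(Lx, Ly, Lz),
      _["series"] = series,
      _["frames"] = frames,
      _["frame_boxes"] = frame_boxes);
}
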