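#include <Rcpp.h>
#include "fullpath.h"

using namespace Rcpp;

static porecv::CVParams params_from_list(const List &p) {
  porecv::CVParams out;
  out.rcyl = as<double>(p["r_cyl"]);
  out.cv_eq = as<double>(p["cv_eq"]);
  out.cv0 = as<double>(p["cv0"]);
  out.alpha = as<double>(p["alpha"]);
  out.r_unit = as<double>(p["r_unit"]);
  out.beta = as<double>(p["softmin_beta"]);
  IntegerVector be = p["boundary_exponents"];
  out.nexp = be[0]; out.mexp = be[1];
  out.dfloor = as<double>(p["dist_floor"]);
  return out;
}

// [[Rcpp::export]]
List cpp_fullpath_cv(NumericMatrix pos, IntegerVector roles,
                     NumericVector box, NumericVector center,
                     List params, bool gradient) {
  int n = pos.nrow();
  porecv::CVParams p = params_from_list(params);
  std::vector<double> gx, gy;
  double *gxp = nullptr, *gyp = nullptr;
  if (gradient) {
    gx.assign(n, 0.0); gy.assign(n, 0.0);
    gxp = gx.data(); gyp = gy.data();
  }
  int n_sel = 0;
  porecv::CVResult r = porecv::fullpath_eval(
      &pos(0, 0), &pos(0, 1), n, roles.begin(), box[0], box[1],
      center[0], center[1], p, gxp, gyp, &n_sel);
  if (n_sel == 0) stop("configuration contains no tail-role beads");
  List out = List::create(
      _["value"] = r.value, _["cv_cyl"] = r.cv_cyl,
      _["cv_radius"] = r.cv_radius, _["d"] = r.d, _["r_soft"] = r.r_soft,
      _["s1"] = r.s1, _["s2"] = r.s2);
  if (gradient) {
    NumericMatrix g(n, 3);
    for (int i = 0; i < n; ++i) { g(i, 0) = gx[i]; g(i, 1) = gy[i]; }
    out["gradient"] = g;
  }
  return out;
}
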