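#include <Rcpp.h>
#include <vector>
#include "pt_likelihood.h"
using namespace Rcpp;

// One No-U-Turn transition on the joint non-centered state
// theta = (group means m[8], log group SDs v[8], whitened individuals u[n x 8]).
// Diagonal mass given through inv_sd (sqrt of inverse mass); coordinates with
// inv_sd == 0 are frozen. Uses R's RNG, so draws are reproducible under
// set.seed(). Returns the new state, its per-participant log-likelihoods and
// the mean Metropolis acceptance statistic of the trajectory.

namespace {

struct Model {
  const double *gain, *loss, *guar, *sout;
  const double *lg, *llo, *lgu;
  const int *choice, *starts;
  int n;                      // participants
  const double *loc, *scl, *A;
  bool fixed_sd;
  double floor_eps;
  int npar() const { return 16 + 8 * n; }

  // log target and gradient; returns false on non-finite density
  bool eval(const std::vector<double>& th, double& lp,
            std::vector<double>& g, std::vector<double>& lls) const {
    const double* m = th.data();
    const double* v = th.data() + 8;
    double sv[8];
    for (int j = 0; j < 8; ++j) sv[j] = std::exp(v[j]);
    lp = 0.0;
    std::fill(g.begin(), g.end(), 0.0);
    double z[8], gi[8], uij[8];
    for (int i = 0; i < n; ++i) {
      // the individuals block is column-major (R matrix layout):
      // coordinate j of participant i sits at 16 + j*n + i
      for (int j = 0; j < 8; ++j) {
        uij[j] = th[16 + j * n + i];
        z[j] = m[j] + sv[j] * uij[j];
      }
      double ll = pt_ll_grad(gain + starts[i], loss + starts[i],
                             guar + starts[i], choice + starts[i],
                             sout + starts[i], starts[i + 1] - starts[i],
                             z, floor_eps, gi,
                             lg + starts[i], llo + starts[i],
                             lgu + starts[i]);
      if (!std::isfinite(ll)) return false;
      lls[i] = ll;
      lp += ll;
      for (int j = 0; j < 8; ++j) {
        g[j] += gi[j];                         // d/dm
        g[8 + j] += gi[j] * sv[j] * uij[j];    // d/dv (likelihood part)
        g[16 + j * n + i] = gi[j] * sv[j] - uij[j];
        lp += -0.5 * uij[j] * uij[j];
      }
    }
    for (int j = 0; j < 8; ++j) {
      double d = m[j] - loc[j];
      lp += -0.5 * d * d / (scl[j] * scl[j]) - std::log(scl[j]);
      g[j] += -d / (scl[j] * scl[j]);
      if (!fixed_sd) {
        // half-Cauchy prior on s plus the log Jacobian of s = exp(v)
        lp += std::log(2.0) - std::log(M_PI) - std::log(A[j]) -
              log1p((sv[j] / A[j]) * (sv[j] / A[j])) + v[j];
        g[8 + j] += -2.0 * sv[j] * sv[j] / (A[j] * A[j] + sv[j] * sv[j]) + 1.0;
      } else {
        g[8 + j] = 0.0;
      }
    }
    return std::isfinite(lp);
  }
};

struct PState {
  std::vector<double> th, p, g, lls;
  double lp, joint;
};

struct Tree {
  bool ok;
  PState minus, plus, prop;
  double nvalid, dsum;
  int ntot;
  bool has_prop;
};

class Nuts {
public:
  const Model& mod;
  const std::vector<double>& eps;
  double logu, joint0;
  int npar;
  Nuts(const Model& mod_, const std::vector<double>& eps_)
    : mod(mod_), eps(eps_), npar(mod_.npar()) {}

  bool leapfrog(PState& st, int dir) {
    for (int k = 0; k < npar; ++k) st.p[k] += dir * 0.5 * eps[k] * st.g[k];
    for (int k = 0; k < npar; ++k) st.th[k] += dir * eps[k] * st.p[k];
    if (!mod.eval(st.th, st.lp, st.g, st.lls)) return false;
    for (int k = 0; k < npar; ++k) st.p[k] += dir * 0.5 * eps[k] * st.g[k];
    double ke = 0.0;
    for (int k = 0; k < npar; ++k) ke += st.p[k] * st.p[k];
    st.joint = st.lp - 0.5 * ke;
    return std::isfinite(st.joint);
  }

  void build(const PState& from, int dir, int depth, Tree& out) {
    if (depth == 0) {
      PState st = from;
      if (!leapfrog(st, dir) || logu >= 1000.0 + st.joint) {
        out.ok = false; out.nvalid = 0; out.ntot = 1; out.has_prop = false;
        out.dsum = 0.0;
        return;
      }
      out.ok = true;
      out.minus = st; out.plus = st; out.prop = st;
      out.nvalid = (logu <= st.joint) ? 1.0 : 0.0;
      double d = st.joint - joint0;
      out.dsum = d > 0 ? 1.0 : std::exp(d);
      out.ntot = 1;
      out.has_prop = out.nvalid > 0;
      return;
    }
    Tree t1;
    build(from, dir, depth - 1, t1);
    if (!t1.ok) { out = t1; return; }
    Tree t2;
    build(dir == -1 ? t1.minus : t1.plus, dir, depth - 1, t2);
    out.nvalid = t1.nvalid + t2.nvalid;
    out.dsum = t1.dsum + t2.dsum;
    out.ntot = t1.ntot + t2.ntot;
    if (!t2.ok) { out.ok = false; out.has_prop = false; return; }
    out.has_prop = t1.has_prop;
    out.prop = t1.prop;
    if (t2.has_prop && out.nvalid > 0 &&
        unif_rand() < t2.nvalid / out.nvalid) {
      out.prop = t2.prop;
      out.has_prop = true;
    }
    out.minus = (dir == -1) ? t2.minus : t1.minus;
    out.plus = (dir == -1) ? t1.plus : t2.plus;
    double dot_m = 0.0, dot_p = 0.0;
    for (int k = 0; k < npar; ++k) {
      double dth = out.plus.th[k] - out.minus.th[k];
      dot_m += dth * out.minus.p[k];
      dot_p += dth * out.plus.p[k];
    }
    out.ok = dot_m >= 0.0 && dot_p >= 0.0;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_nuts_draw(NumericVector gain, NumericVector loss, NumericVector guar,
                   IntegerVector choice, NumericVector sout,
                   IntegerVector starts, NumericVector theta,
                   NumericVector inv_sd, double eps_scale,
                   NumericVector loc, NumericVector scl, NumericVector A,
                   bool fixed_sd, double floor_eps, int max_depth) {
  Model mod;
  mod.gain = gain.begin(); mod.loss = loss.begin(); mod.guar = guar.begin();
  mod.sout = sout.begin(); mod.choice = choice.begin();
  mod.starts = starts.begin();
  const int ntr = gain.size();
  std::vector<double> lgv(ntr), llov(ntr), lguv(ntr);
  for (int t = 0; t < ntr; ++t) {
    lgv[t] = gain[t] > 0.0 ? std::log(gain[t]) : 0.0;
    llov[t] = loss[t] < 0.0 ? std::log(-loss[t]) : 0.0;
    lguv[t] = guar[t] != 0.0 ? std::log(std::fabs(guar[t])) : 0.0;
  }
  mod.lg = lgv.data(); mod.llo = llov.data(); mod.lgu = lguv.data();
  mod.n = starts.size() - 1;
  mod.loc = loc.begin(); mod.scl = scl.begin(); mod.A = A.begin();
  mod.fixed_sd = fixed_sd;
  mod.floor_eps = floor_eps;
  const int npar = mod.npar();

  std::vector<double> eps(npar);
  for (int k = 0; k < npar; ++k) eps[k] = eps_scale * inv_sd[k];
  Nuts nuts(mod, eps);

  PState st0;
  st0.th.assign(theta.begin(), theta.end());
  st0.p.resize(npar); st0.g.resize(npar); st0.lls.resize(mod.n);
  if (!mod.eval(st0.th, st0.lp, st0.g, st0.lls)) {
    return List::create(Named("ok") = false);
  }
  double ke = 0.0;
  for (int k = 0; k < npar; ++k) {
    st0.p[k] = norm_rand();
    ke += st0.p[k] * st0.p[k];
  }
  st0.joint = st0.lp - 0.5 * ke;
  nuts.joint0 = st0.joint;
  nuts.logu = st0.joint - exp_rand();

  PState minus = st0, plus = st0, prop = st0;
  bool moved = false;
  double nvalid = 1.0, dsum = 0.0;
  int ntot = 0;
  for (int depth = 0; depth <= max_depth; ++depth) {
    int dir = unif_rand() < 0.5 ? -1 : 1;
    Tree sub;
    nuts.build(dir == -1 ? minus : plus, dir, depth, sub);
    dsum += sub.dsum;
    ntot += sub.ntot;
    if (sub.ok || sub.nvalid > 0) {
      if (dir == -1) minus = sub.minus; else plus = sub.plus;
    }
    if (sub.ok && sub.has_prop && sub.nvalid > 0 &&
        unif_rand() < sub.nvalid / nvalid) {
      prop = sub.prop;
      moved = true;
    }
    nvalid += sub.nvalid;
    if (!sub.ok) break;
    double dot_m = 0.0, dot_p = 0.0;
    for (int k = 0; k < npar; ++k) {
      double dth = plus.th[k] - minus.th[k];
      dot_m += dth * minus.p[k];
      dot_p += dth * plus.p[k];
    }
    if (dot_m < 0.0 || dot_p < 0.0) break;
  }

  NumericVector th_out(prop.th.begin(), prop.th.end());
  NumericVector lls_out(prop.lls.begin(), prop.lls.end());
  return List::create(Named("ok") = true, Named("theta") = th_out,
                      Named("lls") = lls_out, Named("moved") = moved,
                      Named("accept_stat") = ntot > 0 ? dsum / ntot : 0.0,
                      Named("ntot") = ntot);
}

// debug/verification hook: joint log density and gradient at a given state
// [[Rcpp::export]]
List cpp_joint_eval(NumericVector gain, NumericVector loss, NumericVector guar,
                    IntegerVector choice, NumericVector sout,
                    IntegerVector starts, NumericVector theta,
                    NumericVector loc, NumericVector scl, NumericVector A,
                    bool fixed_sd, double floor_eps) {
  Model mod;
  mod.gain = gain.begin(); mod.loss = loss.begin(); mod.guar = guar.begin();
  mod.sout = sout.begin(); mod.choice = choice.begin();
  mod.starts = starts.begin();
  const int ntr = gain.size();
  std::vector<double> lgv(ntr), llov(ntr), lguv(ntr);
  for (int t = 0; t < ntr; ++t) {
    lgv[t] = gain[t] > 0.0 ? std::log(gain[t]) : 0.0;
    llov[t] = loss[t] < 0.0 ? std::log(-loss[t]) : 0.0;
    lguv[t] = guar[t] != 0.0 ? std::log(std::fabs(guar[t])) : 0.0;
  }
  mod.lg = lgv.data(); mod.llo = llov.data(); mod.lgu = lguv.data();
  mod.n = starts.size() - 1;
  mod.loc = loc.begin(); mod.scl = scl.begin(); mod.A = A.begin();
  mod.fixed_sd = fixed_sd;
  mod.floor_eps = floor_eps;
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> g(mod.npar()), lls(mod.n);
  double lp;
  bool ok = mod.eval(th, lp, g, lls);
  return List::create(Named("ok") = ok, Named("lp") = lp,
                      Named("grad") = NumericVector(g.begin(), g.end()),
                      Named("lls") = NumericVector(lls.begin(), lls.end()));
}
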