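#include <Rcpp.h>
using namespace Rcpp;

// log(1/(1+exp(-x))) without overflow for large |x|
static inline double log_sigmoid(double x) {
  if (x >= 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// support floor applied only to downward crossings: a parameter already at
// or below the floor that is not being pushed further down is left alone
static inline double floor_pos(double prev, double next, double eps) {
  return (next < eps && next < prev) ? eps : next;
}

// Per-participant PT+ choice log-likelihood with trial-by-trial parameter
// updating. `scaled_outcome[t]` is the realized outcome of trial t mapped
// linearly to [0,1]; it only feeds the update applied before trial t+1.
// Probabilities are clipped 1e-12 away from {0,1} inside the log only.
// [[Rcpp::export]]
double cpp_choice_loglik(NumericVector gain, NumericVector loss,
                         NumericVector guar, IntegerVector choice,
                         NumericVector scaled_outcome,
                         double rho, double lam, double mu, double db,
                         double d_rho, double d_lam, double d_mu, double d_db,
                         double floor_eps) {
  const int n = gain.size();
  const double log_clip = std::log(1e-12);
  double ll = 0.0;
  double r = rho, l = lam, m = mu, b = db;
  for (int t = 0; t < n; ++t) {
    double ug = 0.5 * std::pow(gain[t], r);
    if (loss[t] < 0.0) ug += 0.5 * (-l * std::pow(-loss[t], r));
    double us = (guar[t] >= 0.0) ? std::pow(guar[t], r)
                                 : -l * std::pow(-guar[t], r);
    double eta = m * (ug - us - b);
    double lp = choice[t] == 1 ? log_sigmoid(eta) : log_sigmoid(-eta);
    if (lp < log_clip) lp = log_clip;
    ll += lp;
    if (t + 1 < n) {
      double s = scaled_outcome[t];
      r = floor_pos(r, r + s * d_rho, floor_eps);
      l = floor_pos(l, l + s * d_lam, floor_eps);
      m = floor_pos(m, m + s * d_mu, floor_eps);
      b = b + s * d_db;
    }
  }
  return ll;
}

// Log-likelihood and its gradient with respect to the unconstrained
// parameter vector z = (log rho, log lam, log mu, db, d_rho, d_lam, d_mu,
// d_db). Forward-mode accumulation through the sequential updating; a
// floored parameter's partials are zeroed from the flooring step on.
// [[Rcpp::export]]
List cpp_choice_loglik_grad(NumericVector gain, NumericVector loss,
                            NumericVector guar, IntegerVector choice,
                            NumericVector scaled_outcome,
                            NumericVector z, double floor_eps) {
  const int n = gain.size();
  double r = std::exp(z[0]), l = std::exp(z[1]), m = std::exp(z[2]), b = z[3];
  const double dr = z[4], dl = z[5], dm = z[6], dbv = z[7];
  // partials of the current (r, l, m, b) wrt (its init, its delta)
  double r_i = r, r_d = 0.0;   // d r_t / d z1, d r_t / d z5
  double l_i = l, l_d = 0.0;
  double m_i = m, m_d = 0.0;
  double b_i = 1.0, b_d = 0.0;
  double ll = 0.0;
  NumericVector g(8);
  for (int t = 0; t < n; ++t) {
    double lg = gain[t] > 0.0 ? std::log(gain[t]) : 0.0;
    double pg = std::pow(gain[t], r);
    double ug = 0.5 * pg;
    double dug_dr = 0.5 * pg * lg;
    double dug_dl = 0.0;
    if (loss[t] < 0.0) {
      double pl = std::pow(-loss[t], r);
      ug += -0.5 * l * pl;
      dug_dr += -0.5 * l * pl * std::log(-loss[t]);
      dug_dl = -0.5 * pl;
    }
    double us, dus_dr, dus_dl = 0.0;
    if (guar[t] > 0.0) {
      double ps = std::pow(guar[t], r);
      us = ps; dus_dr = ps * std::log(guar[t]);
    } else if (guar[t] == 0.0) {
      us = 0.0; dus_dr = 0.0;
    } else {
      double ps = std::pow(-guar[t], r);
      us = -l * ps;
      dus_dr = -l * ps * std::log(-guar[t]);
      dus_dl = -ps;
    }
    double du = ug - us - b;
    double eta = m * du;
    double p = 1.0 / (1.0 + std::exp(-eta));
    ll += choice[t] == 1 ? (eta >= 0 ? -log1p(std::exp(-eta))
                                     : eta - log1p(std::exp(eta)))
                         : (eta >= 0 ? -eta - log1p(std::exp(-eta))
                                     : -log1p(std::exp(eta)));
    double dl_deta = (choice[t] == 1 ? 1.0 : 0.0) - p;
    // deta wrt current-trial (r, l, m, b)
    double deta_dr = m * (dug_dr - dus_dr);
    double deta_dl = m * (dug_dl - dus_dl);
    double deta_dm = du;
    double deta_db = -m;
    g[0] += dl_deta * (deta_dr * r_i);
    g[4] += dl_deta * (deta_dr * r_d);
    g[1] += dl_deta * (deta_dl * l_i);
    g[5] += dl_deta * (deta_dl * l_d);
    g[2] += dl_deta * (deta_dm * m_i);
    g[6] += dl_deta * (deta_dm * m_d);
    g[3] += dl_deta * (deta_db * b_i);
    g[7] += dl_deta * (deta_db * b_d);
    if (t + 1 < n) {
      double sv = scaled_outcome[t];
      double rn = r + sv * dr;
      if (rn < floor_eps && rn < r) { r = floor_eps; r_i = 0.0; r_d = 0.0; }
      else { r = rn; r_d += sv; }
      double ln = l + sv * dl;
      if (ln < floor_eps && ln < l) { l = floor_eps; l_i = 0.0; l_d = 0.0; }
      else { l = ln; l_d += sv; }
      double mn = m + sv * dm;
      if (mn < floor_eps && mn < m) { m = floor_eps; m_i = 0.0; m_d = 0.0; }
      else { m = mn; m_d += sv; }
      b = b + sv * dbv;
      b_d += sv;
    }
  }
  return List::create(Named("ll") = ll, Named("grad") = g);
}

// Cohort-level batched evaluations: participants are concatenated with
// 0-based offsets in `starts` (length n+1); Z holds one unconstrained
// 8-vector per row.
// [[Rcpp::export]]
NumericVector cpp_cohort_loglik(NumericVector gain, NumericVector loss,
                                NumericVector guar, IntegerVector choice,
                                NumericVector scaled_outcome,
                                IntegerVector starts, NumericMatrix Z,
                                double floor_eps,
                                NumericVector lg, NumericVector llo,
                                NumericVector lgu) {
  const int n = Z.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int a = starts[i], b = starts[i + 1];
    double r = std::exp(Z(i, 0)), l = std::exp(Z(i, 1)),
           m = std::exp(Z(i, 2)), bb = Z(i, 3);
    double ll = 0.0;
    for (int t = a; t < b; ++t) {
      double ug = 0.5 * (gain[t] > 0.0 ? std::exp(r * lg[t]) : 0.0);
      if (loss[t] < 0.0) ug += 0.5 * (-l * std::exp(r * llo[t]));
      double us = guar[t] == 0.0 ? 0.0
        : (guar[t] > 0.0 ? std::exp(r * lgu[t]) : -l * std::exp(r * lgu[t]));
      double eta = m * (ug - us - bb);
      // unclipped: must match the gradient evaluation exactly
      double lp = choice[t] == 1
        ? (eta >= 0 ? -log1p(std::exp(-eta)) : eta - log1p(std::exp(eta)))
        : (eta >= 0 ? -eta - log1p(std::exp(-eta)) : -log1p(std::exp(eta)));
      ll += lp;
      if (t + 1 < b) {
        double sv = scaled_outcome[t];
        r = floor_pos(r, r + sv * Z(i, 4), floor_eps);
        l = floor_pos(l, l + sv * Z(i, 5), floor_eps);
        m = floor_pos(m, m + sv * Z(i, 6), floor_eps);
        bb = bb + sv * Z(i, 7);
      }
    }
    out[i] = ll;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cohort_loglik_grad(NumericVector gain, NumericVector loss,
                            NumericVector guar, IntegerVector choice,
                            NumericVector scaled_outcome,
                            IntegerVector starts, NumericMatrix Z,
                            double floor_eps) {
  const int n = Z.nrow();
  NumericVector lls(n);
  NumericMatrix G(n, 8);
  for (int i = 0; i < n; ++i) {
    int a = starts[i], b = starts[i + 1];
    NumericVector z = Z(i, _);
    NumericVector gseg(b - a), lseg(b - a), useg(b - a), sseg(b - a);
    IntegerVector cseg(b - a);
    for (int t = a; t < b; ++t) {
      gseg[t - a] = gain[t]; lseg[t - a] = loss[t]; useg[t - a] = guar[t];
      cseg[t - a] = choice[t]; sseg[t - a] = scaled_outcome[t];
    }
    List gl = cpp_choice_loglik_grad(gseg, lseg, useg, cseg, sseg, z,
                                     floor_eps);
    lls[i] = as<double>(gl["ll"]);
    NumericVector gg = gl["grad"];
    for (int j = 0; j < 8; ++j) G(i, j) = gg[j];
  }
  return List::create(Named("ll") = lls, Named("grad") = G);
}
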