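#ifndef DYNPT_PT_LIKELIHOOD_H
#define DYNPT_PT_LIKELIHOOD_H

#include <cmath>

// One participant's dynamic PT+ choice log-likelihood and, optionally, its
// gradient with respect to the unconstrained parameter vector
// z = (log rho, log lam, log mu, db, d_rho, d_lam, d_mu, d_db).
// Forward-mode accumulation through the sequential updating; a floored
// parameter's partials are zeroed from the flooring step on.
// lg = log(gain), llo = log(-loss) (0 where loss == 0), lgu = log(|guar|)
// (0 where guar == 0): precomputed once, the amounts are fixed data.
inline double pt_ll_grad(const double* gain, const double* loss,
                         const double* guar, const int* choice,
                         const double* sout, int n, const double* z,
                         double floor_eps, double* grad /* 8 or null */,
                         const double* lg, const double* llo,
                         const double* lgu) {
  double r = std::exp(z[0]), l = std::exp(z[1]), m = std::exp(z[2]),
         b = z[3];
  const double dr = z[4], dl = z[5], dm = z[6], dbv = z[7];
  double r_i = r, r_d = 0.0, l_i = l, l_d = 0.0, m_i = m, m_d = 0.0,
         b_i = 1.0, b_d = 0.0;
  double ll = 0.0;
  if (grad) for (int j = 0; j < 8; ++j) grad[j] = 0.0;
  for (int t = 0; t < n; ++t) {
    double pg = gain[t] > 0.0 ? std::exp(r * lg[t]) : 0.0;
    double ug = 0.5 * pg;
    double dug_dr = 0.0, dug_dl = 0.0;
    if (grad) dug_dr = 0.5 * pg * (gain[t] > 0.0 ? lg[t] : 0.0);
    if (loss[t] < 0.0) {
      double pl = std::exp(r * llo[t]);
      ug += -0.5 * l * pl;
      if (grad) {
        dug_dr += -0.5 * l * pl * llo[t];
        dug_dl = -0.5 * pl;
      }
    }
    double us, dus_dr = 0.0, dus_dl = 0.0;
    if (guar[t] > 0.0) {
      double ps = std::exp(r * lgu[t]);
      us = ps;
      if (grad) dus_dr = ps * lgu[t];
    } else if (guar[t] == 0.0) {
      us = 0.0;
    } else {
      double ps = std::exp(r * lgu[t]);
      us = -l * ps;
      if (grad) {
        dus_dr = -l * ps * lgu[t];
        dus_dl = -ps;
      }
    }
    double du = ug - us - b;
    double eta = m * du;
    ll += choice[t] == 1
      ? (eta >= 0 ? -log1p(std::exp(-eta)) : eta - log1p(std::exp(eta)))
      : (eta >= 0 ? -eta - log1p(std::exp(-eta)) : -log1p(std::exp(eta)));
    if (grad) {
      double p = 1.0 / (1.0 + std::exp(-eta));
      double dl_deta = (choice[t] == 1 ? 1.0 : 0.0) - p;
      double deta_dr = m * (dug_dr - dus_dr);
      double deta_dl = m * (dug_dl - dus_dl);
      grad[0] += dl_deta * deta_dr * r_i;
      grad[4] += dl_deta * deta_dr * r_d;
      grad[1] += dl_deta * deta_dl * l_i;
      grad[5] += dl_deta * deta_dl * l_d;
      grad[2] += dl_deta * du * m_i;
      grad[6] += dl_deta * du * m_d;
      grad[3] += dl_deta * (-m) * b_i;
      grad[7] += dl_deta * (-m) * b_d;
    }
    if (t + 1 < n) {
      double sv = sout[t];
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
  return ll;
}

#endif
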