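// Per-unit likelihood and derivative pass for the stacked occupancy model.
// The R side assembles the linear predictors (BLAS); this kernel does the
// elementwise link evaluations and the record -> unit reductions in one
// sweep over the data. Records must arrive contiguous by unit, in unit
// order (the layout occu_data() guarantees).

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_plogis(double x) {
  if (x > 0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// [[Rcpp::export(name = ".occu_terms_cpp")]]
List occu_terms_cpp(NumericVector eta_psi, NumericVector zeta,
                    NumericVector y, IntegerVector rec_end,
                    NumericVector allzero) {
  const int U = eta_psi.size();
  const int R = zeta.size();
  NumericVector logB(U), s(U), q(U), p(R);
  int r = 0;
  for (int u = 0; u < U; ++u) {
    const int end = rec_end[u];
    double lb = 0.0, ss = 0.0, qq = 0.0;
    for (; r < end; ++r) {
      const double lp = log_plogis(zeta[r]);
      const double pr = std::exp(lp);
      p[r] = pr;
      lb += (y[r] > 0.5) ? lp : (lp - zeta[r]);
      ss += y[r] - pr;
      qq += pr * (1.0 - pr);
    }
    logB[u] = lb; s[u] = ss; q[u] = qq;
  }

  NumericVector logL(U), gu(U), gv(U), huu(U), hvv(U), huv(U), psi(U);
  for (int u = 0; u < U; ++u) {
    const double lpsi = log_plogis(eta_psi[u]);
    const double l1m = lpsi - eta_psi[u];
    const double ps = std::exp(lpsi);
    const double t1 = lpsi + logB[u];
    double lL, R1;
    if (allzero[u] > 0.5) {
      const double m = (t1 > l1m) ? t1 : l1m;
      lL = m + log1p(std::exp(-std::fabs(t1 - l1m)));
      R1 = std::exp(t1 - lL);
    } else {
      lL = t1; R1 = 1.0;
    }
    psi[u] = ps;
    logL[u] = lL;
    const double g_u = (1.0 - ps) * R1 - ps * (1.0 - R1);
    const double g_v = R1 * s[u];
    gu[u] = g_u; gv[u] = g_v;
    huu[u] = (1.0 - 2.0 * ps) * g_u - g_u * g_u;
    hvv[u] = R1 * (s[u] * s[u] - q[u]) - g_v * g_v;
    huv[u] = (1.0 - ps) * R1 * s[u] - g_u * g_v;
  }
  return List::create(_["logL"] = logL, _["gu"] = gu, _["gv"] = gv,
                      _["huu"] = huu, _["hvv"] = hvv, _["huv"] = huv,
                      _["psi"] = psi, _["p"] = p);
}

// likelihood-only sweep (line searches, quadrature nodes)
// [[Rcpp::export(name = ".occu_logL_cpp")]]
NumericVector occu_logL_cpp(NumericVector eta_psi, NumericVector zeta,
                            NumericVector y, IntegerVector rec_end,
                            NumericVector allzero) {
  const int U = eta_psi.size();
  NumericVector logL(U);
  int r = 0;
  for (int u = 0; u < U; ++u) {
    const int end = rec_end[u];
    double lb = 0.0;
    for (; r < end; ++r) {
      const double lp = log_plogis(zeta[r]);
      lb += (y[r] > 0.5) ? lp : (lp - zeta[r]);
    }
    const double lpsi = log_plogis(eta_psi[u]);
    const double t1 = lpsi + lb;
    if (allzero[u] > 0.5) {
      const double l1m = lpsi - eta_psi[u];
      const double m = (t1 > l1m) ? t1 : l1m;
      logL[u] = m + log1p(std::exp(-std::fabs(t1 - l1m)));
    } else {
      logL[u] = t1;
    }
  }
  return logL;
}

// AGHQ sweep for a territory random effect: per-unit psi terms are
// node-invariant, only the detection product shifts. Returns group
// log-likelihood sums (M x K) accumulated over each territory's units.
// [[Rcpp::export(name = ".occu_aghq_v_cpp")]]
NumericMatrix occu_aghq_v(NumericVector eta_psi, NumericVector zeta,
                          NumericVector y, IntegerVector rec_end,
                          NumericVector allzero, IntegerVector rec_i,
                          IntegerVector unit_i, NumericMatrix vshift,
                          int n_terr) {
  const int U = eta_psi.size();
  const int K = vshift.ncol();
  NumericVector lpsi(U), l1m(U);
  for (int u = 0; u < U; ++u) {
    lpsi[u] = log_plogis(eta_psi[u]);
    l1m[u] = lpsi[u] - eta_psi[u];
  }
  NumericMatrix h(n_terr, K);
  for (int k = 0; k < K; ++k) {
    int r = 0;
    for (int u = 0; u < U; ++u) {
      const int end = rec_end[u];
      double lb = 0.0;
      for (; r < end; ++r) {
        const double z = zeta[r] + vshift(rec_i[r] - 1, k);
        const double lp = log_plogis(z);
        lb += (y[r] > 0.5) ? lp : (lp - z);
      }
      const double t1 = lpsi[u] + lb;
      double lL;
      if (allzero[u] > 0.5) {
        const double m = (t1 > l1m[u]) ? t1 : l1m[u];
        lL = m + log1p(std::exp(-std::fabs(t1 - l1m[u])));
      } else {
        lL = t1;
      }
      h(unit_i[u] - 1, k) += lL;
    }
  }
  return h;
}

// AGHQ sweep for a year random effect: the detection product is
// node-invariant, only psi shifts. Returns group sums (T x K).
// [[Rcpp::export(name = ".occu_aghq_u_cpp")]]
NumericMatrix occu_aghq_u(NumericVector eta_psi, NumericVector zeta,
                          NumericVector y, IntegerVector rec_end,
                          NumericVector allzero, IntegerVector unit_t,
                          NumericMatrix ushift, int n_years) {
  const int U = eta_psi.size();
  const int K = ushift.ncol();
  NumericVector logB(U);
  int r = 0;
  for (int u = 0; u < U; ++u) {
    const int end = rec_end[u];
    double lb = 0.0;
    for (; r < end; ++r) {
      const double lp = log_plogis(zeta[r]);
      lb += (y[r] > 0.5) ? lp : (lp - zeta[r]);
    }
    logB[u] = lb;
  }
  NumericMatrix h(n_years, K);
  for (int k = 0; k < K; ++k) {
    for (int u = 0; u < U; ++u) {
      const double e = eta_psi[u] + ushift(unit_t[u] - 1, k);
      const double lpsi = log_plogis(e);
      const double t1 = lpsi + logB[u];
      double lL;
      if (allzero[u] > 0.5) {
        const double l1m = lpsi - e;
        const double m = (t1 > l1m) ? t1 : l1m;
        lL = m + log1p(std::exp(-std::fabs(t1 - l1m)));
      } else {
        lL = t1;
      }
      h(unit_t[u] - 1, k) += lL;
    }
  }
  return h;
}
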