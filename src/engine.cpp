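#include <Rcpp.h>
using namespace Rcpp;

// Compiled twin of grl_engine_r(): one pass over a trial table, either
// evaluating the likelihood of recorded choices (mode 0) or sampling
// choices from the policy with supplied uniform draws (mode 1). The
// arithmetic is ordered identically to the R reference so the two routes
// agree bit-for-bit.

static inline double clamp01(double x) {
  return x > 1.0 ? 1.0 : (x < 0.0 ? 0.0 : x);
}

// hypothesis 1 ("AL/BR") is congruent with (state, action) = (A, left) or
// (B, right)
static inline bool congruent_h1(int st, int a) {
  return (st == 1 && a == 1) || (st == 2 && a == 2);
}

// parameter vector order (see .par_names in R):
// 0 alpha, 1 g_a, 2 g_s, 3 g_sa, 4 lambda, 5 tau, 6 beta0, 7 lambda_beta,
// 8 beta_r, 9 alpha_spe, 10 theta0, 11 theta1, 12 w_mb, 13 p_left

// [[Rcpp::export]]
List engine_cpp(IntegerVector run, IntegerVector category, IntegerVector state,
                IntegerVector rewarded_action, IntegerVector reward_available,
                NumericVector par, int mb_code, int is_static, int mode,
                IntegerVector chosen_in, IntegerVector reward_in,
                IntegerVector missed_in, NumericVector u,
                int q_reset, int belief_reset, int v_reset, int svpe_on_missed,
                double p_floor, int want_traces) {
  const int n = run.size();
  const double alpha = par[0], g_a = par[1], g_s = par[2], g_sa = par[3],
               lambda = par[4], tau = par[5], beta0 = par[6],
               lambda_beta = par[7], beta_r = par[8], alpha_spe = par[9],
               theta0 = par[10], theta1 = par[11], w_mb = par[12],
               p_left_par = par[13];
  if (!is_static && tau <= 0) stop("parameter error: tau must be > 0");

  double V = 0.0;
  double Q[2][2][2] = {{{0, 0}, {0, 0}}, {{0, 0}, {0, 0}}};
  double beta[2] = {0, 0};
  double bel[2][2] = {{0.5, 0.5}, {0.5, 0.5}};

  IntegerVector chosen(n), reward(n);
  if (mode == 0) { chosen = clone(chosen_in); reward = clone(reward_in); }
  NumericVector tr_v, tr_ql, tr_qr, tr_dv, tr_dq, tr_pl;
  if (want_traces) {
    tr_v = NumericVector(n, NA_REAL); tr_ql = NumericVector(n, NA_REAL);
    tr_qr = NumericVector(n, NA_REAL); tr_dv = NumericVector(n, NA_REAL);
    tr_dq = NumericVector(n, NA_REAL); tr_pl = NumericVector(n, NA_REAL);
  }

  double nll = 0.0;
  int prev_run = -1;
  for (int t = 0; t < n; t++) {
    const int c = category[t] - 1, s = state[t];  // s kept 1-based for congruency rule
    const int si = s - 1;
    if (run[t] != prev_run) {
      if (q_reset) for (int i = 0; i < 2; i++) for (int j = 0; j < 2; j++)
        for (int k = 0; k < 2; k++) Q[i][j][k] = 0.0;
      beta[0] = beta[1] = 0.0;
      if (belief_reset) { bel[0][0] = bel[0][1] = bel[1][0] = bel[1][1] = 0.5; }
      if (v_reset) V = 0.0;
      prev_run = run[t];
    }
    const bool miss = (mode == 0) && missed_in[t];
    double delta_v = NA_REAL;
    if (!is_static && (svpe_on_missed || !miss)) {
      const double qmax = Q[c][si][0] > Q[c][si][1] ? Q[c][si][0] : Q[c][si][1];
      delta_v = qmax - V;
      V = V + alpha * delta_v;
    }
    if (!is_static && mb_code == 2) {  // HMM prior propagation
      const double p0 = bel[c][0], p1 = bel[c][1];
      bel[c][0] = theta1 * p1 + (1 - theta1) * p0;
      bel[c][1] = theta1 * p0 + (1 - theta1) * p1;
    }
    double pL, pR;
    if (is_static) {
      pL = p_left_par; pR = 1.0 - pL;
    } else {
      double qmb_l = 0.0, qmb_r = 0.0;
      if (mb_code > 0) {
        qmb_l = congruent_h1(s, 1) ? bel[c][0] : bel[c][1];
        qmb_r = congruent_h1(s, 2) ? bel[c][0] : bel[c][1];
      }
      double xl = (w_mb * qmb_l + (1 - w_mb) * Q[c][si][0] + beta[0]) / tau;
      double xr = (w_mb * qmb_r + (1 - w_mb) * Q[c][si][1] + beta[1] + beta_r) / tau;
      const double m = xl > xr ? xl : xr;
      const double el = exp(xl - m), er = exp(xr - m);
      pL = el / (el + er);
      pR = er / (el + er);
    }
    if (want_traces) {
      tr_v[t] = V; tr_ql[t] = Q[c][si][0]; tr_qr[t] = Q[c][si][1];
      tr_dv[t] = delta_v; tr_pl[t] = pL;
    }
    if (mode == 1) {
      chosen[t] = (u[t] < pL) ? 1 : 2;
      reward[t] = (chosen[t] == rewarded_action[t] && reward_available[t]) ? 1 : 0;
    }
    if (miss) continue;
    const int a = chosen[t];
    const double pa = (a == 1) ? pL : pR;
    nll -= log(pa > p_floor ? pa : p_floor);
    if (is_static) continue;
    // hysteresis recursion
    beta[0] *= lambda_beta; beta[1] *= lambda_beta;
    beta[a - 1] += beta0;
    // outcome updates
    const int ai = a - 1, aci = 1 - ai, sci = 1 - si;
    const double r = (double) reward[t];
    const double dq = r - Q[c][si][ai];
    Q[c][si][ai] += alpha * dq;
    V = clamp01(V + lambda * alpha * dq);
    Q[c][si][aci] = clamp01(Q[c][si][aci] + g_a * alpha * dq);
    Q[c][sci][ai] = clamp01(Q[c][sci][ai] + g_s * alpha * dq);
    Q[c][sci][aci] = clamp01(Q[c][sci][aci] + g_s * g_sa * alpha * dq);
    if (want_traces) tr_dq[t] = dq;
    if (mb_code == 1) {  // SPE delta rule
      const int hat = (congruent_h1(s, a) == (reward[t] == 1)) ? 0 : 1;
      const int alt = 1 - hat;
      const double d = 1.0 - bel[c][hat];
      bel[c][hat] += alpha_spe * d;
      bel[c][alt] -= alpha_spe * bel[c][alt];
    } else if (mb_code == 2) {  // HMM Bayes update
      const int hat = (congruent_h1(s, a) == (reward[t] == 1)) ? 0 : 1;
      double lik[2];
      lik[hat] = theta0; lik[1 - hat] = 1 - theta0;
      double p0 = lik[0] * bel[c][0], p1 = lik[1] * bel[c][1];
      const double z = p0 + p1;
      if (z < 1e-12) { bel[c][0] = 0.5; bel[c][1] = 0.5; }
      else { bel[c][0] = p0 / z; bel[c][1] = p1 / z; }
    }
  }

  List out = List::create(_["nll"] = nll, _["chosen"] = chosen,
                          _["reward"] = reward);
  if (want_traces) {
    out["v0"] = tr_v; out["q_left"] = tr_ql; out["q_right"] = tr_qr;
    out["delta_v"] = tr_dv; out["delta_q"] = tr_dq; out["p_left"] = tr_pl;
  }
  return out;
}
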