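#include <Rcpp.h>
using namespace Rcpp;

// Hybrid MF/MB agent core shared by the simulator and the likelihood.
// Parameter order: a1, beta1, a2, beta2, lam, omega, pi.

namespace {

struct Agent {
  double qmf[2];
  double q2[2][2]; // state x option
  int prev;        // previous stage-1 choice, -1 if none

  void init(double q_init) {
    qmf[0] = qmf[1] = q_init;
    q2[0][0] = q2[0][1] = q2[1][0] = q2[1][1] = q_init;
    prev = -1;
  }

  void stage1_probs(const double *par, double p_common, double *p) const {
    double best0 = std::max(q2[0][0], q2[0][1]);
    double best1 = std::max(q2[1][0], q2[1][1]);
    double qmb0 = p_common * best0 + (1.0 - p_common) * best1;
    double qmb1 = p_common * best1 + (1.0 - p_common) * best0;
    double w = par[5];
    double u0 = par[1] * (w * qmb0 + (1.0 - w) * qmf[0]);
    double u1 = par[1] * (w * qmb1 + (1.0 - w) * qmf[1]);
    if (prev == 0) u0 += par[6];
    if (prev == 1) u1 += par[6];
    double m = std::max(u0, u1);
    double e0 = std::exp(u0 - m), e1 = std::exp(u1 - m);
    p[0] = e0 / (e0 + e1);
    p[1] = 1.0 - p[0];
  }

  void stage2_probs(const double *par, int s2, double *p) const {
    double u0 = par[3] * q2[s2][0], u1 = par[3] * q2[s2][1];
    double m = std::max(u0, u1);
    double e0 = std::exp(u0 - m), e1 = std::exp(u1 - m);
    p[0] = e0 / (e0 + e1);
    p[1] = 1.0 - p[0];
  }

  // SARSA(lambda)-style update, order fixed by the package contract
  void update(const double *par, int c1, int s2, int c2, double reward) {
    double d1 = q2[s2][c2] - qmf[c1];
    qmf[c1] += par[0] * d1;
    double d2 = reward - q2[s2][c2];
    q2[s2][c2] += par[2] * d2;
    qmf[c1] += par[0] * par[4] * d2;
    prev = c1;
  }
};

double session_loglik_core(const double *par, int n, const int *choice1,
                           const int *state2, const int *choice2,
                           const double *reward, const int *missed,
                           double p_common, double q_init) {
  Agent ag;
  ag.init(q_init);
  double ll = 0.0, p[2];
  for (int t = 0; t < n; ++t) {
    if (missed[t]) { ag.prev = -1; continue; }
    ag.stage1_probs(par, p_common, p);
    ll += std::log(p[choice1[t]]);
    ag.stage2_probs(par, state2[t], p);
    ll += std::log(p[choice2[t]]);
    ag.update(par, choice1[t], state2[t], choice2[t], reward[t]);
  }
  return ll;
}

} // namespace

// [[Rcpp::export]]
double loglik_session_cpp(NumericVector par, IntegerVector choice1,
                          IntegerVector state2, IntegerVector choice2,
                          NumericVector reward, IntegerVector missed,
                          double p_common, double q_init) {
  return session_loglik_core(REAL(par), choice1.size(), INTEGER(choice1),
                             INTEGER(state2), INTEGER(choice2), REAL(reward),
                             INTEGER(missed), p_common, q_init);
}

// Likelihood of every subject's session at subject-specific parameters.
// par_mat is n_subj x 7 (natural scale); sessions are concatenated with
// 0-based offsets (offset[i], offset[i] + len[i]).
// [[Rcpp::export]]
NumericVector loglik_cohort_cpp(NumericMatrix par_mat, IntegerVector offset,
                                IntegerVector len, IntegerVector choice1,
                                IntegerVector state2, IntegerVector choice2,
                                NumericVector reward, IntegerVector missed,
                                double p_common, double q_init) {
  int ns = par_mat.nrow();
  NumericVector out(ns);
  double par[7];
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < 7; ++j) par[j] = par_mat(i, j);
    int o = offset[i];
    out[i] = session_loglik_core(par, len[i], INTEGER(choice1) + o,
                                 INTEGER(state2) + o, INTEGER(choice2) + o,
                                 REAL(reward) + o, INTEGER(missed) + o,
                                 p_common, q_init);
  }
  return out;
}

// Samples a session given pre-drawn per-component uniforms, so the
// result is bit-identical to the pure-R policy path.
// [[Rcpp::export]]
List simulate_hybrid_cpp(NumericVector par, NumericMatrix walk,
                         double p_common, double q_init,
                         NumericVector u_tr, NumericVector u_rw,
                         NumericVector u_c1, NumericVector u_c2) {
  int n = walk.nrow();
  IntegerVector choice1(n), state2(n), choice2(n), reward(n), common(n);
  Agent ag;
  ag.init(q_init);
  double p[2];
  const double *pp = REAL(par);
  for (int t = 0; t < n; ++t) {
    ag.stage1_probs(pp, p_common, p);
    int c1 = u_c1[t] >= p[0] ? 1 : 0;
    int com = u_tr[t] < p_common ? 1 : 0;
    int s2 = com ? c1 : 1 - c1; // option 0 -> state A (0), option 1 -> B (1)
    ag.stage2_probs(pp, s2, p);
    int c2 = u_c2[t] >= p[0] ? 1 : 0;
    int rew = u_rw[t] < walk(t, 2 * s2 + c2) ? 1 : 0;
    ag.update(pp, c1, s2, c2, (double)rew);
    choice1[t] = c1; state2[t] = s2; choice2[t] = c2;
    reward[t] = rew; common[t] = com;
  }
  return List::create(_["choice1"] = choice1, _["state2"] = state2,
                      _["choice2"] = choice2, _["reward"] = reward,
                      _["common"] = common);
}
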