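#include <Rcpp.h>
using namespace Rcpp;

// Model codes: 1 RL1a, 2 RL1b, 3 RL2a, 4 RL2b, 5 RL3a, 6 RL3b, 7 RL4a, 8 RL4b
// Canonical parameter order (length 9):
//   0 alpha, 1 beta, 2 gamma, 3 alpha_F, 4 alpha_C,
//   5 alpha_pos, 6 alpha_neg, 7 eta, 8 kappa
static inline bool has_trace(int m)  { return m == 3 || m == 4; }
static inline bool has_forget(int m) { return m % 2 == 0; }
static inline bool is_asym(int m)    { return m == 5 || m == 6; }
static inline bool is_ph(int m)      { return m == 7 || m == 8; }

// softmax over beta*Q + gamma*trace, max-subtracted, floored away from 0/1
static inline void softmax3(const double* Q, const double* tr,
                            double beta, double gamma, double* p) {
  double l[3];
  double mx = -1e300;
  for (int a = 0; a < 3; ++a) {
    l[a] = beta * Q[a] + gamma * tr[a];
    if (l[a] > mx) mx = l[a];
  }
  double s = 0.0;
  for (int a = 0; a < 3; ++a) { p[a] = std::exp(l[a] - mx); s += p[a]; }
  double s2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    p[a] /= s;
    if (p[a] < 1e-10) p[a] = 1e-10;
    s2 += p[a];
  }
  for (int a = 0; a < 3; ++a) p[a] /= s2;
}

static inline void rl_update(int m, const NumericVector& par,
                             double* Q, double* tr, double& assoc,
                             int c, double outcome, double Q0) {
  double delta = outcome - Q[c];
  double a_eff;
  if (is_asym(m))      a_eff = (delta >= 0.0) ? par[5] : par[6];
  else if (is_ph(m))   a_eff = par[8] * assoc;
  else                 a_eff = par[0];
  Q[c] += a_eff * delta;
  if (has_forget(m)) {
    double aF = par[3];
    for (int u = 0; u < 3; ++u)
      if (u != c) Q[u] = (1.0 - aF) * Q[u] + aF * Q0;
  }
  if (is_ph(m)) assoc = par[7] * std::fabs(delta) + (1.0 - par[7]) * assoc;
  if (has_trace(m)) {
    double aC = par[4];
    for (int a = 0; a < 3; ++a)
      tr[a] = (1.0 - aC) * tr[a] + aC * (a == c ? 1.0 : 0.0);
  }
}

// [[Rcpp::export(name = ".nll_cpp")]]
double nll_cpp(IntegerVector choices, NumericVector outcomes,
               int model, NumericVector par, double Q0) {
  int T = choices.size();
  double Q[3] = {Q0, Q0, Q0};
  double tr[3] = {0.0, 0.0, 0.0};
  double assoc = 1.0;
  double beta = par[1];
  double gamma = has_trace(model) ? par[2] : 0.0;
  double p[3];
  double nll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (choices[t] == NA_INTEGER) continue;  // missed: no term, no update
    int c = choices[t] - 1;
    softmax3(Q, tr, beta, gamma, p);
    nll -= std::log(p[c]);
    rl_update(model, par, Q, tr, assoc, c, outcomes[t], Q0);
  }
  return nll;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericMatrix probs, int reward_context,
                  int model, NumericVector par,
                  double miss_rate, double Q0) {
  int T = probs.nrow();
  IntegerVector choices(T);
  NumericVector outcomes(T);
  double Q[3] = {Q0, Q0, Q0};
  double tr[3] = {0.0, 0.0, 0.0};
  double assoc = 1.0;
  double beta = par[1];
  double gamma = has_trace(model) ? par[2] : 0.0;
  double p[3];
  RNGScope scope;
  for (int t = 0; t < T; ++t) {
    if (miss_rate > 0.0 && R::runif(0.0, 1.0) < miss_rate) {
      choices[t] = NA_INTEGER;
      outcomes[t] = NA_REAL;
      continue;
    }
    softmax3(Q, tr, beta, gamma, p);
    double u = R::runif(0.0, 1.0);
    int c = (u < p[0]) ? 0 : (u < p[0] + p[1] ? 1 : 2);
    bool success = R::runif(0.0, 1.0) < probs(t, c);
    double outcome = reward_context ? (success ? 1.0 : 0.0)
                                    : (success ? 0.0 : -1.0);
    choices[t] = c + 1;
    outcomes[t] = outcome;
    rl_update(model, par, Q, tr, assoc, c, outcome, Q0);
  }
  return List::create(_["choices"] = choices, _["outcomes"] = outcomes);
}

// Forward-mode gradient of the negative log-likelihood with respect to the
// nine canonical parameters (inactive entries get zero gradient). Sensitivity
// recursions mirror rl_update exactly.
// [[Rcpp::export(name = ".nll_grad_cpp")]]
List nll_grad_cpp(IntegerVector choices, NumericVector outcomes,
                  int model, NumericVector par, double Q0) {
  const int NP = 9;
  int T = choices.size();
  double Q[3] = {Q0, Q0, Q0};
  double tr[3] = {0.0, 0.0, 0.0};
  double A = 1.0;
  double dQ[3][NP] = {{0}}, dtr[3][NP] = {{0}}, dA[NP] = {0};
  double beta = par[1];
  bool trace_m = has_trace(model);
  bool forget = has_forget(model);
  bool asym = is_asym(model);
  bool ph = is_ph(model);
  double gamma = trace_m ? par[2] : 0.0;
  double p[3];
  double nll = 0.0;
  NumericVector grad(NP);
  for (int t = 0; t < T; ++t) {
    if (choices[t] == NA_INTEGER) continue;
    int c = choices[t] - 1;
    softmax3(Q, tr, beta, gamma, p);
    nll -= std::log(p[c]);
    // dl[a][j] and gradient contribution -(dl_c - sum_a p_a dl_a)
    for (int j = 0; j < NP; ++j) {
      double dl[3], dlbar = 0.0;
      for (int a = 0; a < 3; ++a) {
        dl[a] = beta * dQ[a][j] + gamma * dtr[a][j];
        if (j == 1) dl[a] += Q[a];
        if (j == 2 && trace_m) dl[a] += tr[a];
        dlbar += p[a] * dl[a];
      }
      grad[j] -= dl[c] - dlbar;
    }
    // value update with sensitivities
    double delta = outcomes[t] - Q[c];
    double a_eff;
    double da[NP] = {0};
    if (asym) {
      a_eff = (delta >= 0.0) ? par[5] : par[6];
      da[(delta >= 0.0) ? 5 : 6] = 1.0;
    } else if (ph) {
      a_eff = par[8] * A;
      for (int j = 0; j < NP; ++j) da[j] = par[8] * dA[j];
      da[8] += A;
    } else {
      a_eff = par[0];
      da[0] = 1.0;
    }
    double Qc_old = Q[c];
    double A_old = A;
    double ddelta[NP];  // sensitivity of delta = outcome - Q_old[c]
    for (int j = 0; j < NP; ++j) ddelta[j] = -dQ[c][j];
    Q[c] = Qc_old + a_eff * delta;
    for (int j = 0; j < NP; ++j)
      dQ[c][j] += da[j] * delta + a_eff * ddelta[j];
    if (forget) {
      double aF = par[3];
      for (int u = 0; u < 3; ++u) {
        if (u == c) continue;
        double Qu_old = Q[u];
        Q[u] = (1.0 - aF) * Qu_old + aF * Q0;
        for (int j = 0; j < NP; ++j) dQ[u][j] *= (1.0 - aF);
        dQ[u][3] += Q0 - Qu_old;
      }
    }
    if (ph) {
      double eta = par[7];
      double sgn = (delta >= 0.0) ? 1.0 : -1.0;
      A = eta * std::fabs(delta) + (1.0 - eta) * A_old;
      for (int j = 0; j < NP; ++j)
        dA[j] = eta * sgn * ddelta[j] + (1.0 - eta) * dA[j];
      dA[7] += std::fabs(delta) - A_old;
    }
    if (trace_m) {
      double aC = par[4];
      for (int a = 0; a < 3; ++a) {
        double tr_old = tr[a];
        double ind = (a == c) ? 1.0 : 0.0;
        tr[a] = (1.0 - aC) * tr_old + aC * ind;
        for (int j = 0; j < NP; ++j) dtr[a][j] *= (1.0 - aC);
        dtr[a][4] += ind - tr_old;
      }
    }
  }
  return List::create(_["value"] = nll, _["gradient"] = grad);
}
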