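#include <Rcpp.h>
using namespace Rcpp;

// Condition codes shared with the R side:
//   0 = private, 1 = social_choice, 2 = social_choice_outcome
// Parameter vector layout: beta_p, alpha_p, beta_s, alpha_s, kappa, alpha_o.
// All per-trial arithmetic lives in the inline helpers below so that the
// simulator and the likelihood walk bit-identical code paths.

inline double softmax_p0(double q0, double q1, double beta) {
  // P(option 0) under a two-option logistic softmax
  return 1.0 / (1.0 + std::exp(-beta * (q0 - q1)));
}

inline double imitate(double p_dem, double kappa) {
  // bias the probability of the demonstrator's last choice upward:
  // P' = P + kappa * (1 - P); closed in [0,1] for kappa in [0,1]
  return p_dem + kappa * (1.0 - p_dem);
}

inline void delta_update(double q[2], int choice, double r, double alpha) {
  q[choice] += alpha * (r - q[choice]);
}

// current reward probability of option 0 at trial t (0-based); contingencies
// swap between options from the reversal trial onward
inline double p0_at(double pr0, int rev, int t) {
  return (rev >= 0 && t >= rev) ? 1.0 - pr0 : pr0;
}

inline int best_option(double pr0_cur) {
  return pr0_cur >= 0.5 ? 0 : 1;
}

inline double draw_reward(double p_win) {
  return (unif_rand() < p_win) ? 1.0 : -1.0;
}

// Per-trial choice probability pair for the participant model, given state.
// Fills p[2]. last_dem is the demonstrator choice displayed on the previous
// trial of the block (-1 if none / private). The imitation bias is applied
// to the demonstrator's option and the other option renormalized, exactly
// mirroring the exported R operations.
inline void participant_probs(const double q[2], int cond, int last_dem,
                              double beta_p, double beta_s, double kappa,
                              double p[2]) {
  double beta = (cond == 0) ? beta_p : beta_s;
  p[0] = softmax_p0(q[0], q[1], beta);
  p[1] = 1.0 - p[0];
  if (cond == 1 && last_dem >= 0) {
    p[last_dem] = imitate(p[last_dem], kappa);
    p[1 - last_dem] = 1.0 - p[last_dem];
  }
}

// [[Rcpp::export]]
List cpp_simulate_demonstrator(IntegerVector n_trials, NumericVector pr0,
                               IntegerVector rev, double alpha, double beta) {
  int n_blocks = n_trials.size();
  int total = 0;
  for (int b = 0; b < n_blocks; ++b) total += n_trials[b];
  IntegerVector choice(total), block(total), trial(total);
  NumericVector outcome(total);
  RNGScope scope;
  int i = 0;
  for (int b = 0; b < n_blocks; ++b) {
    double q[2] = {0.0, 0.0};
    for (int t = 0; t < n_trials[b]; ++t, ++i) {
      double p0 = softmax_p0(q[0], q[1], beta);
      int c = (unif_rand() < p0) ? 0 : 1;
      double p0c = p0_at(pr0[b], rev[b], t);
      double r = draw_reward(c == 0 ? p0c : 1.0 - p0c);
      delta_update(q, c, r, alpha);
      block[i] = b + 1;
      trial[i] = t;
      choice[i] = c;
      outcome[i] = r;
    }
  }
  return List::create(_["block_id"] = block, _["trial"] = trial,
                      _["choice"] = choice, _["outcome"] = outcome);
}

// [[Rcpp::export]]
List cpp_simulate_participant(IntegerVector n_trials, IntegerVector cond,
                              NumericVector pr0, IntegerVector rev,
                              IntegerVector dem_choice, NumericVector dem_outcome,
                              NumericVector pars, double eps) {
  int n_blocks = n_trials.size();
  int total = 0;
  for (int b = 0; b < n_blocks; ++b) total += n_trials[b];
  double beta_p = pars[0], alpha_p = pars[1], beta_s = pars[2],
         alpha_s = pars[3], kappa = pars[4], alpha_o = pars[5];
  IntegerVector block(total), trial(total), choice(total);
  NumericVector outcome(total), logp(total);
  LogicalVector correct(total);
  RNGScope scope;
  int i = 0;
  for (int b = 0; b < n_blocks; ++b) {
    double q[2] = {0.0, 0.0};
    int last_dem = -1;
    for (int t = 0; t < n_trials[b]; ++t, ++i) {
      int cd = cond[b];
      double p[2];
      participant_probs(q, cd, last_dem, beta_p, beta_s, kappa, p);
      int c = (unif_rand() < p[0]) ? 0 : 1;
      logp[i] = std::log(std::max(p[c], eps));
      double p0c = p0_at(pr0[b], rev[b], t);
      double r = draw_reward(c == 0 ? p0c : 1.0 - p0c);
      double alpha = (cd == 0) ? alpha_p : alpha_s;
      delta_update(q, c, r, alpha);
      if (cd == 1) last_dem = dem_choice[i];
      if (cd == 2) delta_update(q, dem_choice[i], dem_outcome[i], alpha_o);
      block[i] = b + 1;
      trial[i] = t;
      choice[i] = c;
      outcome[i] = r;
      correct[i] = (c == best_option(p0c));
    }
  }
  return List::create(_["block_id"] = block, _["trial"] = trial,
                      _["choice"] = choice, _["outcome"] = outcome,
                      _["correct"] = correct, _["logp_choice"] = logp);
}

// core likelihood walk shared by the exported trial-wise version and the
// optimizer objective
static double session_loglik_core(const int *block_id, const int *trial,
                                  const int *cond, const int *choice,
                                  const double *outcome,
                                  const int *dem_choice,
                                  const double *dem_outcome, int n,
                                  const double *pars, double eps,
                                  double *logp_out) {
  double beta_p = pars[0], alpha_p = pars[1], beta_s = pars[2],
         alpha_s = pars[3], kappa = pars[4], alpha_o = pars[5];
  double q[2] = {0.0, 0.0};
  int last_dem = -1;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (trial[i] == 0) { q[0] = 0.0; q[1] = 0.0; last_dem = -1; }
    int cd = cond[i];
    double p[2];
    participant_probs(q, cd, last_dem, beta_p, beta_s, kappa, p);
    int c = choice[i];
    double lp = std::log(std::max(p[c], eps));
    if (logp_out) logp_out[i] = lp;
    total += lp;
    double alpha = (cd == 0) ? alpha_p : alpha_s;
    delta_update(q, c, outcome[i], alpha);
    if (cd == 1) last_dem = dem_choice[i];
    if (cd == 2 && dem_choice[i] >= 0)
      delta_update(q, dem_choice[i], dem_outcome[i], alpha_o);
  }
  return total;
}

// Trial-wise log-probability of the participant's recorded choices under the
// social RL policy. The plain Q-learner is the kappa = alpha_o = 0,
// beta_s = beta_p, alpha_s = alpha_p special case.
// [[Rcpp::export]]
NumericVector cpp_session_logp(IntegerVector block_id, IntegerVector trial,
                               IntegerVector cond, IntegerVector choice,
                               NumericVector outcome, IntegerVector dem_choice,
                               NumericVector dem_outcome, NumericVector pars,
                               double eps) {
  int n = block_id.size();
  NumericVector logp(n);
  session_loglik_core(INTEGER(block_id), INTEGER(trial), INTEGER(cond),
                      INTEGER(choice), REAL(outcome), INTEGER(dem_choice),
                      REAL(dem_outcome), n, REAL(pars), eps, REAL(logp));
  return logp;
}

// ---- MAP objective in transformed space ------------------------------------
// x holds log temperatures and logit rates. model_code 0 = social (6 free
// parameters), 1 = plain Q-learner (x = log beta, logit alpha; mapped onto
// the 6-parameter kernel with kappa = alpha_o = 0). prior = (gamma shape,
// gamma scale, beta shape1, beta shape2). Returns the negative log
// posterior.

static double nlp_core(const double *x, int model_code, const int *block_id,
                       const int *trial, const int *cond, const int *choice,
                       const double *outcome, const int *dem_choice,
                       const double *dem_outcome, int n,
                       const double *prior, double eps) {
  double th[6], pars[6];
  int np = (model_code == 1) ? 2 : 6;
  bool is_temp[6] = {true, false, true, false, false, false};
  if (model_code == 1) { is_temp[0] = true; is_temp[1] = false; }
  for (int k = 0; k < np; ++k)
    th[k] = is_temp[k] ? std::exp(x[k]) : 1.0 / (1.0 + std::exp(-x[k]));
  if (model_code == 1) {
    pars[0] = th[0]; pars[1] = th[1]; pars[2] = th[0]; pars[3] = th[1];
    pars[4] = 0.0; pars[5] = 0.0;
  } else {
    for (int k = 0; k < 6; ++k) pars[k] = th[k];
  }
  double lp = session_loglik_core(block_id, trial, cond, choice, outcome,
                                  dem_choice, dem_outcome, n, pars, eps,
                                  nullptr);
  for (int k = 0; k < np; ++k) {
    lp += is_temp[k]
      ? R::dgamma(th[k], prior[0], prior[1], 1)
      : R::dbeta(th[k], prior[2], prior[3], 1);
  }
  return -lp;
}

// [[Rcpp::export]]
double cpp_nlp(NumericVector x, int model_code, IntegerVector block_id,
               IntegerVector trial, IntegerVector cond, IntegerVector choice,
               NumericVector outcome, IntegerVector dem_choice,
               NumericVector dem_outcome, NumericVector prior, double eps) {
  return nlp_core(REAL(x), model_code, INTEGER(block_id), INTEGER(trial),
                  INTEGER(cond), INTEGER(choice), REAL(outcome),
                  INTEGER(dem_choice), REAL(dem_outcome), block_id.size(),
                  REAL(prior), eps);
}

// central-difference gradient of cpp_nlp, evaluated entirely in C++
// [[Rcpp::export]]
NumericVector cpp_nlp_grad(NumericVector x, int model_code,
                           IntegerVector block_id, IntegerVector trial,
                           IntegerVector cond, IntegerVector choice,
                           NumericVector outcome, IntegerVector dem_choice,
                           NumericVector dem_outcome, NumericVector prior,
                           double eps, double h) {
  int np = x.size();
  NumericVector g(np);
  std::vector<double> xi(REAL(x), REAL(x) + np);
  for (int k = 0; k < np; ++k) {
    double x0 = xi[k];
    xi[k] = x0 + h;
    double fp = nlp_core(xi.data(), model_code, INTEGER(block_id),
                         INTEGER(trial), INTEGER(cond), INTEGER(choice),
                         REAL(outcome), INTEGER(dem_choice),
                         REAL(dem_outcome), block_id.size(), REAL(prior),
                         eps);
    xi[k] = x0 - h;
    double fm = nlp_core(xi.data(), model_code, INTEGER(block_id),
                         INTEGER(trial), INTEGER(cond), INTEGER(choice),
                         REAL(outcome), INTEGER(dem_choice),
                         REAL(dem_outcome), block_id.size(), REAL(prior),
                         eps);
    xi[k] = x0;
    g[k] = (fp - fm) / (2.0 * h);
  }
  return g;
}
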