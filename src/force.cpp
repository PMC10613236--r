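// FORCE (recursive-least-squares) training and forward simulation of a
// rate network with sigmoidal transfer. Uses R's RNG so results are
// reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& x, double beta, double theta) {
  return 1.0 / (1.0 + arma::exp(-beta * (x - theta)));
}

static arma::vec draw_noise(int n, double sd) {
  if (sd <= 0.0) return arma::zeros<arma::vec>(n);
  NumericVector z = rnorm(n, 0.0, sd);
  return arma::vec(z.begin(), n, true);
}

// Train J in place over alternating right/left episodes. target_index maps
// each 1-ms step to a (1-based) target sample column; stim_shape/cue_shape
// are unit-amplitude input waveforms per step. The stimulus peak for right
// episodes is redrawn each episode from N(peak_mean, peak_sd); left
// episodes have zero stimulus.
// [[Rcpp::export]]
List force_train_cpp(arma::mat J, arma::vec Wstim, arma::vec Wcue,
                     arma::mat P, const arma::mat& f_right,
                     const arma::mat& f_left, const arma::vec& stim_shape,
                     const arma::vec& cue_shape,
                     const arma::ivec& target_index, double dt_over_tau,
                     double beta, double theta, double noise_sd,
                     double alpha_learn, int epochs, double peak_mean,
                     double peak_sd) {
  const int n = J.n_rows;
  const int n_steps = stim_shape.n_elem;
  arma::vec x(n), r(n), z(n), e(n), Pr(n);
  for (int ep = 0; ep < epochs; ++ep) {
    const bool right = (ep % 2 == 0);
    const arma::mat& f = right ? f_right : f_left;
    double peak = right ? R::rnorm(peak_mean, peak_sd) : 0.0;
    // start each episode at the target-consistent state (x = first target
    // sample): the entry transient from x = 0 visits degenerate
    // near-constant rate vectors that poison the least-squares state
    x = f.col(0);
    r = sigm(x, beta, theta);
    for (int s = 0; s < n_steps; ++s) {
      z = J * r + Wstim * (peak * stim_shape[s]) + Wcue * cue_shape[s] +
          draw_noise(n, noise_sd);
      x += dt_over_tau * (-x + z);
      r = sigm(x, beta, theta);
      e = z - f.col(target_index[s] - 1);
      Pr = P * r;
      double c = 1.0 / (1.0 + arma::dot(r, Pr));
      J -= alpha_learn * (e * c) * Pr.t();
      P -= c * (Pr * Pr.t());
      if (!x.is_finite()) {
        stop("force_train: non-finite state at epoch %d, step %d", ep + 1,
             s + 1);
      }
    }
  }
  return List::create(_["J"] = J, _["P"] = P);
}

// Forward-simulate one trial with frozen weights; stim_input/cue_input are
// fully scaled per-step drives. Returns unit rates at every ds-th step
// (n x n_steps/ds).
// [[Rcpp::export]]
arma::mat sim_trial_cpp(const arma::mat& J, const arma::vec& Wstim,
                        const arma::vec& Wcue, const arma::vec& stim_input,
                        const arma::vec& cue_input, double dt_over_tau,
                        double beta, double theta, double noise_sd, int ds,
                        const arma::vec& x0) {
  const int n = J.n_rows;
  const int n_steps = stim_input.n_elem;
  const int n_out = n_steps / ds;
  arma::mat out(n, n_out);
  arma::vec x = x0;
  arma::vec r = sigm(x, beta, theta);
  int k = 0;
  for (int s = 0; s < n_steps; ++s) {
    arma::vec z = J * r + Wstim * stim_input[s] + Wcue * cue_input[s] +
                  draw_noise(n, noise_sd);
    x += dt_over_tau * (-x + z);
    r = sigm(x, beta, theta);
    if ((s + 1) % ds == 0 && k < n_out) out.col(k++) = r;
  }
  if (!out.is_finite()) stop("sim_trial: non-finite activity");
  return out;
}
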