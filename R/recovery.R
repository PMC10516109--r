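# End-to-end recovery battery: generate synthetic sessions with known ground
# truth, run every pipeline stage, and score the recoveries against stated
# tolerances. This is the package's own acceptance machinery.

#' Run the generate -> analyze -> compare recovery battery
#'
#' Executes, under one seed: (1) theory-versus-simulation error-rate curves
#' on a small grid; (2) a geometry-recovery session (binary value coding)
#' pushed through crossnobis + non-negative least squares, the disattenuated
#' subspace-correlation pipeline, and predicted-versus-empirical (SVM)
#' generalization; (3) the planted- and null-effect error-trial projection
#' batteries; (4) behavior-model parameter recovery averaged over replicate
#' agents; (5) a zero-noise session for exact recovery. Returns a scorecard
#' with one row per check.
#'
#' @param n_neurons Neurons in the geometry-recovery session (default 200).
#' @param trials_per_condition Trials per value x side condition (default
#'   500).
#' @param sim_trials Monte-Carlo trials per theory-validation grid point.
#' @param n_proj_sessions Sessions per error-projection battery (default 20).
#' @param behavior_reps Replicate agents for behavior recovery (default 8).
#' @param behavior_trials Trials per replicate agent (default 5000).
#' @param n_boot Bootstrap resamples for CIs (default 200).
#' @param seed Integer seed for all stages.
#' @return A data.frame scorecard: `check`, `value`, `tolerance`,
#'   `direction` (`"le"`: value must be <= tolerance; `"ge"`: >=), `pass`;
#'   detailed stage outputs in `attr(, "details")`.
#' @export
recovery_suite <- function(n_neurons = 200, trials_per_condition = 500,
                           sim_trials = 2e4, n_proj_sessions = 20,
                           behavior_reps = 8, behavior_trials = 5000,
                           n_boot = 200, seed = 1L) {
  seed <- as.integer(seed)
  details <- list()
  rows <- list()
  add <- function(check, value, tolerance, direction = "le") {
    pass <- if (direction == "le") value <= tolerance else value >= tolerance
    rows[[length(rows) + 1L]] <<- data.frame(check = check, value = value,
                                             tolerance = tolerance,
                                             direction = direction, pass = pass)
  }

  ## 1. theory vs simulation
  curves <- simulate_error_curves(stimulus_spec(2, 2, 2),
                                  dL_grid = c(1, 1.25), dN_grid = c(0.5, 1),
                                  sigma_grid = c(0.2, 0.25, 0.3),
                                  trials = sim_trials, seed = seed)
  gap <- abs(curves$empirical - curves$analytic)
  tol <- pmax(0.02, 3 * curves$se)
  add("theory_sim_max_excess_gap", max(gap - tol), 0)
  details$curves <- curves

  ## 2. geometry recovery session
  # pure space-value code (time-value conjunction zeroed) with per-neuron
  # coefficients in the realistic 0.1-0.2 z-unit range; the decomposition
  # pools the two offer epochs, as the space-value analysis averages over
  # first and second offers
  truth <- list(dLV = 2, dLA = 1.6, dN = 1.2, sigma = 1)
  ses <- generate_population_session(
    n_neurons = n_neurons, n_trials = 2L * trials_per_condition * 2L,
    dLV = truth$dLV, dLA = truth$dLA, dN_space = truth$dN,
    dN_time = 0, dLA_time = 0,
    sigma = truth$sigma, heterogeneity = 0, value_coding = "binary",
    seed = seed + 1L)
  ctx_all <- ifelse(ses$trials$side == 1, "left", "right")
  dec <- decompose_session(ses$rates, ses$trials$level, ctx_all,
                           n_boot = n_boot, seed = seed + 2L)
  e1 <- ses$trials$epoch == 1L
  ctx <- ctx_all[e1]
  add("decomp_rel_err_dLV", abs(dec$decomp$dLV - truth$dLV) / truth$dLV, 0.10)
  add("decomp_rel_err_dLA", abs(dec$decomp$dLA - truth$dLA) / truth$dLA, 0.10)
  add("decomp_rel_err_dN", abs(dec$decomp$dN - truth$dN) / truth$dN, 0.10)
  details$decomposition <- dec

  rho <- estimate_subspace_rho(ses$rates, ses$trials$value, ses$trials$side,
                               seed = seed + 3L)
  rho_true <- ses$truth$rho_space
  add("rho_truth_in_ci",
      as.numeric(rho_true >= rho$ci[1] && rho_true <= rho$ci[2]), 1, "ge")
  details$rho <- c(rho, truth = rho_true)

  pred <- predicted_error_rates(dec$decomp, dec$sigma_hat, dec$epsilon_hat)
  pseudo <- build_pseudopopulation(
    list(list(rates = ses$rates[e1, , drop = FALSE],
              value = ses$trials$level[e1], context = ctx)),
    split = "broad", seed = seed + 4L)
  dr <- decode_value(pseudo, "left", "right", cost = "cv", seed = seed + 5L)
  emp_gen_err <- 1 - dr$generalization
  add("ccgp_pred_vs_empirical_gap", abs(pred$generalization - emp_gen_err), 0.05)
  details$predicted <- pred; details$decoder <- dr

  ## 3. planted-effect projection batteries (default-length sessions; the
  ## cross-session t-test needs per-session means in their normal regime)
  mk <- function(sd, shift) generate_population_session(
    n_neurons = 30, n_trials = 800, planted_misbinding = shift, seed = sd)
  planted <- error_projection_battery(
    lapply(seq_len(n_proj_sessions), function(i) mk(seed + 100L + i, 0.8)),
    seed = seed)
  null <- error_projection_battery(
    lapply(seq_len(n_proj_sessions), function(i) mk(seed + 200L + i, 0)),
    seed = seed)
  add("planted_spatial_p", planted$spatial$p, 0.05)
  add("planted_temporal_p", planted$temporal$p, 0.05, "ge")
  add("null_spatial_p", null$spatial$p, 0.05, "ge")
  details$planted <- planted; details$null <- null

  ## 4. behavior recovery (mean signed relative error over replicates)
  agent <- sv_model(gamma = 1.3, alpha = 0.7, beta = 1, temperature = 60,
                    variant = "full")
  truth_b <- unlist(agent[c("gamma", "alpha", "beta", "temperature")])
  rel <- matrix(NA_real_, behavior_reps, 4,
                dimnames = list(NULL, names(truth_b)))
  for (r in seq_len(behavior_reps)) {
    tt <- generate_task_trials(task_config(behavior_trials,
                                           seed = seed + 300L + r))
    beh <- simulate_agent(tt, agent, seed = seed + 400L + r)
    fit <- fit_choice_model(beh, "full", n_starts = 6, cv_folds = 2,
                            seed = seed + r)
    est <- unlist(fit$model[names(truth_b)])
    rel[r, ] <- (est - truth_b) / truth_b
  }
  add("behavior_recovery_max_mean_rel_err", max(abs(colMeans(rel))), 0.10)
  details$behavior_rel_err <- rel

  ## 5. zero-noise exact recovery
  ses0 <- generate_population_session(n_neurons = 40, n_trials = 400,
                                      dN_time = 0, dLA_time = 0,
                                      sigma = 1e-8, heterogeneity = 0,
                                      value_coding = "binary", seed = seed + 6L)
  e1 <- ses0$trials$epoch == 1L
  dec0 <- decompose_session(ses0$rates[e1, , drop = FALSE],
                            ses0$trials$level[e1],
                            ifelse(ses0$trials$side[e1] == 1, "left", "right"),
                            n_boot = 0, seed = seed + 7L)
  add("zero_noise_decomp_err",
      max(abs(c(dec0$decomp$dLV - 1, dec0$decomp$dLA - 0.8,
                dec0$decomp$dN - 0.6))), 1e-6)
  details$zero_noise <- dec0

  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}

#' Type-I error rate of the permutation ANOVA on null neurons
#'
#' Generates pure-noise neurons with task-like labels (uniform value, random
#' sides), runs [permutation_anova()], and returns the rejection rate at
#' `alpha` pooled across the three effects.
#'
#' @param n_neurons Number of null neurons (default 500).
#' @param n_trials Trials per neuron (default 300).
#' @param n_perm Permutations (default 1000).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return List with `rate` (pooled rejection rate), `per_effect`, `n_tests`.
#' @export
anova_type1_rate <- function(n_neurons = 500, n_trials = 300, n_perm = 1000,
                             alpha = 0.05, seed = 1L) {
  set.seed(seed)
  rates <- matrix(stats::rnorm(n_trials * n_neurons), n_trials, n_neurons)
  value <- stats::runif(n_trials)
  side <- sample(c(-1, 1), n_trials, replace = TRUE)
  pa <- permutation_anova(rates, value, side, n_perm = n_perm, seed = seed + 1L)
  rej <- pa$p < alpha
  list(rate = mean(rej), per_effect = rowMeans(rej),
       n_tests = length(rej))
}

#' Noise-ceiling non-rejection rate on parallel-subspace populations
#'
#' Generates populations whose left and right value subspaces are identical
#' (`dN = 0`, generative `rho = 1`) with moderate noise, runs
#' [noise_ceiling_test()], and reports the fraction of replicates whose
#' observed distribution is *not* distinguishable from the ceiling
#' (`p_vs_ceiling > alpha`) -- the test's specificity.
#'
#' @param n_rep Number of replicate populations (default 10).
#' @param n_neurons,n_trials Population size per replicate.
#' @param n_boot Bootstrap resamples per test (default 400).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return List with `rate`, `p_values`.
#' @export
ceiling_nonreject_rate <- function(n_rep = 10, n_neurons = 40, n_trials = 400,
                                   n_boot = 400, alpha = 0.05, seed = 1L) {
  ps <- vapply(seq_len(n_rep), function(r) {
    ses <- generate_population_session(
      n_neurons = n_neurons, n_trials = n_trials, dN_space = 0, dN_time = 0,
      heterogeneity = 0, value_coding = "binary", seed = seed + r)
    e1 <- ses$trials$epoch == 1L
    noise_ceiling_test(ses$rates[e1, , drop = FALSE], ses$trials$value[e1],
                       ses$trials$side[e1], contrast = "left-right",
                       n_boot = n_boot, seed = seed + 100L + r)$p_vs_ceiling
  }, numeric(1))
  list(rate = mean(ps > alpha), p_values = ps)
}
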