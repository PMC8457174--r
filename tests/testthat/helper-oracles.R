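# Shared fixtures and independent oracle helpers.

# constant schedule with fixed per-option success probabilities
const_schedule <- function(probs = c(0.7, 0.4, 0.2), n_trials = 500L) {
  generate_schedule(n_trials = n_trials, n_options = length(probs),
                    bounds = c(min(probs) - 0.01, max(probs) + 0.01),
                    drift_sd = 0, switch_rate = 0, start = probs, seed = 1L)
}

# Tucker congruence between matched factors of two loading matrices:
# greedily pairs columns by absolute congruence, returns the matched
# absolute congruence per reference column.
tucker_congruence <- function(ref, est) {
  stopifnot(ncol(ref) == ncol(est))
  K <- ncol(ref)
  phi <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  C <- abs(outer(seq_len(K), seq_len(K),
                 Vectorize(function(i, j) phi(ref[, i], est[, j]))))
  out <- numeric(K)
  for (step in seq_len(K)) {
    idx <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[idx[1]] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  out
}

# validation priors documented in the methods vignette: identifiable at
# T = 500 with the default schedule
recovery_prior_sample <- function(n, seed) {
  set.seed(seed)
  data.frame(alpha = runif(n, 0.1, 0.8),
             beta = exp(rnorm(n, log(5), 0.5)),
             gamma = rnorm(n, 0, 2),
             alpha_F = runif(n, 0.02, 0.25),
             alpha_C = runif(n, 0.3, 0.7))
}

# model-recovery generating distribution: forgetting and choice trace both
# strong enough to earn their information penalty at T = 500
model_recovery_sample <- function(n, seed) {
  set.seed(seed)
  data.frame(alpha = runif(n, 0.15, 0.7),
             beta = exp(rnorm(n, log(5), 0.5)),
             gamma = sample(c(-1, 1), n, TRUE) * (1.2 + abs(rnorm(n, 0, 1.5))),
             alpha_F = runif(n, 0.2, 0.55),
             alpha_C = runif(n, 0.3, 0.7))
}

# small planted cohort summaries for dimension-level tests
quick_cohort <- function(scenario = "paper_like", seed = 1L, n_per_arm = NULL,
                         n_trials = NULL, questionnaire = FALSE) {
  cfg <- scenario_library(scenario)
  if (!is.null(n_per_arm)) cfg$n_per_arm <- as.integer(n_per_arm)
  if (!is.null(n_trials)) cfg$n_trials <- as.integer(n_trials)
  generate_cohort(cfg, seed = seed, questionnaire = questionnaire)
}

cohort_factor_df <- function(cohort) {
  data.frame(participant_id = rownames(cohort$ground_truth$scores),
             cohort$ground_truth$scores)
}
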