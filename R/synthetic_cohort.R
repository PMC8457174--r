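#' Default instrument-blocked loading template (154 items, 3 factors)
#'
#' Five instrument blocks sized like the real symptom battery (schizotypy 22,
#' OCD 42, depression 20, anxiety 40, impulsivity 30). The compulsivity
#' dimension (CIT) loads strongly on OCD items, cross-loads on schizotypy and
#' moderately on depression/anxiety; anxious-depression (AD) loads on the
#' depression and anxiety blocks; impulsivity (IM) on its own block.
#' Within each block, loadings are evenly spaced across the block's
#' interquartile-style range so that medians match the documented profile.
#'
#' @param block_sizes named integer vector of items per instrument.
#' @return list with `loadings` (P x 3 matrix, columns CIT/AD/IM) and
#'   `item_instrument` (length-P character vector).
#' @export
default_loading_template <- function(block_sizes = c(schizotypy = 22,
                                                     OCD = 42,
                                                     depression = 20,
                                                     anxiety = 40,
                                                     impulsivity = 30)) {
  P <- sum(block_sizes)
  instrument <- rep(names(block_sizes), block_sizes)
  L <- matrix(0, P, 3, dimnames = list(
    sprintf("item_%03d", seq_len(P)), c("CIT", "AD", "IM")))
  spread <- function(lo, hi, n) seq(lo, hi, length.out = n)
  blocks <- split(seq_len(P), factor(instrument, levels = names(block_sizes)))
  # CIT profile: OCD 0.63-0.74, schizotypy 0.22-0.37, depression -0.05-0.31,
  # anxiety -0.01-0.36
  L[blocks$OCD, "CIT"] <- spread(0.63, 0.74, block_sizes["OCD"])
  L[blocks$schizotypy, "CIT"] <- spread(0.22, 0.37, block_sizes["schizotypy"])
  L[blocks$depression, "CIT"] <- spread(-0.05, 0.31, block_sizes["depression"])
  L[blocks$anxiety, "CIT"] <- spread(-0.01, 0.36, block_sizes["anxiety"])
  # AD profile: depression 0.16-0.58, anxiety 0.26-0.75
  L[blocks$depression, "AD"] <- spread(0.16, 0.58, block_sizes["depression"])
  L[blocks$anxiety, "AD"] <- spread(0.26, 0.75, block_sizes["anxiety"])
  # IM profile: impulsivity 0.21-0.55
  L[blocks$impulsivity, "IM"] <- spread(0.21, 0.55, block_sizes["impulsivity"])
  list(loadings = L, item_instrument = instrument)
}

#' Construct a synthetic-cohort configuration
#'
#' The stated world of the generator: two task arms of `n_per_arm`
#' participants, 500-trial sessions on one shared drifting schedule, RL2b
#' agents whose learning rate is negatively and whose choice-trace weight is
#' positively linked to the latent CIT dimension, ~0.9% missed responses, and
#' a 154-item ordinal battery generated from the three correlated latent
#' dimensions. Pairwise factor correlations share at most 15% variance.
#'
#' @param n_per_arm participants per task arm (default 200).
#' @param n_trials trials per session (default 500).
#' @param factor_corr 3x3 latent correlation matrix (CIT, AD, IM).
#' @param block_sizes instrument block sizes for the battery.
#' @param thresholds ordinal thresholds applied to every item latent (default
#'   three cuts giving 4 response levels, skewed toward low endorsement).
#' @param model_id generating model (default `"RL2b"`).
#' @param miss_rate per-trial failure-to-respond probability (default 0.009).
#' @param alpha_link,gamma_link named per-arm CIT slopes for the learning rate
#'   (logit scale) and the choice-trace weight.
#' @param alpha_base,alpha_sd logit-scale intercept and residual SD of alpha.
#' @param gamma_base,gamma_sd intercept and residual SD of gamma.
#' @param beta_meanlog,beta_sdlog log-normal parameters of beta.
#' @param alpha_F_base,alpha_F_sd,alpha_C_base,alpha_C_sd logit-scale
#'   intercepts/SDs for the forgetting and trace-decay rates.
#' @param schedule list of arguments to [generate_schedule()].
#' @return a `transdx_cohort_config` list.
#' @export
cohort_config <- function(n_per_arm = 200L, n_trials = 500L,
                          factor_corr = matrix(c(1, 0.3, 0.37,
                                                 0.3, 1, 0.2,
                                                 0.37, 0.2, 1), 3, 3),
                          block_sizes = c(schizotypy = 22, OCD = 42,
                                          depression = 20, anxiety = 40,
                                          impulsivity = 30),
                          thresholds = c(-0.8, 0.3, 1.2),
                          model_id = "RL2b", miss_rate = 0.009,
                          alpha_link = c(reward = -0.9, loss = -0.9),
                          gamma_link = c(reward = 0.5, loss = 0.5),
                          alpha_base = qlogis(0.12), alpha_sd = 0.4,
                          gamma_base = -0.5, gamma_sd = 0.3,
                          beta_meanlog = log(4), beta_sdlog = 0.8,
                          alpha_F_base = qlogis(0.2), alpha_F_sd = 0.5,
                          alpha_C_base = qlogis(0.3), alpha_C_sd = 0.5,
                          schedule = list()) {
  dimnames(factor_corr) <- list(c("CIT", "AD", "IM"), c("CIT", "AD", "IM"))
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("factor covariance must be PSD")
  off <- factor_corr[upper.tri(factor_corr)]
  if (any(off^2 > 0.15 + 1e-12))
    stop("pairwise shared variance among factors must not exceed 15%")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  validate_model_id(model_id)
  structure(list(n_per_arm = as.integer(n_per_arm),
                 n_trials = as.integer(n_trials),
                 factor_corr = factor_corr, block_sizes = block_sizes,
                 thresholds = thresholds, model_id = model_id,
                 miss_rate = miss_rate,
                 alpha_link = alpha_link, gamma_link = gamma_link,
                 alpha_base = alpha_base, alpha_sd = alpha_sd,
                 gamma_base = gamma_base, gamma_sd = gamma_sd,
                 beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
                 alpha_F_base = alpha_F_base, alpha_F_sd = alpha_F_sd,
                 alpha_C_base = alpha_C_base, alpha_C_sd = alpha_C_sd,
                 schedule = schedule),
            class = "transdx_cohort_config")
}

#' Generate ordinal questionnaire responses from latent factor scores
#'
#' Each item latent is `Lambda f + e` with unique noise
#' `e ~ N(0, 1 - communality)` (communality `l' Phi l`); responses are the
#' ordinal bins of the item latent under the thresholds.
#'
#' @param scores N x 3 latent factor scores.
#' @param loadings P x 3 loading matrix.
#' @param thresholds numeric vector of strictly increasing cuts (shared by all
#'   items) or a list of per-item cut vectors.
#' @param seed integer seed.
#' @param factor_corr latent factor correlation used for the communality
#'   (default identity).
#' @param item_instrument optional instrument map carried into the result.
#' @return a `transdx_questionnaire`: list with `responses` (N x P integer
#'   matrix, levels `1..K+1`) and `item_instrument`.
#' @export
questionnaire_from_factors <- function(scores, loadings, thresholds, seed = 1L,
                                       factor_corr = diag(3),
                                       item_instrument = NULL) {
  scores <- as.matrix(scores)
  loadings <- as.matrix(loadings)
  if (ncol(scores) != ncol(loadings))
    stop("scores and loadings disagree on factor count")
  P <- nrow(loadings)
  thr <- if (is.list(thresholds)) thresholds else rep(list(thresholds), P)
  if (length(thr) != P) stop("one threshold vector per item required")
  for (tt in thr) if (length(tt) < 1L || any(diff(tt) <= 0))
    stop("thresholds must be strictly increasing with at least one cut")
  communality <- rowSums((loadings %*% factor_corr) * loadings)
  if (any(communality >= 1))
    stop("item communality >= 1: rescale loadings")
  set.seed(as.integer(seed))
  latent <- tcrossprod(scores, loadings) +
    matrix(rnorm(nrow(scores) * P), nrow(scores), P) *
      rep(sqrt(1 - communality), each = nrow(scores))
  resp <- matrix(1L, nrow(scores), P)
  for (p in seq_len(P))
    resp[, p] <- 1L + findInterval(latent[, p], thr[[p]])
  dimnames(resp) <- list(rownames(scores), rownames(loadings))
  structure(list(responses = resp, item_instrument = item_instrument),
            class = "transdx_questionnaire")
}

#' @export
print.transdx_questionnaire <- function(x, ...) {
  cat(sprintf("<transdx_questionnaire> %d participants x %d items\n",
              nrow(x$responses), ncol(x$responses)))
  invisible(x)
}

#' Generate a full synthetic study with planted ground truth
#'
#' Latent psychiatric scores are multivariate normal with the configured
#' correlation; RL parameters derive from them (`alpha` by inverse-logit of a
#' linear CIT link, `gamma` by a linear CIT link, others factor-independent);
#' sessions are simulated with the generating model on one schedule shared by
#' both arms (as in the task, where the reward and no-loss probability
#' sequences were identical); questionnaires are thresholded factor-plus-noise
#' latents. Everything is reproducible from `(config, seed)`.
#'
#' @param config a `transdx_cohort_config`.
#' @param seed integer master seed (sub-seeds are derived from it).
#' @param questionnaire generate the ordinal battery (default TRUE; switch off
#'   to save time when only behaviour is needed).
#' @return list with `sessions` (named list of `transdx_session`), `schedule`,
#'   `questionnaire`, `ground_truth` (scores, params, loadings, covariates,
#'   arm), and `labeling`.
#' @export
generate_cohort <- function(config, seed = 1L, questionnaire = TRUE) {
  stopifnot(inherits(config, "transdx_cohort_config"))
  base <- as.integer(seed)
  n_arm <- config$n_per_arm
  N <- 2L * n_arm
  arms <- rep(c("reward", "loss"), each = n_arm)
  ids <- sprintf("%s%04d", ifelse(arms == "reward", "R", "L"),
                 c(seq_len(n_arm), seq_len(n_arm)))

  sched_args <- c(list(n_trials = config$n_trials, seed = base + 1L),
                  config$schedule)
  schedule <- do.call(generate_schedule, sched_args)

  set.seed(base + 2L)
  Zl <- matrix(rnorm(N * 3), N, 3)
  scores <- Zl %*% chol(config$factor_corr)
  colnames(scores) <- c("CIT", "AD", "IM")
  rownames(scores) <- ids

  set.seed(base + 3L)
  covariates <- data.frame(
    participant_id = ids,
    age = round(runif(N, 20, 69)),
    sex = sample(1:2, N, replace = TRUE),
    education = sample(1:7, N, replace = TRUE,
                       prob = c(0.02, 0.25, 0.08, 0.12, 0.12, 0.32, 0.09)),
    ses = sample(1:10, N, replace = TRUE))

  set.seed(base + 4L)
  cit <- scores[, "CIT"]
  a_link <- config$alpha_link[arms]
  g_link <- config$gamma_link[arms]
  params <- data.frame(
    participant_id = ids,
    alpha = plogis(config$alpha_base + a_link * cit +
                     rnorm(N, 0, config$alpha_sd)),
    beta = exp(rnorm(N, config$beta_meanlog, config$beta_sdlog)),
    gamma = config$gamma_base + g_link * cit + rnorm(N, 0, config$gamma_sd),
    alpha_F = plogis(config$alpha_F_base + rnorm(N, 0, config$alpha_F_sd)),
    alpha_C = plogis(config$alpha_C_base + rnorm(N, 0, config$alpha_C_sd)))
  params <- clip_to_boxes(params)

  pnames <- rl_param_names(config$model_id)
  sessions <- vector("list", N)
  for (i in seq_len(N)) {
    pv <- unlist(params[i, pnames])
    sessions[[i]] <- simulate_agent(
      schedule, arms[i], config$model_id, pv,
      miss_rate = config$miss_rate,
      seed = (base %% 1000000L) * 2000L + i,
      participant_id = ids[i],
      learn_coding = "success")  # arms differ only by the planted links
  }
  names(sessions) <- ids

  quest <- NULL
  if (questionnaire) {
    tmpl <- default_loading_template(config$block_sizes)
    quest <- questionnaire_from_factors(
      scores, tmpl$loadings, config$thresholds, seed = base + 5L,
      factor_corr = config$factor_corr,
      item_instrument = tmpl$item_instrument)
  }

  ground_truth <- list(scores = scores, params = params,
                       loadings = if (questionnaire) tmpl$loadings else
                         default_loading_template(config$block_sizes)$loadings,
                       factor_corr = config$factor_corr,
                       covariates = covariates,
                       arm = setNames(arms, ids),
                       config = config, seed = base)
  list(sessions = sessions, schedule = schedule, questionnaire = quest,
       ground_truth = ground_truth, labeling = label_correct(schedule))
}

# clip the <1% of generated parameters that fall outside the fitting boxes;
# error if the links push clearly more than 1% out (binomial test at the 1%
# rate so small cohorts do not trip on 2-3 chance violations)
clip_to_boxes <- function(params) {
  n <- nrow(params)
  for (nm in setdiff(names(params), "participant_id")) {
    b <- param_box(nm)
    n_out <- sum(params[[nm]] < b[1] | params[[nm]] > b[2])
    if (n_out > 0 &&
        stats::pbinom(n_out - 1L, n, 0.01, lower.tail = FALSE) < 1e-3)
      stop(sprintf("%.1f%% of '%s' values outside the fitting box; rescale the links",
                   100 * n_out / n, nm))
    params[[nm]] <- pmin(pmax(params[[nm]], b[1]), b[2])
  }
  params
}

#' Named library of study scenarios
#'
#' * `paper_like` - both arms, CIT negatively linked to the learning rate in
#'   both arms, CIT positively linked to the choice-trace weight in the reward
#'   arm only (the planted dissociation).
#' * `null` - no links between dimensions and RL parameters.
#' * `strong_effects` - doubled link slopes in both arms.
#' * `small_n_smoke` - 20 participants per arm, 100 trials, 30-item battery;
#'   completes the whole CLI pipeline quickly.
#'
#' @param name scenario name; omit for the full named list.
#' @return a `transdx_cohort_config` (or named list of them).
#' @export
scenario_library <- function(name = NULL) {
  lib <- list(
    paper_like = cohort_config(gamma_link = c(reward = 0.5, loss = 0)),
    null = cohort_config(alpha_link = c(reward = 0, loss = 0),
                         gamma_link = c(reward = 0, loss = 0)),
    strong_effects = cohort_config(alpha_link = c(reward = -1.3, loss = -1.3),
                                   gamma_link = c(reward = 0.8, loss = 0.8)),
    small_n_smoke = cohort_config(n_per_arm = 20L, n_trials = 100L,
                                  block_sizes = c(schizotypy = 4, OCD = 8,
                                                  depression = 4, anxiety = 8,
                                                  impulsivity = 6)))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(lib), collapse = ", ")))
  lib[[name]]
}

#' Per-participant summaries for the dimension-level analyses
#'
#' Computes each participant's correct/responded counts against the schedule
#' labeling and joins factor scores (true by default), covariates, task
#' coding, and, when a fit table is supplied, the generating model's fitted
#' parameters.
#'
#' @param cohort output of [generate_cohort()].
#' @param scores N x 3 matrix of factor scores to use (default: planted truth;
#'   pass Harman scores for the estimated pipeline).
#' @param fits optional [fit_cohort()] table filtered to one model.
#' @return data.frame, one row per participant.
#' @export
summarize_cohort <- function(cohort, scores = NULL, fits = NULL) {
  if (is.null(scores)) scores <- cohort$ground_truth$scores
  ids <- names(cohort$sessions)
  perf <- t(vapply(cohort$sessions, function(s) {
    pf <- performance(s, cohort$labeling)
    c(n_correct = sum(pf$is_correct), n_responded = pf$n_responded)
  }, numeric(2)))
  out <- data.frame(participant_id = ids,
                    n_correct = perf[, "n_correct"],
                    n_responded = perf[, "n_responded"],
                    task = ifelse(cohort$ground_truth$arm[ids] == "reward",
                                  1, -1),
                    scores[ids, , drop = FALSE])
  out <- merge(out, cohort$ground_truth$covariates, by = "participant_id",
               sort = TRUE)
  if (!is.null(fits)) {
    keep <- c("participant_id", "alpha", "beta", "gamma", "alpha_F", "alpha_C")
    out <- merge(out, fits[, intersect(keep, names(fits))],
                 by = "participant_id", sort = TRUE)
  }
  rownames(out) <- NULL
  out
}
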