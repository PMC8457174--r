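# Parameter boxes and transforms used by the maximum-likelihood fitter.
# Rates live in [0.001, 0.999] via logit, beta in [0.001, 30] via log,
# gamma in [-10, 10] untransformed.
param_box <- function(name) {
  switch(name,
         beta = c(0.001, 30),
         gamma = c(-10, 10),
         c(0.001, 0.999))  # all rate parameters
}

to_transformed <- function(name, v) {
  switch(name, beta = log(v), gamma = v, qlogis(v))
}

from_transformed <- function(name, x) {
  switch(name, beta = exp(x), gamma = x, plogis(x))
}

transformed_bounds <- function(name) {
  b <- param_box(name)
  vapply(b, function(v) to_transformed(name, v), numeric(1))
}

#' Fit one RL model to one participant
#'
#' Box-constrained quasi-Newton (`optim` L-BFGS-B with the exact
#' forward-sensitivity gradient) on transformed parameters (rates via logit,
#' `beta` via log, `gamma` untransformed), taking the best of `n_starts`
#' seeded random initializations drawn uniformly in transformed space.
#' Deterministic given `seed`.
#'
#' By default the objective is weakly penalized ("weak"): logit-rates get a
#' `N(0, 2)` penalty, `beta` a half-normal(10) penalty on its natural scale,
#' `gamma` a `N(0, 3)` penalty. These priors are flat over the plausible
#' parameter range and only suppress the likelihood's degenerate ridges (the
#' trace-decay/trace-weight trade-off and the small-alpha/large-beta mode)
#' that otherwise make the trace and forgetting models unrecoverable from
#' single 500-trial sessions. `penalty = "none"` gives plain maximum
#' likelihood. The reported `nll` is always the unpenalized negative
#' log-likelihood at the returned estimate.
#'
#' @param session a `transdx_session` with at least `min_trials` responded
#'   trials.
#' @param model_id model id.
#' @param n_starts number of random restarts (default 10).
#' @param seed integer seed for the restarts.
#' @param Q0,loss_coding passed to [negative_log_likelihood()].
#' @param min_trials responded-trial floor (default 50).
#' @param penalty `"weak"` (default) or `"none"`.
#' @return A `ModelFitResult`-style list: `participant_id`, `model_id`,
#'   `params` (named vector), `nll`, `n_obs`, `k`, `bic`, `evidence`
#'   (`-bic/2`), `n_starts`, `converged`.
#' @export
fit_participant <- function(session, model_id, n_starts = 10L, seed = 1L,
                            Q0 = 0, loss_coding = "raw", min_trials = 50L,
                            penalty = c("weak", "none")) {
  penalty <- match.arg(penalty)
  validate_model_id(model_id)
  n_obs <- sum(!is.na(session$choices))
  if (n_obs < min_trials)
    stop(sprintf("session %s has %d responded trials (< floor %d)",
                 session$participant_id, n_obs, min_trials))
  nm <- rl_param_names(model_id)
  k <- length(nm)
  code <- model_code(model_id)
  out <- session$outcomes
  if (session$context == "loss" && loss_coding == "success") out <- out + 1
  out[is.na(out)] <- 0
  choices <- session$choices

  lower <- vapply(nm, function(p) transformed_bounds(p)[1], numeric(1))
  upper <- vapply(nm, function(p) transformed_bounds(p)[2], numeric(1))

  canon <- setNames(numeric(9),
                    c("alpha", "beta", "gamma", "alpha_F", "alpha_C",
                      "alpha_pos", "alpha_neg", "eta", "kappa"))
  idx <- match(nm, names(canon))
  kind <- vapply(nm, function(p)
    switch(p, beta = "log", gamma = "id", "logit"), character(1))
  # value and exact chain-ruled gradient in transformed space, memoized so
  # optim's paired fn/gr calls cost one likelihood pass
  cache_x <- NULL; cache <- NULL
  pen_on <- penalty == "weak"
  eval_both <- function(x) {
    if (!is.null(cache_x) && identical(x, cache_x)) return(cache)
    v <- x
    v[kind == "log"] <- exp(x[kind == "log"])
    v[kind == "logit"] <- plogis(x[kind == "logit"])
    full <- canon
    full[idx] <- v
    r <- .nll_grad_cpp(choices, out, code, full, Q0)
    jac <- ifelse(kind == "log", v,
                  ifelse(kind == "id", 1, v * (1 - v)))
    val <- r$value
    g <- r$gradient[idx] * jac
    if (pen_on) {
      val <- val +
        sum(0.5 * (x[kind == "logit"] / 2)^2) +      # rates: logit N(0, 2)
        sum(0.5 * (v[kind == "log"] / 10)^2) +       # beta: half-normal(10)
        sum(0.5 * (x[kind == "id"] / 3)^2)           # gamma: N(0, 3)
      g[kind == "logit"] <- g[kind == "logit"] + x[kind == "logit"] / 4
      g[kind == "log"] <- g[kind == "log"] + v[kind == "log"]^2 / 100
      g[kind == "id"] <- g[kind == "id"] + x[kind == "id"] / 9
    }
    cache_x <<- x
    cache <<- list(value = val, grad = g)
    cache
  }

  set.seed(as.integer(seed))
  starts <- matrix(runif(n_starts * k, rep(lower, each = n_starts),
                         rep(upper, each = n_starts)), nrow = n_starts)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[s, ], function(x) eval_both(x)$value,
            function(x) eval_both(x)$grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")
  if (!any_conv)
    warning(sprintf("no start converged for %s / %s; returning best incumbent",
                    session$participant_id, model_id))
  params <- setNames(mapply(from_transformed, nm, best$par), nm)
  full <- canon
  full[idx] <- params
  nll <- .nll_cpp(choices, out, code, full, Q0)  # unpenalized, at the estimate
  bic <- 2 * nll + k * log(n_obs)
  structure(list(participant_id = session$participant_id,
                 model_id = model_id,
                 params = params,
                 nll = nll, n_obs = n_obs, k = k,
                 bic = bic, evidence = -bic / 2,
                 n_starts = n_starts, converged = any_conv),
            class = "transdx_fit")
}

#' @export
print.transdx_fit <- function(x, ...) {
  cat(sprintf("<transdx_fit> %s / %s: nll %.2f, bic %.2f (%s)\n",
              x$participant_id, x$model_id, x$nll, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$params, 4))
  invisible(x)
}

# stable per-participant seed so fit_cohort is order-independent
participant_seed <- function(base_seed, participant_id, model_index) {
  h <- sum(utf8ToInt(as.character(participant_id)) *
             (seq_along(utf8ToInt(as.character(participant_id))) %% 97 + 1))
  as.integer((as.integer(base_seed) %% 100000L) * 17L +
               h %% 1000003L + 131L * model_index) %% 2000000000L
}

#' Fit several models to a cohort of sessions
#'
#' Produces one row per participant-model cell. Per-fit seeds are derived from
#' the participant id and model, so results do not depend on the order of
#' `sessions`. Individual fit failures are recorded (`converged = NA` row), not
#' fatal.
#'
#' @param sessions list of `transdx_session`.
#' @param model_ids character vector of model ids (default all eight).
#' @param penalty passed to [fit_participant()].
#' @param n_starts,seed,Q0,loss_coding passed to [fit_participant()].
#' @param parallel_workers number of worker processes (default 1, sequential).
#' @return data.frame with participant_id, model_id, one column per canonical
#'   parameter (NA where unused), nll, n_obs, k, bic, evidence, converged.
#' @export
fit_cohort <- function(sessions, model_ids = rl_model_ids(), n_starts = 10L,
                       seed = 1L, Q0 = 0, loss_coding = "raw",
                       parallel_workers = 1L, penalty = "weak") {
  if (length(sessions) == 0L) stop("no sessions supplied")
  for (m in model_ids) validate_model_id(m)
  cells <- expand.grid(i = seq_along(sessions), m = seq_along(model_ids))
  one <- function(row) {
    s <- sessions[[row$i]]
    mid <- model_ids[row$m]
    fit <- tryCatch(
      fit_participant(s, mid, n_starts = n_starts,
                      seed = participant_seed(seed, s$participant_id,
                                              model_code(mid)),
                      Q0 = Q0, loss_coding = loss_coding, penalty = penalty),
      error = function(e) NULL)
    all_par <- c("alpha", "beta", "gamma", "alpha_F", "alpha_C",
                 "alpha_pos", "alpha_neg", "eta", "kappa")
    pv <- setNames(rep(NA_real_, length(all_par)), all_par)
    if (is.null(fit)) {
      d <- data.frame(participant_id = s$participant_id, model_id = mid,
                      t(pv), nll = NA_real_, n_obs = sum(!is.na(s$choices)),
                      k = length(rl_param_names(mid)), bic = NA_real_,
                      evidence = NA_real_, converged = NA)
    } else {
      pv[names(fit$params)] <- fit$params
      d <- data.frame(participant_id = fit$participant_id, model_id = mid,
                      t(pv), nll = fit$nll, n_obs = fit$n_obs, k = fit$k,
                      bic = fit$bic, evidence = fit$evidence,
                      converged = fit$converged)
    }
    d
  }
  rows <- if (parallel_workers > 1L) {
    parallel::mclapply(split(cells, seq_len(nrow(cells))), one,
                       mc.cores = parallel_workers)
  } else {
    lapply(split(cells, seq_len(nrow(cells))), one)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$participant_id, match(res$model_id, rl_model_ids())), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Approximate log model evidence of a fit
#'
#' Default `-BIC/2`, the standard per-subject input to random-effects Bayesian
#' model selection. A rough Laplace alternative (`method = "laplace"`) uses the
#' numeric Hessian of the negative log-likelihood at the MLE under a uniform
#' prior over the parameter boxes.
#'
#' @param fit a `transdx_fit` (or a list with `nll`, `k`, `n_obs`).
#' @param method `"bic"` (default) or `"laplace"`.
#' @param session required for `method = "laplace"`.
#' @param Q0,loss_coding passed through for the Laplace evaluation.
#' @return scalar approximate log evidence.
#' @export
evidence_approximation <- function(fit, method = c("bic", "laplace"),
                                   session = NULL, Q0 = 0,
                                   loss_coding = "raw") {
  method <- match.arg(method)
  if (method == "bic") return(-(2 * fit$nll + fit$k * log(fit$n_obs)) / 2)
  if (is.null(session)) stop("laplace evidence needs the session")
  nm <- names(fit$params)
  f <- function(v) negative_log_likelihood(
    session, fit$model_id, setNames(v, nm), Q0 = Q0, loss_coding = loss_coding)
  H <- stats::optimHess(fit$params, f)
  widths <- vapply(nm, function(p) diff(param_box(p)), numeric(1))
  ldetH <- determinant(H, logarithm = TRUE)$modulus
  if (!is.finite(ldetH)) return(-fit$bic / 2)
  as.numeric(-fit$nll - sum(log(widths)) +
               (fit$k / 2) * log(2 * pi) - 0.5 * ldetH)
}
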