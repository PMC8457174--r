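#' The reinforcement-learning model registry
#'
#' Eight models of three-option bandit behaviour. `RL1` is plain Q-learning
#' (learning rate `alpha`, inverse temperature `beta`); `RL2` adds an
#' exponentially decaying choice trace entering the softmax with weight
#' `gamma` (decay rate `alpha_C`); `RL3` splits the learning rate by the sign
#' of the reward prediction error (`alpha_pos` / `alpha_neg`); `RL4` is a
#' hybrid Pearce-Hall model whose effective learning rate is
#' `kappa * associability`, the associability tracking `|delta|` at rate
#' `eta`. The `b` variants add value forgetting: unchosen options decay toward
#' the initial value `Q0` at rate `alpha_F`.
#'
#' @return `rl_model_ids()`: character vector of the eight model ids.
#' @export
rl_model_ids <- function() {
  c("RL1a", "RL1b", "RL2a", "RL2b", "RL3a", "RL3b", "RL4a", "RL4b")
}

#' @rdname rl_model_ids
#' @param model_id one of `rl_model_ids()`.
#' @return `rl_param_names()`: the model's free-parameter names, in order.
#' @export
rl_param_names <- function(model_id) {
  switch(validate_model_id(model_id),
         RL1a = c("alpha", "beta"),
         RL1b = c("alpha", "beta", "alpha_F"),
         RL2a = c("alpha", "beta", "gamma", "alpha_C"),
         RL2b = c("alpha", "beta", "gamma", "alpha_F", "alpha_C"),
         RL3a = c("alpha_pos", "alpha_neg", "beta"),
         RL3b = c("alpha_pos", "alpha_neg", "beta", "alpha_F"),
         RL4a = c("eta", "kappa", "beta"),
         RL4b = c("eta", "kappa", "beta", "alpha_F"))
}

validate_model_id <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !model_id %in% rl_model_ids())
    stop(sprintf("unknown model_id '%s'; known: %s",
                 as.character(model_id)[1], paste(rl_model_ids(), collapse = ", ")))
  model_id
}

model_code <- function(model_id) match(validate_model_id(model_id), rl_model_ids())

# expand a named parameter vector/list to the canonical length-9 vector used
# by the C++ kernels: alpha, beta, gamma, alpha_F, alpha_C, alpha_pos,
# alpha_neg, eta, kappa (inactive entries zero)
canonical_params <- function(model_id, params) {
  nm <- rl_param_names(model_id)
  params <- unlist(params)
  if (!all(nm %in% names(params)))
    stop(sprintf("model %s needs parameters: %s", model_id,
                 paste(nm, collapse = ", ")))
  if (any(!is.finite(params[nm]))) stop("non-finite value in params")
  full <- setNames(numeric(9),
                   c("alpha", "beta", "gamma", "alpha_F", "alpha_C",
                     "alpha_pos", "alpha_neg", "eta", "kappa"))
  full[nm] <- params[nm]
  full
}

#' Softmax choice probabilities over values and choice traces
#'
#' `p_a` proportional to `exp(beta * Q_a + gamma * trace_a)`, computed with
#' max-subtraction and floored at 1e-10 (then renormalized) so no option ever
#' has probability exactly 0 or 1. The trace term is active only for the RL2
#' models; pass `gamma = 0` otherwise.
#'
#' @param Q numeric 3-vector of option values.
#' @param trace numeric 3-vector of choice traces (entries in `[0,1]`).
#' @param beta inverse temperature, `>= 0`.
#' @param gamma choice-trace weight.
#' @return probability 3-vector summing to 1.
#' @export
choice_probabilities <- function(Q, trace = c(0, 0, 0), beta, gamma = 0) {
  if (any(!is.finite(Q)) || any(!is.finite(trace)))
    stop("state must be finite")
  l <- beta * Q + gamma * trace
  p <- exp(l - max(l))
  p <- p / sum(p)
  p <- pmax(p, 1e-10)
  p / sum(p)
}

#' One value-update step
#'
#' Applies the reward-prediction-error update for the chosen option and, for
#' the forgetting (`b`) variants, decays unchosen values toward `Q0`. For RL4
#' models the associability is updated after the value update.
#'
#' @param state list with `Q` (3-vector), `trace` (3-vector), `assoc` scalar.
#' @param chosen chosen option, 1-based.
#' @param outcome observed outcome in the context coding.
#' @param params named parameter vector for the model.
#' @param model_id model id.
#' @param Q0 initial/forgetting target value (default 0).
#' @return updated state list.
#' @export
update_values <- function(state, chosen, outcome, params, model_id, Q0 = 0) {
  m <- model_code(model_id)
  par <- canonical_params(model_id, params)
  stopifnot(chosen %in% 1:3)
  Q <- state$Q
  delta <- outcome - Q[chosen]
  a_eff <- if (m %in% c(5, 6)) {
    if (delta >= 0) par[["alpha_pos"]] else par[["alpha_neg"]]
  } else if (m %in% c(7, 8)) {
    par[["kappa"]] * state$assoc
  } else par[["alpha"]]
  Q[chosen] <- Q[chosen] + a_eff * delta
  if (m %% 2 == 0) {
    aF <- par[["alpha_F"]]
    u <- setdiff(1:3, chosen)
    Q[u] <- (1 - aF) * Q[u] + aF * Q0
  }
  assoc <- state$assoc
  if (m %in% c(7, 8)) assoc <- par[["eta"]] * abs(delta) + (1 - par[["eta"]]) * assoc
  list(Q = Q, trace = state$trace, assoc = assoc)
}

#' One choice-trace update step
#'
#' `trace_a <- (1 - alpha_C) * trace_a + alpha_C * 1[a == chosen]`.
#'
#' @inheritParams update_values
#' @param alpha_C trace decay rate in `[0,1]`.
#' @return updated state list.
#' @export
update_trace <- function(state, chosen, alpha_C) {
  stopifnot(chosen %in% 1:3)
  ind <- as.numeric(1:3 == chosen)
  state$trace <- (1 - alpha_C) * state$trace + alpha_C * ind
  state
}

#' Negative log-likelihood of a session under an RL model
#'
#' Sums `-log p(choice_t)` over responded trials. Missed trials contribute no
#' likelihood term and trigger no state update. Loss-context outcomes are used
#' in their native `{0, -1}` coding by default; `loss_coding = "success"`
#' recodes them to `{1, 0}` (no-loss treated as reward) before evaluation.
#'
#' @param session a `transdx_session`.
#' @param model_id model id.
#' @param params named parameters for the model.
#' @param Q0 initial option value (default 0).
#' @param loss_coding `"raw"` or `"success"`.
#' @return scalar negative log-likelihood (`>= 0`).
#' @export
negative_log_likelihood <- function(session, model_id, params, Q0 = 0,
                                    loss_coding = c("raw", "success")) {
  loss_coding <- match.arg(loss_coding)
  if (all(is.na(session$choices))) stop("empty session: no responded trials")
  par <- canonical_params(model_id, params)
  out <- session$outcomes
  if (session$context == "loss" && loss_coding == "success") out <- out + 1
  out[is.na(out)] <- 0  # never read: missed trials are skipped in C++
  .nll_cpp(session$choices, out, model_code(model_id), par, Q0)
}

#' Simulate an RL agent on a probability schedule
#'
#' Choices are drawn from the model's softmax probabilities; the outcome of a
#' chosen option is Bernoulli with the scheduled success probability, mapped
#' to the context coding (reward: `1`/`0`; loss: `0`/`-1`). Each trial is
#' independently missed with probability `miss_rate` (no choice, no outcome,
#' no state update).
#'
#' @param schedule a `transdx_schedule`.
#' @param context `"reward"` or `"loss"`.
#' @param model_id model id.
#' @param params named parameters.
#' @param miss_rate per-trial miss probability (default 0).
#' @param seed integer seed; simulation is reproducible given the seed.
#' @param participant_id id for the returned session.
#' @param Q0 initial option value.
#' @param learn_coding outcome coding the agent learns on in the loss
#'   context: `"raw"` (default; experiences `{0, -1}`) or `"success"`
#'   (experiences no-loss as `1`, loss as `0`). Stored session outcomes are
#'   always in the native loss coding.
#' @return a `transdx_session`.
#' @export
simulate_agent <- function(schedule, context, model_id, params,
                           miss_rate = 0, seed = 1L, participant_id = "sim",
                           Q0 = 0, learn_coding = c("raw", "success")) {
  stopifnot(inherits(schedule, "transdx_schedule"))
  context <- match.arg(context, c("reward", "loss"))
  learn_coding <- match.arg(learn_coding)
  par <- canonical_params(model_id, params)
  set.seed(as.integer(seed))
  as_reward <- context == "reward" ||
    (context == "loss" && learn_coding == "success")
  res <- .simulate_cpp(schedule$probs, as.integer(as_reward),
                       model_code(model_id), par, miss_rate, Q0)
  outcomes <- res$outcomes
  if (context == "loss" && learn_coding == "success")
    outcomes <- outcomes - 1  # back to native {0, -1} storage
  choice_session(participant_id, context, res$choices, outcomes)
}
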