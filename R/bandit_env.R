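#' @useDynLib transdx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif plogis qlogis optim qgamma pnorm qnorm sd
#'   cor coef lm pt setNames median
#' @importFrom utils read.csv write.csv
NULL

#' Generate a drifting probability schedule for a three-option bandit
#'
#' Builds the per-trial success-probability matrix shared by every participant
#' in a cohort arm: a reward probability in the reward-seeking context, a
#' no-loss probability in the loss-avoidance context. Each option follows an
#' independent Gaussian random walk reflected at `bounds`; occasionally
#' (rate `switch_rate` per trial) the currently best option swaps its walker
#' state with another option so the identity of the correct option changes
#' abruptly as well as by drift.
#'
#' @param n_trials number of trials (default 500, one session).
#' @param n_options number of options (default 3).
#' @param bounds length-2 numeric, `0 <= low < high <= 1`; probabilities are
#'   reflected into this interval.
#' @param drift_sd standard deviation of the per-trial Gaussian increment
#'   (probability units). Zero gives a constant schedule.
#' @param switch_rate per-trial probability of a best-option swap event.
#' @param start optional length-`n_options` vector of initial probabilities;
#'   drawn uniformly inside `bounds` if omitted.
#' @param seed integer seed; the schedule is bit-reproducible given the seed.
#' @return A `transdx_schedule`: list with `n_trials`, `n_options`, `probs`
#'   (`n_trials x n_options` matrix), `bounds`.
#' @export
generate_schedule <- function(n_trials = 500L, n_options = 3L,
                              bounds = c(0.2, 0.8), drift_sd = 0.02,
                              switch_rate = 0.005, start = NULL, seed = 1L) {
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("n_trials must be a positive integer")
  if (length(bounds) != 2L || !(bounds[1] >= 0 && bounds[1] < bounds[2] && bounds[2] <= 1))
    stop("bounds must satisfy 0 <= low < high <= 1")
  if (drift_sd < 0) stop("drift_sd must be non-negative")
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate must be in [0,1]")
  n_trials <- as.integer(n_trials)
  n_options <- as.integer(n_options)
  lo <- bounds[1]; hi <- bounds[2]

  set.seed(as.integer(seed))
  p <- if (is.null(start)) runif(n_options, lo, hi) else as.numeric(start)
  if (length(p) != n_options) stop("start must have one entry per option")
  if (any(p < lo - 1e-12) || any(p > hi + 1e-12))
    stop("start probabilities must lie within bounds")

  probs <- matrix(NA_real_, n_trials, n_options)
  for (t in seq_len(n_trials)) {
    probs[t, ] <- p
    if (drift_sd > 0)
      p <- reflect_into(p + rnorm(n_options, 0, drift_sd), lo, hi)
    if (switch_rate > 0 && runif(1) < switch_rate) {
      best <- which.max(p)
      other <- if (n_options > 1) sample(setdiff(seq_len(n_options), best), 1L) else best
      p[c(best, other)] <- p[c(other, best)]
    }
  }
  structure(list(n_trials = n_trials, n_options = n_options,
                 probs = probs, bounds = bounds),
            class = "transdx_schedule")
}

# reflect x into [lo, hi] (triangle-wave folding; handles multiple bounces)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' @export
print.transdx_schedule <- function(x, ...) {
  cat(sprintf("<transdx_schedule> %d trials x %d options, bounds [%.2f, %.2f]\n",
              x$n_trials, x$n_options, x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Construct a choice session
#'
#' One participant's trial-by-trial choices and outcomes in one task context.
#' Choices are 1-based option indices (`NA` = failure to respond). Outcomes use
#' the context's native coding: reward context `1` = reward, `0` = no-reward;
#' loss context `0` = no-loss, `-1` = loss. Outcomes on missed trials are `NA`.
#'
#' @param participant_id identifier string.
#' @param context `"reward"` or `"loss"`.
#' @param choices integer vector over `{1, 2, 3, NA}`.
#' @param outcomes numeric vector in the context coding; `NA` where missed.
#' @return A `transdx_session` list.
#' @export
choice_session <- function(participant_id, context, choices, outcomes) {
  context <- match.arg(context, c("reward", "loss"))
  if (length(choices) != length(outcomes))
    stop("choices and outcomes must have equal length")
  responded <- !is.na(choices)
  ok <- if (context == "reward") c(0, 1) else c(-1, 0)
  if (any(!outcomes[responded] %in% ok))
    stop(sprintf("outcomes inconsistent with %s-context coding {%s}",
                 context, paste(ok, collapse = ", ")))
  structure(list(participant_id = as.character(participant_id),
                 context = context,
                 choices = as.integer(choices),
                 outcomes = as.numeric(outcomes),
                 n_trials = length(choices)),
            class = "transdx_session")
}

#' @export
print.transdx_session <- function(x, ...) {
  cat(sprintf("<transdx_session> %s [%s]: %d trials, %d missed\n",
              x$participant_id, x$context, x$n_trials, sum(is.na(x$choices))))
  invisible(x)
}

#' Label the correct option on every trial
#'
#' The correct option on a trial is the one with the highest success
#' probability; ties are broken deterministically toward the lowest option
#' index.
#'
#' @param schedule a `transdx_schedule`.
#' @return list with `correct_option` (integer vector, 1-based).
#' @export
label_correct <- function(schedule) {
  stopifnot(inherits(schedule, "transdx_schedule"))
  correct <- apply(schedule$probs, 1L, which.max)  # which.max = lowest-index tie-break
  list(correct_option = as.integer(correct))
}

#' Proportion of correct choices in a session
#'
#' Computed over responded trials only: missed trials are excluded from both
#' numerator and denominator.
#'
#' @param session a `transdx_session`.
#' @param labeling output of [label_correct()] for the session's schedule.
#' @return list with `proportion` (scalar in `[0,1]`), `is_correct` (logical
#'   vector over responded trials), `n_responded`.
#' @export
performance <- function(session, labeling) {
  if (session$n_trials != length(labeling$correct_option))
    stop("session and labeling differ in n_trials")
  responded <- which(!is.na(session$choices))
  if (length(responded) == 0L)
    stop("all trials missing: performance undefined")
  is_correct <- session$choices[responded] == labeling$correct_option[responded]
  list(proportion = mean(is_correct),
       is_correct = is_correct,
       n_responded = length(responded))
}

#' Write / read session tables as CSV
#'
#' Long format, one row per trial: `participant_id, trial, choice, outcome,
#' context` with 1-based trials, choices 1-3 or `NA`.
#'
#' @param sessions list of `transdx_session`.
#' @param path output CSV path.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "transdx_session")) sessions <- list(sessions)
  tabs <- lapply(sessions, function(s)
    data.frame(participant_id = s$participant_id,
               trial = seq_len(s$n_trials),
               choice = s$choices,
               outcome = s$outcomes,
               context = s$context))
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @param path CSV path written by [write_sessions()].
#' @return `read_sessions`: named list of `transdx_session`.
#' @export
read_sessions <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial", "choice", "outcome", "context")
  if (!all(need %in% names(tab))) stop("session CSV lacks required columns")
  out <- lapply(split(tab, tab$participant_id), function(d) {
    d <- d[order(d$trial), , drop = FALSE]
    choice_session(d$participant_id[1], d$context[1], d$choice, d$outcome)
  })
  out[order(names(out))]
}

#' Write / read a probability schedule as CSV
#'
#' Columns `trial, p1, p2, p3` (one `p` column per option).
#' @param schedule a `transdx_schedule`.
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  d <- data.frame(trial = seq_len(schedule$n_trials), schedule$probs)
  names(d) <- c("trial", paste0("p", seq_len(schedule$n_options)))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  d <- read.csv(path)
  probs <- as.matrix(d[, grep("^p[0-9]+$", names(d)), drop = FALSE])
  dimnames(probs) <- NULL
  structure(list(n_trials = nrow(probs), n_options = ncol(probs),
                 probs = probs, bounds = c(min(probs), max(probs))),
            class = "transdx_schedule")
}
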