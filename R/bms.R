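#' Random-effects Bayesian model selection
#'
#' Variational inference for the random-effects model in which each subject's
#' data are generated by one of K models and model frequencies follow a
#' Dirichlet distribution. Subject-level responsibilities and Dirichlet counts
#' are iterated to convergence:
#' `u_nk proportional to exp(log_evidence_nk + digamma(alpha_k) - digamma(sum alpha))`,
#' `alpha_k = alpha0 + sum_n u_nk`. Exceedance probabilities (the posterior
#' probability that each model is the most frequent) are then estimated by
#' seeded Monte-Carlo sampling of the fitted Dirichlet.
#'
#' @param log_evidence N x K matrix of per-subject log model evidences
#'   (e.g. `-BIC/2` from [fit_cohort()]).
#' @param alpha0 Dirichlet prior count (default 1, uniform).
#' @param tol convergence tolerance on the alpha update (default 1e-6).
#' @param max_iter maximum variational iterations.
#' @param n_draws Monte-Carlo draws for the exceedance step (default 1e6).
#' @param seed seed for the Monte-Carlo step.
#' @return A `BMSResult` list: `dirichlet_alpha`, `expected_frequencies`,
#'   `exceedance_prob`, `n_subjects`, `converged`.
#' @export
fit_bms <- function(log_evidence, alpha0 = 1, tol = 1e-6, max_iter = 1000L,
                    n_draws = 1e6, seed = 1L) {
  log_evidence <- as.matrix(log_evidence)
  if (any(!is.finite(log_evidence))) stop("log_evidence must be finite")
  N <- nrow(log_evidence); K <- ncol(log_evidence)
  if (N < 2L || K < 2L) stop("need N >= 2 subjects and K >= 2 models")
  alpha <- rep(alpha0, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1L, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  xp <- exceedance_from_dirichlet(alpha, n_draws = n_draws, seed = seed)
  names(alpha) <- colnames(log_evidence)
  names(xp) <- colnames(log_evidence)
  structure(list(dirichlet_alpha = alpha,
                 expected_frequencies = alpha / sum(alpha),
                 exceedance_prob = xp,
                 n_subjects = N,
                 converged = converged),
            class = "transdx_bms")
}

#' @export
print.transdx_bms <- function(x, ...) {
  cat(sprintf("<transdx_bms> %d subjects, %d models%s\n", x$n_subjects,
              length(x$dirichlet_alpha),
              if (x$converged) "" else " (NOT converged)"))
  print(round(rbind(freq = x$expected_frequencies,
                    exceedance = x$exceedance_prob), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' Monte-Carlo frequency with which each component of a Dirichlet draw is the
#' largest. Sampling is chunked and seeded.
#'
#' @param alpha positive Dirichlet parameter vector.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return probability vector summing to 1.
#' @export
exceedance_from_dirichlet <- function(alpha, n_draws = 1e6, seed = 1L) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  K <- length(alpha)
  # inverse-CDF sampling in canonical (sorted) order: the j-th uniform
  # column always feeds the j-th smallest alpha, so permuting alpha (with
  # distinct entries) permutes the result exactly
  ord <- order(alpha)
  asort <- alpha[ord]
  set.seed(as.integer(seed))
  counts_sorted <- integer(K)
  left <- as.integer(n_draws)
  chunk <- 100000L
  while (left > 0L) {
    m <- min(chunk, left)
    u <- matrix(runif(m * K), nrow = m)
    g <- vapply(seq_len(K), function(j) qgamma(u[, j], shape = asort[j]),
                numeric(m))
    counts_sorted <- counts_sorted +
      tabulate(max.col(g, ties.method = "first"), K)
    left <- left - m
  }
  counts <- integer(K)
  counts[ord] <- counts_sorted
  counts / n_draws
}
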