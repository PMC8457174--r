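# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) by Golub-Welsch
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1L, idx]^2)
}

# Adaptive Gauss-Hermite log-likelihood of the random-intercept binomial
# model: per-participant successes k out of n with logit(p) = eta_i + b,
# b ~ N(0, sigma^2). Vectorized over participants.
aghq_loglik <- function(eta, k, n, sigma, gh) {
  if (any(!is.finite(eta)) || !is.finite(sigma)) return(-1e10)
  sigma <- min(max(sigma, 1e-4), 25)
  s2 <- sigma^2
  b <- rep(0, length(eta))
  for (it in 1:30) {  # Newton for the posterior mode (concave objective)
    p <- plogis(eta + b)
    g <- k - n * p - b / s2
    h <- -n * p * (1 - p) - 1 / s2
    step <- g / h
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- plogis(eta + b)
  h <- -n * p * (1 - p) - 1 / s2
  tau <- 1 / sqrt(-h)
  # log integrand at the shifted/scaled nodes, log-sum-exp over nodes
  const <- lchoose(n, k)
  lse <- rep(-Inf, length(eta))
  for (j in seq_along(gh$nodes)) {
    bj <- b + sqrt(2) * tau * gh$nodes[j]
    pj <- plogis(eta + bj)
    lh <- k * log(pmax(pj, 1e-300)) + (n - k) * log(pmax(1 - pj, 1e-300)) -
      bj^2 / (2 * s2)
    term <- log(gh$weights[j]) + gh$nodes[j]^2 + lh
    m <- pmax(lse, term)
    lse <- m + log(exp(lse - m) + exp(term - m))
  }
  sum(const + log(sqrt(2) * tau) + lse - 0.5 * log(2 * pi * s2))
}

#' Mixed logistic model of task performance on psychiatric dimensions
#'
#' Per-trial correct/incorrect responses are modelled as Bernoulli with a
#' participant-level Gaussian random intercept:
#' `logit P(correct) ~ 1 + CIT + AD + IM + covariates + (1 | participant)`.
#' The default estimator integrates the random intercept by adaptive
#' Gauss-Hermite quadrature on the participant-level binomial sufficient
#' statistics; `aggregated_ols` is an empirical-logit OLS fallback with HC3
#' robust errors. All predictors are z-normalized within the sample; FDR is
#' applied over the three factor terms.
#'
#' @param summaries data.frame with `participant_id`, `n_correct`,
#'   `n_responded`, `CIT`, `AD`, `IM`, and any covariate columns.
#' @param estimator `"random_intercept_logit"` (default) or
#'   `"aggregated_ols"`.
#' @param n_nodes quadrature nodes (default 15).
#' @return effect table (term, estimate, se, z, p, q) with attribute
#'   `sigma` (random-intercept SD) for the quadrature estimator.
#' @export
performance_model <- function(summaries,
                              estimator = c("random_intercept_logit",
                                            "aggregated_ols"),
                              n_nodes = 15L) {
  estimator <- match.arg(estimator)
  if (nrow(summaries) < 30L) stop("need at least 30 participants")
  pred_cols <- setdiff(names(summaries),
                       c("participant_id", "n_correct", "n_responded"))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(summaries[pred_cols], z_scale))))
  k <- summaries$n_correct
  n <- summaries$n_responded
  if (estimator == "aggregated_ols") {
    elogit <- log((k + 0.5) / (n - k + 0.5))
    tab <- robust_ols(elogit, X)
    names(tab)[names(tab) == "t"] <- "z"
  } else {
    gh <- gauss_hermite(n_nodes)
    start_glm <- stats::glm.fit(X, cbind(k, n - k),
                                family = stats::binomial())
    theta0 <- c(coef(start_glm), log_sigma = log(0.3))
    negll <- function(th) {
      if (any(!is.finite(th)) || any(abs(th) > 50)) return(1e10)
      sigma <- exp(th[length(th)])
      -aghq_loglik(drop(X %*% th[-length(th)]), k, n, sigma, gh)
    }
    opt <- optim(theta0, negll, method = "BFGS",
                 control = list(maxit = 500L, reltol = 1e-10))
    if (opt$convergence != 0) {
      warning("quadrature fit did not converge; falling back to aggregated OLS")
      return(performance_model(summaries, "aggregated_ols"))
    }
    H <- stats::optimHess(opt$par, negll)
    # clipped-eigen pseudo-inverse: the log-sigma direction can be singular
    # when the random-intercept variance sits near zero
    eH <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(eH$values, 1e-8)
    V <- eH$vectors %*% (t(eH$vectors) / lam)
    est <- opt$par[-length(opt$par)]
    se <- sqrt(diag(V))[-length(opt$par)]
    zval <- est / se
    tab <- data.frame(term = colnames(X), estimate = est, se = se, z = zval,
                      p = 2 * pnorm(-abs(zval)), row.names = NULL)
    attr(tab, "sigma") <- exp(opt$par[length(opt$par)])
    attr(tab, "logLik") <- -opt$value
  }
  tab$q <- NA_real_
  fam <- tab$term %in% c("CIT", "AD", "IM")
  tab$q[fam] <- bh_fdr(tab$p[fam])
  tab
}

# sample skewness and (raw) kurtosis
moments_skew_kurt <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  c(skewness = mean((x - m)^3) / s2^1.5,
    kurtosis = mean((x - m)^4) / s2^2)
}

#' Regression of the CIT dimension on fitted RL parameters
#'
#' OLS of CIT on the z-scored learning rate, log inverse temperature, and
#' choice-trace weight, controlling for the forgetting and trace-decay rates,
#' demographic covariates, and the other psychiatric dimensions. `beta` is
#' always log-transformed (its raw skewness/kurtosis are reported, and a flag
#' records whether they exceed the severe non-normality thresholds of
#' skewness > 2 and kurtosis > 7). One-tailed p-values are computed in the
#' hypothesized directions (`alpha` negative, `beta` negative, `gamma`
#' positive by default) with FDR over those three terms.
#'
#' @param summaries data.frame with `participant_id`, `CIT`, `AD`, `IM`,
#'   fitted `alpha`, `beta`, `gamma`, `alpha_F`, `alpha_C`, and covariates.
#' @param directions named vector of hypothesis directions for the one-tailed
#'   tests.
#' @return effect table with one-tailed `p` and `q` on the three parameter
#'   terms; attributes `beta_moments` and `log_transform_flagged`.
#' @export
parameter_regression <- function(summaries,
                                 directions = c(alpha = -1, beta = -1,
                                                gamma = 1)) {
  need <- c("CIT", "AD", "IM", "alpha", "beta", "gamma", "alpha_F", "alpha_C")
  if (!all(need %in% names(summaries)))
    stop("summaries must contain fitted RL2b parameters and factor scores")
  mom <- moments_skew_kurt(summaries$beta)
  flagged <- mom["skewness"] > 2 && mom["kurtosis"] > 7
  d <- summaries
  d$beta <- log(d$beta)
  pred_cols <- setdiff(names(d), c("participant_id", "CIT"))
  M <- as.matrix(as.data.frame(lapply(d[pred_cols], z_scale)))
  kappa_c <- kappa(cbind(1, M), exact = TRUE)
  if (kappa_c > 1e8) {
    cc <- stats::cor(M)
    diag(cc) <- 0
    bad <- which(abs(cc) > 0.999, arr.ind = TRUE)
    stop(sprintf("collinear predictors (condition number %.2g): %s", kappa_c,
                 paste(unique(rownames(cc)[bad[, 1]]), collapse = ", ")))
  }
  y <- z_scale(d$CIT)
  fit <- lm(y ~ M)
  sm <- summary(fit)$coefficients
  terms <- c("(Intercept)", pred_cols)
  tab <- data.frame(term = terms, estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], row.names = NULL)
  df <- fit$df.residual
  tab$p <- 2 * pt(-abs(tab$t), df)
  for (nm in names(directions)) {
    i <- tab$term == nm
    tab$p[i] <- pt(directions[[nm]] * tab$t[i], df, lower.tail = FALSE)
  }
  tab$q <- NA_real_
  fam <- tab$term %in% names(directions)
  tab$q[fam] <- bh_fdr(tab$p[fam])
  attr(tab, "beta_moments") <- mom
  attr(tab, "log_transform_flagged") <- unname(flagged)
  tab
}

# closed-form leave-one-out predictions of a linear model (hat-matrix trick)
loo_predictions <- function(y, M) {
  H <- M %*% solve(crossprod(M), t(M))
  h <- diag(H)
  e <- y - drop(H %*% y)
  y - e / (1 - h)
}

#' Leave-one-out cross-validated prediction of behaviour from dimensions
#'
#' For each participant, a linear model `y ~ CIT + AD + IM` (or `y ~ AD + IM`
#' for `model = "without_CIT"`) is fit on everyone else and used to predict
#' the held-out value; the returned accuracy is the Pearson correlation of
#' predicted and actual values.
#'
#' @param y predicted variable (e.g. performance or learning rate).
#' @param X data.frame/matrix with columns `CIT`, `AD`, `IM`.
#' @param model `"full"` or `"without_CIT"`.
#' @return scalar correlation; `NA` with attribute `flagged = TRUE` when the
#'   predictions have zero variance.
#' @export
loo_cv_prediction <- function(y, X, model = c("full", "without_CIT")) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (length(y) < 20L) stop("need n >= 20 for leave-one-out prediction")
  cols <- if (model == "full") c("CIT", "AD", "IM") else c("AD", "IM")
  M <- cbind(1, X[, cols, drop = FALSE])
  pred <- loo_predictions(y, M)
  if (sd(pred) < 1e-12) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cor(pred, y)
}

#' Permutation test of the CIT contribution to predictability
#'
#' Observed statistic: difference between the full-model and the
#' CIT-omitting-model leave-one-out correlations. The null distribution is
#' built by permuting the predicted variable `n_perm` times and refitting both
#' models (closed-form LOO makes each permutation cheap); the p-value is the
#' fraction of null differences at least as large as the observed one.
#'
#' @param y predicted variable.
#' @param X data.frame/matrix with columns `CIT`, `AD`, `IM`.
#' @param n_perm number of permutations (default 10000; a warning is issued
#'   below 100).
#' @param seed integer seed.
#' @return list with `p_value`, `observed`, `full_r`, `reduced_r`, `null`
#'   (the permuted differences).
#' @export
permutation_test <- function(y, X, n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: permutation p-value is coarse")
  X <- as.matrix(X)
  n <- length(y)
  Mf <- cbind(1, X[, c("CIT", "AD", "IM")])
  Mr <- cbind(1, X[, c("AD", "IM")])
  # LOO predictions are linear in y: pred = A y
  Afun <- function(M) {
    H <- M %*% solve(crossprod(M), t(M))
    h <- diag(H)
    diag(n) - (diag(n) - H) / (1 - h)  # row-scale (I - H) by 1/(1-h)
  }
  Af <- Afun(Mf)
  Ar <- Afun(Mr)
  rstat <- function(P, Y) {
    Pc <- sweep(P, 2L, colMeans(P))
    Yc <- sweep(Y, 2L, colMeans(Y))
    colSums(Pc * Yc) / sqrt(colSums(Pc^2) * colSums(Yc^2))
  }
  obs <- rstat(cbind(Af %*% y), cbind(y)) - rstat(cbind(Ar %*% y), cbind(y))
  set.seed(as.integer(seed))
  chunk <- 2000L
  null <- numeric(0)
  left <- as.integer(n_perm)
  while (left > 0L) {
    m <- min(chunk, left)
    Y <- vapply(seq_len(m), function(j) y[sample.int(n)], numeric(n))
    null <- c(null, rstat(Af %*% Y, Y) - rstat(Ar %*% Y, Y))
    left <- left - m
  }
  list(p_value = mean(null >= drop(obs)),
       observed = drop(obs),
       full_r = drop(rstat(cbind(Af %*% y), cbind(y))),
       reduced_r = drop(rstat(cbind(Ar %*% y), cbind(y))),
       null = null)
}
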