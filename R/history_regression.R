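#' Build the lagged reward/choice history design for one session
#'
#' One row per responded trial `t` with `t > tau_max`. The response is
#' `y = 1` if the target option `X` was chosen at `t`. For each lag
#' `tau = 1..tau_max`, the past-reward regressor is `+1` if `X` was chosen and
#' successful at `t - tau`, `-1` if another option was chosen and successful,
#' and `0` if the lagged trial was unsuccessful; the past-choice regressor is
#' `+1` if `X` was chosen at `t - tau` and `-1` otherwise. In the loss context
#' "success" means no-loss (no-loss treated as reward). A missed lagged trial
#' carries no information and codes `0` on both regressors.
#'
#' @param session a `transdx_session`.
#' @param target_option the option `X` (1-based, default 1).
#' @param tau_max history length, in `[2, 6]` (default 4).
#' @return data.frame with `participant_id`, `trial`, `y`, `R1..Rtau_max`,
#'   `C1..Ctau_max`.
#' @export
build_history_design <- function(session, target_option = 1L, tau_max = 4L) {
  if (!(tau_max %in% 2:6)) stop("tau_max must be in [2, 6]")
  stopifnot(target_option %in% 1:3)
  n <- session$n_trials
  cols <- c(paste0("R", seq_len(tau_max)), paste0("C", seq_len(tau_max)))
  if (n < tau_max + 1L) {
    warning("session shorter than tau_max + 1: empty design")
    empty <- as.data.frame(matrix(numeric(0), 0L, 3L + 2L * tau_max))
    names(empty) <- c("participant_id", "trial", "y", cols)
    return(empty)
  }
  ch <- session$choices
  success <- if (session$context == "reward") session$outcomes == 1
             else session$outcomes == 0
  t_idx <- which(!is.na(ch) & seq_len(n) > tau_max)
  y <- as.integer(ch[t_idx] == target_option)
  M <- matrix(0, length(t_idx), 2L * tau_max,
              dimnames = list(NULL, cols))
  for (tau in seq_len(tau_max)) {
    j <- t_idx - tau
    resp <- !is.na(ch[j])
    isX <- resp & ch[j] == target_option
    succ <- resp & success[j] %in% TRUE
    M[, tau] <- ifelse(succ, ifelse(isX, 1, -1), 0)
    M[, tau_max + tau] <- ifelse(resp, ifelse(isX, 1, -1), 0)
  }
  data.frame(participant_id = session$participant_id, trial = t_idx, y = y,
             M, check.names = FALSE)
}

# logistic regression with a ridge penalty on the non-intercept coefficients,
# escalated if separation makes the fit diverge
ridge_logistic <- function(X, y, lambda = 1) {
  p <- ncol(X)
  pen <- c(0, rep(1, p - 1L))
  for (try_l in lambda * 10^(0:6)) {
    b <- rep(0, p)
    ok <- TRUE
    for (it in 1:50) {
      eta <- drop(X %*% b)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(X, X * w) + diag(try_l * pen, p)
      g <- crossprod(X, y - mu) - try_l * pen * b
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
      b <- b + step
      if (max(abs(step)) < 1e-8) break
    }
    if (ok && all(is.finite(b)) && max(abs(b)) < 50) {
      attr(b, "lambda") <- try_l
      return(b)
    }
  }
  stop("ridge logistic fit failed at all penalty levels")
}

# OLS with HC3 heteroscedasticity-robust standard errors
robust_ols <- function(y, Z) {
  n <- nrow(Z); p <- ncol(Z)
  XtXi <- solve(crossprod(Z))
  b <- drop(XtXi %*% crossprod(Z, y))
  h <- rowSums((Z %*% XtXi) * Z)
  e <- y - drop(Z %*% b)
  u <- e / pmax(1 - h, 1e-8)
  meat <- crossprod(Z * u)
  V <- XtXi %*% meat %*% XtXi
  se <- sqrt(diag(V))
  tval <- b / se
  data.frame(term = colnames(Z), estimate = b, se = se, t = tval,
             p = 2 * pt(-abs(tval), df = n - p), row.names = NULL)
}

z_scale <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

# group-level stage shared by fit_history_model and joint_task_model:
# regress each column of the per-participant coefficient matrix B on Z
group_stage <- function(B, Z, prefix_map) {
  out <- NULL
  for (j in seq_len(ncol(B))) {
    r <- robust_ols(B[, j], Z)
    r$term <- ifelse(r$term == "(Intercept)", colnames(B)[j],
                     paste0(colnames(B)[j], ":", r$term))
    out <- rbind(out, r)
  }
  out
}

#' Two-stage hierarchical estimation of history effects
#'
#' Stage 1 fits each participant's lagged logistic regression with a mild
#' ridge penalty; stage 2 regresses every per-participant coefficient on the
#' z-normalized psychiatric factors and covariates by OLS with HC3 robust
#' standard errors. Slopes are the factor-interaction effects; intercepts are
#' the group main effects. Totals over lags (`R_total`, `C_total` and their
#' factor interactions) are estimated by regressing the lag-summed
#' coefficients on the same group design. FDR (Benjamini-Hochberg) is applied
#' within each family of interest: the two main totals, the reward-total
#' factor interactions, and the choice-total factor interactions.
#'
#' `estimator = "laplace_glmm"` instead fits a joint random-slope logistic
#' model by an iterated Laplace/EM scheme (slower; same estimands).
#'
#' @param designs list of per-participant design data.frames from
#'   [build_history_design()].
#' @param factor_scores data.frame with `participant_id`, `CIT`, `AD`, `IM`.
#' @param covariates optional data.frame with `participant_id` plus numeric
#'   covariate columns (e.g. age, sex, education, ses).
#' @param estimator `"two_stage"` (default) or `"laplace_glmm"`.
#' @param ridge_lambda stage-1 ridge penalty (default 1).
#' @return An effect table (data.frame: `term`, `estimate`, `se`, `t`, `p`,
#'   `q`) with attributes `per_participant` (stage-1 coefficient matrix) and
#'   `group_design`.
#' @export
fit_history_model <- function(designs, factor_scores, covariates = NULL,
                              estimator = c("two_stage", "laplace_glmm"),
                              ridge_lambda = 1) {
  estimator <- match.arg(estimator)
  stage1 <- history_stage1(designs, ridge_lambda)
  Z <- history_group_design(rownames(stage1$B), factor_scores, covariates)
  if (nrow(Z) <= ncol(Z))
    stop("too few participants for the group-level stage")
  if (estimator == "laplace_glmm")
    return(history_laplace_glmm(designs, Z, stage1))
  tab <- history_effect_table(stage1$B, Z, stage1$tau_max)
  attr(tab, "per_participant") <- stage1$B
  attr(tab, "group_design") <- Z
  tab
}

history_stage1 <- function(designs, ridge_lambda) {
  if (is.data.frame(designs))
    designs <- split(designs, designs$participant_id)
  if (length(designs) == 0L) stop("no designs supplied")
  cols <- grep("^[RC][0-9]+$", names(designs[[1]]), value = TRUE)
  tau_max <- sum(grepl("^R", cols))
  B <- t(vapply(designs, function(d) {
    X <- cbind(1, as.matrix(d[, cols]))
    b <- ridge_logistic(X, d$y, ridge_lambda)
    b[-1]
  }, numeric(length(cols))))
  colnames(B) <- cols
  rownames(B) <- vapply(designs, function(d)
    as.character(d$participant_id[1]), character(1))
  list(B = B, tau_max = tau_max)
}

history_group_design <- function(ids, factor_scores, covariates,
                                 task = NULL) {
  fs <- factor_scores[match(ids, factor_scores$participant_id), , drop = FALSE]
  if (any(is.na(fs$participant_id)))
    stop("factor_scores missing for some participants")
  Zc <- fs[, setdiff(names(fs), "participant_id"), drop = FALSE]
  if (!is.null(covariates)) {
    cv <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
    if (any(is.na(cv$participant_id)))
      stop("covariates missing for some participants")
    Zc <- cbind(Zc, cv[, setdiff(names(cv), "participant_id"), drop = FALSE])
  }
  Zc <- as.data.frame(lapply(Zc, z_scale))
  if (!is.null(task)) {
    base <- Zc
    for (v in names(base)) Zc[[paste0(v, ":task")]] <- base[[v]] * task
    Zc$task <- task
  }
  Z <- cbind(`(Intercept)` = 1, as.matrix(Zc))
  rownames(Z) <- ids
  Z
}

history_effect_table <- function(B, Z, tau_max) {
  Rcols <- paste0("R", seq_len(tau_max))
  Ccols <- paste0("C", seq_len(tau_max))
  tot <- cbind(R_total = rowSums(B[, Rcols, drop = FALSE]),
               C_total = rowSums(B[, Ccols, drop = FALSE]))
  tab <- rbind(group_stage(B, Z), group_stage(tot, Z))
  tab$q <- NA_real_
  fam_main <- tab$term %in% c("R_total", "C_total")
  tab$q[fam_main] <- bh_fdr(tab$p[fam_main])
  for (f in c("R_total", "C_total")) {
    fam <- tab$term %in% paste0(f, ":", c("CIT", "AD", "IM"))
    tab$q[fam] <- bh_fdr(tab$p[fam])
    fam3 <- tab$term %in% paste0(f, ":", c("CIT", "AD", "IM"), ":task")
    if (any(fam3)) tab$q[fam3] <- bh_fdr(tab$p[fam3])
  }
  tab
}

#' Total history effects from an effect table
#'
#' Sums per-lag coefficients within each regressor family (past rewards, past
#' choices, and each family's interaction with each group-level predictor) and
#' checks they match the directly estimated `*_total` rows of the table.
#'
#' @param effect_table output of [fit_history_model()].
#' @param tau_max history length used to build the designs.
#' @return named vector of total effects.
#' @export
total_effects <- function(effect_table, tau_max) {
  terms <- effect_table$term
  est <- setNames(effect_table$estimate, terms)
  suffixes <- unique(sub("^[RC][0-9]+:?", "", terms[grepl("^[RC][0-9]+", terms)]))
  out <- c()
  for (fam in c("R", "C")) {
    for (sfx in suffixes) {
      lag_terms <- paste0(fam, seq_len(tau_max), ifelse(sfx == "", "",
                                                        paste0(":", sfx)))
      if (all(lag_terms %in% terms)) {
        nm <- paste0(fam, "_total", ifelse(sfx == "", "", paste0(":", sfx)))
        out[nm] <- sum(est[lag_terms])
      }
    }
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1, reported in the original order.
#'
#' @param p_values vector of p-values in `[0,1]`.
#' @param n_tests number of tests `m` (defaults to `length(p_values)`).
#' @return adjusted q-values.
#' @export
bh_fdr <- function(p_values, n_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  m <- n_tests
  n <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Joint two-task model with task interactions
#'
#' Pools the reward-seeking and loss-avoidance arms (task coded `+1` / `-1`)
#' and adds task main and task-interaction terms (including the three-way
#' history x factor x task terms) to the group-level stage.
#'
#' @param designs_reward,designs_loss per-participant design lists for the two
#'   arms.
#' @param factor_scores,covariates as in [fit_history_model()].
#' @param task_coding length-2 numeric, codes for (reward, loss); default
#'   `c(1, -1)`.
#' @param ridge_lambda stage-1 ridge penalty.
#' @return effect table as in [fit_history_model()], with `:task` terms.
#' @export
joint_task_model <- function(designs_reward, designs_loss, factor_scores,
                             covariates = NULL, task_coding = c(1, -1),
                             ridge_lambda = 1) {
  if (length(designs_reward) == 0L || length(designs_loss) == 0L)
    stop("both task arms must be present")
  s1 <- history_stage1(designs_reward, ridge_lambda)
  s2 <- history_stage1(designs_loss, ridge_lambda)
  B <- rbind(s1$B, s2$B)
  task <- c(rep(task_coding[1], nrow(s1$B)), rep(task_coding[2], nrow(s2$B)))
  Z <- history_group_design(rownames(B), factor_scores, covariates,
                            task = task)
  if (nrow(Z) <= ncol(Z))
    stop("too few participants for the group-level stage")
  tab <- history_effect_table(B, Z, s1$tau_max)
  attr(tab, "per_participant") <- B
  attr(tab, "group_design") <- Z
  tab
}

# Iterated Laplace/EM fit of the joint random-slope logistic model: the
# participant-level coefficients get Gaussian priors centred on Z delta with
# diagonal covariance D; E-step = per-participant penalized IRLS (posterior
# mode + curvature), M-step = closed-form updates of delta and D.
history_laplace_glmm <- function(designs, Z, stage1, max_iter = 30L) {
  if (is.data.frame(designs))
    designs <- split(designs, designs$participant_id)
  ids <- rownames(Z)
  designs <- designs[match(ids, vapply(designs, function(d)
    as.character(d$participant_id[1]), character(1)))]
  cols <- colnames(stage1$B)
  p <- length(cols) + 1L  # + intercept
  Xs <- lapply(designs, function(d) cbind(1, as.matrix(d[, cols])))
  ys <- lapply(designs, function(d) d$y)
  n <- length(ids)
  Bhat <- cbind(b0 = 0, stage1$B)  # modes, warm start from two-stage fits
  delta <- matrix(0, ncol(Z), p)   # group-level coefficients per RL column
  D <- rep(1, p)
  for (it in seq_len(max_iter)) {
    mu_i <- Z %*% delta
    Vsum <- rep(0, p)
    for (i in seq_len(n)) {
      b <- Bhat[i, ]
      for (nr in 1:25) {
        eta <- drop(Xs[[i]] %*% b)
        m <- plogis(eta)
        w <- pmax(m * (1 - m), 1e-10)
        H <- crossprod(Xs[[i]], Xs[[i]] * w) + diag(1 / D, p)
        g <- crossprod(Xs[[i]], ys[[i]] - m) - (b - mu_i[i, ]) / D
        step <- solve(H, g)
        b <- b + drop(step)
        if (max(abs(step)) < 1e-6) break
      }
      Bhat[i, ] <- b
      Vsum <- Vsum + diag(solve(H))
    }
    ZtZi <- solve(crossprod(Z))
    delta_new <- ZtZi %*% crossprod(Z, Bhat)
    resid <- Bhat - Z %*% delta_new
    D_new <- pmax(colSums(resid^2) / n + Vsum / n, 1e-4)
    done <- max(abs(delta_new - delta)) < 1e-6
    delta <- delta_new
    D <- D_new
    if (done) break
  }
  tab <- history_effect_table(Bhat[, -1, drop = FALSE], Z, stage1$tau_max)
  attr(tab, "per_participant") <- Bhat[, -1, drop = FALSE]
  attr(tab, "group_design") <- Z
  attr(tab, "random_effect_var") <- setNames(D, c("b0", cols))
  tab
}
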