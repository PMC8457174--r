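#' Polychoric correlation matrix of ordinal questionnaire data
#'
#' Two-step pairwise estimates: item thresholds from the marginal cumulative
#' proportions via the inverse normal, then each pairwise correlation by
#' maximizing the bivariate-normal likelihood of the two-way contingency table
#' (Brent search). If the assembled matrix is not positive semi-definite it is
#' repaired by clipping eigenvalues at 1e-6 and rescaling to unit diagonal
#' (the event is recorded in the `"psd_repaired"` attribute and messaged).
#'
#' @param data integer matrix or data.frame of ordinal responses (levels
#'   coded `1..L` or any integer codes; columns are items), or a
#'   `transdx_questionnaire` from [questionnaire_from_factors()].
#' @return P x P correlation matrix with attribute `psd_repaired`.
#' @export
polychoric_matrix <- function(data) {
  X <- questionnaire_responses(data)
  if (any(is.na(X))) stop("missing responses not supported; impute first")
  P <- ncol(X)
  items <- colnames(X)
  if (is.null(items)) items <- paste0("item_", seq_len(P))
  Xc <- matrix(0L, nrow(X), P)
  thresholds <- vector("list", P)
  n_levels <- integer(P)
  for (p in seq_len(P)) {
    lev <- sort(unique(X[, p]))
    if (length(lev) < 2L)
      stop(sprintf("item '%s' has a single observed level", items[p]))
    codes <- match(X[, p], lev)
    Xc[, p] <- codes
    n_levels[p] <- length(lev)
    cum <- cumsum(tabulate(codes, length(lev))) / nrow(X)
    thresholds[[p]] <- qnorm(cum[-length(lev)])
  }
  R <- .polychoric_all_cpp(Xc, thresholds, n_levels)
  dimnames(R) <- list(items, items)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (min(ev) < 0) {
    e <- eigen(R, symmetric = TRUE)
    lam <- pmax(e$values, 1e-6)
    R2 <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(R2))
    R <- R2 / tcrossprod(d)
    dimnames(R) <- list(items, items)
    repaired <- TRUE
    message("polychoric matrix was indefinite; nearest-PSD repair applied")
  }
  attr(R, "psd_repaired") <- repaired
  R
}

# pull the response matrix out of whatever container the caller has
questionnaire_responses <- function(data) {
  if (inherits(data, "transdx_questionnaire")) return(data$responses)
  if (is.data.frame(data)) {
    data <- data[, setdiff(names(data), "participant_id"), drop = FALSE]
    return(as.matrix(data))
  }
  as.matrix(data)
}

#' Cattell-Nelson-Gorsuch (CNG) factor-number test
#'
#' Fits a least-squares slope to every triplet of adjacent eigenvalues of the
#' scree and returns the factor count at which the drop between the slope of
#' the triplet ending there and the slope of the following triplet is largest:
#' with triplets starting at positions `i` and `i + 3`, the returned count is
#' `argmax_i (slope_{i+3} - slope_i) + 2`. A flat (linear) scree has no elbow;
#' the function then returns 1 with a warning.
#'
#' @param eigenvalues eigenvalues sorted in decreasing order, length >= 6.
#' @return integer number of factors.
#' @export
cng_factor_count <- function(eigenvalues) {
  L <- length(eigenvalues)
  if (L < 6L) stop("need at least 6 eigenvalues for the CNG test")
  if (is.unsorted(rev(eigenvalues)))
    eigenvalues <- sort(eigenvalues, decreasing = TRUE)
  slope3 <- function(y) {
    x <- seq_along(y)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  ncand <- L - 5L
  diffs <- vapply(seq_len(ncand), function(i) {
    slope3(eigenvalues[(i + 3):(i + 5)]) - slope3(eigenvalues[i:(i + 2)])
  }, numeric(1))
  if (max(diffs) < 1e-10 * max(abs(eigenvalues), 1)) {
    warning("flat scree: no dominant elbow, returning 1 factor")
    return(1L)
  }
  as.integer(which.max(diffs) + 2L)
}

# Minimum-residual (ULS) factor extraction: minimize the sum of squared
# off-diagonal residuals over the uniquenesses, loadings conditionally from
# the top-m eigen pairs of (R - Psi). Envelope theorem gives the analytic
# gradient: minus the diagonal of the residual matrix.
minres_extract <- function(R, n_factors, max_iter = 500L) {
  P <- ncol(R)
  lambda_from_psi <- function(psi) {
    e <- eigen(R - diag(psi, P), symmetric = TRUE)
    m <- seq_len(n_factors)
    lam <- e$vectors[, m, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[m], 0)), n_factors)
    lam
  }
  fobj <- function(psi) {
    lam <- lambda_from_psi(psi)
    res <- R - tcrossprod(lam) - diag(psi, P)
    sum(res^2) / 2
  }
  fgrad <- function(psi) {
    lam <- lambda_from_psi(psi)
    -diag(R - tcrossprod(lam) - diag(psi, P))
  }
  start <- pmin(pmax(1 - 0.5 * smc(R), 0.05), 0.95)
  opt <- optim(start, fobj, fgrad, method = "L-BFGS-B",
               lower = rep(0.001, P), upper = rep(1, P),
               control = list(maxit = max_iter))
  psi <- opt$par
  heywood <- psi <= 0.0011
  if (any(heywood))
    warning(sprintf("Heywood case: %d communalities clipped at 1", sum(heywood)))
  lam <- lambda_from_psi(psi)
  # sign convention: dominant direction of each factor positive
  s <- sign(colSums(lam^3))
  s[s == 0] <- 1
  lam <- sweep(lam, 2L, s, "*")
  list(loadings = lam, uniquenesses = psi,
       converged = opt$convergence == 0)
}

# squared multiple correlations (initial communality estimates)
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(0.01, ncol(R))))
  1 - 1 / diag(Ri)
}

#' Factor extraction with promax rotation
#'
#' Minimum-residual extraction of `n_factors` factors from a correlation
#' matrix, followed by varimax and the promax power-4 oblique transform (the
#' conventional default of the cited factor-analysis routines). Explained
#' variance per rotated factor is the sum over items of pattern x structure
#' contributions divided by the number of items.
#'
#' @param corr_matrix PSD correlation matrix (e.g. from
#'   [polychoric_matrix()]).
#' @param n_factors number of factors (default 3).
#' @param rotation `"promax"` (default), `"varimax"`, or `"none"`.
#' @return A `transdx_factors` solution: `loadings` (pattern), `structure`,
#'   `factor_corr`, `eigenvalues`, `n_factors`, `explained_variance`,
#'   `uniquenesses`, `converged`. `scores` is `NULL` until
#'   [harman_scores()] is run.
#' @export
extract_and_rotate <- function(corr_matrix, n_factors = 3L,
                               rotation = c("promax", "varimax", "none")) {
  rotation <- match.arg(rotation)
  R <- as.matrix(corr_matrix)
  P <- ncol(R)
  if (n_factors < 1L || n_factors >= P) stop("invalid n_factors")
  ex <- minres_extract(R, n_factors)
  lam <- ex$loadings
  Phi <- diag(n_factors)
  if (rotation != "none" && n_factors > 1L) {
    vm <- stats::varimax(lam)
    lam <- unclass(vm$loadings)
    if (rotation == "promax") {
      pm <- stats::promax(lam, m = 4)
      lam <- unclass(pm$loadings)
      U <- pm$rotmat
      Phi <- solve(crossprod(U))
      # normalize in case of numerical drift off the unit diagonal
      dph <- sqrt(diag(Phi))
      Phi <- Phi / tcrossprod(dph)
    }
  }
  struct <- lam %*% Phi
  expl <- colSums(lam * struct) / P
  o <- order(expl, decreasing = TRUE)
  lam <- lam[, o, drop = FALSE]
  Phi <- Phi[o, o, drop = FALSE]
  struct <- struct[, o, drop = FALSE]
  expl <- expl[o]
  fac_names <- paste0("F", seq_len(n_factors))
  dimnames(lam) <- list(rownames(R), fac_names)
  dimnames(struct) <- dimnames(lam)
  dimnames(Phi) <- list(fac_names, fac_names)
  structure(list(loadings = lam, structure = struct, factor_corr = Phi,
                 eigenvalues = eigen(R, symmetric = TRUE,
                                     only.values = TRUE)$values,
                 n_factors = as.integer(n_factors),
                 explained_variance = setNames(expl, fac_names),
                 uniquenesses = ex$uniquenesses,
                 scores = NULL, converged = ex$converged),
            class = "transdx_factors")
}

#' @export
print.transdx_factors <- function(x, ...) {
  cat(sprintf("<transdx_factors> %d items, %d factors; explained variance %s\n",
              nrow(x$loadings), x$n_factors,
              paste(round(x$explained_variance, 3), collapse = ", ")))
  invisible(x)
}

#' Harman factor scores
#'
#' Idealized-variable weights `W = L (L' L)^-1` applied to the standardized
#' item responses, with each score column z-scored afterwards.
#'
#' @param data response matrix / data.frame / `transdx_questionnaire` (no
#'   missing values; imputation is the caller's duty).
#' @param solution a `transdx_factors` solution fitted on the same items.
#' @return N x n_factors matrix of factor scores (mean 0, sd 1 per column).
#' @export
harman_scores <- function(data, solution) {
  X <- questionnaire_responses(data)
  if (any(is.na(X))) stop("missing responses: impute before scoring")
  if (ncol(X) != nrow(solution$loadings))
    stop("data and solution differ in item count")
  Zs <- scale(X)
  Zs[is.nan(Zs)] <- 0  # constant item safeguard (cannot occur after fitting)
  L <- solution$loadings
  W <- L %*% solve(crossprod(L))
  S <- Zs %*% W
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  colnames(S) <- colnames(L)
  rownames(S) <- rownames(X)
  S
}

#' Drop low-loading items
#'
#' Keeps items whose maximum absolute pattern loading is at least `cutoff`
#' (default 0.4) so the pipeline can be re-run on the reduced battery.
#'
#' @param data response container as in [polychoric_matrix()].
#' @param solution fitted `transdx_factors`.
#' @param cutoff loading cutoff (default 0.4).
#' @return list with `responses` (reduced matrix), `kept` (logical vector over
#'   items), and, when `data` is a `transdx_questionnaire`, the reduced
#'   `item_instrument` map.
#' @export
low_loading_filter <- function(data, solution, cutoff = 0.4) {
  X <- questionnaire_responses(data)
  keep <- apply(abs(solution$loadings), 1L, max) >= cutoff
  names(keep) <- colnames(X)
  if (!any(keep)) stop("all items fall below the loading cutoff")
  out <- list(responses = X[, keep, drop = FALSE], kept = keep)
  if (inherits(data, "transdx_questionnaire"))
    out$item_instrument <- data$item_instrument[keep]
  out
}

#' Label and sign-align factors as CIT / AD / IM
#'
#' Assigns the transdiagnostic labels by instrument profile: CIT is the factor
#' with the highest median absolute loading on OCD items, AD on the pooled
#' depression and anxiety items, IM on impulsivity items (greedy assignment,
#' ties to the stronger claim). Each factor's sign is flipped if needed so its
#' defining instrument loads positively.
#'
#' @param solution a `transdx_factors` with 3 factors.
#' @param item_instrument character vector mapping each item to an instrument
#'   in `{schizotypy, OCD, depression, anxiety, impulsivity}`.
#' @return the solution with columns reordered/sign-aligned and renamed
#'   `CIT`, `AD`, `IM`.
#' @export
label_factors <- function(solution, item_instrument) {
  if (solution$n_factors != 3L) stop("labeling expects a 3-factor solution")
  L <- solution$loadings
  defn <- list(CIT = item_instrument == "OCD",
               AD = item_instrument %in% c("depression", "anxiety"),
               IM = item_instrument == "impulsivity")
  claim <- sapply(defn, function(idx)
    apply(L[idx, , drop = FALSE], 2L, function(v) median(abs(v))))
  # claim: 3 factors x 3 labels; greedy assignment of labels to factors
  assign <- rep(NA_integer_, 3)
  names(assign) <- colnames(claim)
  cl <- claim
  for (k in 1:3) {
    idx <- which(cl == max(cl), arr.ind = TRUE)[1, ]
    assign[idx[2]] <- idx[1]
    cl[idx[1], ] <- -Inf
    cl[, idx[2]] <- -Inf
  }
  o <- assign[c("CIT", "AD", "IM")]
  flip <- vapply(c("CIT", "AD", "IM"), function(lab)
    sign(median(L[defn[[lab]], o[lab]])), numeric(1))
  flip[flip == 0] <- 1
  relabel <- function(M) {
    M <- M[, o, drop = FALSE] %*% diag(flip, 3)
    colnames(M) <- c("CIT", "AD", "IM")
    M
  }
  solution$loadings <- relabel(solution$loadings)
  rownames(solution$loadings) <- rownames(L)
  solution$structure <- relabel(solution$structure)
  rownames(solution$structure) <- rownames(L)
  Phi <- diag(flip, 3) %*% solution$factor_corr[o, o] %*% diag(flip, 3)
  dimnames(Phi) <- list(c("CIT", "AD", "IM"), c("CIT", "AD", "IM"))
  solution$factor_corr <- Phi
  solution$explained_variance <-
    setNames(solution$explained_variance[o], c("CIT", "AD", "IM"))
  if (!is.null(solution$scores)) {
    solution$scores <- relabel(solution$scores)
  }
  solution
}

#' Run the whole factor pipeline on a questionnaire battery
#'
#' Polychoric matrix, CNG factor count (capped/forced by `n_factors` if
#' given), minres + promax, Harman scores, and CIT/AD/IM labeling when an
#' instrument map is available.
#'
#' @param data response container (matrix / data.frame /
#'   `transdx_questionnaire`).
#' @param item_instrument optional instrument map (taken from the
#'   questionnaire object when present).
#' @param n_factors optional fixed factor count; default uses the CNG test.
#' @return list with `corr`, `n_factors_cng`, `solution` (scores filled in).
#' @export
run_factor_pipeline <- function(data, item_instrument = NULL,
                                n_factors = NULL) {
  if (is.null(item_instrument) && inherits(data, "transdx_questionnaire"))
    item_instrument <- data$item_instrument
  R <- polychoric_matrix(data)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  k_cng <- cng_factor_count(ev)
  k <- if (is.null(n_factors)) k_cng else as.integer(n_factors)
  sol <- extract_and_rotate(R, n_factors = k)
  sol$scores <- harman_scores(data, sol)
  if (!is.null(item_instrument) && k == 3L)
    sol <- label_factors_with_scores(sol, data, item_instrument)
  list(corr = R, n_factors_cng = k_cng, solution = sol)
}

# label the solution then recompute scores so score columns match labels
label_factors_with_scores <- function(sol, data, item_instrument) {
  sol <- label_factors(sol, item_instrument)
  sol$scores <- harman_scores(data, sol)
  sol
}
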