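test_that("polychoric estimates recover generative correlations", {
  set.seed(31)
  N <- 5000
  z1 <- rnorm(N)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(N)
  z3 <- rnorm(N)  # independent of z1
  cuts <- c(-1, 0, 1)
  X <- cbind(a = findInterval(z1, cuts), b = findInterval(z2, cuts),
             c = findInterval(z3, cuts)) + 1L
  R <- polychoric_matrix(X)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_lt(abs(R["a", "b"] - 0.5), 0.05)
  expect_lt(abs(R["a", "c"]), 0.05)
  expect_true(isSymmetric(R))
})

test_that("polychoric approaches Pearson in the continuous limit", {
  set.seed(32)
  N <- 10000
  z1 <- rnorm(N)
  z2 <- 0.6 * z1 + 0.8 * rnorm(N)
  cuts <- qnorm(seq(0.05, 0.95, length.out = 19))  # 20 levels
  X <- cbind(a = findInterval(z1, cuts), b = findInterval(z2, cuts)) + 1L
  R <- polychoric_matrix(X)
  expect_lt(abs(R["a", "b"] - cor(z1, z2)), 0.02)
})

test_that("polychoric rejects constant items and missing data", {
  X <- cbind(a = rep(1L, 50), b = rep(1:2, 25))
  expect_error(polychoric_matrix(X), "'a'")
  X2 <- cbind(a = c(NA, rep(1:2, 25)), b = rep(1:2, length.out = 51))
  expect_error(polychoric_matrix(X2), "missing")
})

test_that("CNG slope-difference rule matches the hand application", {
  ev <- c(6, 3.5, 1.8, 0.31, 0.30, 0.29, 0.28, 0.27, 0.26)
  expect_identical(cng_factor_count(ev), 3L)
  expect_warning(k <- cng_factor_count(seq(10, 1, length.out = 12)), "flat")
  expect_identical(k, 1L)
  expect_error(cng_factor_count(c(3, 2, 1)), "at least 6")
})

test_that("extraction plus promax recovers a planted oblique structure", {
  # known 3-factor oblique model, loadings 0.4-0.8, inter-factor r = 0.3
  set.seed(33)
  P <- 30
  L <- matrix(0, P, 3)
  L[1:10, 1] <- runif(10, 0.4, 0.8)
  L[11:20, 2] <- runif(10, 0.4, 0.8)
  L[21:30, 3] <- runif(10, 0.4, 0.8)
  Phi <- matrix(0.3, 3, 3); diag(Phi) <- 1
  Sigma <- L %*% Phi %*% t(L)
  diag(Sigma) <- 1
  sol <- extract_and_rotate(Sigma, n_factors = 3)
  expect_true(all(tucker_congruence(L, sol$loadings) >= 0.95))
  # recovered factor correlations close to the planted 0.3
  off <- sol$factor_corr[upper.tri(sol$factor_corr)]
  expect_true(all(abs(abs(off) - 0.3) < 0.15))

  # orthogonal planted factors: promax stays near-orthogonal
  Sigma0 <- L %*% t(L)
  diag(Sigma0) <- 1
  sol0 <- extract_and_rotate(Sigma0, n_factors = 3)
  expect_true(all(abs(sol0$factor_corr[upper.tri(sol0$factor_corr)]) < 0.1))
})

test_that("permuting items permutes loading rows identically", {
  set.seed(34)
  P <- 18
  L <- matrix(0, P, 3)
  L[1:6, 1] <- 0.7; L[7:12, 2] <- 0.6; L[13:18, 3] <- 0.65
  Sigma <- L %*% t(L); diag(Sigma) <- 1
  dimnames(Sigma) <- list(paste0("i", 1:P), paste0("i", 1:P))
  perm <- sample(P)
  s1 <- extract_and_rotate(Sigma, 3)
  s2 <- extract_and_rotate(Sigma[perm, perm], 3)
  expect_equal(abs(s1$loadings[perm, ]), abs(s2$loadings),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("harman scores recover planted latent scores", {
  set.seed(35)
  N <- 1000
  tmpl <- default_loading_template()
  Phi <- matrix(c(1, 0.3, 0.37, 0.3, 1, 0.2, 0.37, 0.2, 1), 3, 3)
  scores <- matrix(rnorm(N * 3), N, 3) %*% chol(Phi)
  colnames(scores) <- c("CIT", "AD", "IM")
  q <- questionnaire_from_factors(scores, tmpl$loadings, c(-0.8, 0.3, 1.2),
                                  seed = 36L, factor_corr = Phi,
                                  item_instrument = tmpl$item_instrument)
  R <- suppressMessages(polychoric_matrix(q))
  sol <- extract_and_rotate(R, 3)
  sol <- label_factors(sol, q$item_instrument)
  sc <- harman_scores(q, sol)
  for (f in c("CIT", "AD", "IM")) {
    expect_gte(cor(sc[, f], scores[, f]), 0.9)
    expect_equal(mean(sc[, f]), 0, tolerance = 1e-10)
    expect_equal(sd(sc[, f]), 1, tolerance = 1e-10)
  }
  # duplicated participants give identical scores
  q2 <- q
  q2$responses <- rbind(q$responses[1:10, ], q$responses[1:10, ])
  sc2 <- harman_scores(q2$responses, sol)
  expect_equal(sc2[1:10, ], sc2[11:20, ], ignore_attr = TRUE)

  bad <- q$responses
  bad[1, 1] <- NA
  expect_error(harman_scores(bad, sol), "missing")
})

test_that("low-loading filter keeps items by max absolute loading", {
  L <- matrix(c(0.7, 0.39, 0.6, 0, 0.2, -0.45), 3, 2)
  sol <- list(loadings = L)
  X <- matrix(sample(1:4, 300, TRUE), 100, 3,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  red <- low_loading_filter(X, sol, cutoff = 0.4)
  expect_equal(red$kept, c(i1 = TRUE, i2 = FALSE, i3 = TRUE))

  sol_hi <- list(loadings = matrix(0.6, 3, 2))
  expect_equal(sum(low_loading_filter(X, sol_hi)$kept), 3L)

  sol_lo <- list(loadings = matrix(0.1, 3, 2))
  expect_error(low_loading_filter(X, sol_lo), "all items")
})

test_that("full pipeline labels the planted transdiagnostic structure", {
  coh <- quick_cohort(seed = 37L, n_per_arm = 250, questionnaire = TRUE)
  fp <- suppressMessages(run_factor_pipeline(coh$questionnaire))
  expect_identical(fp$n_factors_cng, 3L)
  sol <- fp$solution
  inst <- coh$questionnaire$item_instrument
  # OCD items define CIT; impulsivity defines IM; anxiety/depression define AD
  expect_gt(median(sol$loadings[inst == "OCD", "CIT"]), 0.4)
  expect_gt(median(sol$loadings[inst == "anxiety", "AD"]),
            median(sol$loadings[inst == "anxiety", "IM"]))
  expect_gt(median(sol$loadings[inst == "impulsivity", "IM"]), 0.2)
  # reduced battery preserves the structure (loading filter robustness)
  red <- low_loading_filter(coh$questionnaire, sol, cutoff = 0.4)
  R2 <- suppressMessages(polychoric_matrix(red$responses))
  sol2 <- extract_and_rotate(R2, 3)
  cong <- tucker_congruence(sol$loadings[red$kept, ], sol2$loadings)
  expect_true(all(cong >= 0.95))
})
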