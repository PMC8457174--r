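test_that("history design reproduces the hand-coded 6-trial fixture", {
  # reward context, target X = option 1, tau_max = 2
  # trials: choice  1  2  1  NA 3  1
  #         outcome 1  1  0  NA 1  0
  s <- choice_session("h", "reward",
                      c(1L, 2L, 1L, NA, 3L, 1L),
                      c(1, 1, 0, NA, 1, 0))
  d <- build_history_design(s, target_option = 1L, tau_max = 2L)
  # rows for responded trials t = 3, 5, 6 (t = 4 missed)
  expect_equal(d$trial, c(3L, 5L, 6L))
  expect_equal(d$y, c(1L, 0L, 1L))
  # t = 3: lag1 = trial2 (chose Y, rewarded -> R = -1, C = -1),
  #        lag2 = trial1 (chose X, rewarded -> R = +1, C = +1)
  expect_equal(unlist(d[1, c("R1", "R2", "C1", "C2")]),
               c(R1 = -1, R2 = 1, C1 = -1, C2 = 1))
  # t = 5: lag1 = trial4 missed -> R = 0, C = 0;
  #        lag2 = trial3 (chose X, no reward -> R = 0, C = +1)
  expect_equal(unlist(d[2, c("R1", "R2", "C1", "C2")]),
               c(R1 = 0, R2 = 0, C1 = 0, C2 = 1))
  # t = 6: lag1 = trial5 (chose Z, rewarded -> R = -1, C = -1);
  #        lag2 = trial4 missed -> 0, 0
  expect_equal(unlist(d[3, c("R1", "R2", "C1", "C2")]),
               c(R1 = -1, R2 = 0, C1 = -1, C2 = 0))
})

test_that("loss context treats no-loss as success in the history coding", {
  s <- choice_session("h", "loss", c(1L, 2L, 3L), c(0, -1, 0))
  d <- build_history_design(s, target_option = 1L, tau_max = 2L)
  # t = 3: lag1 = trial2 (chose Y, lost -> R = 0, C = -1);
  #        lag2 = trial1 (chose X, no-loss = success -> R = +1, C = +1)
  expect_equal(unlist(d[1, c("R1", "R2", "C1", "C2")]),
               c(R1 = 0, R2 = 1, C1 = -1, C2 = 1))
})

test_that("a fully-responded 500-trial session yields 496 rows at tau 4", {
  sch <- generate_schedule(seed = 61L)
  s <- simulate_agent(sch, "reward", "RL1a", c(alpha = 0.3, beta = 4),
                      miss_rate = 0, seed = 12L)
  d <- build_history_design(s, tau_max = 4L)
  expect_equal(nrow(d), 496L)
  expect_error(build_history_design(s, tau_max = 1L), "tau_max")
  expect_error(build_history_design(s, tau_max = 7L), "tau_max")

  short <- choice_session("s", "reward", c(1L, 2L), c(1, 0))
  expect_warning(d0 <- build_history_design(short, tau_max = 4L), "empty")
  expect_equal(nrow(d0), 0L)
})

test_that("bh_fdr matches the hand computation and p.adjust oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("two-stage fit recovers group effects; totals sum per-lag rows", {
  coh <- quick_cohort(seed = 21L, n_per_arm = 60, n_trials = 300)
  ctx <- vapply(coh$sessions, function(s) s$context, character(1))
  designs <- lapply(coh$sessions[ctx == "reward"], build_history_design)
  fs <- cohort_factor_df(coh)
  tab <- fit_history_model(designs, fs, coh$ground_truth$covariates)

  est <- setNames(tab$estimate, tab$term)
  expect_gt(est["R_total"], 0)          # reward history reinforces
  # totals equal the sums of their per-lag rows (linearity of the group stage)
  tot <- total_effects(tab, 4L)
  expect_equal(unname(tot["R_total"]), unname(est["R_total"]),
               tolerance = 1e-10)
  expect_equal(unname(tot["C_total:CIT"]), unname(est["C_total:CIT"]),
               tolerance = 1e-10)

  expect_error(fit_history_model(designs[1], fs), "too few")
})

test_that("agents that avoid recent choices show negative choice totals", {
  sch <- generate_schedule(n_trials = 400L, seed = 62L)
  designs <- lapply(1:40, function(i) {
    s <- simulate_agent(sch, "reward", "RL2a",
                        c(alpha = 0.3, beta = 4, gamma = -1.5, alpha_C = 0.4),
                        seed = 70 + i, participant_id = sprintf("A%02d", i))
    build_history_design(s)
  })
  s1 <- transdx:::history_stage1(designs, 1)
  C_tot <- rowSums(s1$B[, paste0("C", 1:4)])
  expect_lt(mean(C_tot), 0)
  expect_gt(mean(rowSums(s1$B[, paste0("R", 1:4)])), 0)
})

test_that("history totals track the generating RL parameters monotonically", {
  sch <- generate_schedule(n_trials = 500L, seed = 63L)
  set.seed(64)
  n <- 100
  alpha <- runif(n, 0.05, 0.6)
  gamma <- runif(n, -2, 2)
  designs <- lapply(1:n, function(i) {
    s <- simulate_agent(sch, "reward", "RL2b",
                        c(alpha = alpha[i], beta = 5, gamma = gamma[i],
                          alpha_F = 0.2, alpha_C = 0.4),
                        seed = 200 + i, participant_id = sprintf("M%03d", i))
    build_history_design(s)
  })
  s1 <- transdx:::history_stage1(designs, 1)
  R_tot <- rowSums(s1$B[, paste0("R", 1:4)])
  C_tot <- rowSums(s1$B[, paste0("C", 1:4)])
  expect_gt(cor(alpha, R_tot, method = "spearman"), 0.5)
  expect_gt(cor(gamma, C_tot, method = "spearman"), 0.5)
})

test_that("group-stage attenuation shrinks as sessions lengthen", {
  est_at <- function(n_trials, seed) {
    coh <- quick_cohort(seed = seed, n_per_arm = 100, n_trials = n_trials)
    ctx <- vapply(coh$sessions, function(s) s$context, character(1))
    designs <- lapply(coh$sessions[ctx == "reward"], build_history_design)
    tab <- fit_history_model(designs, cohort_factor_df(coh))
    tab$estimate[tab$term == "C_total:CIT"]
  }
  # planted positive choice-trace link: the stage-1 noise and ridge at short
  # T attenuate the group slope toward zero
  expect_gt(est_at(1000L, 23L), est_at(200L, 23L))
})

test_that("joint task model codes arms symmetrically", {
  coh <- quick_cohort("strong_effects", seed = 24L, n_per_arm = 50,
                      n_trials = 250)
  ctx <- vapply(coh$sessions, function(s) s$context, character(1))
  dR <- lapply(coh$sessions[ctx == "reward"], build_history_design)
  dL <- lapply(coh$sessions[ctx == "loss"], build_history_design)
  fs <- cohort_factor_df(coh)
  j1 <- joint_task_model(dR, dL, fs)
  j2 <- joint_task_model(dR, dL, fs, task_coding = c(-1, 1))
  t1 <- setNames(j1$estimate, j1$term)
  t2 <- setNames(j2$estimate, j2$term)
  task_terms <- grep(":task$|^task", names(t1), value = TRUE)
  expect_equal(t1[task_terms], -t2[task_terms], tolerance = 1e-10)
  other <- setdiff(names(t1), task_terms)
  expect_equal(t1[other], t2[other], tolerance = 1e-10)

  # identical planted links in both arms: three-way terms are noise around 0
  se <- setNames(j1$se, j1$term)
  expect_lt(abs(t1["C_total:CIT:task"]), 3 * se["C_total:CIT:task"])

  expect_error(joint_task_model(list(), dL, fs), "both task arms")
})

test_that("laplace GLMM estimator agrees directionally with two-stage", {
  coh <- quick_cohort("strong_effects", seed = 25L, n_per_arm = 60,
                      n_trials = 250)
  ctx <- vapply(coh$sessions, function(s) s$context, character(1))
  designs <- lapply(coh$sessions[ctx == "reward"], build_history_design)
  fs <- cohort_factor_df(coh)
  t2s <- fit_history_model(designs, fs)
  tlp <- fit_history_model(designs, fs, estimator = "laplace_glmm")
  for (term in c("R_total", "C_total:CIT", "R_total:CIT")) {
    a <- t2s$estimate[t2s$term == term]
    b <- tlp$estimate[tlp$term == term]
    expect_equal(sign(a), sign(b), label = term)
  }
  expect_true(all(attr(tlp, "random_effect_var") > 0))
})
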