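test_that("choice probabilities match closed-form softmax values", {
  expect_equal(choice_probabilities(c(0.4, -1, 2), beta = 0, gamma = 0),
               rep(1 / 3, 3))
  # p_0 = e^2 / (e^2 + 2) at Q = (1,0,0), beta = 2
  p <- choice_probabilities(c(1, 0, 0), beta = 2)
  expect_equal(p[1], exp(2) / (exp(2) + 2), tolerance = 1e-12)
  # equal Q, trace = (1,0,0), gamma = 1, beta = 5 -> p_0 = e/(e+2)
  p <- choice_probabilities(c(0.3, 0.3, 0.3), trace = c(1, 0, 0),
                            beta = 5, gamma = 1)
  expect_equal(p[1], exp(1) / (exp(1) + 2), tolerance = 1e-12)
  expect_error(choice_probabilities(c(Inf, 0, 0), beta = 1), "finite")
})

test_that("choice probabilities form a simplex point and avoid 0/1", {
  set.seed(11)
  for (i in 1:50) {
    p <- choice_probabilities(rnorm(3, 0, 3), runif(3), beta = runif(1, 0, 30),
                              gamma = runif(1, -10, 10))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0) && all(p < 1))
  }
})

test_that("value updates follow each model's learning rule", {
  st <- list(Q = c(0.5, 0.2, 0), trace = c(0, 0, 0), assoc = 1)
  up <- update_values(st, 1L, 1, c(alpha = 1, beta = 2), "RL1a")
  expect_equal(up$Q[1], 1)
  expect_equal(up$Q[2:3], c(0.2, 0))

  # alpha_F = 0 reduces the forgetting variant to its base model
  up_b <- update_values(st, 1L, 1, c(alpha = 0.4, beta = 2, alpha_F = 0),
                        "RL1b")
  up_a <- update_values(st, 1L, 1, c(alpha = 0.4, beta = 2), "RL1a")
  expect_equal(up_b$Q, up_a$Q)

  # Pearce-Hall with eta = 0 keeps associability constant
  st4 <- list(Q = c(0, 0, 0), trace = c(0, 0, 0), assoc = 1)
  up4 <- update_values(st4, 2L, 1, c(eta = 0, kappa = 0.5, beta = 1), "RL4a")
  expect_equal(up4$assoc, 1)
  expect_equal(up4$Q[2], 0.5)  # alpha_eff = kappa * assoc0 = 0.5

  expect_error(update_values(st, 1L, 1, c(alpha = 0.5), "RL9z"), "unknown")
})

test_that("trace updates decay and accumulate correctly", {
  st <- list(Q = c(0, 0, 0), trace = c(0.4, 0.1, 0.5), assoc = 1)
  expect_equal(update_trace(st, 2L, 1)$trace, c(0, 1, 0))
  expect_equal(update_trace(st, 2L, 0)$trace, st$trace)
  # two updates of the same choice at alpha_C = 0.3: 0.3 + 0.7 * 0.3 = 0.51
  s0 <- list(Q = c(0, 0, 0), trace = c(0, 0, 0), assoc = 1)
  s1 <- update_trace(update_trace(s0, 2L, 0.3), 2L, 0.3)
  expect_equal(s1$trace[2], 0.51, tolerance = 1e-12)
})

test_that("uniform-likelihood bound holds exactly at beta = 0", {
  ch <- c(rep(1:3, 33), 1L)           # 100 responded trials
  ch <- c(ch, rep(NA_integer_, 10))   # plus 10 missed
  oc <- c(rep(c(1, 0), 50), rep(NA_real_, 10))
  s <- choice_session("u", "reward", ch, oc)
  nll <- negative_log_likelihood(s, "RL1a", c(alpha = 0.5, beta = 0))
  expect_equal(nll, 100 * log(3), tolerance = 1e-9)
})

test_that("3-trial RL1a likelihood matches the hand-unrolled computation", {
  s <- choice_session("t", "reward", c(1L, 2L, 1L), c(1, 0, 1))
  nll <- negative_log_likelihood(s, "RL1a", c(alpha = 0.5, beta = 1))
  # t1: Q=(0,0,0), p = 1/3; update Q1 <- 0.5
  # t2: p(choice 2) = 1 / (exp(0.5) + 2); update Q2 <- 0
  # t3: p(choice 1) = exp(0.5) / (exp(0.5) + 2)
  hand <- log(3) + log(exp(0.5) + 2) + (log(exp(0.5) + 2) - 0.5)
  expect_equal(nll, hand, tolerance = 1e-10)
})

test_that("3-trial RL2b likelihood matches the hand-unrolled computation", {
  s <- choice_session("t", "reward", c(1L, 2L, 2L), c(1, 0, 1))
  pars <- c(alpha = 0.5, beta = 1, gamma = 0.8, alpha_F = 0.2, alpha_C = 0.5)
  nll <- negative_log_likelihood(s, "RL2b", pars)
  # t1: p = 1/3; Q -> (0.5, 0, 0); forget leaves 0s; trace -> (0.5, 0, 0)
  # t2: logits (0.5 + 0.4, 0, 0); p(2) = 1/(e^0.9 + 2)
  #     Q2 update: 0; forget: Q1 <- 0.8*0.5 = 0.4; trace -> (0.25, 0.5, 0)
  # t3: logits (0.4 + 0.8*0.25, 0 + 0.8*0.5, 0) = (0.6, 0.4, 0)
  #     p(2) = e^0.4 / (e^0.6 + e^0.4 + 1)
  hand <- log(3) + log(exp(0.9) + 2) +
    (log(exp(0.6) + exp(0.4) + 1) - 0.4)
  expect_equal(nll, hand, tolerance = 1e-10)
})

test_that("model nesting identities hold exactly", {
  sch <- generate_schedule(n_trials = 200L, seed = 21L)
  s <- simulate_agent(sch, "reward", "RL2b",
                      c(alpha = 0.4, beta = 4, gamma = 1, alpha_F = 0.3,
                        alpha_C = 0.4), seed = 2L)
  nll1a <- negative_log_likelihood(s, "RL1a", c(alpha = 0.37, beta = 5.1))
  # RL2b with gamma = 0, alpha_F = 0 collapses to RL1a
  expect_equal(negative_log_likelihood(
    s, "RL2b", c(alpha = 0.37, beta = 5.1, gamma = 0, alpha_F = 0,
                 alpha_C = 0.77)), nll1a, tolerance = 1e-12)
  # RL3 with equal learning rates collapses to RL1a
  expect_equal(negative_log_likelihood(
    s, "RL3a", c(alpha_pos = 0.37, alpha_neg = 0.37, beta = 5.1)),
    nll1a, tolerance = 1e-12)
  # RL1b with alpha_F = 0 collapses to RL1a
  expect_equal(negative_log_likelihood(
    s, "RL1b", c(alpha = 0.37, beta = 5.1, alpha_F = 0)),
    nll1a, tolerance = 1e-12)
})

test_that("R step functions reproduce the compiled likelihood", {
  sch <- generate_schedule(n_trials = 80L, seed = 31L)
  set.seed(5)
  for (m in rl_model_ids()) {
    pn <- rl_param_names(m)
    pv <- setNames(runif(length(pn), 0.2, 0.8), pn)
    pv["beta"] <- 3
    if ("gamma" %in% pn) pv["gamma"] <- -1.2
    s <- simulate_agent(sch, "reward", m, pv, miss_rate = 0.05,
                        seed = 100 + which(rl_model_ids() == m))
    # unroll with the exported R step functions
    st <- list(Q = c(0, 0, 0), trace = c(0, 0, 0), assoc = 1)
    gam <- if ("gamma" %in% pn) pv[["gamma"]] else 0
    nll_r <- 0
    for (t in seq_len(s$n_trials)) {
      if (is.na(s$choices[t])) next
      p <- choice_probabilities(st$Q, st$trace, pv[["beta"]], gam)
      nll_r <- nll_r - log(p[s$choices[t]])
      st <- update_values(st, s$choices[t], s$outcomes[t], pv, m)
      if (m %in% c("RL2a", "RL2b"))
        st <- update_trace(st, s$choices[t], pv[["alpha_C"]])
    }
    expect_equal(negative_log_likelihood(s, m, pv), nll_r,
                 tolerance = 1e-9, label = m)
  }
})

test_that("simulate_agent respects miss_rate, seed, and the greedy limit", {
  sch <- const_schedule(c(0.7, 0.4, 0.2), 400L)
  pars <- c(alpha = 0.5, beta = 20)
  s <- simulate_agent(sch, "reward", "RL1a", pars, miss_rate = 0, seed = 6L)
  expect_false(anyNA(s$choices))
  s2 <- simulate_agent(sch, "reward", "RL1a", pars, miss_rate = 0, seed = 6L)
  expect_identical(s$choices, s2$choices)
  expect_identical(s$outcomes, s2$outcomes)
  # greedy limit: after burn-in the modal choice is the correct option
  burn <- s$choices[101:400]
  expect_identical(as.integer(names(which.max(table(burn)))), 1L)

  s3 <- simulate_agent(sch, "reward", "RL1a", pars, miss_rate = 0.3, seed = 6L)
  expect_gt(sum(is.na(s3$choices)), 0)
  expect_true(all(is.na(s3$outcomes[is.na(s3$choices)])))
})

test_that("loss sessions code outcomes natively under both learn codings", {
  sch <- generate_schedule(n_trials = 150L, seed = 41L)
  pars <- c(alpha = 0.4, beta = 4)
  raw <- simulate_agent(sch, "loss", "RL1a", pars, seed = 7L)
  suc <- simulate_agent(sch, "loss", "RL1a", pars, seed = 7L,
                        learn_coding = "success")
  expect_true(all(raw$outcomes %in% c(0, -1)))
  expect_true(all(suc$outcomes %in% c(0, -1)))
  # a success-coded learner on the loss arm behaves like a reward learner
  rew <- simulate_agent(sch, "reward", "RL1a", pars, seed = 7L)
  expect_identical(suc$choices, rew$choices)
  expect_equal(suc$outcomes, rew$outcomes - 1)
  # success-coded likelihood of the loss session equals the reward twin's
  expect_equal(
    negative_log_likelihood(suc, "RL1a", pars, loss_coding = "success"),
    negative_log_likelihood(rew, "RL1a", pars),
    tolerance = 1e-12)
})

test_that("generating parameters beat perturbed parameters on long sessions", {
  sch <- generate_schedule(n_trials = 500L, seed = 51L)
  true_p <- c(alpha = 0.35, beta = 5, gamma = -1, alpha_F = 0.2,
              alpha_C = 0.4)
  pert_p <- c(alpha = 0.8, beta = 1.5, gamma = 1.5, alpha_F = 0.6,
              alpha_C = 0.1)
  wins <- vapply(1:100, function(seed) {
    s <- simulate_agent(sch, "reward", "RL2b", true_p, seed = seed)
    negative_log_likelihood(s, "RL2b", true_p) <
      negative_log_likelihood(s, "RL2b", pert_p)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("likelihood rejects bad inputs", {
  s <- choice_session("e", "reward", rep(NA_integer_, 5), rep(NA_real_, 5))
  expect_error(negative_log_likelihood(s, "RL1a", c(alpha = 0.5, beta = 1)),
               "empty")
  s2 <- choice_session("e", "reward", c(1L, 2L), c(1, 0))
  expect_error(negative_log_likelihood(s2, "RL1a",
                                       c(alpha = NaN, beta = 1)),
               "non-finite")
  expect_error(negative_log_likelihood(s2, "RLxx", c(alpha = 0.1, beta = 1)),
               "unknown")
})
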