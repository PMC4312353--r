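test_that("predicted terminals handle absorbing starts and immediate acceptance", {
  cfg <- task_config(horizon = 4)
  tm <- transition_model(hazard_schedule(cfg, 1))
  for (k in c(2, 3, Inf)) {
    p <- predict_terminal("HIGH_OBTAINED", 2, k, tm)
    expect_equal(unname(p), c(0, 1, 0, 0))
  }
  p <- predict_terminal("LOW_PENDING", 3, 3, tm)
  expect_equal(unname(p), c(0, 0, 0, 1))
  expect_error(predict_terminal("LOW_PENDING", 3, 2, tm), "before")
})

test_that("terminal distributions equal exhaustive event-tree enumeration", {
  cfg <- task_config(horizon = 4, base_withdrawal_hazard = 0.15,
                     base_offer_prob = 0.2, offer_decay = 0.6)
  sch <- hazard_schedule(cfg, 1)
  tm <- transition_model(sch)
  for (trial in 1:4) {
    for (k in c(seq(trial, 4), Inf)) {
      expect_equal(predict_terminal("LOW_PENDING", trial, k, tm),
                   enum_terminal(sch, trial, k), tolerance = 1e-12)
    }
  }
})

test_that("policy value is a negative KL divergence with its identities", {
  cfg <- task_config(low_offer = 35, high_offer = 80)
  d <- desired_outcome(cfg, 2)
  expect_equal(policy_value(d, d), 0, tolerance = 1e-12)
  wd <- c(0, 0, 1, 0)
  expect_equal(policy_value(wd, d), log(d[["WITHDRAWN"]]), tolerance = 1e-12)
  expect_lt(policy_value(c(0.7, 0.1, 0.1, 0.1), d), 0)
  expect_error(policy_value(wd, c(0.5, 0.5, 0, 0)), "positive")
})

test_that("acceptance timing is value-irrelevant when hazards vanish", {
  sch <- toy_schedule(rep(0, 5), rep(0, 5))
  tm <- transition_model(sch)
  d <- desired_outcome(task_config(), 4)
  Q <- sapply(1:5, function(k)
    policy_value(predict_terminal("LOW_PENDING", 1, k, tm), d))
  expect_equal(max(Q) - min(Q), 0, tolerance = 1e-12)
})

test_that("policy posterior is the precision-weighted softmax with its limits", {
  Q <- c(-0.1, -0.5)
  expect_equal(policy_posterior(Q, 4),
               exp(c(-0.4, -2)) / sum(exp(c(-0.4, -2))), tolerance = 1e-12)
  expect_equal(policy_posterior(c(-1, -2, -3), 0), rep(1 / 3, 3))
  expect_equal(policy_posterior(c(-1, -0.2, -0.2), Inf), c(0, 0.5, 0.5))
})

test_that("precision belief is Gamma with Bayes-optimal rate update", {
  for (a in c(4, 8, 16)) {
    pb <- precision_update(c(0, 0, 0), rep(1 / 3, 3), a)
    expect_identical(pb$expected, a)
  }
  pb <- precision_update(c(-1, -1), c(0.5, 0.5), 8, prior_rate = 1)
  expect_equal(pb$shape, 8)
  expect_equal(pb$rate, 2)
  expect_equal(pb$expected, 4)
  worse <- precision_update(c(-2, -2), c(0.5, 0.5), 8)
  expect_lt(worse$expected, pb$expected)
})

test_that("variational fixed point matches an independent scalar root-solve", {
  cases <- list(
    list(Q = c(-0.1, -2.0), alpha = 8),
    list(Q = c(-0.5, -0.6, -0.7), alpha = 4),
    list(Q = c(0, -1, -2, -3, -4), alpha = 16),
    list(Q = c(-1.5, -1.5), alpha = 2)
  )
  for (cs in cases) {
    vs <- variational_fixed_point(cs$Q, cs$alpha, tol = 1e-12,
                                  max_iter = 4096)
    expect_true(vs$converged)
    expect_equal(vs$gamma, oracle_gamma(cs$Q, cs$alpha), tolerance = 1e-8)
    # self-consistency of both update equations at the fixed point
    expect_equal(vs$posterior, policy_posterior(cs$Q, vs$gamma),
                 tolerance = 1e-8)
    expect_lte(vs$gamma, cs$alpha + 1e-12)
  }
})

test_that("single-policy fixed point reduces to closed form without iteration", {
  vs <- variational_fixed_point(-0.7, 8, prior_rate = 2, tol = 1e-12,
                                max_iter = 1024)
  expect_equal(vs$posterior, 1)
  expect_equal(vs$gamma, 8 * 2 / (2 + 0.7), tolerance = 1e-9)
})

test_that("fixed point is invariant to permuting the policy list", {
  Q <- c(-0.2, -1.1, -0.6, -3)
  perm <- c(3, 1, 4, 2)
  a <- variational_fixed_point(Q, 8, tol = 1e-12, max_iter = 1024)
  b <- variational_fixed_point(Q[perm], 8, tol = 1e-12, max_iter = 1024)
  expect_equal(a$gamma, b$gamma, tolerance = 1e-10)
  expect_equal(a$posterior[perm], b$posterior, tolerance = 1e-10)
})

test_that("non-convergence is flagged and warned about", {
  expect_warning(
    vs <- variational_fixed_point(c(-0.1, -2), 8, max_iter = 1),
    "converge")
  expect_false(vs$converged)
})

test_that("posterior stays normalised and bounded over random instances", {
  set.seed(42)
  for (i in 1:50) {
    K <- sample(2:8, 1)
    Q <- -rexp(K)
    a <- runif(1, 0.5, 30)
    vs <- variational_fixed_point(Q, a, tol = 1e-10, max_iter = 2048)
    expect_equal(sum(vs$posterior), 1, tolerance = 1e-9)
    expect_true(all(vs$posterior >= 0))
    expect_lte(vs$gamma, a + 1e-10)
    expect_gt(vs$gamma, 0)
  }
})

test_that("accept probability is the mass of the accept-now policy", {
  cfg <- task_config(horizon = 6)
  ag <- agent_params(8, 1, 4)
  dec <- evaluate_decision(cfg, ag, trial = 4)
  expect_equal(nrow(dec$policies), 6 - 4 + 2)
  expect_equal(dec$p_accept,
               dec$policies$posterior[dec$policies$accept_at == 4])
  pols <- policy_set(3, 6)
  vs <- variational_fixed_point(rep(-1, nrow(pols)), 8)
  p <- action_probability(vs, pols, 3)
  expect_equal(unname(p["accept"]), 1 / nrow(pols), tolerance = 1e-9)
  expect_equal(sum(p), 1)
})

test_that("precision rises on the high offer and falls on withdrawal", {
  cfg <- task_config()
  drops <- sapply(c(4, 8, 16), function(a) {
    tab <- limitedoffer:::decision_tables(cfg, agent_params(a, 1, 4))
    before <- tab$gamma_dec[3]
    expect_gt(tab$gamma_abs[["HIGH_OBTAINED"]], before)
    expect_lt(tab$gamma_abs[["WITHDRAWN"]], before)
    before - tab$gamma_abs[["WITHDRAWN"]]
  })
  expect_true(all(diff(drops) > 0))
})
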