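cfg_small <- task_config(horizon = 4)

test_that("log-likelihood is additive over independent games", {
  coh <- simulate_cohort(agent_params(8, 1, 4), cfg_small, n_games = 6,
                         seed = 3)
  ag <- agent_params(6, 1.2, 3)
  ll1 <- action_loglik(ag, coh)
  doubled <- coh
  shifted <- dplyr::mutate(coh$games, game_id = game_id + max(game_id))
  doubled$games <- dplyr::bind_rows(coh$games, shifted)
  doubled$n_games <- 2L * coh$n_games
  expect_equal(action_loglik(ag, doubled), 2 * ll1, tolerance = 1e-12)
})

test_that("datasets without decision points are rejected", {
  coh <- simulate_cohort(agent_params(8, 1, 4), cfg_small, n_games = 2,
                         seed = 3)
  coh$games <- coh$games[0, ]
  expect_error(action_loglik(agent_params(8, 1, 4), coh), "decision points")
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  truth <- agent_params(8, 1, 4)
  coh <- simulate_cohort(truth, task_config(), n_games = 256, seed = 31)
  ll_true <- action_loglik(truth, coh)
  perturbed <- list(
    agent_params(2, 1, 4), agent_params(32, 1, 4),
    agent_params(8, 0.2, 4), agent_params(8, 5, 4),
    agent_params(8, 1, 1), agent_params(8, 1, 12)
  )
  for (p in perturbed) {
    expect_lt(action_loglik(p, coh), ll_true)
  }
})

test_that("MAP refinement never falls below the truth's grid cell", {
  truth <- agent_params(8, 1, 4)
  coh <- simulate_cohort(truth, cfg_small, n_games = 64, seed = 13)
  grid <- grid_spec(prior_precision = c(4, 8, 16), hazard_scale = 1,
                    sensitivity = 4)
  fit <- map_fit(coh, grid = grid)
  lpfun <- limitedoffer:::log_posterior_fn(coh, cfg_small, parameter_prior(),
                                           1e-12, limitedoffer:::engine_control())
  expect_gte(fit$log_posterior, lpfun(log(c(8, 1, 4))) - 1e-9)
  expect_gte(fit$log_posterior, fit$grid_best$log_posterior - 1e-9)
  expect_true(all(fit$estimates > 0))
  expect_equal(fit$log_likelihood,
               action_loglik(agent_params(fit$estimates[1], fit$estimates[2],
                                          fit$estimates[3]), coh),
               tolerance = 1e-9)
})

test_that("a tight prior dominates when the data are scarce", {
  coh <- simulate_cohort(agent_params(8, 1, 4), cfg_small, n_games = 1,
                         seed = 2)
  prior <- parameter_prior(
    location = c(prior_precision = log(10), hazard_scale = log(0.8),
                 sensitivity = log(3)),
    scale = c(prior_precision = 0.02, hazard_scale = 0.02,
              sensitivity = 0.02))
  grid <- grid_spec(prior_precision = 10, hazard_scale = 0.8,
                    sensitivity = 3)
  fit <- map_fit(coh, prior = prior, grid = grid)
  expect_equal(unname(fit$estimates),
               c(10, 0.8, 3), tolerance = 0.1)
})

test_that("fit accessors are tidy", {
  coh <- simulate_cohort(agent_params(8, 1, 4), cfg_small, n_games = 8,
                         seed = 4)
  fit <- map_fit(coh, grid = grid_spec(prior_precision = c(4, 16),
                                       hazard_scale = 1, sensitivity = 4))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("prior_precision", "hazard_scale", "sensitivity"))
  gl <- glance(fit)
  expect_true(is.finite(gl$log_posterior))
  expect_true(is.logical(gl$converged))
})

test_that("recovery flags the hazard scale as unidentifiable without hazards", {
  cfg0 <- task_config(horizon = 4, base_withdrawal_hazard = 0)
  rec <- recovery_study(list(agent_params(8, 1, 4)), cfg0, n_games = 4,
                        n_reps = 1, seed = 9,
                        grid = grid_spec(prior_precision = c(4, 16),
                                         hazard_scale = 1, sensitivity = 4))
  expect_true("hazard_scale" %in% rec$unidentifiable)
  expect_true(rec$summary$unidentifiable[rec$summary$term == "hazard_scale"])
  expect_error(recovery_study(list(), cfg0), "at least one")
  expect_named(tidy(rec), names(rec$fits))
})
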