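test_that("agent parameters and presets validate their inputs", {
  expect_error(agent_params(0), "prior_precision")
  expect_error(agent_params(4, -1), "hazard_scale")
  expect_error(agent_params(4, 1, -0.5), "sensitivity")
  expect_error(phenotype_preset("impulsive"), "control, addiction, ocd_like")
  ctl <- phenotype_preset("control")
  add <- phenotype_preset("addiction")
  ocd <- phenotype_preset("ocd_like")
  expect_gt(ctl$prior_precision, add$prior_precision)
  expect_lt(add$hazard_scale, 1)
  expect_gt(ocd$hazard_scale, 1)
})

test_that("a seeded game is exactly reproducible", {
  cfg <- task_config()
  ag <- phenotype_preset("control")
  g1 <- simulate_game(ag, cfg, seed = 99)
  g2 <- simulate_game(ag, cfg, seed = 99)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_identical(attr(g1, "outcome"), attr(g2, "outcome"))
  coh1 <- simulate_cohort(ag, cfg, n_games = 20, seed = 7)
  coh2 <- simulate_cohort(ag, cfg, n_games = 20, seed = 7)
  expect_identical(coh1$games, coh2$games)
})

test_that("scripted games expose the precision dynamics of each event", {
  cfg <- task_config()
  ag <- agent_params(8, 1, 4)
  wd3 <- simulate_game(ag, cfg, seed = 1,
                       actions = rep("wait", 8),
                       events = c("none", "none", "withdrawal"))
  expect_identical(attr(wd3, "outcome"), "withdrawn")
  expect_equal(nrow(wd3), 3)
  expect_equal(attr(wd3, "payoff"), 0)
  tr <- dopamine_trace(wd3)
  expect_lt(tr$delta_gamma[3], 0)

  hi5 <- simulate_game(ag, cfg, seed = 1,
                       actions = rep("wait", 8),
                       events = c(rep("none", 4), "high_offer"))
  expect_identical(attr(hi5, "outcome"), "high_offer")
  expect_equal(attr(hi5, "payoff"), cfg$high_offer)
  expect_gt(dopamine_trace(hi5)$delta_gamma[5], 0)

  # waiting through an uneventful horizon times out with zero payoff
  full <- simulate_game(ag, cfg, seed = 1, actions = rep("wait", 8),
                        events = rep("none", 8))
  expect_identical(attr(full, "outcome"), "timed_out")
  expect_equal(attr(full, "payoff"), 0)
  expect_equal(nrow(full), 8)
})

test_that("dopamine trace differences anchor at the precision prior", {
  cfg <- task_config()
  ag <- agent_params(6, 1, 4)
  g <- simulate_game(ag, cfg, seed = 2, actions = rep("wait", 8),
                     events = c("none", "none", "none", "withdrawal"))
  tr <- dopamine_trace(g)
  expect_equal(tr$delta_gamma,
               diff(c(6, g$gamma_hat)), tolerance = 1e-12)
  one <- simulate_game(ag, cfg, seed = 3, events = "withdrawal",
                       actions = "wait")
  expect_equal(nrow(dopamine_trace(one)), 0)
})

test_that("cohort outcome accounting is exact", {
  cfg <- task_config(horizon = 4)
  for (nm in c("control", "addiction", "ocd_like")) {
    coh <- simulate_cohort(phenotype_preset(nm), cfg, n_games = 64, seed = 5)
    pr <- acceptance_profile(coh)
    expect_equal(sum(pr$outcomes$n), 64)
    expect_equal(sum(pr$by_trial$accepted) + sum(pr$by_trial$high_offer) +
                 sum(pr$by_trial$withdrawn) +
                 pr$by_trial$still_waiting[cfg$horizon], 64)
    gl <- glance(coh)
    expect_equal(gl$accepted + gl$high_offer + gl$withdrawn + gl$timed_out,
                 64)
  }
})

test_that("a one-game cohort profiles exactly that game", {
  cfg <- task_config()
  ag <- phenotype_preset("ocd_like")
  coh <- simulate_cohort(ag, cfg, n_games = 1, seed = 11)
  pr <- acceptance_profile(coh)
  expect_equal(sum(pr$outcomes$n), 1)
  last <- coh$games[nrow(coh$games), ]
  if (last$action == "accept") {
    expect_equal(pr$mean_latency, last$trial)
    expect_equal(pr$latency_entropy, 0)
  }
})

test_that("empirical acceptance frequencies match engine action probabilities", {
  cfg <- task_config(horizon = 4)
  ag <- agent_params(4, 1, 4)
  n <- 1024
  coh <- simulate_cohort(ag, cfg, n_games = n, seed = 21)
  p1 <- limitedoffer:::decision_tables(cfg, ag)$p_accept[1]
  f1 <- acceptance_profile(coh)$by_trial$accepted[1] / n
  se <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(f1 - p1), 4 * se)
})

test_that("cohort CSV round trip is lossless and schema-checked", {
  cfg <- task_config(horizon = 4)
  coh <- simulate_cohort(phenotype_preset("control"), cfg, n_games = 12,
                         seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path, config = cfg)
  expect_equal(as.data.frame(back$games), as.data.frame(coh$games))
  expect_equal(back$n_games, 12)

  # CRLF dialect reads identically
  crlf <- withr::local_tempfile(fileext = ".csv")
  writeLines(readLines(path), crlf, sep = "\r\n")
  expect_equal(as.data.frame(read_cohort_csv(crlf, config = cfg)$games),
               as.data.frame(coh$games))

  # missing required column is a schema error
  broken <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(coh$games[, setdiff(names(coh$games), "p_accept")], broken)
  expect_error(read_cohort_csv(broken), "p_accept")

  # malformed categorical values are reported with their line
  bad <- coh$games
  bad$action[3] <- "shrug"
  badf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, badf)
  expect_error(read_cohort_csv(badf), "line 3")
})
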