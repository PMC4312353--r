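# Game and cohort simulation: the agent chooses under its own subjective
# model of the hazards, while events are drawn from the objective schedule.

#' Subject-level agent parameters
#'
#' Three parameters characterise an agent: `prior_precision` (alpha), the
#' prior expectation of the precision of policy beliefs -- a
#' "trait confidence" that the chosen policy will succeed; `hazard_scale`
#' (eta), multiplying the task's base withdrawal hazard to give the agent's
#' subjective schedule (1 = veridical, < 1 optimistic/risk-seeking, > 1
#' pessimistic/over-cautious); and `sensitivity` (c), scaling how strongly
#' the agent prefers high-utility outcomes in its goal prior.
#'
#' @param prior_precision Positive scalar alpha.
#' @param hazard_scale Positive scalar eta.
#' @param sensitivity Non-negative scalar c.
#' @param prior_rate Rate b0 of the Gamma prior over precision (default 1;
#'   the prior shape is `alpha * b0` so the prior mean is alpha regardless).
#' @return An object of class `lo_agent`.
#' @export
#' @examples
#' agent_params(prior_precision = 8, hazard_scale = 1, sensitivity = 2)
agent_params <- function(prior_precision, hazard_scale = 1, sensitivity = 4,
                         prior_rate = 1) {
  ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!ok(prior_precision) || prior_precision <= 0) {
    abort("`prior_precision` must be a positive finite number.")
  }
  if (!ok(hazard_scale) || hazard_scale <= 0) {
    abort("`hazard_scale` must be a positive finite number.")
  }
  if (!ok(sensitivity) || sensitivity < 0) {
    abort("`sensitivity` must be a non-negative finite number.")
  }
  if (!ok(prior_rate) || prior_rate <= 0) {
    abort("`prior_rate` must be a positive finite number.")
  }
  structure(list(prior_precision = as.numeric(prior_precision),
                 hazard_scale = as.numeric(hazard_scale),
                 sensitivity = as.numeric(sensitivity),
                 prior_rate = as.numeric(prior_rate)),
            class = "lo_agent")
}

#' @export
print.lo_agent <- function(x, ...) {
  cat(sprintf(
    "<agent: prior precision %.3g, hazard scale %.3g, sensitivity %.3g>\n",
    x$prior_precision, x$hazard_scale, x$sensitivity))
  invisible(x)
}

#' Choice-phenotype presets
#'
#' Package conventions for three qualitative phenotypes of the limited-offer
#' task. `control` has high trait confidence and a veridical hazard belief.
#' `addiction` combines low prior precision (stochastic, impulsive, less
#' goal-directed choice) with an optimistically low hazard belief
#' (risk-seeking: waiting too long and suffering withdrawals). `ocd_like`
#' keeps moderate precision but holds a pessimistically high hazard belief,
#' producing early, habitual acceptance of the safe offer. The numeric values
#' are package defaults chosen to reproduce these qualitative orderings, not
#' measured quantities.
#'
#' @param name One of `"control"`, `"addiction"`, `"ocd_like"`.
#' @return An [agent_params()] object.
#' @export
#' @examples
#' phenotype_preset("addiction")
phenotype_preset <- function(name) {
  presets <- list(
    control   = agent_params(prior_precision = 16, hazard_scale = 1,   sensitivity = 4),
    addiction = agent_params(prior_precision = 4,  hazard_scale = 0.2, sensitivity = 4),
    ocd_like  = agent_params(prior_precision = 8,  hazard_scale = 2.5, sensitivity = 4)
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets)) {
    abort(sprintf("Unknown preset; valid presets are: %s.",
                  paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

# Per-(config, agent) lookup tables: everything the engine computes is a
# function of the trial alone (state beliefs are point masses), so one pass
# over trials serves any number of simulated games.
#  - p_accept[t], gamma_dec[t]: fixed point at the trial-t decision.
#  - gamma_abs[s]: end-of-trial precision once the state is s and no real
#    choice remains (all residual policies share terminal s), in closed form
#    gamma = alpha * b0 / (b0 - log desired[s]).
decision_tables <- function(config, agent, control = engine_control()) {
  T_ <- config$horizon
  trans <- transition_model(hazard_schedule(config, agent$hazard_scale))
  desired <- desired_outcome(config, agent$sensitivity)
  dec <- lapply(seq_len(T_), function(t) {
    evaluate_decision_core(trans, desired, agent, t, control = control)
  })
  a <- agent$prior_precision * agent$prior_rate
  gamma_abs <- a / (agent$prior_rate - log(desired))
  list(
    p_accept = vapply(dec, `[[`, numeric(1), "p_accept"),
    gamma_dec = vapply(dec, `[[`, numeric(1), "gamma"),
    gamma_abs = gamma_abs,
    decisions = dec,
    schedule = hazard_schedule(config, 1)  # objective world
  )
}

# end-of-trial expected precision given what happened on trial t
end_of_trial_gamma <- function(tables, t, action, event, horizon) {
  if (action == "accept") return(unname(tables$gamma_abs["ACCEPTED_LOW"]))
  switch(event,
    withdrawal = unname(tables$gamma_abs["WITHDRAWN"]),
    high_offer = unname(tables$gamma_abs["HIGH_OBTAINED"]),
    none = if (t < horizon) tables$gamma_dec[t + 1]
           else unname(tables$gamma_abs["LOW_PENDING"])
  )
}

#' Simulate a single limited-offer game
#'
#' Plays one game: at each trial the agent evaluates its policies under its
#' subjective hazard model, samples accept/wait from the resulting action
#' probability, and -- if it waits -- the world draws a withdrawal or
#' high-offer event from the objective schedule. The recorded expected
#' precision `gamma_hat` is the end-of-trial value, re-inferred from the
#' prior after the trial's events (so a high offer produces a jump and a
#' withdrawal a drop); its trial-to-trial differences are the simulated
#' dopamine response ([dopamine_trace()]).
#'
#' @param agent An [agent_params()].
#' @param config A [task_config()].
#' @param seed Integer seed; required for reproducibility.
#' @param events Optional scripted world: character vector (length up to the
#'   horizon) from `"none"`, `"withdrawal"`, `"high_offer"` overriding the
#'   objective draw, e.g. to replay a withdrawal at trial three.
#' @param actions Optional scripted agent: character vector from `"wait"`,
#'   `"accept"` overriding the sampled action.
#' @param tables Internal precomputed decision tables (used by
#'   [simulate_cohort()]).
#' @return A tibble of class `lo_game` with one row per played trial and
#'   columns `trial`, `state` (at the decision), `p_accept`, `action`,
#'   `event`, `gamma_hat`, plus attributes `outcome` (one of `accepted`,
#'   `high_offer`, `withdrawn`, `timed_out`), `payoff` (pence), `agent`,
#'   `config`.
#' @export
#' @examples
#' g <- simulate_game(phenotype_preset("control"), task_config(), seed = 1)
#' attr(g, "outcome")
simulate_game <- function(agent, config, seed = NULL, events = NULL,
                          actions = NULL, tables = NULL) {
  stopifnot(inherits(agent, "lo_agent"), inherits(config, "lo_task"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tables)) tables <- decision_tables(config, agent)
  T_ <- config$horizon
  sched <- tables$schedule
  act_v <- ev_v <- character(T_)
  p_v <- g_v <- numeric(T_)
  outcome <- "timed_out"
  payoff <- 0
  n_rows <- 0
  for (t in seq_len(T_)) {
    p <- tables$p_accept[t]
    act <- if (!is.null(actions) && length(actions) >= t && !is.na(actions[t])) {
      match.arg(actions[t], c("wait", "accept"))
    } else if (runif(1) < p) "accept" else "wait"
    ev <- "none"
    if (act == "accept") {
      outcome <- "accepted"
      payoff <- config$low_offer
    } else {
      ev <- if (!is.null(events) && length(events) >= t && !is.na(events[t])) {
        match.arg(events[t], c("none", "withdrawal", "high_offer"))
      } else {
        u <- runif(1)
        if (u < sched$withdrawal[t]) "withdrawal"
        else if (u < sched$withdrawal[t] + sched$high_offer[t]) "high_offer"
        else "none"
      }
      if (ev == "withdrawal") outcome <- "withdrawn"
      if (ev == "high_offer") {
        outcome <- "high_offer"
        payoff <- config$high_offer
      }
    }
    n_rows <- t
    p_v[t] <- p
    act_v[t] <- act
    ev_v[t] <- ev
    g_v[t] <- end_of_trial_gamma(tables, t, act, ev, T_)
    if (act == "accept" || ev != "none") break
  }
  keep <- seq_len(n_rows)
  game <- tibble(trial = keep, state = "LOW_PENDING", p_accept = p_v[keep],
                 action = act_v[keep], event = ev_v[keep],
                 gamma_hat = g_v[keep])
  structure(game, outcome = outcome, payoff = payoff, agent = agent,
            config = config, class = c("lo_game", class(game)))
}

#' Simulate a cohort of limited-offer games
#'
#' Plays `n_games` independent games with the same agent and task. Per-game
#' seeds are derived from the master seed by a counter scheme, so a cohort is
#' exactly reproducible from `(agent, config, n_games, seed)` and games are
#' insensitive to reordering.
#'
#' @param agent An [agent_params()].
#' @param config A [task_config()].
#' @param n_games Number of games (default 256, the conventional cohort
#'   size).
#' @param seed Master integer seed.
#' @param control Engine control list.
#' @return An object of class `lo_cohort`: list with `games` (tibble; columns
#'   `game_id`, `trial`, `horizon`, `low_offer`, `high_offer`, `state`,
#'   `p_accept`, `action`, `event`, `gamma_hat`, `outcome`, `payoff`),
#'   `config`, `agent`, `n_games`, `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(phenotype_preset("control"), task_config(),
#'                        n_games = 16, seed = 42)
#' glance(coh)
simulate_cohort <- function(agent, config, n_games = 256, seed = 1,
                            control = engine_control()) {
  stopifnot(n_games >= 1)
  tables <- decision_tables(config, agent, control)
  games <- purrr::map(seq_len(n_games), function(i) {
    g <- simulate_game(agent, config, seed = game_seed(seed, i),
                       tables = tables)
    tibble(game_id = i, trial = g$trial, horizon = config$horizon,
           low_offer = config$low_offer, high_offer = config$high_offer,
           state = g$state, p_accept = g$p_accept, action = g$action,
           event = g$event, gamma_hat = g$gamma_hat,
           outcome = attr(g, "outcome"), payoff = attr(g, "payoff"))
  })
  structure(list(games = bind_rows(games), config = config, agent = agent,
                 n_games = as.integer(n_games), seed = seed),
            class = "lo_cohort")
}

# counter-based per-game seed below 2^31
game_seed <- function(master, i) {
  as.integer((as.numeric(master) + 9973 * as.numeric(i)) %% 2147483647) + 1L
}

#' @export
print.lo_cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d games, horizon %d>\n", x$n_games,
              x$config$horizon))
  print(glance(x))
  invisible(x)
}

#' Per-trial acceptance profile of a cohort
#'
#' Tabulates, per trial, how many games accepted the low offer, received the
#' high offer, had the offer withdrawn, or were still waiting afterwards, and
#' summarises acceptance latency (trial of acceptance among games that
#' accepted). Game-termination accounting is exact:
#' accepted + high-offer + withdrawn + timed-out = number of games.
#'
#' @param cohort An `lo_cohort`.
#' @return An object of class `lo_profile`: list with `by_trial` (tibble of
#'   per-trial counts and frequencies), `outcomes` (tibble of outcome
#'   totals), `mean_latency`, `latency_entropy` (Shannon entropy in nats of
#'   the acceptance-latency distribution) and `n_games`.
#' @export
acceptance_profile <- function(cohort) {
  stopifnot(inherits(cohort, "lo_cohort"))
  g <- cohort$games
  T_ <- cohort$config$horizon
  last <- g |>
    group_by(.data$game_id) |>
    filter(.data$trial == max(.data$trial)) |>
    ungroup()
  by_trial <- tibble(trial = seq_len(T_)) |>
    mutate(
      accepted = vapply(.data$trial, function(t)
        sum(last$action == "accept" & last$trial == t), numeric(1)),
      high_offer = vapply(.data$trial, function(t)
        sum(last$event == "high_offer" & last$trial == t), numeric(1)),
      withdrawn = vapply(.data$trial, function(t)
        sum(last$event == "withdrawal" & last$trial == t), numeric(1)),
      still_waiting = cohort$n_games -
        cumsum(.data$accepted + .data$high_offer + .data$withdrawn)
    )
  acc_trials <- last$trial[last$action == "accept"]
  outcomes <- tibble(
    outcome = c("accepted", "high_offer", "withdrawn", "timed_out"),
    n = c(sum(last$action == "accept"),
          sum(last$event == "high_offer"),
          sum(last$event == "withdrawal"),
          sum(last$action != "accept" & last$event == "none"))
  )
  stopifnot(sum(outcomes$n) == cohort$n_games)
  structure(list(
    by_trial = by_trial,
    outcomes = outcomes,
    mean_latency = if (length(acc_trials)) mean(acc_trials) else NA_real_,
    latency_entropy = shannon_entropy(tabulate(acc_trials, nbins = T_)),
    n_games = cohort$n_games
  ), class = "lo_profile")
}

shannon_entropy <- function(counts) {
  if (sum(counts) == 0) return(NA_real_)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' @export
print.lo_profile <- function(x, ...) {
  cat(sprintf("<acceptance profile: %d games>\n", x$n_games))
  print(x$outcomes)
  cat(sprintf("  mean acceptance latency %.3f, latency entropy %.3f nats\n",
              x$mean_latency, x$latency_entropy))
  invisible(x)
}

#' @describeIn acceptance_profile one-row cohort summary (outcome counts,
#'   mean latency, latency entropy, mean payoff).
#' @param x An `lo_cohort`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.lo_cohort <- function(x, ...) {
  pr <- acceptance_profile(x)
  payoff <- x$games |>
    group_by(.data$game_id) |>
    summarise(payoff = .data$payoff[1])
  tibble(
    n_games = x$n_games,
    accepted = pr$outcomes$n[pr$outcomes$outcome == "accepted"],
    high_offer = pr$outcomes$n[pr$outcomes$outcome == "high_offer"],
    withdrawn = pr$outcomes$n[pr$outcomes$outcome == "withdrawn"],
    timed_out = pr$outcomes$n[pr$outcomes$outcome == "timed_out"],
    mean_latency = pr$mean_latency,
    latency_entropy = pr$latency_entropy,
    mean_payoff = mean(payoff$payoff)
  )
}

#' @describeIn acceptance_profile per-trial tidy profile of a cohort.
#' @exportS3Method generics::tidy
tidy.lo_cohort <- function(x, ...) {
  acceptance_profile(x)$by_trial
}

#' Simulated dopamine response: trial-to-trial precision changes
#'
#' The simulated dopamine signal of a game is the sequence of changes in
#' end-of-trial expected precision, `delta_gamma[t] = gamma_hat[t] -
#' gamma_hat[t - 1]`, anchored at the prior, `gamma_hat[0] = alpha`. Receipt
#' of the high offer yields a positive deflection; a withdrawal yields a
#' negative one whose magnitude grows with prior precision.
#'
#' @param game An `lo_game` (at least two played trials; a single-trial game
#'   returns an empty trace).
#' @return A tibble with columns `trial` and `delta_gamma`.
#' @export
dopamine_trace <- function(game) {
  stopifnot(inherits(game, "lo_game"))
  agent <- attr(game, "agent")
  if (nrow(game) < 2) {
    return(tibble(trial = integer(), delta_gamma = numeric()))
  }
  tibble(
    trial = game$trial,
    delta_gamma = diff(c(agent$prior_precision, game$gamma_hat))
  )
}
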