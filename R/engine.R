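# Active-inference decision rule: KL policy values, precision-weighted
# softmax policy posterior, and the variational fixed point coupling them.
#
# A policy available at trial t is "wait until trial k, then accept"
# (k = t..T), or "never accept". Policies are encoded by their acceptance
# trial `accept_at`, with Inf for never-accept.

#' Policies available from a given trial
#'
#' @param trial Current trial (1-based).
#' @param horizon Game horizon T.
#' @return A tibble with columns `policy` (label) and `accept_at` (the trial
#'   at which the policy accepts; `Inf` for never accepting). From trial t
#'   there are `T - t + 2` policies.
#' @export
policy_set <- function(trial, horizon) {
  stopifnot(trial >= 1, trial <= horizon)
  accept_at <- c(seq(trial, horizon), Inf)
  tibble(
    policy = c(sprintf("accept_at_%d", seq(trial, horizon)), "never_accept"),
    accept_at = accept_at
  )
}

as_belief <- function(belief) {
  states <- lo_states()
  if (is.character(belief) && length(belief) == 1) {
    stopifnot(belief %in% states)
    b <- setNames(as.numeric(states == belief), states)
    return(b)
  }
  stopifnot(is.numeric(belief), length(belief) == 4)
  if (abs(sum(belief) - 1) > 1e-9 || any(belief < 0)) {
    abort("`belief` must be a probability vector over the four states.")
  }
  setNames(as.numeric(belief), states)
}

#' Predicted terminal-state distribution under a policy
#'
#' Chains the action-conditioned transition matrices from the current trial
#' to the end of the game: the policy waits on every trial before
#' `accept_at`, accepts on `accept_at`, and (being then in an absorbing
#' state) stays put afterwards. Waiting on the final trial still exposes the
#' offer to that trial's withdrawal/high-offer events, so a never-accept
#' policy can end with the offer still pending -- which pays nothing.
#'
#' @param belief Current belief: a state label or a probability vector over
#'   [lo_states()].
#' @param trial Trial the belief refers to.
#' @param accept_at Acceptance trial of the policy (`Inf` = never accept).
#'   Must not precede `trial`.
#' @param transitions A [transition_model()].
#' @return Named probability vector over states at the end of trial T.
#' @export
predict_terminal <- function(belief, trial, accept_at, transitions) {
  stopifnot(inherits(transitions, "lo_transitions"))
  T_ <- dim(transitions$WAIT)[3]
  if (trial < 1 || trial > T_) abort("`trial` outside the game horizon.")
  if (accept_at < trial) abort("Policy accepts before the current trial.")
  p <- as_belief(belief)
  for (j in seq(trial, T_)) {
    M <- if (j == accept_at) transitions$ACCEPT[, , j] else transitions$WAIT[, , j]
    p <- as.numeric(p %*% M)
  }
  setNames(p, lo_states())
}

#' Policy value: negative KL divergence to the desired outcome
#'
#' The value of a policy is `-KL(terminal || desired)` in nats: zero exactly
#' when the predicted terminal distribution equals the goal prior, negative
#' otherwise. The desired distribution must be strictly positive (guaranteed
#' by its softmax construction for finite sensitivity).
#'
#' @param terminal Probability vector over states (policy prediction).
#' @param desired Strictly positive probability vector (goal prior).
#' @return Non-positive scalar in nats.
#' @export
policy_value <- function(terminal, desired) {
  stopifnot(length(terminal) == length(desired))
  if (any(desired <= 0)) abort("`desired` must be strictly positive.")
  if (abs(sum(terminal) - 1) > 1e-9 || abs(sum(desired) - 1) > 1e-9) {
    abort("Both distributions must be normalised.")
  }
  pos <- terminal > 0
  -sum(terminal[pos] * (log(terminal[pos]) - log(desired[pos])))
}

#' Softmax policy posterior at a given expected precision
#'
#' Expected precision plays the role of an inverse temperature: the posterior
#' over policies is `softmax(gamma * Q)`. As `gamma -> 0` the posterior tends
#' to uniform; as `gamma -> Inf` it concentrates on the best policies (ties
#' split equally).
#'
#' @param Q Numeric vector of policy values (non-positive, finite).
#' @param expected_precision Non-negative scalar `gamma`.
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(Q, expected_precision) {
  stopifnot(is.numeric(Q), all(is.finite(Q)), expected_precision >= 0)
  if (is.infinite(expected_precision)) {
    best <- Q >= max(Q) - 1e-15
    return(as.numeric(best) / sum(best))
  }
  softmax(expected_precision * Q)
}

#' Bayes-optimal update of the Gamma belief over precision
#'
#' Precision carries a Gamma belief with prior shape `alpha * prior_rate` and
#' prior rate `prior_rate`, so the prior expectation is exactly the
#' subject-level prior precision `alpha`. Observing the policy evaluation
#' updates the rate by the posterior-expected policy cost:
#' `b = prior_rate - sum(posterior * Q)`. Because every Q is non-positive the
#' rate can only grow, so expected precision `a / b` never exceeds `alpha`,
#' with equality exactly when the expected KL cost is zero -- precision reads
#' as confidence that the selected policies will reach the goal.
#'
#' @param Q Policy values (non-positive).
#' @param posterior Probability vector over the same policies.
#' @param prior_precision Prior expected precision `alpha` (> 0).
#' @param prior_rate Prior rate `b0` of the Gamma belief (> 0, default 1).
#' @return A list of class `lo_precision` with fields `shape`, `rate` and
#'   `expected` (= shape / rate).
#' @export
precision_update <- function(Q, posterior, prior_precision, prior_rate = 1) {
  stopifnot(prior_precision > 0, prior_rate > 0,
            length(Q) == length(posterior))
  shape <- prior_precision * prior_rate
  rate <- prior_rate - sum(posterior * Q)
  structure(list(shape = shape, rate = rate, expected = shape / rate),
            class = "lo_precision")
}

#' Variational fixed point of policy posterior and precision
#'
#' The policy posterior depends on expected precision, and the precision
#' update depends on the posterior-expected policy value, so the two are
#' iterated to self-consistency: starting from `gamma = alpha`, alternate
#' [policy_posterior()] and [precision_update()], damping the precision step
#' (`gamma <- (1 - damping) * gamma + damping * gamma_new`) until both the
#' precision and the posterior move less than `tol`. At the fixed point the
#' pair satisfies both update equations simultaneously.
#'
#' @param Q Policy values (non-positive, finite).
#' @param prior_precision Prior expected precision `alpha`.
#' @param prior_rate Gamma prior rate `b0` (default 1).
#' @param tol Convergence tolerance on successive iterates (default 1e-6).
#' @param max_iter Iteration cap (default 64); non-convergence returns the
#'   best iterate with a warning and `converged = FALSE`.
#' @param damping Step damping in (0, 1] for the precision update
#'   (default 0.5).
#' @return An object of class `lo_variational`: list with `posterior`
#'   (probability vector over policies), `precision` (an `lo_precision`),
#'   `gamma` (expected precision), `iterations` and `converged`.
#' @export
variational_fixed_point <- function(Q, prior_precision, prior_rate = 1,
                                    tol = 1e-6, max_iter = 64,
                                    damping = 0.5) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  gamma <- prior_precision
  post <- policy_posterior(Q, gamma)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    prec <- precision_update(Q, post, prior_precision, prior_rate)
    gamma_new <- (1 - damping) * gamma + damping * prec$expected
    post_new <- policy_posterior(Q, gamma_new)
    delta <- max(abs(gamma_new - gamma), max(abs(post_new - post)))
    gamma <- gamma_new
    post <- post_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("Variational iteration did not converge; returning best iterate.")
  }
  prec <- precision_update(Q, post, prior_precision, prior_rate)
  structure(list(posterior = post, precision = prec, gamma = prec$expected,
                 iterations = it, converged = converged),
            class = "lo_variational")
}

#' Probability of accepting now implied by a variational state
#'
#' The accept probability at the current trial is the posterior mass of the
#' policy that accepts immediately; all other policies wait at this trial.
#'
#' @param vs An `lo_variational` state whose posterior is aligned with a
#'   policy set.
#' @param policies The [policy_set()] the posterior refers to.
#' @param trial The current trial.
#' @return Named numeric vector `c(accept = ..., wait = ...)` summing to 1.
#' @export
action_probability <- function(vs, policies, trial) {
  stopifnot(inherits(vs, "lo_variational"),
            length(vs$posterior) == nrow(policies))
  p_accept <- sum(vs$posterior[policies$accept_at == trial])
  c(accept = p_accept, wait = 1 - p_accept)
}

engine_control <- function(tol = 1e-6, max_iter = 64, damping = 0.5) {
  list(tol = tol, max_iter = max_iter, damping = damping)
}

# Lean per-trial accept probabilities for likelihood evaluation: same
# computation as evaluate_decision() at every trial, skipping the policy
# tibble (the accept-now policy is always the first entry of the set).
p_accept_table <- function(config, agent, control = engine_control()) {
  trans <- transition_model(hazard_schedule(config, agent$hazard_scale))
  desired <- desired_outcome(config, agent$sensitivity)
  b <- as_belief("LOW_PENDING")
  vapply(seq_len(config$horizon), function(t) {
    Q <- policy_values_from(b, t, trans, desired)
    vs <- variational_fixed_point(Q, agent$prior_precision, agent$prior_rate,
                                  tol = control$tol,
                                  max_iter = control$max_iter,
                                  damping = control$damping)
    vs$posterior[1]
  }, numeric(1))
}

# Policy values via one incremental wait-chain pass: the belief after waiting
# through trials t..k-1 determines the terminal of accept-at-k directly
# (accepting absorbs), and the full wait chain is the never-accept terminal.
# Equivalent to predict_terminal() policy by policy, at O(T) matrix products.
policy_values_from <- function(belief, trial, trans, desired) {
  T_ <- dim(trans$WAIT)[3]
  accept_at <- c(seq(trial, T_), Inf)
  Q <- numeric(length(accept_at))
  cur <- belief
  for (i in seq_along(accept_at)) {
    k <- accept_at[i]
    if (is.finite(k)) {
      Q[i] <- policy_value(as.numeric(cur %*% trans$ACCEPT[, , k]), desired)
      cur <- as.numeric(cur %*% trans$WAIT[, , k])
    } else {
      Q[i] <- policy_value(cur, desired)
    }
  }
  Q
}

#' Evaluate one decision point of the limited-offer game
#'
#' Runs the full active-inference step an agent performs at a decision point:
#' build the agent's subjective hazard schedule (its `hazard_scale` times the
#' task's base withdrawal hazard), predict the terminal distribution of every
#' available policy, score each by its KL divergence from the desired
#' outcome, and solve the coupled posterior/precision fixed point.
#'
#' @param config A [task_config()].
#' @param agent An [agent_params()].
#' @param trial Current trial (1-based).
#' @param state Current state label (default `"LOW_PENDING"`; from absorbing
#'   states all policies predict the same terminal distribution).
#' @param control Engine control list: `tol`, `max_iter`, `damping`.
#' @return An object of class `lo_decision`: list with `policies` (tibble of
#'   `policy`, `accept_at`, `Q`, `posterior`), `gamma` (expected precision at
#'   the fixed point), `p_accept`, `trial`, `state`, `converged`,
#'   `iterations`.
#' @export
#' @examples
#' d <- evaluate_decision(task_config(), phenotype_preset("control"), trial = 1)
#' d$p_accept
evaluate_decision <- function(config, agent, trial, state = "LOW_PENDING",
                              control = engine_control()) {
  stopifnot(inherits(config, "lo_task"), inherits(agent, "lo_agent"))
  sched <- hazard_schedule(config, hazard_scale = agent$hazard_scale)
  trans <- transition_model(sched)
  desired <- desired_outcome(config, agent$sensitivity)
  evaluate_decision_core(trans, desired, agent, trial, state, control)
}

evaluate_decision_core <- function(trans, desired, agent, trial,
                                   state = "LOW_PENDING",
                                   control = engine_control()) {
  T_ <- dim(trans$WAIT)[3]
  pols <- policy_set(trial, T_)
  Q <- policy_values_from(as_belief(state), trial, trans, desired)
  vs <- variational_fixed_point(Q, agent$prior_precision, agent$prior_rate,
                                tol = control$tol, max_iter = control$max_iter,
                                damping = control$damping)
  p <- action_probability(vs, pols, trial)
  structure(
    list(policies = mutate(pols, Q = Q, posterior = vs$posterior),
         gamma = vs$gamma, p_accept = unname(p["accept"]),
         trial = trial, state = state,
         converged = vs$converged, iterations = vs$iterations),
    class = "lo_decision"
  )
}

#' @export
print.lo_decision <- function(x, ...) {
  cat(sprintf("<decision point: trial %d, state %s>\n", x$trial, x$state))
  cat(sprintf("  expected precision %.4f, P(accept) = %.4f\n",
              x$gamma, x$p_accept))
  print(x$policies)
  invisible(x)
}
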