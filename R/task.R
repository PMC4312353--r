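# Task model for the limited-offer game.
#
# State indexing is fixed package-wide as
#   (LOW_PENDING, HIGH_OBTAINED, WITHDRAWN, ACCEPTED_LOW);
# LOW_PENDING is the only non-absorbing state. Trials are 1-based.

#' State labels of the limited-offer game
#'
#' The game has four states: `LOW_PENDING` (the small offer is still on the
#' table), `HIGH_OBTAINED` (the large offer arrived while waiting),
#' `WITHDRAWN` (the small offer was withdrawn while waiting) and
#' `ACCEPTED_LOW` (the agent accepted the small offer). All states except
#' `LOW_PENDING` are absorbing. This ordering is used by every probability
#' vector and transition matrix in the package.
#'
#' @return Character vector of the four state labels, in canonical order.
#' @export
#' @examples
#' lo_states()
lo_states <- function() {
  c("LOW_PENDING", "HIGH_OBTAINED", "WITHDRAWN", "ACCEPTED_LOW")
}

lo_absorbing <- function() {
  c(LOW_PENDING = FALSE, HIGH_OBTAINED = TRUE, WITHDRAWN = TRUE,
    ACCEPTED_LOW = TRUE)
}

#' Configure a limited-offer game
#'
#' A game lasts `horizon` trials. On each trial the agent either accepts the
#' standing low offer or waits; while waiting, the offer may be withdrawn
#' (probability `r_t`) or replaced by the high offer (probability `q_t`),
#' otherwise it carries over with probability `1 - r_t - q_t`. The two event
#' probabilities follow hazard schedules: withdrawal grows over trials as the
#' cumulative geometric hazard `1 - (1 - base_withdrawal_hazard)^t`, while the
#' high-offer probability decays geometrically,
#' `base_offer_prob * offer_decay^(t - 1)`. A game that ends with the low
#' offer still pending (never accepted, never withdrawn) pays nothing.
#'
#' @param horizon Number of trials in a game (integer, at least 2). The task
#'   uses short (4) and long (8) games.
#' @param low_offer Low-offer magnitude in pence, between 9 and 35 in the
#'   task; must be strictly below `high_offer`.
#' @param high_offer High-offer magnitude in pence (80 in the task).
#' @param base_withdrawal_hazard Per-trial conditional withdrawal probability
#'   in (0, 1) (may be 0 only for degenerate no-risk variants).
#' @param base_offer_prob Trial-1 probability of the high offer arriving,
#'   in (0, 1).
#' @param offer_decay Multiplicative per-trial decay of the high-offer
#'   probability, in (0, 1].
#' @return An object of class `lo_task`: a named list with the six fields
#'   above, validated.
#' @seealso [hazard_schedule()], [transition_model()], [desired_outcome()]
#' @export
#' @examples
#' task_config(horizon = 4, low_offer = 20)
task_config <- function(horizon = 8,
                        low_offer = 30,
                        high_offer = 80,
                        base_withdrawal_hazard = 0.12,
                        base_offer_prob = 0.05,
                        offer_decay = 0.7) {
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 2 ||
      horizon != round(horizon)) {
    abort("`horizon` must be a single integer >= 2.")
  }
  if (!is.numeric(low_offer) || !is.numeric(high_offer) ||
      low_offer <= 0 || low_offer >= high_offer) {
    abort("Offers must satisfy 0 < low_offer < high_offer.")
  }
  if (base_withdrawal_hazard < 0 || base_withdrawal_hazard >= 1) {
    abort("`base_withdrawal_hazard` must lie in [0, 1).")
  }
  if (base_offer_prob <= 0 || base_offer_prob >= 1) {
    abort("`base_offer_prob` must lie in (0, 1).")
  }
  if (offer_decay <= 0 || offer_decay > 1) {
    abort("`offer_decay` must lie in (0, 1].")
  }
  structure(
    list(horizon = as.integer(horizon),
         low_offer = as.numeric(low_offer),
         high_offer = as.numeric(high_offer),
         base_withdrawal_hazard = as.numeric(base_withdrawal_hazard),
         base_offer_prob = as.numeric(base_offer_prob),
         offer_decay = as.numeric(offer_decay)),
    class = "lo_task"
  )
}

#' @export
print.lo_task <- function(x, ...) {
  cat("<limited-offer task>\n")
  cat(sprintf("  horizon: %d trials; offers: %g / %g pence\n",
              x$horizon, x$low_offer, x$high_offer))
  cat(sprintf("  base withdrawal hazard %g, offer prob %g (decay %g)\n",
              x$base_withdrawal_hazard, x$base_offer_prob, x$offer_decay))
  invisible(x)
}

#' Hazard schedule of withdrawal and high-offer probabilities
#'
#' Builds the per-trial event probabilities `r_t` (withdrawal) and `q_t`
#' (high-offer arrival) implied by a task configuration. `hazard_scale`
#' rescales the per-trial withdrawal hazard and is how an agent's subjective
#' beliefs enter: `hazard_scale = 1` gives the objective schedule the world
#' runs on, values above 1 a pessimistic belief (withdrawal thought likely),
#' values below 1 an optimistic one. The withdrawal probability is clipped so
#' that `r_t + q_t <= 1` always holds:
#' `r_t = min(1 - q_t, 1 - (1 - hazard_scale * base_withdrawal_hazard)^t)`
#' with the scaled per-trial hazard itself clipped into \[0, 1\].
#'
#' @param config An [task_config()] object.
#' @param hazard_scale Positive scalar multiplying the per-trial withdrawal
#'   hazard.
#' @return A tibble with columns `trial`, `withdrawal` (`r_t`) and
#'   `high_offer` (`q_t`), one row per trial. `withdrawal` is non-decreasing,
#'   `high_offer` non-increasing, and their sum never exceeds 1.
#' @export
#' @examples
#' hazard_schedule(task_config(horizon = 4, base_withdrawal_hazard = 0.1))
hazard_schedule <- function(config, hazard_scale = 1) {
  stopifnot(inherits(config, "lo_task"))
  if (!is.numeric(hazard_scale) || length(hazard_scale) != 1 ||
      !is.finite(hazard_scale) || hazard_scale <= 0) {
    abort("`hazard_scale` must be a single positive number.")
  }
  t <- seq_len(config$horizon)
  h <- min(max(hazard_scale * config$base_withdrawal_hazard, 0), 1)
  q <- config$base_offer_prob * config$offer_decay^(t - 1)
  r <- pmin(1 - q, 1 - (1 - h)^t)
  tibble(trial = t, withdrawal = r, high_offer = q)
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("trial", "withdrawal", "high_offer") %in% names(schedule)))
  r <- schedule$withdrawal
  q <- schedule$high_offer
  if (any(r < 0 | r > 1) || any(q < 0 | q > 1)) {
    abort("Schedule probabilities must lie in [0, 1].")
  }
  if (any(r + q > 1 + 1e-12)) {
    abort("Schedule violates r_t + q_t <= 1.")
  }
  if (is.unsorted(r) || is.unsorted(rev(q))) {
    abort("Schedule must have non-decreasing withdrawal and non-increasing high-offer probabilities.")
  }
  invisible(schedule)
}

#' Action-conditioned transition matrices
#'
#' For each trial and each action (`WAIT`, `ACCEPT`) returns the 4x4
#' row-stochastic matrix over the canonical state order ([lo_states()]).
#' Waiting in `LOW_PENDING` at trial t leads to `WITHDRAWN` with probability
#' `r_t`, `HIGH_OBTAINED` with probability `q_t` and stays in `LOW_PENDING`
#' otherwise; accepting moves deterministically to `ACCEPTED_LOW`. Absorbing
#' states map to themselves under both actions.
#'
#' @param schedule A hazard schedule as returned by [hazard_schedule()].
#' @return An object of class `lo_transitions`: a list with elements `WAIT`
#'   and `ACCEPT`, each a `4 x 4 x horizon` array whose `[, , t]` slice is the
#'   trial-t transition matrix, plus the schedule as an attribute.
#' @export
transition_model <- function(schedule) {
  validate_schedule(schedule)
  states <- lo_states()
  T_ <- nrow(schedule)
  wait <- array(0, dim = c(4, 4, T_), dimnames = list(states, states, NULL))
  accept <- wait
  for (t in seq_len(T_)) {
    m <- diag(4)
    dimnames(m) <- list(states, states)
    r <- schedule$withdrawal[t]
    q <- schedule$high_offer[t]
    m["LOW_PENDING", ] <- c(1 - r - q, q, r, 0)
    wait[, , t] <- m
    a <- diag(4)
    dimnames(a) <- list(states, states)
    a["LOW_PENDING", ] <- c(0, 0, 0, 1)
    accept[, , t] <- a
  }
  structure(list(WAIT = wait, ACCEPT = accept),
            schedule = schedule, class = "lo_transitions")
}

#' Desired-outcome (goal) distribution over terminal states
#'
#' Encodes how much the agent values each way the game can end. Outcome
#' utilities are the payoffs in pence -- 0 for a pending or withdrawn offer,
#' `low_offer` for accepting the small offer, `high_offer` for obtaining the
#' large one -- normalised by `high_offer` so the sensitivity parameter is
#' dimensionless. The goal prior is the softmax
#' `p(s) = exp(sensitivity * u(s) / high_offer) / Z`: with `sensitivity = 0`
#' every outcome is equally acceptable; as it grows, the goal mass
#' concentrates on obtaining the high offer. Because the softmax keeps every
#' entry strictly positive, Kullback-Leibler policy values are always finite.
#'
#' @param config An [task_config()] object.
#' @param sensitivity Non-negative scalar `c` scaling the utility differences.
#' @return Named numeric probability vector over [lo_states()], summing to 1.
#' @export
#' @examples
#' desired_outcome(task_config(), sensitivity = 2)
desired_outcome <- function(config, sensitivity) {
  stopifnot(inherits(config, "lo_task"))
  if (!is.numeric(sensitivity) || length(sensitivity) != 1 ||
      !is.finite(sensitivity) || sensitivity < 0) {
    abort("`sensitivity` must be a single non-negative number.")
  }
  u <- c(LOW_PENDING = 0, HIGH_OBTAINED = config$high_offer,
         WITHDRAWN = 0, ACCEPTED_LOW = config$low_offer)
  softmax(sensitivity * u / config$high_offer)
}

# numerically safe softmax
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
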