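# Independent oracles used to pin down engine behaviour.

oracle_states <- c("LOW_PENDING", "HIGH_OBTAINED", "WITHDRAWN", "ACCEPTED_LOW")

# Terminal-state distribution of a wait-until-k-then-accept policy by
# exhaustive recursion over the event tree (no matrix algebra involved).
enum_terminal <- function(schedule, trial, accept_at,
                          state = "LOW_PENDING") {
  T_ <- nrow(schedule)
  rec <- function(s, j) {
    out <- stats::setNames(numeric(4), oracle_states)
    if (j > T_ || s != "LOW_PENDING") {
      out[s] <- 1
      return(out)
    }
    if (j == accept_at) {
      out["ACCEPTED_LOW"] <- 1
      return(out)
    }
    r <- schedule$withdrawal[j]
    q <- schedule$high_offer[j]
    r * rec("WITHDRAWN", j + 1) + q * rec("HIGH_OBTAINED", j + 1) +
      (1 - r - q) * rec("LOW_PENDING", j + 1)
  }
  rec(state, trial)
}

oracle_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

oracle_kl_value <- function(terminal, desired) {
  pos <- terminal > 0
  -sum(terminal[pos] * (log(terminal[pos]) - log(desired[pos])))
}

# Self-consistent expected precision by scalar root-solving of
# gamma = alpha * b0 / (b0 - softmax(gamma * Q) . Q), independent of the
# package's alternating update scheme.
oracle_gamma <- function(Q, alpha, b0 = 1) {
  g <- function(gam) {
    gam - alpha * b0 / (b0 - sum(oracle_softmax(gam * Q) * Q))
  }
  stats::uniroot(g, c(1e-9, alpha + 1), tol = 1e-13)$root
}

# small helper: deterministic test schedule as a plain tibble
toy_schedule <- function(withdrawal, high_offer) {
  tibble::tibble(trial = seq_along(withdrawal), withdrawal = withdrawal,
                 high_offer = high_offer)
}
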