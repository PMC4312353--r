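---
title: "The limited-offer task as active inference: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The limited-offer task as active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limitedoffer)
```

## The generative model of the game

A game of the limited-offer task is a finite-horizon Markov decision problem
over four states, indexed package-wide as `LOW_PENDING`, `HIGH_OBTAINED`,
`WITHDRAWN`, `ACCEPTED_LOW`; only `LOW_PENDING` is non-absorbing and trials
are 1-based. At trial $t$ the agent in `LOW_PENDING` chooses `ACCEPT`
(deterministic move to `ACCEPTED_LOW`) or `WAIT`, in which case the world
draws withdrawal with probability $r_t$, the high offer with probability
$q_t$, or carry-over with probability $1 - r_t - q_t$.

The task description fixes the qualitative shape of the event schedules —
withdrawal becomes more likely and the high offer less likely the longer one
waits — but not their numerical form. We adopt the minimal parameterisation
with those monotonicities:

$$r_t = \min\!\big(1 - q_t,\; 1 - (1 - \eta h)^t\big), \qquad
  q_t = q_1\,\delta^{t-1},$$

a cumulative geometric withdrawal hazard with per-trial rate $h$
(`base_withdrawal_hazard`) and a geometrically decaying high-offer
probability (`base_offer_prob`, `offer_decay`). The single scale factor
$\eta$ is the lever by which *subjective* beliefs enter: the world always
runs at $\eta = 1$, while the agent evaluates its policies under its own
$\eta$-scaled schedule. The clipping through $\min$ (and of $\eta h$ into
$[0,1]$) guarantees $r_t + q_t \le 1$ by construction for every $\eta > 0$.

A game that ends with the offer still pending pays nothing, so utilities
over terminal states are $u = (0, 80, 0, \text{low})$ pence. The
goal ("desired outcome") prior is their softmax,
$P^*(s) \propto \exp(c\,u(s)/u_{\max})$, normalised by the high offer so the
sensitivity $c$ is dimensionless. For $c = 0$ every ending is equally
acceptable; for large $c$ the goal concentrates on winning the high offer.
Because the softmax is strictly positive, every KL divergence below is
finite.

## Policy evaluation and precision

From trial $t$ the agent entertains $T - t + 2$ policies: *accept at
$k$* for $k = t, \dots, T$, and *never accept*. Chaining the
action-conditioned transition matrices gives each policy's predicted
terminal distribution $P_\pi$, and its value is

$$Q(\pi) = -\,\mathrm{KL}\big(P_\pi \,\|\, P^*\big) \le 0,$$

zero exactly when a policy reaches the goal distribution. Policy selection
is a precision-weighted softmax, $P(\pi) \propto \exp(\hat\gamma\,Q(\pi))$,
but $\hat\gamma$ is itself inferred. It carries a Gamma belief with prior
shape $\alpha b_0$ and rate $b_0$ (so the prior expectation is exactly the
subject-level prior precision $\alpha$), and the Bayes-optimal rate update

$$b = b_0 - \textstyle\sum_\pi P(\pi) Q(\pi), \qquad
  \hat\gamma = \alpha b_0 / b$$

is alternated with the policy softmax to a self-consistent fixed point at
every decision. Since every $Q \le 0$, the rate can only grow:
$\hat\gamma \le \alpha$ always, with equality exactly when the expected KL
cost is zero. Precision therefore reads as confidence that the selected
policies will reach the goal — good prospects keep choice sharp, poor
prospects flatten it toward habit.

The update equations are not uniquely pinned down by the task description;
this Gamma parameterisation with fixed $b_0 = 1$ was chosen as the smallest
scheme that yields all the qualitative precision properties the model is
meant to show: $\alpha$ as the prior expectation, a drop on withdrawal whose
size grows with $\alpha$, and a jump on receipt of the high offer. The
recorded per-trial `gamma_hat` is the *end-of-trial* value, re-inferred from
the prior after the trial's events; its first differences (anchored at
$\hat\gamma_0 = \alpha$) are the simulated dopamine trace. Whether precision
should instead carry over between trials as a running posterior is left
open by the task description; re-inference from the prior at each trial is
the package's convention, matching the end-of-each-trial framing of the
precision trajectories it reports.

### Numerical choices

The fixed point is solved by damped alternation ($\hat\gamma \leftarrow
(1-d)\hat\gamma + d\,\alpha b_0/b$ with $d = 0.5$), tolerance $10^{-6}$ on
both the precision and the posterior, and at most 64 iterations;
non-convergence is flagged and warned about but has not been observed on
any tested instance. The tests pin the fixed point against an independent
scalar root-solve of $\gamma = \alpha b_0 / (b_0 - \mathrm{softmax}(\gamma
Q)\cdot Q)$ to $10^{-8}$. At $\hat\gamma \to \infty$ ties in $Q$ are split
equally. Likelihood probabilities are floored at $10^{-12}$ before logs.
State inference itself is exact point-mass tracking — the task is fully
observed — but the belief-vector interface is retained so partial
observability would be an extension, not a rewrite.

Two consequences of the KL-to-goal objective are worth knowing. First,
mixed (risky) terminal distributions enjoy an entropy advantage over the
point mass produced by accepting immediately, so accepting is never
attractive out of proportion to the hazards; this is a property of KL
control, not a bug. Second, sensitivity $c = 0$ makes the *goal* uniform
but not the *policy posterior*: higher-entropy terminal distributions are
then closer to the uniform goal, so an indifferent agent still weakly
prefers gambling. Relatedly, when withdrawal is believed near-certain, even
a moderate-$\alpha$ agent accepts only stochastically — all prospects being
poor, inferred precision collapses and behaviour de-concentrates — while a
high-$\alpha$ agent accepts at once.

## What the simulator emulates

`simulate_cohort()` plays independent games in which the agent samples
accept/wait from its fixed-point action probability and the world draws
events from the objective ($\eta = 1$) schedule; per-game seeds derive from
the master seed by a counter scheme. Games ending with the offer pending
are recorded as `timed_out` with payoff 0. The default study conditions are
an 8-trial game, offers of 30 vs 80 pence, $h = 0.12$, $q_1 = 0.05$,
$\delta = 0.7$, sensitivity $c = 4$, and cohorts of 256 games. The task
description fixes the offer magnitudes, horizons and cohort size; the
hazard constants and $c$ are package conventions, chosen once so that a
veridical agent faces a real accept-or-gamble tension (mid-game acceptance
optimal, waiting genuinely risky) and the documented qualitative orderings
are expressed. They are exposed in `task_config()` and the YAML config, not
hard-wired.

Phenotype presets are likewise conventions, not measured values:
`control` $(\alpha, \eta, c) = (16, 1, 4)$,
`addiction` $(4, 0.2, 4)$ — low trait confidence plus optimism about
withdrawal, yielding more stochastic latencies and more suffered
withdrawals — and `ocd_like` $(8, 2.5, 4)$ — pessimism about withdrawal,
yielding early, habitual acceptance.

The generator emulates the *structure* of the task, not everything about
real sessions: no reaction times, no learning or fatigue across games, no
within-game hazard learning, and one low plus one high offer only. Passing
tests therefore show that the implementation realises this model faithfully
and that the model separates these phenotypes at realistic cohort sizes —
not that real patient groups will separate equally well.

## Model inversion

`map_fit()` maximises the log-posterior of $(\alpha, \eta, c)$: the sum of
$\log P(\text{observed action}\mid t)$ over decision points (only trials
spent in `LOW_PENDING` contribute — no choice exists after absorption) plus
independent Gaussian priors on the log-parameters, located at the control
preset $(\log 16, 0, \log 4)$ with unit scales. Because the accept
probability depends only on the trial index, per-trial accept/wait counts
are sufficient statistics and the likelihood is cheap. A $5^3$ log-spaced
grid locates the basin and Nelder–Mead refines it on the log scale, so the
refined optimum can never fall below the best grid cell; optimiser failure
falls back to the grid best with `converged = FALSE`. The task description
names the three fitted parameters but not their parameterisation; reading
the fitted "hazard rate" as the multiplicative withdrawal-hazard scale
$\eta$ is the package's convention. With a zero objective withdrawal hazard
$\eta$ has no behavioural consequence, and `recovery_study()` flags it as
unidentifiable rather than reporting a meaningless estimate.

`recovery_study()` wraps the simulate-then-fit loop and reports
per-parameter bias, RMSE and Spearman correlation. At the conventional 256
games per cohort, prior-precision levels $\{4, 8, 16\}$ are recovered in
the correct rank order in essentially every replicate (the acceptance test
requires at least 9 of 10 and Spearman $\rho \ge 0.8$).

## Problem sizes and limitations

The shipped tests and the acceptance script use cohorts of 256 games (the
task's conventional cohort size), five master seeds for the ordering
checks, and 10 replicates per precision level for recovery — sizes at which
every documented ordering has been stable in practice while a full run
stays in the low minutes on a single core.

Known limitations: policy values score terminal states only (no per-trial
cost accumulation and no epistemic information-gain term); precision is
re-inferred each trial rather than propagated; the hazard schedules are a
two-family parameterisation, not estimates of any empirical schedule; and
the phenotype presets are illustrative conventions whose numeric values
should not be read as clinical claims.
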