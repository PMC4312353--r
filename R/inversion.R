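# Model inversion: MAP estimation of (prior precision, hazard scale,
# sensitivity) from trial-by-trial choices, and parameter-recovery studies.

#' Gaussian prior on log-parameters for MAP inversion
#'
#' Weakly informative Gaussians on the logarithms of the three subject-level
#' parameters. Default locations sit at the control phenotype
#' (`log(16), log(1), log(4)`) with unit scales, which keeps all three
#' parameters positive and regularises flat likelihoods towards the control
#' preset without overwhelming 256 games of choices.
#'
#' @param location Named numeric vector of prior means for
#'   `log(prior_precision)`, `log(hazard_scale)`, `log(sensitivity)`.
#' @param scale Named numeric vector of prior standard deviations (> 0).
#' @return An object of class `lo_prior`: tibble with columns `term`,
#'   `location`, `scale`.
#' @export
parameter_prior <- function(location = c(prior_precision = log(16),
                                         hazard_scale = 0,
                                         sensitivity = log(4)),
                            scale = c(prior_precision = 1,
                                      hazard_scale = 1,
                                      sensitivity = 1)) {
  terms <- c("prior_precision", "hazard_scale", "sensitivity")
  stopifnot(all(terms %in% names(location)), all(terms %in% names(scale)))
  if (any(scale[terms] <= 0)) abort("Prior scales must be positive.")
  structure(tibble(term = terms,
                   location = unname(location[terms]),
                   scale = unname(scale[terms])),
            class = c("lo_prior", "tbl_df", "tbl", "data.frame"))
}

# per-trial (accept, wait) counts at decision points; the engine's accept
# probability depends on the trial alone, so these are sufficient statistics
decision_counts <- function(games, horizon) {
  rows <- games[games$state == "LOW_PENDING", , drop = FALSE]
  if (nrow(rows) == 0) abort("Dataset contains no decision points.")
  t <- seq_len(horizon)
  list(
    accept = vapply(t, function(k)
      sum(rows$trial == k & rows$action == "accept"), numeric(1)),
    wait = vapply(t, function(k)
      sum(rows$trial == k & rows$action == "wait"), numeric(1))
  )
}

#' Log-likelihood of observed choices under agent parameters
#'
#' Sums `log P(observed action | trial, params)` over every decision point
#' (trials on which the actor still held the pending low offer; after
#' absorption no choice exists). The accept probability comes from the
#' engine's variational fixed point under the candidate agent's subjective
#' hazard model. Probabilities are floored at `floor` before taking logs so
#' the result is always finite.
#'
#' @param agent An [agent_params()] (the candidate parameters).
#' @param cohort An `lo_cohort` (simulated or read from CSV with a task
#'   config attached).
#' @param config Task configuration; defaults to the cohort's.
#' @param floor Probability floor (default 1e-12).
#' @param control Engine control list.
#' @return A finite scalar log-likelihood.
#' @export
action_loglik <- function(agent, cohort, config = cohort$config,
                          floor = 1e-12, control = engine_control()) {
  stopifnot(inherits(agent, "lo_agent"), inherits(cohort, "lo_cohort"))
  if (is.null(config)) {
    abort("A task config is required (cohorts read from CSV need `config`).")
  }
  counts <- decision_counts(cohort$games, config$horizon)
  p <- p_accept_table(config, agent, control)
  sum(counts$accept * log(pmax(p, floor)) +
      counts$wait * log(pmax(1 - p, floor)))
}

#' Log-spaced grid for the MAP search
#'
#' @param prior_precision,hazard_scale,sensitivity Numeric vectors of grid
#'   values for each parameter (positive).
#' @return A named list of grid values.
#' @export
grid_spec <- function(prior_precision = exp(seq(log(2), log(32), length.out = 5)),
                      hazard_scale = exp(seq(log(0.25), log(4), length.out = 5)),
                      sensitivity = exp(seq(log(0.5), log(8), length.out = 5))) {
  stopifnot(all(prior_precision > 0), all(hazard_scale > 0),
            all(sensitivity > 0))
  list(prior_precision = prior_precision, hazard_scale = hazard_scale,
       sensitivity = sensitivity)
}

log_posterior_fn <- function(cohort, config, prior, floor, control) {
  counts <- decision_counts(cohort$games, config$horizon)
  function(theta_log) {
    agent <- agent_params(exp(theta_log[1]), exp(theta_log[2]),
                          exp(theta_log[3]))
    p <- p_accept_table(config, agent, control)
    ll <- sum(counts$accept * log(pmax(p, floor)) +
              counts$wait * log(pmax(1 - p, floor)))
    lp <- sum(dnorm(theta_log, mean = prior$location, sd = prior$scale,
                    log = TRUE))
    ll + lp
  }
}

#' Maximum a posteriori inversion of the choice model
#'
#' Estimates `(prior_precision, hazard_scale, sensitivity)` from a cohort of
#' choices by maximising the log-posterior (action log-likelihood plus
#' Gaussian prior on the log-parameters). A coarse log-spaced grid search
#' locates the basin; derivative-free Nelder-Mead refinement on the
#' log-parameter scale polishes it. Deterministic given the data, prior and
#' grid.
#'
#' @param cohort An `lo_cohort` with at least one game.
#' @param prior An [parameter_prior()].
#' @param grid A [grid_spec()].
#' @param config Task configuration (defaults to the cohort's).
#' @param floor Probability floor for the likelihood.
#' @param control Engine control list.
#' @return An object of class `lo_fit`: list with `estimates` (named vector
#'   of the three MAP estimates on the natural scale), `log_posterior`,
#'   `log_likelihood`, `grid_best` (best grid point and its log-posterior),
#'   `iterations`, `converged`, `prior`, `config`.
#' @export
#' @examples
#' \donttest{
#' coh <- simulate_cohort(phenotype_preset("control"), task_config(),
#'                        n_games = 32, seed = 7)
#' fit <- map_fit(coh)
#' tidy(fit)
#' }
map_fit <- function(cohort, prior = parameter_prior(), grid = grid_spec(),
                    config = cohort$config, floor = 1e-12,
                    control = engine_control()) {
  stopifnot(inherits(cohort, "lo_cohort"))
  if (is.null(config)) abort("A task config is required to fit.")
  lpfun <- log_posterior_fn(cohort, config, prior, floor, control)

  pts <- expand.grid(prior_precision = grid$prior_precision,
                     hazard_scale = grid$hazard_scale,
                     sensitivity = grid$sensitivity)
  lp <- apply(log(as.matrix(pts)), 1, lpfun)
  best <- which.max(lp)
  grid_best <- tibble(as_tibble(pts[best, ]), log_posterior = lp[best])

  opt <- tryCatch(
    optim(log(as.numeric(pts[best, ])), lpfun, method = "Nelder-Mead",
          control = list(fnscale = -1, maxit = 500, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$value < lp[best]) {
    theta <- log(as.numeric(pts[best, ]))
    value <- lp[best]
    converged <- FALSE
    iters <- 0L
  } else {
    theta <- opt$par
    value <- opt$value
    converged <- opt$convergence == 0
    iters <- unname(opt$counts["function"])
  }
  est <- setNames(exp(theta),
                  c("prior_precision", "hazard_scale", "sensitivity"))
  ll <- action_loglik(agent_params(est[1], est[2], est[3]), cohort,
                      config = config, floor = floor, control = control)
  structure(list(estimates = est, log_posterior = value, log_likelihood = ll,
                 grid_best = grid_best, iterations = iters,
                 converged = converged, prior = prior, config = config),
            class = "lo_fit")
}

#' @export
print.lo_fit <- function(x, ...) {
  cat("<MAP fit>\n")
  cat(sprintf(
    "  prior_precision %.3f, hazard_scale %.3f, sensitivity %.3f\n",
    x$estimates["prior_precision"], x$estimates["hazard_scale"],
    x$estimates["sensitivity"]))
  cat(sprintf("  log-posterior %.3f (log-likelihood %.3f), converged: %s\n",
              x$log_posterior, x$log_likelihood, x$converged))
  invisible(x)
}

#' @describeIn map_fit MAP estimates as a tibble (`term`, `estimate`).
#' @param x An `lo_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lo_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @describeIn map_fit one-row fit summary.
#' @exportS3Method generics::glance
glance.lo_fit <- function(x, ...) {
  tibble(log_posterior = x$log_posterior,
         log_likelihood = x$log_likelihood,
         iterations = x$iterations,
         converged = x$converged)
}

#' Parameter-recovery study
#'
#' Standard validation loop for the inversion: simulate cohorts at known
#' parameter settings, fit each by MAP, and summarise per-parameter bias,
#' RMSE and Spearman rank correlation between generating and recovered
#' values. If the task has a zero objective withdrawal hazard the subjective
#' hazard scale has no behavioural consequence and is flagged unidentifiable.
#'
#' @param true_params_list List of [agent_params()] (the generating
#'   settings).
#' @param config A [task_config()].
#' @param n_games Games per simulated cohort (default 256).
#' @param n_reps Replicates per setting (default 1).
#' @param seed Master seed; cohort seeds are derived per setting and
#'   replicate.
#' @param prior,grid Passed to [map_fit()].
#' @return An object of class `lo_recovery`: list with `fits` (tibble: one
#'   row per setting x replicate with true and estimated parameters,
#'   log-posterior, convergence), `summary` (per-parameter bias, RMSE,
#'   Spearman), `unidentifiable` (character vector of flagged parameters),
#'   `config`, `n_games`, `n_reps`, `seed`.
#' @export
recovery_study <- function(true_params_list, config, n_games = 256,
                           n_reps = 1, seed = 1,
                           prior = parameter_prior(), grid = grid_spec()) {
  if (length(true_params_list) == 0) {
    abort("`true_params_list` must contain at least one parameter setting.")
  }
  stopifnot(n_reps >= 1)
  fits <- purrr::map(seq_len(n_reps), function(rep) {
    purrr::imap(true_params_list, function(truth, j) {
      coh_seed <- game_seed(seed + 104729 * rep, as.integer(j))
      coh <- simulate_cohort(truth, config, n_games = n_games,
                             seed = coh_seed)
      fit <- map_fit(coh, prior = prior, grid = grid, config = config)
      tibble(replicate = rep, setting = as.integer(j),
             true_prior_precision = truth$prior_precision,
             true_hazard_scale = truth$hazard_scale,
             true_sensitivity = truth$sensitivity,
             est_prior_precision = unname(fit$estimates["prior_precision"]),
             est_hazard_scale = unname(fit$estimates["hazard_scale"]),
             est_sensitivity = unname(fit$estimates["sensitivity"]),
             log_posterior = fit$log_posterior,
             converged = fit$converged)
    }) |> bind_rows()
  }) |> bind_rows()

  unident <- character()
  if (config$base_withdrawal_hazard == 0) unident <- c(unident, "hazard_scale")

  terms <- c("prior_precision", "hazard_scale", "sensitivity")
  summ <- purrr::map(terms, function(tm) {
    truth <- fits[[paste0("true_", tm)]]
    est <- fits[[paste0("est_", tm)]]
    tibble(
      term = tm,
      bias = mean(est - truth),
      rmse = sqrt(mean((est - truth)^2)),
      spearman = if (length(unique(truth)) > 1)
        cor(truth, est, method = "spearman") else NA_real_,
      unidentifiable = tm %in% unident
    )
  }) |> bind_rows()

  structure(list(fits = fits, summary = summ, unidentifiable = unident,
                 config = config, n_games = as.integer(n_games),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "lo_recovery")
}

#' @export
print.lo_recovery <- function(x, ...) {
  cat(sprintf("<recovery study: %d settings x %d reps, %d games each>\n",
              length(unique(x$fits$setting)), x$n_reps, x$n_games))
  print(x$summary)
  if (length(x$unidentifiable)) {
    cat("  unidentifiable under this task: ",
        paste(x$unidentifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn recovery_study per-fit results (one row per setting x
#'   replicate).
#' @param x An `lo_recovery`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lo_recovery <- function(x, ...) x$fits

#' @describeIn recovery_study per-parameter recovery summary (bias, RMSE,
#'   Spearman).
#' @exportS3Method generics::glance
glance.lo_recovery <- function(x, ...) x$summary
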