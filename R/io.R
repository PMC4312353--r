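# Plumbing: cohort CSV round trip, run-configuration files, fit JSON.

cohort_csv_cols <- c("game_id", "trial", "horizon", "low_offer", "high_offer",
                     "state", "p_accept", "action", "event", "gamma_hat",
                     "outcome", "payoff")

#' Write / read a cohort as CSV
#'
#' The cohort CSV holds one row per played trial with columns `game_id`,
#' `trial`, `horizon`, `low_offer`, `high_offer`, `state`, `p_accept`,
#' `action`, `event`, `gamma_hat`, `outcome`, `payoff` (UTF-8, 1-based
#' trials). The round trip is lossless for all per-trial fields. Hazard
#' parameters and agent settings are not part of the behavioural record, so
#' reading back attaches whatever `config`/`agent` you pass (fitting needs
#' the task config).
#'
#' @param cohort An `lo_cohort`.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns an `lo_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "lo_cohort"))
  readr::write_csv(cohort$games[, cohort_csv_cols], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param config Optional [task_config()] to attach (required downstream by
#'   [action_loglik()] / [map_fit()]).
#' @param agent Optional [agent_params()] to attach.
#' @export
read_cohort_csv <- function(path, config = NULL, agent = NULL) {
  games <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_csv_cols, names(games))
  if (length(missing_cols)) {
    abort(sprintf("Cohort CSV is missing required columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  problems <- which(!games$state %in% lo_states() |
                    !games$action %in% c("wait", "accept") |
                    !games$event %in% c("none", "withdrawal", "high_offer"))
  if (length(problems)) {
    abort(sprintf("Malformed cohort rows (data line %s).",
                  paste(head(problems, 5), collapse = ", ")))
  }
  if (is.null(config) && nrow(games)) {
    # offers and horizon are stored per row; hazards fall back to defaults
    config <- task_config(horizon = games$horizon[1],
                          low_offer = games$low_offer[1],
                          high_offer = games$high_offer[1])
  }
  structure(list(games = as_tibble(games)[, cohort_csv_cols],
                 config = config, agent = agent,
                 n_games = length(unique(games$game_id)), seed = NA_integer_),
            class = "lo_cohort")
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration has up to five sections -- `task`, `agent`,
#' `simulation`, `fit`, `output` -- and unknown sections or unknown keys
#' within them are rejected. `task` maps onto [task_config()] fields;
#' `agent` is either `preset: <name>` or explicit [agent_params()] fields;
#' `simulation` holds `n_games` and `seed`; `fit` holds optional `prior`
#' (`location`/`scale` named lists) and `grid` (named lists of grid values);
#' `output` holds file paths.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `lo_runconfig` with elements `task`
#'   (`lo_task`), `agent` (`lo_agent`), `simulation`, `fit`, `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("task", "agent", "simulation", "fit", "output")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("Unknown config section(s): %s.",
                  paste(extra, collapse = ", ")))
  }
  check_keys <- function(x, allowed, section) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      abort(sprintf("Unknown key(s) in `%s`: %s.", section,
                    paste(extra, collapse = ", ")))
    }
    x
  }
  task <- do.call(task_config,
                  check_keys(raw$task %||% list(),
                             names(formals(task_config)), "task"))
  agent_raw <- raw$agent %||% list(preset = "control")
  agent <- if (!is.null(agent_raw$preset)) {
    check_keys(agent_raw, "preset", "agent")
    phenotype_preset(agent_raw$preset)
  } else {
    do.call(agent_params,
            check_keys(agent_raw, names(formals(agent_params)), "agent"))
  }
  sim <- check_keys(raw$simulation %||% list(), c("n_games", "seed"),
                    "simulation")
  sim$n_games <- sim$n_games %||% 256
  sim$seed <- sim$seed %||% 1
  fit <- check_keys(raw$fit %||% list(),
                    c("prior", "grid", "true_params", "n_reps"), "fit")
  out <- check_keys(raw$output %||% list(),
                    c("cohort_csv", "fit_json", "recovery_csv"), "output")
  structure(list(task = task, agent = agent, simulation = sim, fit = fit,
                 output = out),
            class = "lo_runconfig")
}

fit_prior_from_config <- function(fit_section) {
  if (is.null(fit_section$prior)) return(parameter_prior())
  parameter_prior(location = unlist(fit_section$prior$location),
                  scale = unlist(fit_section$prior$scale))
}

fit_grid_from_config <- function(fit_section) {
  if (is.null(fit_section$grid)) return(grid_spec())
  do.call(grid_spec, lapply(fit_section$grid, unlist))
}

#' Write a MAP fit as JSON
#'
#' @param fit An `lo_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "lo_fit"))
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates),
         log_posterior = fit$log_posterior,
         log_likelihood = fit$log_likelihood,
         iterations = fit$iterations,
         converged = fit$converged,
         grid_best = as.list(fit$grid_best)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
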