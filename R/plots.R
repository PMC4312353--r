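# Diagnostic plots. These are working plots for model checking, not
# publication figures.

#' @describeIn simulate_game precision trace and simulated dopamine response
#'   of one game.
#' @param object An `lo_game`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.lo_game <- function(object, ...) {
  agent <- attr(object, "agent")
  trace <- tibble(
    trial = c(0, object$trial),
    gamma_hat = c(agent$prior_precision, object$gamma_hat)
  )
  dopa <- dopamine_trace(object)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$trial, y = .data$gamma_hat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    {if (nrow(dopa)) ggplot2::geom_col(
      data = dopa,
      ggplot2::aes(x = .data$trial, y = .data$delta_gamma),
      width = 0.3, alpha = 0.5)} +
    ggplot2::labs(x = "trial",
                  y = "expected precision (line) / change (bars)",
                  title = sprintf("game outcome: %s", attr(object, "outcome"))) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_cohort per-trial outcome frequencies of a cohort.
#' @param object An `lo_cohort`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.lo_cohort <- function(object, ...) {
  prof <- acceptance_profile(object)
  long <- prof$by_trial |>
    tidyr::pivot_longer(c("accepted", "high_offer", "withdrawn"),
                        names_to = "termination", values_to = "n") |>
    mutate(freq = .data$n / prof$n_games)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$trial), y = .data$freq,
                                     fill = .data$termination)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "trial", y = "frequency of games",
                  title = sprintf("acceptance profile (%d games)",
                                  prof$n_games)) +
    ggplot2::theme_minimal()
}

#' @describeIn recovery_study true vs recovered parameters, one facet per
#'   parameter.
#' @param object An `lo_recovery`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.lo_recovery <- function(object, ...) {
  long <- object$fits |>
    tidyr::pivot_longer(dplyr::starts_with(c("true_", "est_")),
                        names_to = c("kind", "term"),
                        names_pattern = "(true|est)_(.*)") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$est)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generating value", y = "MAP estimate") +
    ggplot2::theme_minimal()
}
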