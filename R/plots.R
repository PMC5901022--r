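#' Posterior density comparison between groups
#'
#' Overlaid posterior densities of a group-level parameter for two fitted
#' groups — the separation of the two densities is the visual counterpart
#' of the posterior difference probability \eqn{P_\theta}.
#'
#' @param fit_pd,fit_control `hier_sdt_fit` objects.
#' @param parameter Group-level parameter to plot (default `"mu_d"`).
#' @return A ggplot object.
#' @export
plot_posterior_densities <- function(fit_pd, fit_control,
                                     parameter = "mu_d") {
  df <- dplyr::bind_rows(
    dplyr::mutate(fit_pd$draws[fit_pd$draws$parameter == parameter, ],
                  group = "PD"),
    dplyr::mutate(
      fit_control$draws[fit_control$draws$parameter == parameter, ],
      group = "Control")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::scale_fill_manual(values = c(PD = "grey25", Control = "grey70")) +
    ggplot2::labs(x = parameter, y = "Posterior density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.staircase_run <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(x = .data$step, y = .data$size)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct), size = 2) +
    ggplot2::geom_hline(yintercept = object$acuity_estimate,
                        linetype = "dashed") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "Step", y = "Optotype size (decimal acuity)",
                  shape = "Correct") +
    ggplot2::theme_minimal()
}

#' Group performance by task and difficulty
#'
#' Mean proportion correct with standard-error bars per group, task and
#' difficulty level.
#'
#' @param scores Score tibble from [score_2afc()].
#' @param groups Tibble `participant_id`, `group`.
#' @return A ggplot object.
#' @export
plot_task_performance <- function(scores, groups) {
  df <- dplyr::left_join(scores, groups, by = "participant_id")
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$task, .data$difficulty_level, .data$group),
    mean = mean(.data$proportion_correct),
    se = sd(.data$proportion_correct) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$difficulty_level),
                                     y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "Difficulty level", y = "Proportion correct",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
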