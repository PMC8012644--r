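#' Plot a block-aligned trial course per reward condition
#'
#' @param course Output of [aligned_course()] or [aligned_dprime()].
#' @param var Column to plot (default `"mean"`; use `"dprime"` for
#'   [aligned_dprime()] output).
#' @return A ggplot.
#' @export
plot_aligned_course <- function(course, var = "mean") {
  ggplot2::ggplot(course,
                  ggplot2::aes(x = .data$aligned, y = .data[[var]],
                               colour = .data$reward_cond)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         span = 0.4) +
    ggplot2::labs(x = "trial from first correct after transition", y = var,
                  colour = "reward") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.v4_expfit <- function(object, ...) {
  df <- tibble::tibble(t = object$t, y = object$y, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "trial", y = "response",
                  title = if (object$degenerate) "degenerate (constant) fit"
                  else sprintf("tau = %.2f trials", object$tau)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.v4_decode <- function(object, ...) {
  ggplot2::ggplot(object$trial_table,
                  ggplot2::aes(x = factor(.data$truth), y = .data$posterior)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4,
                         ggplot2::aes(colour = .data$correct)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = object$variable, y = "posterior P(value = 1)",
                  title = sprintf("accuracy %.2f (chance %.2f)",
                                  object$accuracy, object$chance)) +
    ggplot2::theme_minimal()
}

#' Plot mean noise correlation by evoked-response bin
#'
#' @param nc Output of [noise_correlations()].
#' @return A ggplot.
#' @export
plot_noise_correlations <- function(nc) {
  df <- nc |>
    dplyr::group_by(.data$reward_cond, .data$bin) |>
    dplyr::summarise(r = mean(.data$r), n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$r,
                                   colour = .data$reward_cond)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "geometric-mean evoked rate bin (Hz)",
                  y = "mean pairwise r", colour = "reward") +
    ggplot2::theme_minimal()
}

#' Plot population predictor importance for a fitted model set
#'
#' @param glmset A `v4_glmset`.
#' @param alpha Only units with model p-value below this are pooled.
#' @return A ggplot.
#' @export
plot_predictor_importance <- function(glmset, alpha = 0.05) {
  keep <- glmset$summary$unit[glmset$summary$p_value < alpha]
  pi_df <- purrr::map_dfr(glmset$fits[as.character(keep)],
                          predictor_importance)
  pi_df <- pi_df |>
    dplyr::mutate(term = ifelse(grepl("^rhist", .data$term), "reward history",
                                .data$term)) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(importance = mean(.data$importance), .groups = "drop")
  ggplot2::ggplot(pi_df, ggplot2::aes(x = stats::reorder(.data$term,
                                                         .data$importance),
                                      y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predictor importance |z|",
                  title = paste(glmset$model, "model")) +
    ggplot2::theme_minimal()
}
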