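#' Plot context-wise risk preferences
#'
#' Cohort-level bar chart of the mean risky-choice proportion per reward
#' context (and condition, if present), with subject-level points and the
#' chance level marked. Works for the output of
#' [risk_preference_experience()] or [risk_preference_description()].
#'
#' @param prefs A risk-preference tibble.
#' @return A ggplot object.
#' @export
plot_risk_preference <- function(prefs) {
  long <- tidyr::pivot_longer(prefs, c("p_risky_high", "p_risky_low"),
                              names_to = "context",
                              names_prefix = "p_risky_",
                              values_to = "p_risky")
  has_cond <- "condition" %in% names(long)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$context,
                                          y = .data$p_risky)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          fill = "steelblue", alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Reward context", y = "p(risky choice)") +
    ggplot2::theme_minimal()
  if (has_cond) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' @method autoplot peirs_pop_fit
#' @export
autoplot.peirs_pop_fit <- function(object, ...) {
  free <- model_free_params(object$model)
  long <- tidyr::pivot_longer(object$fits, dplyr::all_of(free),
                              names_to = "param", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$param, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = NULL, y = "MAP estimate (natural scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @method autoplot peirs_sim
#' @export
autoplot.peirs_sim <- function(object, ...) {
  n <- nrow(object$q)
  long <- purrr::map_dfr(colnames(object$q), function(id) {
    tibble::tibble(trial = seq_len(n) - 1, id = id,
                   q = object$q[, id], s = object$s[, id])
  }) |>
    tidyr::pivot_longer(c("q", "s"), names_to = "state", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value,
                                     colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = "Estimate (points)",
                  colour = "Stimulus") +
    ggplot2::theme_minimal()
}
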