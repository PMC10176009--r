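#' Context-wise risk preference on the experience task
#'
#' Computes, per subject (and condition, when those columns are present), the
#' proportion of high/low-reward context trials on which the high-spread
#' (risky) stimulus was chosen, using only the second half of each stimulus
#' set's trials (so values are measured after learning has stabilized), and
#' the fraction of mixed-context trials on which the higher-mean stimulus was
#' chosen (an attention/comprehension control, computed over all mixed
#' trials).
#'
#' @param trials Completed experience-task tibble; optional `subject` /
#'   `condition` grouping columns.
#' @param stimuli Stimulus definitions (to identify each option's mean and
#'   spread).
#' @return A tibble with `p_risky_high`, `p_risky_low`, `accuracy_mixed` and
#'   the per-cell trial counts. Empty cells yield `NaN` proportions.
#' @export
risk_preference_experience <- function(trials, stimuli = default_stimuli()) {
  grp <- intersect(c("subject", "condition"), names(trials))
  sd_of <- function(id) stimuli$sd[match(id, stimuli$id)]
  mean_of <- function(id) stimuli$mean[match(id, stimuli$id)]

  df <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "set")))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(second_half = dplyr::row_number() > dplyr::n() / 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      risky_chosen = sd_of(.data$chosen) ==
        pmax(sd_of(.data$option_left), sd_of(.data$option_right)),
      correct_mixed = mean_of(.data$chosen) ==
        pmax(mean_of(.data$option_left), mean_of(.data$option_right))
    )

  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      p_risky_high = mean(.data$risky_chosen[.data$trial_type == "high" &
                                               .data$second_half]),
      p_risky_low = mean(.data$risky_chosen[.data$trial_type == "low" &
                                              .data$second_half]),
      accuracy_mixed = mean(.data$correct_mixed[.data$trial_type == "mixed"]),
      n_high = sum(.data$trial_type == "high" & .data$second_half),
      n_low = sum(.data$trial_type == "low" & .data$second_half),
      n_mixed = sum(.data$trial_type == "mixed"),
      .groups = "drop"
    )
}

#' Context-wise risk preference on the description task
#'
#' All trials enter (no learning occurs): the risky-choice proportion in the
#' low-reward context comes from gamble 9 and in the high-reward context from
#' gamble 10; accuracy is the fraction of mixed-context trials (gambles 1-8)
#' choosing the option with the higher expected value.
#'
#' @param trials Completed description-task tibble; optional `subject` /
#'   `condition` grouping columns.
#' @param gambles Gamble definitions.
#' @return A tibble with `p_risky_high`, `p_risky_low`, `accuracy_mixed` and
#'   per-cell counts.
#' @export
risk_preference_description <- function(trials, gambles = default_gambles()) {
  grp <- intersect(c("subject", "condition"), names(trials))
  g <- gamble_expected_values(gambles)
  df <- dplyr::left_join(trials,
                         dplyr::select(g, "gamble_id", "context",
                                       "ev_safe", "ev_risky"),
                         by = "gamble_id") |>
    dplyr::mutate(
      risky_chosen = .data$chosen == "risky",
      best = dplyr::case_when(.data$ev_risky > .data$ev_safe ~ "risky",
                              .data$ev_risky < .data$ev_safe ~ "safe",
                              TRUE ~ NA_character_),
      correct_mixed = .data$chosen == .data$best
    )
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      p_risky_high = mean(.data$risky_chosen[.data$context == "high"]),
      p_risky_low = mean(.data$risky_chosen[.data$context == "low"]),
      accuracy_mixed = mean(.data$correct_mixed[.data$context == "mixed"]),
      n_high = sum(.data$context == "high"),
      n_low = sum(.data$context == "low"),
      n_mixed = sum(.data$context == "mixed"),
      .groups = "drop"
    )
}

#' Paired t-test with Cohen's d_z
#'
#' @param x,y Paired samples.
#' @return A one-row tibble: `t`, `df`, `p`, `cohens_dz`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0)
    return(tibble::tibble(t = NA_real_, df = n - 1, p = NA_real_,
                          cohens_dz = NA_real_, mean_diff = mean(d),
                          zero_variance = TRUE))
  tt <- mean(d) / (sdd / sqrt(n))
  tibble::tibble(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1),
                 cohens_dz = mean(d) / sdd, mean_diff = mean(d),
                 zero_variance = FALSE)
}

#' Fully-within 2x2 repeated-measures ANOVA
#'
#' Main effects and the interaction of a two-by-two fully-within design,
#' computed from first principles via per-subject difference contrasts: for a
#' single-df within-subject effect, F is exactly the square of the paired t
#' statistic on the corresponding contrast, with df = (1, n - 1). Partial eta
#' squared is `F / (F + df2)`.
#'
#' @param data Tibble with one row per subject x cell.
#' @param dv Name of the value column.
#' @param within Length-2 character vector naming the two within-subject
#'   factor columns (each with exactly 2 levels).
#' @param subject Name of the subject column.
#' @return A tibble with one row per effect (`A`, `B`, `A:B`, named after the
#'   factors): `F`, `df1`, `df2`, `p`, `partial_eta_sq`, plus a
#'   `zero_variance` flag for degenerate contrasts.
#' @export
#' @examples
#' df <- tidyr::expand_grid(subject = 1:8, hunger = c("sated", "hungry"),
#'                          context = c("high", "low"))
#' df$value <- rnorm(nrow(df))
#' rm_anova_2x2(df, dv = "value", within = c("hunger", "context"))
rm_anova_2x2 <- function(data, dv, within, subject = "subject") {
  stopifnot(length(within) == 2)
  fa <- within[1]; fb <- within[2]
  la <- sort(unique(as.character(data[[fa]])))
  lb <- sort(unique(as.character(data[[fb]])))
  if (length(la) != 2 || length(lb) != 2)
    stop("both within factors must have exactly 2 levels", call. = FALSE)

  wide <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, fa, fb)))) |>
    dplyr::summarise(v = mean(.data[[dv]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(c(fa, fb)),
                       values_from = "v")
  cells <- as.matrix(wide[, paste(rep(la, each = 2), rep(lb, 2), sep = "_")])
  if (anyNA(cells))
    stop("every subject needs all four cells", call. = FALSE)
  # columns: a1b1, a1b2, a2b1, a2b2
  contrasts <- list(
    (cells[, 3] + cells[, 4]) / 2 - (cells[, 1] + cells[, 2]) / 2,
    (cells[, 2] + cells[, 4]) / 2 - (cells[, 1] + cells[, 3]) / 2,
    (cells[, 4] - cells[, 3]) - (cells[, 2] - cells[, 1])
  )
  names(contrasts) <- c(fa, fb, paste(fa, fb, sep = ":"))
  n <- nrow(cells)
  purrr::map_dfr(names(contrasts), function(eff) {
    d <- contrasts[[eff]]
    if (sd(d) == 0)
      return(tibble::tibble(effect = eff, F = NA_real_, df1 = 1, df2 = n - 1,
                            p = NA_real_, partial_eta_sq = NA_real_,
                            zero_variance = TRUE))
    tt <- mean(d) / (sd(d) / sqrt(n))
    Fv <- tt^2
    tibble::tibble(effect = eff, F = Fv, df1 = 1, df2 = n - 1,
                   p = pf(Fv, 1, n - 1, lower.tail = FALSE),
                   partial_eta_sq = Fv / (Fv + n - 1), zero_variance = FALSE)
  })
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Standard signed-rank test on paired differences: zero differences are
#' dropped, tied absolute differences receive midranks, and the standardized
#' statistic uses the tie-corrected variance and a 0.5 continuity correction.
#' `z` is positive when `x` tends to exceed `y`.
#'
#' @param x First sample, or the differences if `y` is omitted.
#' @param y Optional second (paired) sample.
#' @return A one-row tibble: `statistic` (W, sum of positive ranks), `z`, `p`,
#'   `n_used`, `n_zero`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(tibble::tibble(statistic = NA_real_, z = NA_real_, p = NA_real_,
                          n_used = 0L, n_zero = n_zero))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w - mu) * 0.5
  z <- if (sigma2 > 0) (w - mu - cc) / sqrt(sigma2) else NA_real_
  tibble::tibble(statistic = w, z = z, p = 2 * pnorm(-abs(z)),
                 n_used = n, n_zero = n_zero)
}

#' Model-derived stimulus utilities
#'
#' Computes each stimulus's utility from final (or otherwise supplied) Q and S
#' estimates using the PEIRS utility with the single-stimulus context signal
#' `delta = Q(stimulus) - mean(Q of all stimuli in its set)`, as appropriate
#' when one stimulus is evaluated in isolation (e.g. rating screens). Sets
#' are handled separately.
#'
#' @param latent Tibble with columns `id`, `set`, `q`, `s` (see
#'   [final_latent_state()]).
#' @param params Parameter vector, see [peirs_params()].
#' @return The input with `delta` and `utility` columns appended.
#' @export
#' @examples
#' lat <- tibble::tibble(id = c("A", "B", "C", "D"), set = 1,
#'                       q = c(35, 35, 65, 65), s = c(4, 16, 4, 16))
#' stimulus_utility(lat, peirs_params(0.3, 0.3, 0.15, 0, 0.05))
stimulus_utility <- function(latent, params) {
  p <- as_params(params)
  latent |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(delta = .data$q - mean(.data$q)) |>
    dplyr::ungroup() |>
    dplyr::mutate(utility = peirs_utility(.data$q, .data$s, .data$delta, p))
}
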