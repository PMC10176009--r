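#' Default gamble set for the description task
#'
#' Ten unique two-option gambles. Gambles 1-8 are mixed-context: the safe
#' option is always a 50:50 chance of winning or losing 10 points (expected
#' value 0) and the risky option crosses win probability (0.6 or 0.4), points
#' to win (30 or 70), and points to lose (30 or 70), giving risky expected
#' values spanning -30 to +30. Gambles 9 (low-reward context) and 10
#' (high-reward context) match the expected values of their safe and risky
#' options; gamble 9 is the sign-flipped mirror of gamble 10. The point
#' magnitudes of gambles 9/10 default to a certain +/-40 versus a 50:50
#' +/-80-or-0 gamble and are configurable.
#'
#' @param context_certain Absolute certain amount in gambles 9/10 (default 40).
#' @param context_extreme Absolute extreme outcome of the risky 50:50 option
#'   in gambles 9/10 (default 80; the other outcome is 0).
#' @return A tibble with columns `gamble_id`, `context`, and per-option
#'   `p_win`, `win`, `lose` (safe_/risky_ prefixes). An option's expected
#'   value is `p_win * win - (1 - p_win) * lose`.
#' @export
#' @examples
#' gamble_expected_values(default_gambles())
default_gambles <- function(context_certain = 40, context_extreme = 80) {
  risky <- expand.grid(p_win = c(0.6, 0.4), win = c(30, 70), lose = c(30, 70))
  mixed <- tibble::tibble(
    gamble_id = 1:8,
    context = "mixed",
    safe_p_win = 0.5, safe_win = 10, safe_lose = 10,
    risky_p_win = risky$p_win, risky_win = risky$win, risky_lose = risky$lose
  )
  ctx <- tibble::tibble(
    gamble_id = c(9L, 10L),
    context = c("low", "high"),
    # gamble 9: certain loss vs 50:50 lose-big-or-nothing (valence mirror of 10)
    safe_p_win = c(0, 1),
    safe_win = c(0, context_certain),
    safe_lose = c(context_certain, 0),
    risky_p_win = c(0.5, 0.5),
    risky_win = c(0, context_extreme),
    risky_lose = c(context_extreme, 0)
  )
  dplyr::bind_rows(mixed, ctx)
}

#' Expected values of both options of each gamble
#'
#' @param gambles A gamble tibble, see [default_gambles()].
#' @return The input with `ev_safe` and `ev_risky` columns appended
#'   (`EV = p_win * win - (1 - p_win) * lose`).
#' @export
gamble_expected_values <- function(gambles) {
  dplyr::mutate(
    gambles,
    ev_safe = .data$safe_p_win * .data$safe_win -
      (1 - .data$safe_p_win) * .data$safe_lose,
    ev_risky = .data$risky_p_win * .data$risky_win -
      (1 - .data$risky_p_win) * .data$risky_lose
  )
}

#' Generate a description-task trial schedule
#'
#' Four blocks of 20 trials by default; each of the 10 gambles appears the
#' same number of times in every block (twice by default, eight times
#' overall), in an order that is a function of the seed only, so the same
#' presentation order can be reused across conditions.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 20); must be a multiple
#'   of the number of gambles.
#' @param gambles Gamble definitions, see [default_gambles()].
#' @param seed Integer seed.
#' @return A tibble of unchosen trials: `trial`, `block`, `gamble_id`.
#' @export
#' @examples
#' table(description_schedule(seed = 1)$gamble_id)
description_schedule <- function(n_blocks = 4, trials_per_block = 20,
                                 gambles = default_gambles(), seed = NULL) {
  n_g <- nrow(gambles)
  reps <- trials_per_block / n_g
  if (abs(reps - round(reps)) > 1e-9)
    stop("trials per block must be a multiple of the number of gambles",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- purrr::map(seq_len(n_blocks), function(b)
    sample(rep(gambles$gamble_id, round(reps))))
  tibble::tibble(
    trial = seq_len(n_blocks * trials_per_block),
    block = rep(seq_len(n_blocks), each = trials_per_block),
    gamble_id = unlist(ids)
  )
}
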