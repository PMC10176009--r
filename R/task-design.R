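#' Default stimulus set for the experience task
#'
#' Four stimuli per stimulus set, crossing mean reward (35 or 65 points) with
#' reward standard deviation (5 or 20 points). Stimulus identities are reset
#' halfway through the task, so the full design carries two independent sets
#' of four (labels A-D for set 1, E-H for set 2) with identical reward
#' statistics.
#'
#' @param n_sets Number of stimulus sets (default 2).
#' @return A tibble with columns `id`, `set`, `mean`, `sd`.
#' @export
#' @examples
#' default_stimuli()
default_stimuli <- function(n_sets = 2) {
  stopifnot(n_sets >= 1, n_sets <= 6)
  base <- tibble::tibble(
    label = c("A", "B", "C", "D"),
    mean = c(35, 35, 65, 65),
    sd = c(5, 20, 5, 20)
  )
  purrr::map_dfr(seq_len(n_sets), function(s) {
    tibble::tibble(
      id = LETTERS[(s - 1) * 4 + 1:4],
      set = s,
      mean = base$mean,
      sd = base$sd
    )
  })
}

# integer trial counts per block implied by the proportions; errors unless the
# proportions resolve exactly
block_counts <- function(trials_per_block, proportions) {
  stopifnot(all(c("context", "mixed", "forced") %in% names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("trial-type proportions must sum to 1", call. = FALSE)
  counts <- proportions[c("context", "mixed", "forced")] * trials_per_block
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("trial-type proportions do not resolve to integer counts per block",
         call. = FALSE)
  counts <- round(counts)
  if (counts[["context"]] %% 2 != 0)
    stop("context-trial count per block must be even (half high, half low)",
         call. = FALSE)
  counts
}

#' Generate an experience-task trial schedule
#'
#' Builds the trial list for the experience-based risk task: four blocks of 72
#' trials by default, split per block into 50% high/low-reward context trials
#' (equal-mean, unequal-spread pairs), 33% mixed-context trials (one high-mean
#' and one low-mean stimulus), and 17% forced-sampling trials (a single
#' stimulus, each stimulus equally often). Stimulus identities switch to a
#' fresh set after half the blocks. Trial order is shuffled under the
#' constraint that a forced trial showing stimulus X is never immediately
#' followed by a high/low-context trial offering X (to avoid priming the next
#' choice).
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 72).
#' @param proportions Named proportions for `context`, `mixed`, `forced`
#'   trials; must resolve to integer per-block counts.
#' @param stimuli Stimulus definitions, see [default_stimuli()]. Must contain
#'   one set per `ceiling(n_blocks / 2)`.
#' @param seed Integer seed; schedules are deterministic given the seed.
#' @param max_attempts Bound on constraint-repair attempts per block.
#'
#' @return A tibble of unchosen trials: `trial`, `block`, `set`, `trial_type`
#'   (`"high"`, `"low"`, `"mixed"`, `"forced"`), `option_left`,
#'   `option_right` (`NA` on forced trials).
#' @export
#' @examples
#' sched <- experience_schedule(seed = 1)
#' dplyr::count(sched, block, trial_type)
experience_schedule <- function(n_blocks = 4, trials_per_block = 72,
                                proportions = c(context = 1/2, mixed = 1/3,
                                                forced = 1/6),
                                stimuli = default_stimuli(
                                  n_sets = max(1, ceiling(n_blocks / 2))),
                                seed = NULL, max_attempts = 10000) {
  counts <- block_counts(trials_per_block, proportions)
  n_sets_needed <- max(1, ceiling(n_blocks / 2))
  if (max(stimuli$set) < n_sets_needed)
    stop("stimuli must provide ", n_sets_needed, " sets", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  blocks <- vector("list", n_blocks)
  prev_tail <- NULL # last trial of previous block, for the boundary constraint
  for (b in seq_len(n_blocks)) {
    set_b <- (b - 1) %/% 2 + 1
    stim_b <- dplyr::filter(stimuli, .data$set == set_b)
    blk <- build_block(counts, stim_b, prev_tail, max_attempts, b)
    blk$block <- b
    blk$set <- set_b
    blocks[[b]] <- blk
    prev_tail <- blk[nrow(blk), ]
  }
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  dplyr::select(out, "trial", "block", "set", "trial_type",
                "option_left", "option_right")
}

# assemble and constraint-shuffle one block
build_block <- function(counts, stim_b, prev_tail, max_attempts, block_id) {
  high_ids <- stim_b$id[stim_b$mean == max(stim_b$mean)]
  low_ids <- stim_b$id[stim_b$mean == min(stim_b$mean)]
  n_ctx <- counts[["context"]]
  n_mixed <- counts[["mixed"]]
  n_forced <- counts[["forced"]]

  # mixed pairs cycle through the high x low cross; forced trials cycle
  # through all stimuli so each is sampled equally often
  mixed_pairs <- expand.grid(hi = high_ids, lo = low_ids,
                             stringsAsFactors = FALSE)
  mixed_idx <- rep_len(seq_len(nrow(mixed_pairs)), n_mixed)
  forced_ids <- rep_len(stim_b$id, n_forced)

  left <- c(rep(high_ids[1], n_ctx / 2), rep(low_ids[1], n_ctx / 2),
            mixed_pairs$hi[mixed_idx], forced_ids)
  right <- c(rep(high_ids[2], n_ctx / 2), rep(low_ids[2], n_ctx / 2),
             mixed_pairs$lo[mixed_idx], rep(NA_character_, n_forced))
  type <- c(rep("high", n_ctx / 2), rep("low", n_ctx / 2),
            rep("mixed", n_mixed), rep("forced", n_forced))

  # randomize left/right presentation on two-option trials
  flip <- runif(length(left)) < 0.5 & !is.na(right)
  tmp <- left[flip]; left[flip] <- right[flip]; right[flip] <- tmp

  blk <- tibble::tibble(trial_type = type, option_left = left,
                        option_right = right)

  attempts <- 0
  repeat {
    ord <- sample.int(nrow(blk))
    cand <- blk[ord, ]
    res <- repair_block(cand, prev_tail, max_attempts - attempts)
    attempts <- attempts + res$attempts
    if (res$ok) return(res$block)
    if (attempts >= max_attempts)
      stop("could not satisfy the forced-then-context ordering constraint in block ",
           block_id, call. = FALSE)
  }
}

# violation: position i is forced on X and position i+1 is a high/low context
# trial offering X; prev_tail extends the check across the block boundary
violation_positions <- function(blk, prev_tail) {
  n <- nrow(blk)
  forced_stim <- ifelse(blk$trial_type == "forced", blk$option_left,
                        NA_character_)
  is_ctx <- blk$trial_type %in% c("high", "low")
  bad <- logical(n)
  if (n > 1) {
    nxt_ctx <- is_ctx[-1]
    nxt_l <- blk$option_left[-1]
    nxt_r <- blk$option_right[-1]
    f <- forced_stim[-n]
    bad[-n] <- !is.na(f) & nxt_ctx & (f == nxt_l | (!is.na(nxt_r) & f == nxt_r))
  }
  first_bad <- FALSE
  if (!is.null(prev_tail) && prev_tail$trial_type == "forced" && is_ctx[1]) {
    # across the mid-task stimulus reset the ids are disjoint, so this is
    # automatically vacuous there
    f <- prev_tail$option_left
    first_bad <- f == blk$option_left[1] ||
      (!is.na(blk$option_right[1]) && f == blk$option_right[1])
  }
  list(internal = which(bad), first = first_bad)
}

repair_block <- function(blk, prev_tail, budget) {
  attempts <- 0
  n <- nrow(blk)
  repeat {
    v <- violation_positions(blk, prev_tail)
    if (length(v$internal) == 0 && !v$first)
      return(list(ok = TRUE, block = blk, attempts = attempts))
    if (attempts >= budget || attempts >= 20 * n)
      return(list(ok = FALSE, block = blk, attempts = attempts))
    # swap the offending successor (or first trial) with a random position
    pos <- if (v$first) 1L else v$internal[1] + 1L
    j <- sample.int(n, 1)
    if (j != pos) blk[c(pos, j), ] <- blk[c(j, pos), ]
    attempts <- attempts + 1
  }
}

#' Count ordering-constraint violations in an experience schedule
#'
#' Counts occurrences of a forced trial on stimulus X immediately followed by
#' a high/low-reward context trial offering X, across the whole trial
#' sequence.
#'
#' @param schedule An experience schedule tibble.
#' @return Integer count (0 for any schedule built by [experience_schedule()]).
#' @export
count_ordering_violations <- function(schedule) {
  n <- nrow(schedule)
  if (n < 2) return(0L)
  f <- ifelse(schedule$trial_type == "forced", schedule$option_left,
              NA_character_)
  is_ctx <- schedule$trial_type %in% c("high", "low")
  bad <- !is.na(f[-n]) & is_ctx[-1] &
    (f[-n] == schedule$option_left[-1] |
       (!is.na(schedule$option_right[-1]) &
          f[-n] == schedule$option_right[-1]))
  sum(bad, na.rm = TRUE)
}

#' Sample a single reward from a stimulus
#'
#' Draws from the stimulus's Gaussian reward distribution, rounds to the
#' nearest integer and clips to the 0-100 point range of the display scale.
#'
#' @param mean,sd Reward distribution parameters (sd >= 0; `sd = 0` is the
#'   degenerate constant case).
#' @param n Number of draws.
#' @return Integer-valued rewards in `[0, 100]`.
#' @export
#' @examples
#' sample_reward(65, 20, n = 5)
sample_reward <- function(mean, sd, n = 1) {
  stopifnot(sd >= 0)
  pmin(100, pmax(0, round(rnorm(n, mean, sd))))
}

#' Pre-generate standardized per-block reward sequences
#'
#' Reward sequences are drawn once per block and affinely rescaled so their
#' empirical mean and standard deviation match the stimulus specification
#' exactly (before rounding), ensuring every block carries the intended
#' reward distribution. Sequences are long enough to cover every possible
#' selection in the block and are consumed in order as a stimulus is chosen.
#' Rounding to integers and clipping to `[0, 100]` happens at consumption.
#'
#' @param stimuli Stimulus tibble (one set), columns `id`, `mean`, `sd`.
#' @param n_trials Worst-case number of picks per stimulus (the block length).
#' @param seed Optional seed.
#' @return A named list of numeric vectors (pre-rounding values), one per
#'   stimulus id.
#' @export
#' @examples
#' seqs <- pregenerate_block_rewards(default_stimuli(1), 72, seed = 1)
#' sapply(seqs, mean); sapply(seqs, sd)
pregenerate_block_rewards <- function(stimuli, n_trials, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_trials >= 2)
  out <- purrr::map(seq_len(nrow(stimuli)), function(i) {
    m <- stimuli$mean[i]; s <- stimuli$sd[i]
    if (s == 0) return(rep(m, n_trials))
    x <- rnorm(n_trials)
    m + s * (x - mean(x)) / sd(x)
  })
  names(out) <- stimuli$id
  out
}

# round-and-clip applied when a pre-generated reward is consumed
finalize_reward <- function(x) pmin(100, pmax(0, round(x)))
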