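#' Population specifications for simulated cohorts
#'
#' A population specification holds per-parameter Gaussian location and scale
#' on the unconstrained scale (see [to_natural()]) plus a condition label.
#' `default_populations()` returns the two default regimes used for surrogate
#' cohorts: a sated regime with a positive context sensitivity (risk-seeking
#' in high-reward contexts, risk-averse in low-reward contexts) and a hungry
#' regime with a reduced spread learning rate and reduced context sensitivity,
#' which flattens the contextual bias. The sated regime doubles as the
#' dispersed default population for parameter-recovery runs.
#'
#' Default locations correspond to natural-scale centers of roughly
#' `alpha_q = 0.30`, `alpha_s = 0.30` (sated) or `0.12` (hungry),
#' `beta = 0.135`, `gamma0 = 0`, and `gamma1 = 0.045` (sated) or `0.005`
#' (hungry). The sated `gamma1` location is calibrated so that the simulated
#' sated cohort is mildly risk-seeking in high-reward contexts
#' (p(risky|high) near 0.65 after learning) on top of the intrinsic
#' risk-aversion that sample-based value learning produces for high-spread
#' options.
#'
#' @param condition Condition label.
#' @param location,scale Named length-5 vectors on the unconstrained scale.
#' @param n_subjects Default cohort size.
#' @return A list of class `peirs_population`.
#' @export
#' @examples
#' default_populations()$sated
population_spec <- function(condition = "sated",
                            location = c(alpha_q = qlogis(0.3),
                                         alpha_s = qlogis(0.3),
                                         beta = log(0.135),
                                         gamma0 = 0, gamma1 = 0.045),
                            scale = c(alpha_q = 0.7, alpha_s = 0.7,
                                      beta = 0.5, gamma0 = 0.2,
                                      gamma1 = 0.02),
                            n_subjects = 32) {
  location <- location[peirs_param_names()]
  scale <- scale[peirs_param_names()]
  stopifnot(!anyNA(location), !anyNA(scale), all(scale > 0), n_subjects >= 1)
  structure(list(condition = condition, location = location, scale = scale,
                 n_subjects = n_subjects),
            class = "peirs_population")
}

#' @rdname population_spec
#' @export
default_populations <- function(n_subjects = 32) {
  sated <- population_spec("sated", n_subjects = n_subjects)
  hungry <- population_spec(
    "hungry",
    location = c(alpha_q = qlogis(0.3), alpha_s = qlogis(0.12),
                 beta = log(0.135), gamma0 = 0, gamma1 = 0.005),
    scale = sated$scale, n_subjects = n_subjects
  )
  list(sated = sated, hungry = hungry)
}

#' Sample agent parameters from a population
#'
#' Draws unconstrained Gaussian vectors from the population specification and
#' maps them through the bounded transform, so every sampled agent respects
#' the parameter bounds.
#'
#' @param spec A [population_spec()].
#' @param n Number of agents (defaults to the spec's `n_subjects`).
#' @param seed Integer seed.
#' @return A tibble with `subject`, `condition`, the five natural-scale
#'   parameters, and the five unconstrained values (suffix `_u`).
#' @export
#' @examples
#' sample_population(population_spec(), n = 4, seed = 1)
sample_population <- function(spec, n = spec$n_subjects, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n * 5), n, 5)
  sample_population_from_z(spec, z)
}

# shared draws -> parameters; used by sample_population and within-subject
# cohorts (where both conditions reuse the same standard-normal draws)
sample_population_from_z <- function(spec, z) {
  n <- nrow(z)
  x <- sweep(sweep(z, 2, spec$scale, `*`), 2, spec$location, `+`)
  colnames(x) <- peirs_param_names()
  nat <- t(apply(x, 1, to_natural))
  out <- tibble::as_tibble(nat)
  out_u <- tibble::as_tibble(x)
  names(out_u) <- paste0(peirs_param_names(), "_u")
  dplyr::bind_cols(
    tibble::tibble(subject = seq_len(n), condition = spec$condition),
    out, out_u
  )
}

#' Simulate one agent playing the experience task
#'
#' Plays a PEIRS (or RW) agent through an experience-task schedule. On choice
#' trials the agent picks via the softmax rule applied to PEIRS utilities; on
#' forced trials the single option is taken with probability 1. After every
#' outcome (including forced trials) the chosen stimulus's Q and S are updated
#' from the initial values `Q = 50`, `S = 5`. Rewards are consumed from
#' per-block pre-generated standardized sequences (see
#' [pregenerate_block_rewards()]).
#'
#' @param params Parameter vector on the natural scale, see [peirs_params()].
#' @param schedule An [experience_schedule()] tibble.
#' @param stimuli Stimulus definitions matching the schedule.
#' @param seed Integer seed; the full dataset is reproducible from
#'   `(seed, schedule, params)`.
#' @param model `"peirs"` or `"rw"` (gammas pinned at zero).
#' @param q0,s0 Initial estimates.
#' @return An object of class `peirs_sim`: a list with `trials` (the schedule
#'   completed with `chosen` and `reward`), `q`/`s` latent state matrices
#'   (`n_trials + 1` rows), `params`, `model`, and `seed`.
#' @export
#' @examples
#' sched <- experience_schedule(seed = 1)
#' sim <- simulate_subject(peirs_params(0.3, 0.3, 0.15, 0, 0.03), sched, seed = 2)
#' head(tidy(sim))
simulate_subject <- function(params, schedule, stimuli = default_stimuli(),
                             seed = NULL, model = c("peirs", "rw"),
                             q0 = 50, s0 = 5) {
  model <- match.arg(model)
  p <- validate_params(as_params(params))
  if (model == "rw") p[c("gamma0", "gamma1")] <- 0
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(schedule)
  n_stim <- nrow(stimuli)
  idx_l <- match(schedule$option_left, stimuli$id)
  idx_r <- match(schedule$option_right, stimuli$id)
  blocks <- unique(schedule$block)

  # standardized reward sequences per block x stimulus, consumed in order
  block_len <- as.integer(table(schedule$block)[as.character(blocks)])
  rewards <- purrr::map2(blocks, block_len, function(b, len) {
    set_b <- schedule$set[match(b, schedule$block)]
    pregenerate_block_rewards(stimuli[stimuli$set == set_b, ], len)
  })
  names(rewards) <- as.character(blocks)
  used <- lapply(rewards, function(r) setNames(integer(length(r)), names(r)))

  q <- rep(q0, n_stim); s <- rep(s0, n_stim)
  qm <- matrix(NA_real_, n + 1, n_stim); sm <- matrix(NA_real_, n + 1, n_stim)
  qm[1, ] <- q; sm[1, ] <- s
  chosen <- character(n); reward <- numeric(n)

  for (t in seq_len(n)) {
    il <- idx_l[t]; ir <- idx_r[t]
    if (is.na(ir)) {
      ch <- il
    } else {
      members <- stimuli$set == stimuli$set[il]
      delta <- delta_context(q[c(il, ir)], q[members])
      u_l <- peirs_utility(q[il], s[il], delta, p)
      u_r <- peirs_utility(q[ir], s[ir], delta, p)
      p_left <- choice_probability(u_l, u_r, p[["beta"]])
      ch <- if (runif(1) < p_left) il else ir
    }
    b <- as.character(schedule$block[t])
    id <- stimuli$id[ch]
    k <- used[[b]][[id]] + 1L
    used[[b]][[id]] <- k
    r <- finalize_reward(rewards[[b]][[id]][k])
    chosen[t] <- id; reward[t] <- r
    s[ch] <- update_s(s[ch], q[ch], r, p[["alpha_s"]])
    q[ch] <- update_q(q[ch], r, p[["alpha_q"]])
    qm[t + 1, ] <- q; sm[t + 1, ] <- s
  }
  colnames(qm) <- colnames(sm) <- stimuli$id
  trials <- dplyr::mutate(schedule, chosen = chosen, reward = reward)
  structure(list(trials = trials, q = qm, s = sm, params = p, model = model,
                 stimuli = stimuli, seed = seed),
            class = "peirs_sim")
}

#' @method tidy peirs_sim
#' @export
tidy.peirs_sim <- function(x, ...) x$trials

#' Final latent state of a simulated session
#'
#' @param sim A `peirs_sim` object.
#' @return A tibble with `id`, `set`, `q`, `s` at the end of the session.
#' @export
final_latent_state <- function(sim) {
  n <- nrow(sim$q)
  tibble::tibble(id = sim$stimuli$id, set = sim$stimuli$set,
                 q = sim$q[n, ], s = sim$s[n, ])
}

# derive reproducible sub-seeds from a run seed, keeping them in integer range
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a cohort of agents on the experience task
#'
#' Each agent receives its own schedule randomization (as each participant
#' did) and its own reward/choice stream, with all sub-seeds derived from the
#' single run seed so that the cohort is fully reproducible.
#'
#' @param params_tbl A tibble of agent parameters with a `subject` column
#'   (e.g. from [sample_population()]).
#' @param seed Run seed.
#' @param model `"peirs"` or `"rw"`.
#' @param schedule_args List of arguments passed to [experience_schedule()].
#' @param stimuli Stimulus definitions.
#' @param shared_schedule Optional schedule reused by every agent (used for
#'   within-subject designs); by default each agent gets a fresh one.
#' @return A list with `trials` (all subjects bound together, with `subject`
#'   and `condition` columns) and `sims` (the per-subject `peirs_sim`
#'   objects).
#' @export
simulate_cohort <- function(params_tbl, seed = NULL, model = "peirs",
                            schedule_args = list(),
                            stimuli = default_stimuli(),
                            shared_schedule = NULL) {
  n <- nrow(params_tbl)
  seeds <- matrix(derive_seeds(seed, 2 * n), n, 2)
  sims <- purrr::map(seq_len(n), function(i) {
    sched <- if (is.null(shared_schedule)) {
      do.call(experience_schedule,
              c(schedule_args, list(stimuli = stimuli, seed = seeds[i, 1])))
    } else shared_schedule
    simulate_subject(params_tbl[i, peirs_param_names()], sched,
                     stimuli = stimuli, seed = seeds[i, 2], model = model)
  })
  cond <- if ("condition" %in% names(params_tbl)) params_tbl$condition else
    rep(NA_character_, n)
  trials <- purrr::map2_dfr(sims, seq_len(n), function(s, i) {
    dplyr::mutate(s$trials, subject = params_tbl$subject[i],
                  condition = cond[i], .before = 1)
  })
  list(trials = trials, sims = sims)
}

#' Simulate a within-subject two-condition cohort
#'
#' Emulates the crossover design: every subject is simulated under both
#' regimes. The two condition-specific parameter vectors of a subject share
#' the same standard-normal draw, shifted and scaled by each condition's
#' population, so condition differences are within-subject parameter shifts.
#' Both sessions of a subject use the same schedule randomization; rewards and
#' choices are drawn independently per session.
#'
#' @param spec_a,spec_b Two [population_spec()]s (e.g.
#'   `default_populations()`).
#' @param n Number of subjects.
#' @param seed Run seed.
#' @param schedule_args Arguments for [experience_schedule()].
#' @param stimuli Stimulus definitions.
#' @return A list with `trials` (both conditions), `params` (per subject x
#'   condition), and `sims`.
#' @export
#' @examples
#' \donttest{
#' pops <- default_populations()
#' coh <- simulate_within_cohort(pops$sated, pops$hungry, n = 4, seed = 1)
#' dplyr::count(coh$trials, condition)
#' }
simulate_within_cohort <- function(spec_a, spec_b, n = 32, seed = NULL,
                                   schedule_args = list(),
                                   stimuli = default_stimuli()) {
  seeds <- matrix(derive_seeds(seed, 3 * n + 1), ncol = 1)
  set.seed(seeds[1])
  z <- matrix(rnorm(n * 5), n, 5)
  pars_a <- sample_population_from_z(spec_a, z)
  pars_b <- sample_population_from_z(spec_b, z)
  sched_seeds <- seeds[1 + seq_len(n)]
  sim_seeds_a <- seeds[1 + n + seq_len(n)]
  sim_seeds_b <- seeds[1 + 2 * n + seq_len(n)]

  run_one <- function(pars, sim_seeds) {
    purrr::map(seq_len(n), function(i) {
      sched <- do.call(experience_schedule,
                       c(schedule_args,
                         list(stimuli = stimuli, seed = sched_seeds[i])))
      simulate_subject(pars[i, peirs_param_names()], sched, stimuli = stimuli,
                       seed = sim_seeds[i])
    })
  }
  sims_a <- run_one(pars_a, sim_seeds_a)
  sims_b <- run_one(pars_b, sim_seeds_b)
  bind_cond <- function(sims, pars) {
    purrr::map2_dfr(sims, seq_len(n), function(s, i) {
      dplyr::mutate(s$trials, subject = pars$subject[i],
                    condition = pars$condition[i], .before = 1)
    })
  }
  list(
    trials = dplyr::bind_rows(bind_cond(sims_a, pars_a),
                              bind_cond(sims_b, pars_b)),
    params = dplyr::bind_rows(pars_a, pars_b),
    sims = list(sims_a, sims_b) |> setNames(c(spec_a$condition,
                                              spec_b$condition))
  )
}

#' Simulate choices on the description task
#'
#' Completes a description-task schedule under a pluggable choice policy: a
#' function mapping a one-row gamble tibble to the probability of choosing
#' the risky option. Choices are Bernoulli draws; outcomes are sampled from
#' the chosen option's stated win probability.
#'
#' @param policy Function `(gamble row) -> p(risky)` in `[0, 1]`, e.g.
#'   [policy_prospect()].
#' @param schedule A [description_schedule()] tibble.
#' @param gambles Gamble definitions.
#' @param seed Integer seed.
#' @return The schedule with `chosen` (`"safe"`/`"risky"`) and `outcome`
#'   (points, signed) appended.
#' @export
#' @examples
#' sched <- description_schedule(seed = 1)
#' trials <- simulate_description_choices(policy_prospect(), sched, seed = 2)
#' mean(trials$chosen == "risky")
simulate_description_choices <- function(policy, schedule,
                                         gambles = default_gambles(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- gambles[match(schedule$gamble_id, gambles$gamble_id), ]
  p_risky <- purrr::map_dbl(seq_len(nrow(g)), function(i) policy(g[i, ]))
  if (any(p_risky < 0 | p_risky > 1 | !is.finite(p_risky)))
    stop("policy returned a probability outside [0, 1]", call. = FALSE)
  chosen <- ifelse(runif(nrow(g)) < p_risky, "risky", "safe")
  p_win <- ifelse(chosen == "risky", g$risky_p_win, g$safe_p_win)
  win <- ifelse(chosen == "risky", g$risky_win, g$safe_win)
  lose <- ifelse(chosen == "risky", g$risky_lose, g$safe_lose)
  won <- runif(nrow(g)) < p_win
  dplyr::mutate(schedule, chosen = chosen,
                outcome = ifelse(won, win, -lose))
}

#' Description-task choice policies
#'
#' `policy_prospect()` builds a prospect-theory-like policy: the probability
#' of choosing the risky option is a logistic function of the expected-value
#' difference plus a valence-dependent weighting of the outcome-spread
#' difference (risk-averse for gains, risk-seeking for losses), which
#' reproduces the classic description-based reversal of contextual risk
#' attitudes. `policy_constant()` always chooses risky with a fixed
#' probability. An option's spread is the standard deviation of its outcome,
#' `(win + lose) * sqrt(p(1-p))`.
#'
#' @param ev_weight Logistic weight on `EV(risky) - EV(safe)` (per point).
#' @param risk_weight Magnitude of the valence-dependent spread weight.
#' @param p Constant risky-choice probability.
#' @return A policy function for [simulate_description_choices()].
#' @export
policy_prospect <- function(ev_weight = 0.1, risk_weight = 0.05) {
  function(g) {
    ev <- gamble_expected_values(g)
    sd_safe <- (g$safe_win + g$safe_lose) *
      sqrt(g$safe_p_win * (1 - g$safe_p_win))
    sd_risky <- (g$risky_win + g$risky_lose) *
      sqrt(g$risky_p_win * (1 - g$risky_p_win))
    valence <- sign(ev$ev_safe + ev$ev_risky)
    plogis(ev_weight * (ev$ev_risky - ev$ev_safe) -
             risk_weight * valence * (sd_risky - sd_safe))
  }
}

#' @rdname policy_prospect
#' @export
policy_constant <- function(p = 0.5) {
  force(p)
  function(g) p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
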