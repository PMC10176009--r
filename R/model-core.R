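#' Learning-rule primitives of the PEIRS model
#'
#' `update_q()` is the delta-rule update of a stimulus's expected mean value,
#' `Q <- Q + alpha_q * (r - Q)`. `update_s()` is the analogous update of the
#' expected outcome spread from the unsigned prediction error,
#' `S <- S + alpha_s * (|r - Q| - S)`; with rewards i.i.d. around `Q` the
#' spread converges to the mean absolute deviation of the reward distribution
#' (`sigma * sqrt(2/pi)` for a Gaussian). Both are applied only to the chosen
#' stimulus.
#'
#' @param q Current mean-value estimate (points).
#' @param s Current spread estimate (points, >= 0).
#' @param reward Observed reward (points).
#' @param alpha_q,alpha_s Learning rates in (0, 1).
#' @return Updated estimate (vectorized over the inputs).
#' @export
#' @examples
#' update_q(50, 65, 0.2) # 53
#' update_s(5, 50, 50, 0.5) # 2.5
update_q <- function(q, reward, alpha_q) {
  q + alpha_q * (reward - q)
}

#' @rdname update_q
#' @export
update_s <- function(s, q, reward, alpha_s) {
  s + alpha_s * (abs(reward - q) - s)
}

#' Context signal of a trial
#'
#' The signed difference between the average estimated value of the stimuli
#' offered on the current trial and the average estimated value of all four
#' stimuli in the current set. With value estimates at the true means (35,
#' 35, 65, 65), a high-reward context trial has a context signal of +15 points
#' and a low-reward context trial -15 points. For forced trials and
#' single-stimulus ratings the presented set is the single stimulus.
#'
#' @param q_presented Value estimates of the offered stimuli (length 1 or 2).
#' @param q_all Value estimates of all stimuli in the current set.
#' @return The context signal in points.
#' @export
#' @examples
#' delta_context(c(65, 65), c(35, 35, 65, 65)) # +15
#' delta_context(c(35, 35), c(35, 35, 65, 65)) # -15
delta_context <- function(q_presented, q_all) {
  if (length(q_presented) == 0) stop("empty presented set", call. = FALSE)
  mean(q_presented) - mean(q_all)
}

#' PEIRS utility of an option
#'
#' `U = Q + gamma0 * S + gamma1 * delta * S`: the learned mean value plus a
#' baseline risk-propensity weighting of the spread plus a context-modulated
#' weighting of the spread. With `gamma0 = gamma1 = 0` this reduces to the
#' Rescorla-Wagner utility `U = Q`.
#'
#' @param q,s Mean-value and spread estimates of the option.
#' @param delta Context signal of the trial, see [delta_context()].
#' @param params Parameter vector, see [peirs_params()].
#' @return Utility in points (vectorized over `q`, `s`).
#' @export
#' @examples
#' peirs_utility(65, 20, 0, peirs_params(0.3, 0.3, 0.1, gamma0 = 0.1)) # 67
peirs_utility <- function(q, s, delta, params) {
  p <- as_params(params)
  q + p[["gamma0"]] * s + p[["gamma1"]] * delta * s
}

#' Softmax probability of the chosen option
#'
#' Logistic choice rule `P = 1 / (1 + exp(-beta * (U_chosen - U_unchosen)))`,
#' computed in log-space so it is stable for arbitrarily large utility
#' differences.
#'
#' @param u_chosen,u_unchosen Utilities of the chosen and unchosen options.
#' @param beta Softmax inverse temperature (>= 0).
#' @param log Return the log-probability instead.
#' @return Choice probability (or its log), vectorized.
#' @export
#' @examples
#' choice_probability(10, 0, 0.1) # 0.731...
choice_probability <- function(u_chosen, u_unchosen, beta, log = FALSE) {
  x <- beta * (u_chosen - u_unchosen)
  lp <- ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))
  if (log) lp else exp(lp)
}

# convert a completed trial tibble into integer-indexed vectors for the
# likelihood kernel; stimuli give the id -> index mapping and set membership
prepare_session <- function(trials, stimuli) {
  req <- c("trial_type", "option_left", "option_right", "chosen", "reward")
  missing <- setdiff(req, names(trials))
  if (length(missing) > 0)
    stop("trials are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  trials <- trials[order(trials$trial), ]
  ch <- match(trials$chosen, stimuli$id)
  if (anyNA(ch)) stop("chosen stimulus not in the stimulus table", call. = FALSE)
  if (anyNA(trials$reward))
    stop("missing reward on a taken action", call. = FALSE)
  other_id <- ifelse(trials$chosen == trials$option_left,
                     trials$option_right, trials$option_left)
  ot <- match(other_id, stimuli$id)
  ot[is.na(other_id)] <- 0L # forced trials: no alternative
  list(chosen = as.integer(ch), other = as.integer(ot),
       reward = as.numeric(trials$reward),
       stim_set = as.integer(stimuli$set), n_stim = nrow(stimuli))
}

#' Session log-likelihood of a choice sequence
#'
#' Runs a single forward pass over a completed session from the initial
#' estimates `Q = 50`, `S = 5`. Every trial (including forced-sampling
#' trials) updates the chosen stimulus's Q and S with the observed outcome;
#' only two-option trials contribute a softmax log-probability term, since a
#' forced trial's single option is taken with probability 1. Under
#' `model = "rw"` both risk weights are pinned at zero, so utilities reduce
#' to the Q values.
#'
#' @param params Parameter vector on the natural scale, see [peirs_params()].
#' @param trials Completed session tibble (columns `trial`, `trial_type`,
#'   `option_left`, `option_right`, `chosen`, `reward`).
#' @param stimuli Stimulus definitions, see [default_stimuli()].
#' @param model `"peirs"` or `"rw"`.
#' @param q0,s0 Initial estimates (defaults 50 and 5 points).
#' @return The summed log-likelihood over choice trials.
#' @export
session_loglik <- function(params, trials, stimuli = default_stimuli(),
                           model = c("peirs", "rw"), q0 = 50, s0 = 5) {
  model <- match.arg(model)
  p <- validate_params(as_params(params))
  if (model == "rw") p[c("gamma0", "gamma1")] <- 0
  ses <- prepare_session(trials, stimuli)
  ll <- peirs_loglik_cpp(ses$chosen, ses$other, ses$reward, ses$stim_set,
                         ses$n_stim, q0, s0,
                         p[["alpha_q"]], p[["alpha_s"]], p[["beta"]],
                         p[["gamma0"]], p[["gamma1"]])
  if (!is.finite(ll)) stop("non-finite session log-likelihood", call. = FALSE)
  ll
}

#' Replay a session through the model in pure R
#'
#' Independent (non-compiled) forward pass used to expose the full latent
#' trace: per-trial Q/S state, context signal, utilities, and choice
#' probabilities. [session_loglik()] must equal the sum of the logged choice
#' probabilities of this replay to machine precision.
#'
#' @inheritParams session_loglik
#' @return A list with `trace` (one row per trial: `trial`, `chosen`,
#'   `reward`, `delta`, `u_chosen`, `u_unchosen`, `p_chosen`, `q_chosen`,
#'   `s_chosen` -- the post-update state of the chosen stimulus), `q`/`s`
#'   (state matrices, `n_trials + 1` rows including the initial state), and
#'   `loglik`.
#' @export
replay_session <- function(params, trials, stimuli = default_stimuli(),
                           model = c("peirs", "rw"), q0 = 50, s0 = 5) {
  model <- match.arg(model)
  p <- validate_params(as_params(params))
  if (model == "rw") p[c("gamma0", "gamma1")] <- 0
  ses <- prepare_session(trials, stimuli)
  n <- length(ses$chosen)
  n_stim <- ses$n_stim
  q <- rep(q0, n_stim); s <- rep(s0, n_stim)
  qm <- matrix(NA_real_, n + 1, n_stim); sm <- matrix(NA_real_, n + 1, n_stim)
  qm[1, ] <- q; sm[1, ] <- s
  delta <- u_c <- u_u <- p_c <- rep(NA_real_, n)
  ll <- 0
  for (t in seq_len(n)) {
    ch <- ses$chosen[t]; ot <- ses$other[t]
    if (ot > 0L) {
      members <- ses$stim_set == ses$stim_set[ch]
      delta[t] <- delta_context(q[c(ch, ot)], q[members])
      u_c[t] <- peirs_utility(q[ch], s[ch], delta[t], p)
      u_u[t] <- peirs_utility(q[ot], s[ot], delta[t], p)
      lp <- choice_probability(u_c[t], u_u[t], p[["beta"]], log = TRUE)
      p_c[t] <- exp(lp)
      ll <- ll + lp
    }
    r <- ses$reward[t]
    s[ch] <- update_s(s[ch], q[ch], r, p[["alpha_s"]])
    q[ch] <- update_q(q[ch], r, p[["alpha_q"]])
    qm[t + 1, ] <- q; sm[t + 1, ] <- s
  }
  colnames(qm) <- colnames(sm) <- stimuli$id
  trace <- tibble::tibble(
    trial = sort(trials$trial), chosen = stimuli$id[ses$chosen],
    reward = ses$reward, delta = delta, u_chosen = u_c, u_unchosen = u_u,
    p_chosen = p_c,
    q_chosen = qm[cbind(seq_len(n) + 1, ses$chosen)],
    s_chosen = sm[cbind(seq_len(n) + 1, ses$chosen)]
  )
  list(trace = trace, q = qm, s = sm, loglik = ll)
}
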