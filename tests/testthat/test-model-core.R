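test_that("value and spread updates follow the delta rules", {
  # zero prediction error leaves the value unchanged
  expect_equal(update_q(50, 50, 0.37), 50)
  expect_equal(update_q(50, 65, 0.2), 53)
  # learning rate 1 jumps straight to the reward
  expect_equal(update_q(12, 80, 1), 80)
  # spread fixed point: |r - q| equal to the current spread
  expect_equal(update_s(5, 60, 65, 0.9), 5)
  expect_equal(update_s(5, 50, 50, 0.5), 2.5)
})

test_that("the spread converges to the mean absolute deviation of outcomes", {
  # for Gaussian rewards E|r - mu| = sigma * sqrt(2/pi)
  set.seed(42)
  sigma <- 20
  r <- rnorm(20000, 65, sigma)
  s <- 5
  trace <- numeric(length(r))
  for (i in seq_along(r)) {
    s <- update_s(s, 65, r[i], 0.05)
    trace[i] <- s
  }
  expect_equal(mean(trace[10001:20000]), sigma * sqrt(2 / pi),
               tolerance = 0.02)
  expect_true(all(trace >= 0))
})

test_that("the context signal matches the true-mean reference values", {
  expect_equal(delta_context(c(65, 65), c(35, 35, 65, 65)), 15)
  expect_equal(delta_context(c(35, 35), c(35, 35, 65, 65)), -15)
  expect_equal(delta_context(c(50), rep(50, 4)), 0)
  # symmetric design: context signals of high and low trials cancel
  expect_equal(delta_context(c(65, 65), c(35, 35, 65, 65)) +
                 delta_context(c(35, 35), c(35, 35, 65, 65)), 0)
  expect_error(delta_context(numeric(0), rep(50, 4)), "empty")
})

test_that("the utility combines value, spread, and context as specified", {
  expect_equal(peirs_utility(65, 20, 0, peirs_params(0.3, 0.3, 1, 0, 0)), 65)
  expect_equal(peirs_utility(65, 20, 0, peirs_params(0.3, 0.3, 1, 0.1, 0)), 67)
  expect_equal(peirs_utility(35, 20, -15,
                             peirs_params(0.3, 0.3, 1, 0, 0.05)), 20)
})

test_that("the softmax choice rule is correct and numerically stable", {
  expect_equal(choice_probability(10, 10, 0.5), 0.5)
  expect_equal(choice_probability(90, 10, 0), 0.5)
  expect_equal(choice_probability(10, 0, 0.1), 1 / (1 + exp(-1)))
  # extreme utility differences stay finite in log space
  expect_equal(choice_probability(1e4, 0, 1), 1)
  lp <- choice_probability(0, 1e4, 1, log = TRUE)
  expect_true(is.finite(lp) && lp < -9999)
})

test_that("session log-likelihood matches a trial-by-trial hand computation", {
  # independent spreadsheet-style oracle: every state written out explicitly
  p <- peirs_params(alpha_q = 0.2, alpha_s = 0.5, beta = 0.1,
                    gamma0 = 0.1, gamma1 = 0.05)
  trials <- toy_session()

  # trial 1: forced D, r = 80; no choice term
  sD <- 5 + 0.5 * (abs(80 - 50) - 5)   # 17.5
  qD <- 50 + 0.2 * (80 - 50)           # 56
  # trial 2: offered C/D, chose D, r = 70
  qall <- (50 + 50 + 50 + qD) / 4
  delta <- (50 + qD) / 2 - qall
  uD <- qD + 0.1 * sD + 0.05 * delta * sD
  uC <- 50 + 0.1 * 5 + 0.05 * delta * 5
  ll <- log(plogis(0.1 * (uD - uC)))
  sD <- sD + 0.5 * (abs(70 - qD) - sD); qD <- qD + 0.2 * (70 - qD)
  # trial 3: offered A/B, chose A, r = 30; A and B identical -> p = 0.5
  ll <- ll + log(0.5)
  sA <- 5 + 0.5 * (abs(30 - 50) - 5); qA <- 50 + 0.2 * (30 - 50)
  # trial 4: offered C/B, chose C, r = 60; C and B identical -> p = 0.5
  ll <- ll + log(0.5)
  sC <- 5 + 0.5 * (abs(60 - 50) - 5); qC <- 50 + 0.2 * (60 - 50)
  # trial 5: offered D/C, chose C, r = 55
  qall <- (qA + 50 + qC + qD) / 4
  delta <- (qC + qD) / 2 - qall
  uC <- qC + 0.1 * sC + 0.05 * delta * sC
  uD <- qD + 0.1 * sD + 0.05 * delta * sD
  ll <- ll + log(plogis(0.1 * (uC - uD)))
  sC <- sC + 0.5 * (abs(55 - qC) - sC); qC <- qC + 0.2 * (55 - qC)
  # trial 6: offered B/A, chose B, r = 20
  qall <- (qA + 50 + qC + qD) / 4
  delta <- (50 + qA) / 2 - qall
  uB <- 50 + 0.1 * 5 + 0.05 * delta * 5
  uA <- qA + 0.1 * sA + 0.05 * delta * sA
  ll <- ll + log(plogis(0.1 * (uB - uA)))

  expect_equal(session_loglik(p, trials), ll, tolerance = 1e-12)
  # frozen value computed from the arithmetic above
  expect_equal(ll, -3.489299644891528, tolerance = 1e-10)
})

test_that("compiled likelihood equals the pure-R replay exactly", {
  p <- default_params()
  sim <- quick_sim(p)
  rep <- replay_session(p, sim$trials)
  expect_equal(session_loglik(p, sim$trials), rep$loglik, tolerance = 1e-13)
  expect_equal(rep$loglik, sum(log(rep$trace$p_chosen), na.rm = TRUE),
               tolerance = 1e-13)
  # the replay reproduces the simulator's latent trace exactly
  expect_identical(rep$q, sim$q)
  expect_identical(rep$s, sim$s)
  # per-trial probabilities are proper probabilities
  pc <- rep$trace$p_chosen[!is.na(rep$trace$p_chosen)]
  expect_true(all(pc > 0 & pc <= 1))
  # same under the RW model
  rep_rw <- replay_session(p, sim$trials, model = "rw")
  expect_equal(session_loglik(p, sim$trials, model = "rw"), rep_rw$loglik,
               tolerance = 1e-13)
})

test_that("beta = 0 gives n * log(1/2) over choice trials", {
  p <- peirs_params(0.3, 0.3, beta = 0, gamma0 = 0.2, gamma1 = 0.1)
  sim <- quick_sim()
  n_choice <- sum(sim$trials$trial_type != "forced")
  expect_equal(session_loglik(p, sim$trials), n_choice * log(0.5))
})

test_that("the generating parameters score at least as well as perturbations", {
  p_true <- default_params()
  set.seed(8)
  sims <- lapply(1:4, function(i) quick_sim(p_true, seed = 100 + i,
                                            sched_seed = 200 + i))
  total_ll <- function(p) sum(vapply(sims, function(s)
    session_loglik(p, s$trials), numeric(1)))
  ll_true <- total_ll(p_true)
  perturb <- list(
    c(alpha_q = 0.35), c(alpha_q = -0.2), c(alpha_s = 0.4),
    c(beta = 0.2), c(beta = -0.1), c(gamma0 = 0.3), c(gamma1 = 0.06),
    c(gamma1 = -0.05)
  )
  for (d in perturb) {
    p2 <- p_true
    p2[names(d)] <- p_true[names(d)] + d
    expect_lt(total_ll(p2), ll_true + 1e-6)
  }
})

test_that("sessions with missing data fail loudly", {
  trials <- toy_session()
  trials$reward[3] <- NA
  expect_error(session_loglik(default_params(), trials), "missing reward")
  trials2 <- dplyr::select(toy_session(), -"chosen")
  expect_error(session_loglik(default_params(), trials2), "chosen")
})
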