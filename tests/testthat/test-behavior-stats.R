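test_that("experience-task risk preferences match a hand count on a toy log", {
  trials <- tibble::tibble(
    trial = 1:8, block = 1L, set = 1L,
    trial_type = c("high", "low", "mixed", "forced",
                   "high", "low", "mixed", "mixed"),
    option_left = c("C", "A", "C", "B", "C", "A", "A", "D"),
    option_right = c("D", "B", "B", NA, "D", "B", "C", "B"),
    chosen = c("C", "B", "C", "B", "D", "A", "A", "D"),
    reward = 50
  )
  pref <- risk_preference_experience(trials)
  # second half = trials 5-8; high trial 5 chose D (high-spread) -> 1;
  # low trial 6 chose A (low-spread) -> 0; mixed accuracy over all mixed
  # trials: C correct, A incorrect, D correct -> 2/3
  expect_equal(pref$p_risky_high, 1)
  expect_equal(pref$p_risky_low, 0)
  expect_equal(pref$accuracy_mixed, 2 / 3)
  expect_equal(pref$n_high, 1)
  expect_equal(pref$n_mixed, 3)
})

test_that("an always-risky agent scores 1 in both contexts", {
  sched <- experience_schedule(seed = 2)
  stim <- default_stimuli()
  sd_of <- function(id) stim$sd[match(id, stim$id)]
  trials <- dplyr::mutate(
    sched,
    chosen = ifelse(is.na(option_right), option_left,
                    ifelse(sd_of(option_left) >= sd_of(option_right),
                           option_left, option_right)),
    reward = 50)
  pref <- risk_preference_experience(trials)
  expect_equal(pref$p_risky_high, 1)
  expect_equal(pref$p_risky_low, 1)
})

test_that("description-task preferences come from the right gambles", {
  sched <- description_schedule(seed = 3)
  trials <- dplyr::mutate(sched,
                          chosen = ifelse(gamble_id == 9, "risky", "safe"),
                          outcome = 0)
  pref <- risk_preference_description(trials)
  expect_equal(pref$p_risky_low, 1)   # gamble 9 = low-reward context
  expect_equal(pref$p_risky_high, 0)  # gamble 10 = high-reward context
  # EV-maximizer accuracy 1 and equal-EV gambles do not crash
  g <- gamble_expected_values(default_gambles())
  best <- ifelse(g$ev_risky > g$ev_safe, "risky", "safe")
  trials2 <- dplyr::mutate(sched, chosen = best[gamble_id], outcome = 0)
  pref2 <- risk_preference_description(trials2)
  expect_equal(pref2$accuracy_mixed, 1)
  expect_true(is.finite(pref2$p_risky_low))
})

test_that("the 2x2 within ANOVA F equals the squared paired t exactly", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    df <- tidyr::expand_grid(subject = seq_len(n),
                             a = c("x", "y"), b = c("p", "q"))
    df$value <- rnorm(nrow(df))
    out <- rm_anova_2x2(df, dv = "value", within = c("a", "b"))
    wide <- tidyr::pivot_wider(df, names_from = c("a", "b"),
                               values_from = "value")
    # contrasts matching the three effects
    dA <- (wide$y_p + wide$y_q) / 2 - (wide$x_p + wide$x_q) / 2
    dB <- (wide$x_q + wide$y_q) / 2 - (wide$x_p + wide$y_p) / 2
    dAB <- (wide$y_q - wide$y_p) - (wide$x_q - wide$x_p)
    t_of <- function(d) mean(d) / (sd(d) / sqrt(n))
    expect_equal(out$F[out$effect == "a"], t_of(dA)^2, tolerance = 1e-10)
    expect_equal(out$F[out$effect == "b"], t_of(dB)^2, tolerance = 1e-10)
    expect_equal(out$F[out$effect == "a:b"], t_of(dAB)^2, tolerance = 1e-10)
    expect_true(all(out$df1 == 1) && all(out$df2 == n - 1))
    expect_true(all(out$partial_eta_sq >= 0 & out$partial_eta_sq <= 1))
  }
})

test_that("the 2x2 within ANOVA matches aov with an error stratum", {
  set.seed(11)
  df <- tidyr::expand_grid(subject = factor(1:12),
                           a = factor(c("x", "y")), b = factor(c("p", "q")))
  df$value <- rnorm(nrow(df)) + as.numeric(df$a) * 0.5 +
    as.numeric(df$a) * as.numeric(df$b) * 0.3
  out <- rm_anova_2x2(df, dv = "value", within = c("a", "b"))
  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = df)
  sm <- summary(fit)
  f_aov <- c(
    a = sm[["Error: subject:a"]][[1]]["a", "F value"],
    b = sm[["Error: subject:b"]][[1]]["b", "F value"],
    ab = sm[["Error: subject:a:b"]][[1]]["a:b", "F value"])
  expect_equal(out$F[out$effect == "a"], unname(f_aov["a"]), tolerance = 1e-8)
  expect_equal(out$F[out$effect == "b"], unname(f_aov["b"]), tolerance = 1e-8)
  expect_equal(out$F[out$effect == "a:b"], unname(f_aov["ab"]),
               tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs are flagged, not crashed", {
  df <- tidyr::expand_grid(subject = 1:6, a = c("x", "y"), b = c("p", "q"))
  df$value <- 1 # identical cells for every subject
  out <- rm_anova_2x2(df, dv = "value", within = c("a", "b"))
  expect_true(all(out$zero_variance))
  expect_true(all(is.na(out$F)))
  df2 <- df[df$subject != 1 | df$a != "x" | df$b != "p", ]
  expect_error(rm_anova_2x2(df2, dv = "value", within = c("a", "b")),
               "all four cells")
})

test_that("wilcoxon signed-rank matches the exact enumeration null", {
  # 10-pair example with distinct magnitudes
  d <- c(4.2, -1.1, 3.3, 2.0, -0.4, 5.6, 7.1, -2.5, 6.0, 1.7)
  got <- wilcoxon_signed_rank(d)
  r <- rank(abs(d))
  expect_equal(got$statistic, sum(r[d > 0]))
  # exact two-sided p by enumerating all 2^10 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  w_all <- signs %*% r
  w_obs <- sum(r[d > 0])
  mu <- 10 * 11 / 4
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu))
  expect_lt(abs(got$p - p_exact), 0.02)
  # and the z/p agree with the reference normal-approximation implementation
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("wilcoxon handles zeros, ties, and the extreme case", {
  # mirror pairs: symmetric differences give z near 0
  d <- c(-5, -3, -1, 1, 3, 5, 0)
  got <- wilcoxon_signed_rank(d)
  expect_equal(got$n_zero, 1L)
  expect_equal(got$n_used, 6L)
  expect_lt(abs(got$z), 0.2)
  # ties against the reference implementation
  dt <- c(2, 2, -2, 5, 5, -1, 3, 3)
  ref <- stats::wilcox.test(dt, exact = FALSE, correct = TRUE)
  expect_equal(wilcoxon_signed_rank(dt)$p, ref$p.value, tolerance = 1e-12)
  # all positive, n = 32: z at its closed-form maximum
  n <- 32
  z_max <- (n * (n + 1) / 4 - 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(wilcoxon_signed_rank(rep(1, n) + runif(n))$z, z_max)
  # all zero differences: undefined, flagged
  expect_true(is.na(wilcoxon_signed_rank(rep(0, 5))$z))
})

test_that("stimulus utilities match a hand-computed four-stimulus example", {
  lat <- tibble::tibble(id = c("A", "B", "C", "D"), set = 1,
                        q = c(35, 35, 65, 65), s = c(4, 16, 4, 16))
  p <- peirs_params(0.3, 0.3, 0.15, gamma0 = 0, gamma1 = 0.05)
  u <- stimulus_utility(lat, p)
  # delta = q - 50; utility = q + 0.05 * delta * s
  expect_equal(u$utility, c(35 - 0.05 * 15 * 4, 35 - 0.05 * 15 * 16,
                            65 + 0.05 * 15 * 4, 65 + 0.05 * 15 * 16))
  # positive gamma1: utility of the risky option is amplified by context
  expect_gt(u$utility[u$id == "D"], u$utility[u$id == "C"])
  expect_lt(u$utility[u$id == "B"], u$utility[u$id == "A"])
  # gammas at zero reduce utilities to the value estimates
  u0 <- stimulus_utility(lat, peirs_params(0.3, 0.3, 0.15, 0, 0))
  expect_equal(u0$utility, lat$q)
})

test_that("paired t reports Cohen's d_z and flags zero variance", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  got <- paired_t(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_equal(got$cohens_dz, mean(x - y) / sd(x - y))
  expect_true(paired_t(as.numeric(1:12), as.numeric(2:13))$zero_variance)
})
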