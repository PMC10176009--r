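test_that("an infinitely tight prior pins the MAP at the prior mean", {
  sim <- quick_sim(n_blocks = 1)
  mu <- c(alpha_q = -0.4, alpha_s = -0.9, beta = -1.8, gamma0 = 0.1,
          gamma1 = 0.02)
  tight <- peirs_prior(mean = mu, var = rep(1e-8, 5) |>
                         setNames(names(mu)))
  f <- fit_subject_map(sim$trials, prior = tight, model = "peirs",
                       n_starts = 2)
  expect_equal(unname(f$map_u), unname(mu), tolerance = 1e-3)
})

test_that("flat-prior MAP matches a dense grid search on two free parameters", {
  # long session; alpha_s, gamma0, gamma1 pinned at truth via a near-delta
  # prior, so only alpha_q and beta are effectively free under a flat prior
  p_true <- default_params()
  stim <- default_stimuli(n_sets = 4)
  sched <- experience_schedule(n_blocks = 8, stimuli = stim, seed = 71)
  sim <- simulate_subject(p_true, sched, stimuli = stim, seed = 72)
  truth_u <- to_unconstrained(p_true)
  flat <- peirs_prior(mean = truth_u,
                      var = setNames(rep(1e4, 5), names(truth_u)))
  f <- fit_subject_map(sim$trials, prior = flat, model = "peirs",
                       stimuli = stim, n_starts = 4,
                       fixed = truth_u[c("alpha_s", "gamma0", "gamma1")])
  # independent oracle: dense likelihood grid over (alpha_q_u, beta_u)
  grid_aq <- seq(truth_u[["alpha_q"]] - 1.5, truth_u[["alpha_q"]] + 1.5,
                 length.out = 41)
  grid_b <- seq(truth_u[["beta"]] - 1, truth_u[["beta"]] + 1,
                length.out = 41)
  ll <- matrix(NA_real_, 41, 41)
  for (i in seq_along(grid_aq)) {
    for (j in seq_along(grid_b)) {
      x <- truth_u
      x[["alpha_q"]] <- grid_aq[i]
      x[["beta"]] <- grid_b[j]
      ll[i, j] <- session_loglik(to_natural(x), sim$trials, stimuli = stim)
    }
  }
  best <- which(ll == max(ll), arr.ind = TRUE)
  step_aq <- diff(grid_aq[1:2])
  step_b <- diff(grid_b[1:2])
  expect_lt(abs(f$map_u[["alpha_q"]] - grid_aq[best[1]]), step_aq)
  expect_lt(abs(f$map_u[["beta"]] - grid_b[best[2]]), step_b)
  # and the optimizer's optimum is at least as good as the grid's
  expect_gte(session_loglik(f$map, sim$trials, stimuli = stim),
             max(ll) - 1e-6)
})

test_that("the RW model pins both risk weights at zero with k = 3", {
  sim <- quick_sim(n_blocks = 1)
  f <- fit_subject_map(sim$trials, model = "rw", n_starts = 3)
  expect_equal(f$map[["gamma0"]], 0)
  expect_equal(f$map[["gamma1"]], 0)
  expect_length(f$post_var, 3)
  expect_equal(f$bic, -2 * f$loglik + 3 * log(f$n_choice))
})

test_that("BIC follows the formula and penalizes extra parameters", {
  expect_equal(peirs:::bic_value(-90, 5, 144), 180 + 5 * log(144))
  expect_equal(180 + 5 * log(144), 204.8552, tolerance = 1e-4)
  # identical log-likelihoods: the smaller model wins
  expect_lt(peirs:::bic_value(-90, 3, 144), peirs:::bic_value(-90, 5, 144))
})

test_that("PEIRS MAP likelihood dominates RW on every subject (nested models)", {
  pars <- sample_population(population_spec(), n = 3, seed = 41)
  coh <- simulate_cohort(pars, seed = 42,
                         schedule_args = list(n_blocks = 2))
  for (s in 1:3) {
    d <- coh$trials[coh$trials$subject == s, ]
    flat <- peirs_prior(var = c(alpha_q = 100, alpha_s = 100, beta = 100,
                                gamma0 = 100, gamma1 = 100))
    f_p <- fit_subject_map(d, prior = flat, model = "peirs", n_starts = 6)
    f_rw <- fit_subject_map(d, prior = flat, model = "rw", n_starts = 6)
    expect_gte(f_p$loglik, f_rw$loglik - 1e-4)
  }
})

test_that("a single EM iteration with a frozen prior equals independent MAP fits", {
  pars <- sample_population(population_spec(), n = 3, seed = 51)
  coh <- simulate_cohort(pars, seed = 52,
                         schedule_args = list(n_blocks = 1))
  pr <- peirs_prior()
  fit <- fit_population_em(coh$trials, model = "peirs", prior = pr,
                           max_iter = 1, n_starts = 4)
  for (s in 1:3) {
    d <- coh$trials[coh$trials$subject == s, ]
    set.seed(1); ind <- fit_subject_map(d, prior = pr, model = "peirs",
                                        n_starts = 8)
    got <- fit$fits[fit$fits$subject == s, ]
    expect_equal(got$loglik, ind$loglik, tolerance = 1e-4)
    expect_equal(unname(unlist(got[paste0(names(ind$map), "_u")])),
                 unname(ind$map_u), tolerance = 0.02)
  }
})

test_that("EM recovers a degenerate population of identical agents", {
  p_true <- peirs_params(0.35, 0.3, 0.18, gamma0 = 0.15, gamma1 = 0.03)
  truth_u <- to_unconstrained(p_true)
  pars <- dplyr::bind_rows(lapply(1:8, function(i)
    tibble::as_tibble(as.list(p_true))))
  pars$subject <- 1:8
  coh <- simulate_cohort(pars, seed = 61)
  fit <- fit_population_em(coh$trials, model = "peirs", max_iter = 30,
                           n_starts = 6)
  # prior mean near the shared truth on the well-identified parameters
  got <- setNames(fit$prior$mean, fit$prior$param)
  expect_lt(abs(got[["alpha_q"]] - truth_u[["alpha_q"]]), 0.35)
  expect_lt(abs(got[["beta"]] - truth_u[["beta"]]), 0.25)
  expect_lt(abs(got[["gamma0"]] - truth_u[["gamma0"]]), 0.1)
  expect_lt(abs(got[["gamma1"]] - truth_u[["gamma1"]]), 0.015)
  # prior variances shrink well below their starting values
  expect_true(all(fit$prior$var < peirs_prior()$var[fit$prior$param] / 4))
})

test_that("model comparison counts per-subject BIC preferences", {
  fits_rw <- structure(list(
    model = "rw",
    fits = tibble::tibble(subject = 1:3, bic = c(100, 200, 300))),
    class = "peirs_pop_fit")
  fits_p <- structure(list(
    model = "peirs",
    fits = tibble::tibble(subject = 1:3, bic = c(90, 210, 290))),
    class = "peirs_pop_fit")
  cmp <- compare_models(fits_rw, fits_p)
  expect_equal(cmp$n_pref_peirs, 2)
  expect_equal(cmp$bic_total_rw, 600)
  expect_equal(cmp$bic_total_peirs, 590)
  expect_equal(cmp$by_subject$preferred, c("peirs", "rw", "peirs"))
  fits_bad <- structure(list(
    model = "peirs",
    fits = tibble::tibble(subject = 4:6, bic = 1)), class = "peirs_pop_fit")
  expect_error(compare_models(fits_rw, fits_bad), "different subject sets")
})

test_that("condition comparisons report Bonferroni-corrected paired tests", {
  mk <- function(shift, seed) {
    set.seed(seed)
    u <- matrix(rnorm(8 * 5), 8, 5)
    u[, 5] <- u[, 5] + shift
    colnames(u) <- paste0(peirs:::peirs_param_names(), "_u")
    structure(list(model = "peirs",
                   fits = dplyr::bind_cols(tibble::tibble(subject = 1:8),
                                           tibble::as_tibble(u))),
              class = "peirs_pop_fit")
  }
  out <- compare_condition_params(mk(4, seed = 3), mk(0, seed = 4))
  expect_equal(nrow(out), 5)
  expect_true(all(out$p_bonferroni >= out$p))
  expect_lt(out$p_bonferroni[out$param == "gamma1"], 0.05)
})
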