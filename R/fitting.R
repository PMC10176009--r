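#' Construct a population prior
#'
#' Per-parameter Gaussian prior on the unconstrained scale. The default is a
#' weakly informative, scale-aware starting prior for the EM procedure: wide
#' on the transformed learning rates and the log inverse temperature, and
#' matched to the natural magnitude of the risk weights (which act on a
#' points x spread product, so values of order 0.01-0.3 already produce large
#' behavioral effects).
#'
#' @param mean,var Named length-5 vectors on the unconstrained scale. For the
#'   RW model only the first three entries are used.
#' @return A list of class `peirs_prior`.
#' @export
peirs_prior <- function(mean = c(alpha_q = 0, alpha_s = 0, beta = -2,
                                 gamma0 = 0, gamma1 = 0),
                        var = c(alpha_q = 2.25, alpha_s = 2.25, beta = 1,
                                gamma0 = 0.25, gamma1 = 0.01)) {
  mean <- mean[peirs_param_names()]
  var <- var[peirs_param_names()]
  stopifnot(!anyNA(mean), !anyNA(var), all(var > 0))
  structure(list(mean = mean, var = var), class = "peirs_prior")
}

# negative penalized objective on the unconstrained scale, restricted to the
# model's free parameters (RW: gammas fixed at 0); `fixed` pins named
# parameters at given unconstrained values (diagnostic use)
make_objective <- function(ses, prior, model, fixed = NULL, q0 = 50, s0 = 5) {
  free <- setdiff(model_free_params(model), names(fixed))
  mu <- prior$mean[free]
  sdv <- sqrt(prior$var[free])
  base <- setNames(numeric(5), peirs_param_names())
  if (!is.null(fixed)) base[names(fixed)] <- fixed
  function(x) {
    full <- base
    full[free] <- x
    nat <- to_natural(full)
    ll <- peirs_loglik_cpp(ses$chosen, ses$other, ses$reward, ses$stim_set,
                           ses$n_stim, q0, s0,
                           nat[["alpha_q"]], nat[["alpha_s"]], nat[["beta"]],
                           nat[["gamma0"]], nat[["gamma1"]])
    lp <- sum(dnorm(x, mu, sdv, log = TRUE))
    obj <- -(ll + lp)
    if (!is.finite(obj)) obj <- .Machine$double.xmax / 1e6
    obj
  }
}

#' Maximum-a-posteriori fit of one subject
#'
#' Maximizes the session log-likelihood plus a Gaussian log-prior on the
#' unconstrained parameter scale, using multistart BFGS (the prior mean plus
#' prior draws as starting points). Forced trials contribute to the learning
#' updates inside the likelihood but carry no choice term. The returned
#' log-likelihood is the likelihood-only value at the MAP; posterior
#' curvature is summarized by the Laplace approximation (diagonal of the
#' inverse Hessian of the negative objective).
#'
#' @param trials Completed session tibble for one subject.
#' @param prior A [peirs_prior()].
#' @param model `"peirs"` (5 free parameters) or `"rw"` (3; both risk weights
#'   pinned at 0).
#' @param stimuli Stimulus definitions.
#' @param n_starts Number of optimizer starts (default 10).
#' @param init Optional matrix of starting points (rows, unconstrained scale,
#'   free parameters only); used for warm starts inside EM.
#' @param fixed Optional named vector of unconstrained values at which to pin
#'   parameters (they are excluded from optimization and from the prior
#'   term); mainly a diagnostic device for profiling subsets of parameters.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @return A list of class `peirs_subject_fit` with `map_u` (unconstrained
#'   MAP, length 5; pinned entries 0), `map` (natural scale), `loglik`
#'   (likelihood-only), `post_var` (Laplace posterior variances, free
#'   parameters), `n_choice`, `bic`, `objective` (penalized, at the MAP),
#'   `model`, and `convergence` (0 = at least one start converged cleanly).
#' @export
fit_subject_map <- function(trials, prior = peirs_prior(),
                            model = c("peirs", "rw"),
                            stimuli = default_stimuli(), n_starts = 10,
                            init = NULL, fixed = NULL, reltol = 1e-8) {
  model <- match.arg(model)
  free <- setdiff(model_free_params(model), names(fixed))
  k <- length(free)
  ses <- prepare_session(trials, stimuli)
  obj <- make_objective(ses, prior, model, fixed = fixed)

  starts <- rbind(matrix(prior$mean[free], 1),
                  if (n_starts > 1)
                    matrix(rnorm((n_starts - 1) * k, prior$mean[free],
                                 sqrt(prior$var[free])),
                           n_starts - 1, k, byrow = TRUE))
  if (!is.null(init)) starts <- rbind(init, starts)

  best <- NULL
  conv <- 1L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "BFGS",
            control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- 0L
  }
  if (is.null(best))
    stop("all optimizer starts failed for model ", model, call. = FALSE)

  x <- best$par
  h <- tryCatch(optimHess(x, obj), error = function(e) NULL)
  post_var <- laplace_variances(h, prior$var[free])

  map_u <- setNames(numeric(5), peirs_param_names())
  if (!is.null(fixed)) map_u[names(fixed)] <- fixed
  map_u[free] <- x
  nat <- to_natural(map_u)
  n_choice <- sum(ses$other > 0L)
  ll <- peirs_loglik_cpp(ses$chosen, ses$other, ses$reward, ses$stim_set,
                         ses$n_stim, 50, 5,
                         nat[["alpha_q"]], nat[["alpha_s"]], nat[["beta"]],
                         nat[["gamma0"]], nat[["gamma1"]])
  structure(list(map_u = map_u, map = nat, loglik = ll,
                 post_var = setNames(post_var, free),
                 n_choice = n_choice, bic = bic_value(ll, k, n_choice),
                 objective = -best$value, model = model,
                 convergence = conv),
            class = "peirs_subject_fit")
}

# Laplace posterior variances from the Hessian of the negative objective;
# falls back to the diagonal when the full inverse is not positive, and to
# the prior variance (posterior ~ prior under no usable curvature) otherwise
laplace_variances <- function(h, prior_var) {
  if (!is.null(h)) {
    v <- tryCatch(diag(solve(h)), error = function(e) NULL)
    if (!is.null(v) && all(is.finite(v)) && all(v > 0)) return(v)
    d <- diag(h)
    if (all(is.finite(d)) && all(d > 0)) return(1 / d)
  }
  unname(prior_var)
}

bic_value <- function(loglik, k, n_choice) -2 * loglik + k * log(n_choice)

#' Bayesian Information Criterion of a subject fit
#'
#' `BIC = -2 loglik + k log(n)`, with the likelihood-only value at the MAP,
#' `k` free parameters (5 for PEIRS, 3 for RW), and `n` the number of choice
#' (two-option) trials; forced trials carry no choice likelihood and are not
#' counted.
#'
#' @param fit A `peirs_subject_fit`.
#' @return The BIC value.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "peirs_subject_fit"))
  fit$bic
}

#' Hierarchical empirical-Bayes EM fit of a cohort
#'
#' Alternates subject-level MAP fits under the current Gaussian population
#' prior (E-step, with Laplace posterior variances) with moment-matching
#' updates of the prior mean and variance from the fitted cohort (M-step,
#' `var = mean(m^2 + v) - mean(m)^2`), on the unconstrained scale. Iterates
#' until the largest absolute change in any prior mean or variance falls
#' below `tol` or `max_iter` is reached. Conditions are fitted separately by
#' calling this once per condition.
#'
#' @param data Tibble of completed trials with a `subject` column.
#' @param model `"peirs"` or `"rw"`.
#' @param stimuli Stimulus definitions.
#' @param prior Starting prior, see [peirs_prior()].
#' @param tol Convergence tolerance on prior parameters (default 1e-3).
#' @param max_iter Maximum EM iterations (default 100).
#' @param n_starts Optimizer starts for the first E-step (default 10).
#' @param warm_starts Starts on subsequent E-steps (warm-started at the
#'   previous MAP; default 3).
#' @param var_floor Lower floor on prior variances (default 1e-6);
#'   collapsing variances are regularized to the floor with a warning.
#' @param verbose Print per-iteration progress.
#' @return An object of class `peirs_pop_fit`: list with `prior` (final
#'   tibble of per-parameter mean/var), `fits` (per-subject tibble: MAP
#'   parameters on both scales, loglik, n_choice, bic), `subject_fits`
#'   (raw `peirs_subject_fit`s), `model`, `n_iter`, `converged`, and
#'   `objective_trace` (per-iteration penalized-objective totals).
#' @export
fit_population_em <- function(data, model = c("peirs", "rw"),
                              stimuli = default_stimuli(),
                              prior = peirs_prior(), tol = 1e-3,
                              max_iter = 100, n_starts = 10, warm_starts = 3,
                              var_floor = 1e-6, verbose = FALSE) {
  model <- match.arg(model)
  free <- model_free_params(model)
  subjects <- unique(data$subject)
  if (length(subjects) < 2)
    stop("EM fitting needs at least 2 subjects", call. = FALSE)
  sessions <- split(data, data$subject)[as.character(subjects)]

  cur <- prior
  fits <- vector("list", length(subjects))
  converged <- FALSE
  obj_trace <- numeric(0)
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    fits <- purrr::map(seq_along(sessions), function(i) {
      init <- if (iter > 1) matrix(fits[[i]]$map_u[free], 1) else NULL
      fit_subject_map(sessions[[i]], prior = cur, model = model,
                      stimuli = stimuli,
                      n_starts = if (iter > 1) warm_starts else n_starts,
                      init = init)
    })
    m <- do.call(rbind, purrr::map(fits, function(f) f$map_u[free]))
    v <- do.call(rbind, purrr::map(fits, function(f) f$post_var[free]))
    new_mean <- colMeans(m)
    new_var <- colMeans(m^2 + v) - new_mean^2
    if (any(new_var < var_floor)) {
      warning("prior variance floor reached for: ",
              paste(free[new_var < var_floor], collapse = ", "),
              call. = FALSE)
      new_var <- pmax(new_var, var_floor)
    }
    obj_trace <- c(obj_trace, sum(purrr::map_dbl(fits, "objective")))
    delta <- max(abs(new_mean - cur$mean[free]), abs(new_var - cur$var[free]))
    cur$mean[free] <- new_mean
    cur$var[free] <- new_var
    if (verbose)
      message(sprintf("EM iter %d: max prior change %.5f", iter, delta))
    if (delta < tol) { converged <- TRUE; break }
  }

  fits_tbl <- purrr::map2_dfr(fits, subjects, function(f, s) {
    row <- tibble::tibble(subject = s, model = model,
                          loglik = f$loglik, n_choice = f$n_choice,
                          bic = f$bic, convergence = f$convergence)
    nat <- tibble::as_tibble(as.list(f$map))
    u <- tibble::as_tibble(as.list(f$map_u))
    names(u) <- paste0(names(f$map_u), "_u")
    dplyr::bind_cols(row, nat, u)
  })
  structure(list(
    prior = tibble::tibble(param = free, mean = cur$mean[free],
                           var = cur$var[free]),
    fits = fits_tbl, subject_fits = setNames(fits, subjects), model = model,
    n_iter = iter, converged = converged, objective_trace = obj_trace
  ), class = "peirs_pop_fit")
}

#' @method tidy peirs_pop_fit
#' @export
tidy.peirs_pop_fit <- function(x, ...) x$fits

#' @method glance peirs_pop_fit
#' @export
glance.peirs_pop_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_subjects = nrow(x$fits),
                 loglik = sum(x$fits$loglik), bic_total = sum(x$fits$bic),
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
print.peirs_pop_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical EM fit (%s): %d subjects, %d iterations, converged: %s\n",
    x$model, nrow(x$fits), x$n_iter, x$converged))
  cat(sprintf("Total BIC: %.1f\n", sum(x$fits$bic)))
  print(x$prior)
  invisible(x)
}

#' Compare RW and PEIRS fits of the same cohort
#'
#' Per-subject BIC comparison of two model fits on identical datasets, plus
#' cohort totals.
#'
#' @param fit_rw,fit_peirs `peirs_pop_fit` objects for the same subjects.
#' @return An object of class `peirs_model_comparison` with a per-subject
#'   tibble (`$by_subject`: both BICs, `preferred`) and totals. `glance()`
#'   returns the one-row summary.
#' @export
compare_models <- function(fit_rw, fit_peirs) {
  stopifnot(fit_rw$model == "rw", fit_peirs$model == "peirs")
  if (!setequal(fit_rw$fits$subject, fit_peirs$fits$subject))
    stop("the two fits cover different subject sets", call. = FALSE)
  by_subj <- dplyr::inner_join(
    dplyr::select(fit_rw$fits, "subject", bic_rw = "bic"),
    dplyr::select(fit_peirs$fits, "subject", bic_peirs = "bic"),
    by = "subject")
  by_subj$preferred <- ifelse(by_subj$bic_peirs < by_subj$bic_rw,
                              "peirs", "rw")
  structure(list(
    by_subject = by_subj,
    n_pref_peirs = sum(by_subj$preferred == "peirs"),
    n_subjects = nrow(by_subj),
    bic_total_rw = sum(by_subj$bic_rw),
    bic_total_peirs = sum(by_subj$bic_peirs)
  ), class = "peirs_model_comparison")
}

#' @method glance peirs_model_comparison
#' @export
glance.peirs_model_comparison <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_pref_peirs = x$n_pref_peirs,
                 prop_pref_peirs = x$n_pref_peirs / x$n_subjects,
                 bic_total_rw = x$bic_total_rw,
                 bic_total_peirs = x$bic_total_peirs)
}

#' @export
print.peirs_model_comparison <- function(x, ...) {
  cat(sprintf("%d / %d subjects better described by PEIRS (total BIC: RW %.0f, PEIRS %.0f)\n",
              x$n_pref_peirs, x$n_subjects, x$bic_total_rw,
              x$bic_total_peirs))
  invisible(x)
}

#' Compare fitted parameters between two conditions
#'
#' Paired t-tests on the unconstrained MAP parameters of the same subjects
#' fitted separately per condition, Bonferroni-corrected across the
#' parameters, with Cohen's d_z effect sizes.
#'
#' @param fit_a,fit_b `peirs_pop_fit` objects for the same subjects under two
#'   conditions.
#' @return A tibble with one row per parameter: `t`, `df`, `p`, `p_bonferroni`,
#'   `cohens_dz`.
#' @export
compare_condition_params <- function(fit_a, fit_b) {
  stopifnot(fit_a$model == fit_b$model)
  free <- model_free_params(fit_a$model)
  a <- fit_a$fits[order(fit_a$fits$subject), paste0(free, "_u")]
  b <- fit_b$fits[order(fit_b$fits$subject), paste0(free, "_u")]
  stopifnot(nrow(a) == nrow(b))
  out <- purrr::map_dfr(free, function(pn) {
    d <- a[[paste0(pn, "_u")]] - b[[paste0(pn, "_u")]]
    tt <- paired_t(a[[paste0(pn, "_u")]], b[[paste0(pn, "_u")]])
    dplyr::mutate(tt, param = pn, .before = 1)
  })
  out$p_bonferroni <- pmin(1, out$p * length(free))
  out
}
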