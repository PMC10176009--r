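#' Parameter-recovery analysis
#'
#' Verifies the fitting pipeline end to end: sample agent parameters from a
#' population, simulate each agent on its own experience-task schedule, refit
#' the cohort with the hierarchical EM procedure, and correlate generating
#' ("true") against recovered (MAP) parameters on the unconstrained scale.
#' Good recovery shows high diagonal correlations and small off-diagonal
#' (cross-parameter) correlations.
#'
#' @param spec Generating population, see [population_spec()]; the default is
#'   the dispersed default population.
#' @param n Number of agents (default 32).
#' @param seed Run seed.
#' @param schedule_args Arguments for [experience_schedule()].
#' @param stimuli Stimulus definitions.
#' @param ... Passed to [fit_population_em()] (e.g. `tol`, `max_iter`).
#' @return An object of class `peirs_recovery`: list with `true` and
#'   `recovered` (n x 5 unconstrained matrices), `cor_matrix` (5 x 5, true
#'   parameter i vs recovered parameter j), `diag_r`, `max_abs_offdiag`,
#'   `n`, `seed`, and the underlying `fit`. `tidy()` returns the correlation
#'   matrix in long form.
#' @export
#' @examples
#' \donttest{
#' rec <- parameter_recovery(n = 8, seed = 1, max_iter = 5)
#' rec$diag_r
#' }
parameter_recovery <- function(spec = population_spec(), n = 32, seed = NULL,
                               schedule_args = list(),
                               stimuli = default_stimuli(), ...) {
  seeds <- derive_seeds(seed, 2)
  pars <- sample_population(spec, n = n, seed = seeds[1])
  cohort <- simulate_cohort(pars, seed = seeds[2],
                            schedule_args = schedule_args, stimuli = stimuli)
  fit <- fit_population_em(cohort$trials, model = "peirs", stimuli = stimuli,
                           ...)
  pn <- peirs_param_names()
  true_u <- as.matrix(pars[, paste0(pn, "_u")])
  rec_tbl <- fit$fits[match(pars$subject, fit$fits$subject), ]
  rec_u <- as.matrix(rec_tbl[, paste0(pn, "_u")])
  colnames(true_u) <- colnames(rec_u) <- pn
  cm <- cor(true_u, rec_u)
  structure(list(true = true_u, recovered = rec_u, cor_matrix = cm,
                 diag_r = setNames(diag(cm), pn),
                 max_abs_offdiag = max(abs(cm[row(cm) != col(cm)])),
                 n = n, seed = seed, fit = fit),
            class = "peirs_recovery")
}

#' @method tidy peirs_recovery
#' @export
tidy.peirs_recovery <- function(x, ...) {
  cm <- x$cor_matrix
  tibble::tibble(
    true_param = rep(rownames(cm), times = ncol(cm)),
    recovered_param = rep(colnames(cm), each = nrow(cm)),
    r = as.vector(cm)
  )
}

#' @method glance peirs_recovery
#' @export
glance.peirs_recovery <- function(x, ...) {
  tibble::tibble(n = x$n, min_diag_r = min(x$diag_r),
                 max_abs_offdiag = x$max_abs_offdiag)
}

#' @export
print.peirs_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery, %d agents\n", x$n))
  cat("True-vs-recovered correlations:\n")
  print(round(x$diag_r, 3))
  cat(sprintf("Max |cross-parameter R|: %.3f\n", x$max_abs_offdiag))
  invisible(x)
}

#' @method autoplot peirs_recovery
#' @export
autoplot.peirs_recovery <- function(object, ...) {
  pn <- peirs_param_names()
  df <- purrr::map_dfr(pn, function(p) {
    tibble::tibble(param = p, true = object$true[, p],
                   recovered = object$recovered[, p])
  })
  labs <- setNames(
    sprintf("%s (R = %.2f)", pn, object$diag_r[pn]), pn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~param, scales = "free",
                        labeller = ggplot2::labeller(param = labs)) +
    ggplot2::labs(x = "Generating parameter (unconstrained scale)",
                  y = "Recovered parameter (unconstrained scale)") +
    ggplot2::theme_minimal()
}
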