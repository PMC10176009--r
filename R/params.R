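#' Construct a PEIRS parameter vector
#'
#' Bundles the five free parameters of the PEIRS model on their natural
#' (bounded) scale. The Rescorla-Wagner baseline is the special case
#' `gamma0 = gamma1 = 0`.
#'
#' @param alpha_q Learning rate for the mean value, in (0, 1).
#' @param alpha_s Learning rate for the outcome spread, in (0, 1).
#' @param beta Softmax inverse temperature, >= 0. Utilities are on the task's
#'   0-100 point scale, so values around 0.1-0.3 already produce near-greedy
#'   choice for typical utility differences.
#' @param gamma0 Baseline risk propensity; positive values make high-spread
#'   options more attractive everywhere.
#' @param gamma1 Context sensitivity; positive values make high-spread options
#'   more attractive in high-reward contexts and less attractive in low-reward
#'   contexts.
#'
#' @return A named numeric vector of length 5.
#' @export
#' @examples
#' peirs_params(alpha_q = 0.3, alpha_s = 0.3, beta = 0.15, gamma0 = 0, gamma1 = 0.03)
peirs_params <- function(alpha_q, alpha_s, beta, gamma0 = 0, gamma1 = 0) {
  p <- c(alpha_q = alpha_q, alpha_s = alpha_s, beta = beta,
         gamma0 = gamma0, gamma1 = gamma1)
  validate_params(p)
  p
}

validate_params <- function(p) {
  p <- as_params(p)
  if (p[["alpha_q"]] <= 0 || p[["alpha_q"]] >= 1)
    stop("alpha_q must be in (0, 1)", call. = FALSE)
  if (p[["alpha_s"]] <= 0 || p[["alpha_s"]] >= 1)
    stop("alpha_s must be in (0, 1)", call. = FALSE)
  if (p[["beta"]] < 0) stop("beta must be >= 0", call. = FALSE)
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  invisible(p)
}

# accept a named vector, list, or one-row data frame
as_params <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- unlist(p[, peirs_param_names()])
  }
  p <- unlist(p)
  missing <- setdiff(peirs_param_names(), names(p))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  p[peirs_param_names()]
}

#' Map parameters between the unconstrained and natural scales
#'
#' Hierarchical fitting places Gaussian population priors on an unconstrained
#' scale: learning rates are logit-transformed, the inverse temperature is
#' log-transformed, and the two risk weights are unchanged. `to_natural()`
#' maps an unconstrained vector to a bounded parameter vector;
#' `to_unconstrained()` is its inverse.
#'
#' @param x Numeric vector of length 5 (unconstrained scale), order
#'   `alpha_q, alpha_s, beta, gamma0, gamma1`.
#' @param p Parameter vector on the natural scale (see [peirs_params()]).
#'
#' @return A named numeric vector of length 5.
#' @export
#' @examples
#' to_natural(c(0, 0, 0, 0, 0))      # alpha = 0.5, beta = 1
#' to_unconstrained(peirs_params(0.5, 0.5, 1))
to_natural <- function(x) {
  x <- unname(as.numeric(x))
  stopifnot(length(x) == 5)
  setNames(c(plogis(x[1]), plogis(x[2]), exp(x[3]), x[4], x[5]),
           peirs_param_names())
}

#' @rdname to_natural
#' @export
to_unconstrained <- function(p) {
  p <- as_params(p)
  if (p[["alpha_q"]] <= 0 || p[["alpha_q"]] >= 1 ||
      p[["alpha_s"]] <= 0 || p[["alpha_s"]] >= 1 || p[["beta"]] <= 0)
    stop("boundary values have no unconstrained image", call. = FALSE)
  setNames(c(qlogis(p[["alpha_q"]]), qlogis(p[["alpha_s"]]), log(p[["beta"]]),
             p[["gamma0"]], p[["gamma1"]]), peirs_param_names())
}
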