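#' Rescorla-Wagner learner parameters
#'
#' Bundles the three parameters of the Rescorla-Wagner discrepancy rule:
#' the cue saliency `alpha`, the learning rate `beta`, and the outcome
#' asymptote `lambda` (the maximum associative strength an outcome can
#' support). The defaults -- `alpha = 1`, `beta = 0.2`, `lambda = 100` --
#' are the parameterization used throughout the headline simulations, so
#' that `alpha` has no influence and the learning rate is the only free
#' parameter.
#'
#' @param alpha Cue saliency, unitless, in \[0, 1\].
#' @param beta Learning rate, unitless, in \[0, 1\].
#' @param lambda Asymptote of associative strength, on a 0--100 scale by
#'   default so weights read as percentages of full prediction.
#'
#' @return An object of class `rw_params`.
#' @examples
#' rw_params()
#' rw_params(beta = 0.1)
#' @export
rw_params <- function(alpha = 1, beta = 0.2, lambda = 100) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
    is.numeric(beta), length(beta) == 1, is.finite(beta),
    is.numeric(lambda), length(lambda) == 1, is.finite(lambda)
  )
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, lambda = lambda),
    class = "rw_params"
  )
}

#' @export
print.rw_params <- function(x, ...) {
  cat(
    "<rw_params> alpha = ", x$alpha, ", beta = ", x$beta,
    ", lambda = ", x$lambda, "\n",
    sep = ""
  )
  invisible(x)
}

#' Closed-form single-cue acquisition curve
#'
#' For a single cue reinforced by a single outcome on every trial, the
#' Rescorla-Wagner recurrence has the closed form
#' `V(t) = lambda * (1 - (1 - alpha * beta)^t)`: a negatively accelerated
#' curve that approaches `lambda`. Useful as an analytic reference for the
#' iterative learner.
#'
#' @param t Vector of trial counts (non-negative integers).
#' @param params An [rw_params()] object.
#' @return Numeric vector of associative strengths after `t` trials.
#' @examples
#' rw_closed_form(0:5)
#' @export
rw_closed_form <- function(t, params = rw_params()) {
  stopifnot(inherits(params, "rw_params"), all(t >= 0))
  params$lambda * (1 - (1 - params$alpha * params$beta)^t)
}
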