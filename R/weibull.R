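#' Cumulative Weibull psychometric parameters
#'
#' Parameter container for the cumulative Weibull psychometric function used
#' to model accuracy as a function of allowed response time,
#' \deqn{a(t) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(t/\tau)^\beta}),}
#' where \eqn{\gamma} is the guess rate (lower asymptote, chance accuracy),
#' \eqn{\lambda} the lapse rate (so \eqn{1 - \lambda} is the upper
#' asymptote), \eqn{\tau} the time scale in milliseconds, and \eqn{\beta} the
#' shape controlling how abruptly accuracy rises.
#'
#' @param gamma Guess rate in \[0, 1); defaults to 1/16, the chance level of
#'   the 16-way task.
#' @param lam Lapse rate in \[0, 0.5).
#' @param tau Scale in milliseconds, > 0.
#' @param beta Shape, > 0.
#' @return An object of class `weibull_params`.
#' @export
#' @examples
#' p <- weibull_params(lam = 0.25, tau = 900, beta = 2)
#' weibull_accuracy(c(500, 900, 1500), p)
weibull_params <- function(gamma = 1 / 16, lam = 0.1, tau = 1000, beta = 2) {
  p <- list(gamma = as.numeric(gamma), lam = as.numeric(lam),
            tau = as.numeric(tau), beta = as.numeric(beta))
  class(p) <- "weibull_params"
  validate_weibull_params(p)
  p
}

validate_weibull_params <- function(p) {
  stopifnot(inherits(p, "weibull_params"))
  if (p$gamma < 0 || p$gamma >= 1) stop("gamma must be in [0, 1)")
  if (p$lam < 0 || p$lam >= 0.5) stop("lam must be in [0, 0.5)")
  if (p$gamma + p$lam >= 1) stop("gamma + lam must be < 1")
  if (p$tau <= 0) stop("tau must be > 0")
  if (p$beta <= 0) stop("beta must be > 0")
  invisible(p)
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf(
    "Cumulative Weibull: gamma = %.4g, lam = %.4g, tau = %.4g ms, beta = %.4g\n",
    x$gamma, x$lam, x$tau, x$beta))
  invisible(x)
}

#' Cumulative Weibull accuracy
#'
#' Evaluates the psychometric function described in [weibull_params()].  The
#' returned accuracy is bounded in \eqn{[\gamma, 1 - \lambda]} and is
#' monotone nondecreasing in `t_ms`.
#'
#' @param t_ms Positive time(s) in milliseconds.
#' @param p A `weibull_params` object.
#' @return Numeric vector of probabilities, same length as `t_ms`.
#' @export
weibull_accuracy <- function(t_ms, p) {
  validate_weibull_params(p)
  t_ms <- as.numeric(t_ms)
  if (any(!is.finite(t_ms)) || any(t_ms <= 0))
    stop("t_ms must be finite and > 0")
  p$gamma + (1 - p$gamma - p$lam) * (1 - exp(-(t_ms / p$tau)^p$beta))
}
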