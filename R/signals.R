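#' Signal function constructors
#'
#' Convenience constructors for the input signals used by the worked models:
#' step-on \eqn{\chi_{[t_on, \infty)}}, step-off \eqn{\chi_{(-\infty, t_off]}},
#' constants and piecewise-linear interpolants.  A signal is a vectorized
#' function of time with an attribute `support` (interval outside which it
#' vanishes, `-Inf`/`Inf` allowed).
#'
#' @param t_on,t_off switching times.
#' @param value constant level.
#' @param t,y nodes for the piecewise-linear signal.
#' @return A function `s(t)`.
#' @name signals
NULL

#' @rdname signals
#' @export
signal_step_on <- function(t_on = 0, value = 1) {
  f <- function(t) value * as.numeric(t >= t_on)
  attr(f, "support") <- c(t_on, Inf)
  f
}

#' @rdname signals
#' @export
signal_step_off <- function(t_off, value = 1) {
  f <- function(t) value * as.numeric(t <= t_off)
  attr(f, "support") <- c(-Inf, t_off)
  f
}

#' @rdname signals
#' @export
signal_constant <- function(value = 1) {
  f <- function(t) rep(value, length(t))
  attr(f, "support") <- c(-Inf, Inf)
  f
}

#' @rdname signals
#' @export
signal_piecewise <- function(t, y) {
  g <- stats::approxfun(t, y, yleft = 0, yright = 0)
  f <- function(tt) g(tt)
  attr(f, "support") <- range(t)
  f
}
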