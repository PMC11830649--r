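#' Coherent type-1 feed-forward loop response
#'
#' The C1FFL motif (signal \eqn{S} activates \eqn{X}; \eqn{X} makes
#' \eqn{Y}; \eqn{X} AND \eqn{Y} make \eqn{Z}) is a sign-sensitive delay:
#' \deqn{\dot X = S - aX,\quad \dot Y = X - bY,\quad \dot Z = XY - cZ.}
#' Because \eqn{Z} is driven by a product of two filtered copies of the
#' signal, its response is a genuinely quadratic functional,
#' \deqn{Z(t) = \int\!\!\int_{-\infty}^{t} K(t-v,\,t-w)\,S(w)\,S(v)\,dw\,dv,}
#' with a closed-form kernel obtained by integrating the three exponential
#' filters (evaluated here analytically).  `c1ffl_response()` computes
#' \eqn{Z} by both routes -- direct ODE integration (classical RK4) and the
#' double convolution -- so their agreement can be verified.
#'
#' @param a,b,c positive degradation rates (pairwise distinct where the
#'   kernel formula requires it; `b != a` always).
#' @param S signal: vectorized function of time, supported on `t >= 0`.
#' @param grid `time_grid`.
#' @return List with `t`, `X`, `Y`, `Z_ode`, `Z_kernel`, `K` (the kernel
#'   function of two lag arguments), `max_route_gap`.
#' @export
c1ffl_response <- function(a, b, c, S, grid) {
  stopifnot(a > 0, b > 0, c > 0)
  if (abs(b - a) < 1e-10) stop("kernel formula requires b != a")
  tt <- grid$t
  np <- grid$n_points
  dt <- grid$dt

  # ODE route: RK4 on (X, Y, Z)
  f <- function(t, y) {
    c(S(t) - a * y[1L], y[1L] - b * y[2L], y[1L] * y[2L] - c * y[3L])
  }
  Y <- matrix(0, 3L, np)
  y <- c(0, 0, 0)
  for (m in 2L:np) {
    t0 <- tt[m - 1L]
    k1 <- f(t0, y)
    k2 <- f(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, y + dt / 2 * k2)
    k4 <- f(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    Y[, m] <- y
  }

  K <- c1ffl_kernel(a, b, c)
  # double convolution over the grid (signal supported on t >= 0)
  Sv <- S(tt)
  wts <- rep(1, np)
  wts[c(1L, np)] <- 0.5
  Zk <- numeric(np)
  for (m in seq_len(np)) {
    if (m == 1L) next
    idx <- 1L:m
    eta <- tt[m] - tt[idx]      # lags
    wq <- rep(1, m); wq[c(1L, m)] <- 0.5
    Kmat <- outer(eta, eta, K)
    sv <- Sv[idx] * wq
    Zk[m] <- dt^2 * as.numeric(t(sv) %*% Kmat %*% sv)
  }
  list(t = tt, X = Y[1L, ], Y = Y[2L, ], Z_ode = Y[3L, ], Z_kernel = Zk,
       K = K, max_route_gap = max(abs(Y[3L, ] - Zk)))
}

# Closed-form C1FFL kernel K(eta, xi) = int_{-min(eta,xi)}^0 e^{(c-2a)s}
#   e^{-a(xi+eta)} (1 - e^{-(b-a)(xi+s)})/(b-a) ds, integrated analytically.
c1ffl_kernel <- function(a, b, c) {
  function(eta, xi) {
    m <- pmin(eta, xi)
    d1 <- c - 2 * a
    d2 <- c - a - b
    I1 <- if (abs(d1) > 1e-10) (1 - exp(-d1 * m)) / d1 else m
    I2 <- exp(-(b - a) * xi) *
      (if (abs(d2) > 1e-10) (1 - exp(-d2 * m)) / d2 else m)
    exp(-a * (xi + eta)) * (I1 - I2) / (b - a)
  }
}

#' Rescaled limit response of the C1FFL
#'
#' In the fast-degradation limit (\eqn{a, c \gg b}) the rescaled output
#' \eqn{\xi(\tau) = a^2 b c\, Z(\tau/b) / S_m^2} obeys the one-dimensional
#' form \eqn{\xi(\tau) = \bar S(\tau)\int_{-\infty}^\tau e^{-(\tau-s)}
#' \bar S(s)\,ds} -- the Dirac factor of the limit kernel is handled
#' analytically, never discretized.  A persistent step-on signal saturates
#' \eqn{\xi} at 1 on a time of order one (delayed ON); a step-off signal
#' gives \eqn{\xi \equiv 0} immediately after switch-off (instant OFF).
#'
#' @param Sbar rescaled signal \eqn{\bar S(\tau)} (vectorized; its value in
#'   the infinite past is taken as `Sbar(-1e9)` to close the history
#'   integral analytically for eventually-constant histories).
#' @param grid `time_grid` in \eqn{\tau}.
#' @return List with `tau` and `xi`.
#' @export
c1ffl_limit_response <- function(Sbar, grid) {
  tau <- grid$t
  past <- Sbar(-1e9)
  Sv <- Sbar(tau)
  conv <- numeric(grid$n_points)
  for (m in seq_len(grid$n_points)) {
    idx <- 1L:m
    conv[m] <- trapz(exp(-(tau[m] - tau[idx])) * Sv[idx], grid$dt)
  }
  hist_part <- past * exp(-tau)   # integral over the constant past s < 0
  list(tau = tau, xi = Sv * (hist_part + conv))
}
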