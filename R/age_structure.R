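#' Age-dependent jump rates between compartments
#'
#' Container for the bounded continuous rates \eqn{\lambda_{\alpha\beta}(\xi)}
#' of the structured-population formulation: the rate at which an element
#' that has spent time \eqn{\xi} in compartment \eqn{\alpha} jumps to
#' \eqn{\beta}.  Rates are supplied as vectorized functions of age (constants
#' are promoted).
#'
#' @param funs nested list `funs[[a]][[b]]` of functions (or single numbers)
#'   for every ordered pair of distinct compartments; missing entries are 0.
#' @param compartments character vector of compartment names.
#' @return Object of class `age_rates` with accessor `lambda(a, b, xi)` and
#'   `Lambda(a, xi)` (total exit rate \eqn{\Lambda_\alpha}).
#' @export
age_rates <- function(funs, compartments) {
  comp <- compartments
  norm <- list()
  for (a in comp) {
    norm[[a]] <- list()
    for (b in setdiff(comp, a)) {
      f <- funs[[a]][[b]]
      if (is.null(f)) f <- function(xi) 0 * xi
      if (is.numeric(f)) {
        f <- local({
          val <- f
          function(xi) rep(val, length(xi))
        })
      }
      norm[[a]][[b]] <- f
    }
  }
  lambda <- function(a, b, xi) {
    v <- norm[[a]][[b]](xi)
    if (any(v < 0)) stop("age rates must be nonnegative")
    v
  }
  Lambda <- function(a, xi) {
    out <- 0 * xi
    for (b in setdiff(comp, a)) out <- out + lambda(a, b, xi)
    out
  }
  structure(list(compartments = comp, lambda = lambda, Lambda = Lambda),
            class = "age_rates")
}

#' Initial age histories
#'
#' Past occupancies \eqn{m_\alpha} on ages \eqn{a \ge 0} (the element was in
#' the compartment at time \eqn{-a}), stored as a tabulated density on a
#' uniform age grid plus optional finite point masses.
#'
#' @param density |X| x n matrix of density values on `ages` (rows named by
#'   compartment), or `NULL`.
#' @param ages age nodes (uniform, starting at 0) for `density`.
#' @param points named list per compartment of `data.frame(age, weight)`.
#' @param compartments compartment names (required if `density` is `NULL`).
#' @return Object of class `age_history`.
#' @export
age_history <- function(density = NULL, ages = NULL, points = list(),
                        compartments = NULL) {
  if (!is.null(density)) {
    stopifnot(!is.null(ages), ncol(density) == length(ages))
    compartments <- compartments %||% rownames(density)
    rownames(density) <- compartments
  }
  stopifnot(!is.null(compartments))
  structure(list(density = density, ages = ages, points = points,
                 compartments = compartments), class = "age_history")
}

history_mass <- function(m, weight_fun = NULL) {
  # per-compartment integral of the history against weight_fun(age) (default 1)
  out <- setNames(rep(0, length(m$compartments)), m$compartments)
  for (a in m$compartments) {
    if (!is.null(m$density)) {
      w <- if (is.null(weight_fun)) rep(1, length(m$ages)) else
        weight_fun(a, m$ages)
      out[[a]] <- trapz(m$density[a, ] * w, m$ages[2L] - m$ages[1L])
    }
    pts <- m$points[[a]]
    if (!is.null(pts) && nrow(pts)) {
      w <- if (is.null(weight_fun)) rep(1, nrow(pts)) else
        weight_fun(a, pts$age)
      out[[a]] <- out[[a]] + sum(pts$weight * w)
    }
  }
  out
}

#' Solve the age-structured population equations
#'
#' Integrates the transport system
#' \deqn{\partial_t f_\alpha + \partial_\xi f_\alpha =
#'   -\Lambda_\alpha(\xi) f_\alpha,\qquad
#'   f_\alpha(t,0) = \sum_{\beta\ne\alpha}\int_0^\infty
#'   \lambda_{\beta\alpha}(\eta) f_\beta(t,\eta)\,d\eta,}
#' with initial condition
#' \eqn{f_\alpha(0,\xi) = m_\alpha(\xi)\,e^{-\int_0^\xi\Lambda_\alpha}},
#' by the method of characteristics on a grid with a single step
#' `h = dt = dxi`, so transport is exact (no numerical diffusion); survival
#' factors use the trapezoid rule in the exponent and the implicit
#' \eqn{\eta = 0} endpoint of the boundary integral is solved as a small
#' linear system per step.  History point masses are transported as weighted
#' particles.
#'
#' @param rates `age_rates`.
#' @param m `age_history` (tabulated density must live on a grid with the
#'   same step `h`).
#' @param grid `time_grid` for \eqn{t}; ages run to
#'   `xi_max = grid$t_end + max initial age`.
#' @return Object of class `age_density`: `f` array |X| x n_points x n_xi,
#'   `xi` age nodes, `particles` (final particle table), `N` aggregated
#'   totals (|X| x n_points).
#' @export
spe_solve <- function(rates, m, grid) {
  stopifnot(inherits(rates, "age_rates"), inherits(m, "age_history"),
            inherits(grid, "time_grid"))
  comp <- rates$compartments
  nX <- length(comp)
  h <- grid$dt
  np <- grid$n_points
  max_age0 <- 0
  if (!is.null(m$density)) {
    da <- m$ages[2L] - m$ages[1L]
    if (abs(da - h) > 1e-9 * h) {
      stop("history age step (", signif(da, 4),
           ") must equal the time step (", signif(h, 4), ")")
    }
    max_age0 <- max(m$ages)
  }
  n_xi <- np + round(max_age0 / h) + 1L
  xi <- seq(0, by = h, length.out = n_xi)

  lam_tab <- array(0, dim = c(nX, nX, n_xi), dimnames = list(comp, comp, NULL))
  Lam_tab <- matrix(0, nX, n_xi, dimnames = list(comp, NULL))
  for (a in comp) {
    for (b in setdiff(comp, a)) lam_tab[a, b, ] <- rates$lambda(a, b, xi)
    Lam_tab[a, ] <- rates$Lambda(a, xi)
  }
  surv_step <- exp(-(h / 2) * (Lam_tab[, -n_xi, drop = FALSE] +
                                 Lam_tab[, -1L, drop = FALSE]))

  # grid part: transported initial density (smooth history); newborn mass is
  # tracked as cohorts (one per step and compartment) so the density jump at
  # the newborn front never meets a quadrature rule
  dens <- matrix(0, nX, n_xi, dimnames = list(comp, NULL))
  for (a in comp) {
    if (!is.null(m$density) && a %in% rownames(m$density)) {
      idx <- seq_along(m$ages)
      cumLam <- cumtrapz(Lam_tab[a, idx], h)
      dens[a, idx] <- m$density[a, idx] * exp(-cumLam)
    }
  }
  # cohorts: per compartment, parallel vectors of age and mass
  coh_age <- coh_mass <- setNames(vector("list", nX), comp)
  for (a in comp) {
    coh_age[[a]] <- numeric(0)
    coh_mass[[a]] <- numeric(0)
    pts <- m$points[[a]]
    if (!is.null(pts) && nrow(pts)) {
      w0 <- vapply(seq_len(nrow(pts)), function(r) {
        age0 <- pts$age[r]
        cumL <- if (age0 > 0)
          trapz(rates$Lambda(a, seq(0, age0, length.out = 65L)), age0 / 64)
        else 0
        pts$weight[r] * exp(-cumL)
      }, numeric(1L))
      coh_age[[a]] <- pts$age
      coh_mass[[a]] <- w0
    }
  }

  inflow <- function(a, dens_now) {
    # boundary rate f_a(t, 0) = sum_b int lambda_{ba} f_b
    acc <- 0
    for (b in setdiff(comp, a)) {
      acc <- acc + trapz(lam_tab[b, a, ] * dens_now[b, ], h)
      if (length(coh_age[[b]])) {
        acc <- acc + sum(rates$lambda(b, a, coh_age[[b]]) * coh_mass[[b]])
      }
    }
    acc
  }

  f <- array(0, dim = c(nX, np, n_xi), dimnames = list(comp, NULL, NULL))
  N <- matrix(0, nX, np, dimnames = list(comp, NULL))
  snapshot <- function(mstep, dens_now) {
    for (a in comp) {
      row <- dens_now[a, ]
      if (length(coh_age[[a]])) {
        nodes <- pmin(round(coh_age[[a]] / h) + 1L, n_xi)
        for (i in seq_along(nodes)) {
          row[nodes[i]] <- row[nodes[i]] + coh_mass[[a]][i] / h
        }
      }
      f[a, mstep, ] <<- row
      N[a, mstep] <<- trapz(dens_now[a, ], h) + sum(coh_mass[[a]])
    }
  }
  snapshot(1L, dens)
  b_cur <- vapply(comp, inflow, numeric(1L), dens_now = dens)

  for (mstep in 2L:np) {
    # transport + decay of the density part (no boundary insertion)
    nxt <- dens
    nxt[, -1L] <- dens[, -n_xi, drop = FALSE] * surv_step
    nxt[, 1L] <- 0
    # age the cohorts with trapezoid survival over the step
    for (a in comp) {
      if (!length(coh_age[[a]])) next
      s <- exp(-(h / 2) * (rates$Lambda(a, coh_age[[a]]) +
                             rates$Lambda(a, coh_age[[a]] + h)))
      coh_mass[[a]] <- coh_mass[[a]] * s
      coh_age[[a]] <- coh_age[[a]] + h
    }
    # newborn cohorts: mass = trapezoid of the boundary rate over the step,
    # with the earliest-born members decayed across the step they were born
    # in; one fixed-point pass accounts for the newborns' own contribution
    decay0 <- exp(-(h / 2) * (Lam_tab[, 1L] + Lam_tab[, 2L]))
    b_new <- vapply(comp, inflow, numeric(1L), dens_now = nxt)
    for (a in comp) {
      coh_age[[a]] <- c(coh_age[[a]], h / 2)
      coh_mass[[a]] <- c(coh_mass[[a]],
                         (h / 2) * (b_cur[[a]] * decay0[[a]] + b_new[[a]]))
    }
    b_new <- vapply(comp, inflow, numeric(1L), dens_now = nxt)
    for (a in comp) {
      coh_mass[[a]][length(coh_mass[[a]])] <-
        (h / 2) * (b_cur[[a]] * decay0[[a]] + b_new[[a]])
    }
    dens <- nxt
    b_cur <- b_new
    snapshot(mstep, dens)
  }

  parts <- list()
  for (a in comp) {
    if (length(coh_age[[a]])) {
      parts[[a]] <- data.frame(age = coh_age[[a]], mass = coh_mass[[a]])
    }
  }
  structure(list(f = f, xi = xi, grid = grid, compartments = comp,
                 particles = parts, N = N), class = "age_density")
}

#' Aggregate an age density into compartment totals
#'
#' \eqn{N_\alpha(t) = \int_0^\infty f_\alpha(t, d\xi)} by trapezoid in age
#' plus particle weights.
#' @param f an `age_density` from [spe_solve()].
#' @return |X| x n_points matrix of totals.
#' @export
aggregate_age_density <- function(f) {
  stopifnot(inherits(f, "age_density"))
  f$N
}

#' Scalar kernels induced by age-dependent rates
#'
#' \deqn{\Phi_{\alpha\beta}(t) = \lambda_{\alpha\beta}(t)\,
#'   e^{-\int_0^t \Lambda_\alpha(s)\,ds},\qquad
#'   k_\alpha(t) = \Lambda_\alpha(t)\, e^{-\int_0^t \Lambda_\alpha}.}
#' The survival identity
#' \eqn{e^{-\int_0^t\Lambda_\alpha} = 1 - \int_0^t\sum_\beta
#' \Phi_{\alpha\beta}} is verified internally on the grid and its maximal
#' deviation attached as attribute `"survival_identity_dev"`.
#'
#' @param rates `age_rates`.
#' @param grid `time_grid`.
#' @return `kernel_family` (tabulated provenance) with scalar kernels.
#' @export
kernels_from_rates <- function(rates, grid) {
  comp <- rates$compartments
  nX <- length(comp)
  np <- grid$n_points
  tt <- grid$t
  Phi <- array(0, dim = c(nX, nX, np), dimnames = list(comp, comp, NULL))
  k_exit <- matrix(0, nX, np, dimnames = list(comp, NULL))
  dev <- 0
  for (a in comp) {
    Lam <- rates$Lambda(a, tt)
    surv <- exp(-cumtrapz(Lam, grid$dt))
    for (b in setdiff(comp, a)) {
      Phi[a, b, ] <- rates$lambda(a, b, tt) * surv
    }
    k_exit[a, ] <- Lam * surv
    # survival identity (exact in the continuum, grid-accurate here)
    tot <- apply(Phi[a, , , drop = FALSE], 3L, sum)
    dev <- max(dev, max(abs(surv - (1 - cumtrapz(tot, grid$dt)))))
  }
  out <- tabulated_kernels(Phi, grid, k_exit)
  attr(out, "survival_identity_dev") <- dev
  out
}

#' Age-dependent rates recovered from scalar kernels
#'
#' Inverts [kernels_from_rates()]:
#' \deqn{\lambda_{\alpha\beta}(t) = \frac{\Phi_{\alpha\beta}(t)}
#'   {1 - \sum_\gamma \int_0^t \Phi_{\alpha\gamma}(s)\,ds}.}
#' The denominator (remaining survival probability) must stay above `floor`
#' on the grid; otherwise the waiting-time law is exhausted inside the grid
#' and no bounded rate representation exists there.
#'
#' @param k `kernel_family` with scalar kernels.
#' @param floor positive lower bound for the survival denominator.
#' @return `age_rates` (kernel values linearly interpolated in age).
#' @export
rates_from_kernels <- function(k, floor = 1e-8) {
  stopifnot(inherits(k, "kernel_family"))
  if (is.null(k$scalar)) stop("scalar kernels required")
  comp <- k$compartments
  tt <- k$grid$t
  funs <- list()
  for (a in comp) {
    tot <- apply(k$scalar$Phi[a, , , drop = FALSE], 3L, sum)
    denom <- 1 - cumtrapz(tot, k$grid$dt)
    if (any(denom < floor)) {
      stop("survival exhausted for compartment ", a,
           ": the kernel mass reaches 1 inside the grid (min denominator ",
           signif(min(denom), 3), " < floor ", floor, ")")
    }
    funs[[a]] <- list()
    for (b in setdiff(comp, a)) {
      lam <- k$scalar$Phi[a, b, ] / denom
      funs[[a]][[b]] <- stats::approxfun(tt, lam, rule = 2L)
    }
  }
  age_rates(funs, comp)
}

#' Scalar forcing functions from an age history
#'
#' Transient forcings of the renewal system induced by past occupancies:
#' \deqn{B^0_\alpha(t) = \sum_{\beta\ne\alpha}\int_{0}^{\infty}
#'   \Phi_{\beta\alpha}(t + a)\, m_\beta(da), \qquad
#'   D^0_\alpha(t) = \int_0^\infty k_\alpha(t + a)\, m_\alpha(da),}
#' with ages \eqn{a \ge 0} counted backwards from time zero.  Initial totals
#' are \eqn{N^0_\alpha = \int (1 - \int_0^a \sum_\beta\Phi_{\alpha\beta})\,
#' m_\alpha(da)} (history weighted by its survival to time zero).
#'
#' @param k `kernel_family` with scalar kernels.
#' @param m `age_history`.
#' @return `forcing_set` with scalar `B0`, `D0`, `N0`.
#' @export
forcing_from_history <- function(k, m) {
  stopifnot(inherits(k, "kernel_family"), inherits(m, "age_history"))
  comp <- k$compartments
  np <- k$grid$n_points
  tt <- k$grid$t
  dt <- k$grid$dt
  Phi_fun <- function(a, b) {
    stats::approxfun(tt, k$scalar$Phi[a, b, ], yleft = 0, yright = 0)
  }
  k_fun <- function(a) {
    stats::approxfun(tt, k$scalar$k_exit[a, ], yleft = 0, yright = 0)
  }
  surv_fun <- function(a) {
    tot <- apply(k$scalar$Phi[a, , , drop = FALSE], 3L, sum)
    stats::approxfun(tt, pmax(0, 1 - cumtrapz(tot, dt)), yleft = 1,
                     yright = 0)
  }
  B0 <- D0 <- matrix(0, length(comp), np, dimnames = list(comp, NULL))
  N0 <- setNames(rep(0, length(comp)), comp)
  integrate_hist <- function(b, g) {
    # integral of g(age) against history m_b(da)
    acc <- 0
    if (!is.null(m$density) && b %in% rownames(m$density)) {
      acc <- acc + trapz(m$density[b, ] * g(m$ages),
                         m$ages[2L] - m$ages[1L])
    }
    pts <- m$points[[b]]
    if (!is.null(pts) && nrow(pts)) acc <- acc + sum(pts$weight * g(pts$age))
    acc
  }
  for (a in comp) {
    for (b in setdiff(comp, a)) {
      pf <- Phi_fun(b, a)
      for (i in seq_len(np)) {
        B0[a, i] <- B0[a, i] + integrate_hist(b, function(x) pf(tt[i] + x))
      }
    }
    kf <- k_fun(a)
    for (i in seq_len(np)) {
      D0[a, i] <- integrate_hist(a, function(x) kf(tt[i] + x))
    }
    sf <- surv_fun(a)
    N0[[a]] <- integrate_hist(a, sf)
  }
  scalar_forcing(k$grid, B0, D0, N0)
}

#' Is an initial ODE state compatible with an age-structure reformulation?
#'
#' Checks the compatibility condition
#' \eqn{n^0_\beta = \int_0^\infty e^{a A_{\beta\beta}}\, m_\beta(da)}
#' (ages counted positively backwards) by quadrature plus point masses, and
#' reports the residual against the proposed history.
#'
#' @param net `compartment_network`.
#' @param n0 initial per-state occupancy vector.
#' @param m `age_history` whose densities/points are vector-valued per state:
#'   `density` rows named by state (not compartment) and `points` entries
#'   `data.frame(age, weight)` per state.
#' @param tol admissibility tolerance on the residual norm (relative).
#' @return List with `admissible`, `residual` (per-state), `residual_norm`.
#' @export
admissible_history <- function(net, n0, m, tol = 1e-6) {
  states <- net$states
  if (!is.null(names(n0))) n0 <- n0[states]
  names(n0) <- states
  recon <- setNames(rep(0, length(states)), states)
  for (a in net$compartments) {
    sa <- net$partition[[a]]
    Aaa <- net$E[[a]] - net$C[[a]]
    # tabulated density part
    if (!is.null(m$density)) {
      present <- intersect(rownames(m$density), sa)
      if (length(present)) {
        da <- m$ages[2L] - m$ages[1L]
        P <- expm_dense(da * Aaa)
        cur <- diag(length(sa))
        w <- rep(1, length(m$ages))
        w[c(1L, length(m$ages))] <- 0.5
        for (i in seq_along(m$ages)) {
          vec <- setNames(rep(0, length(sa)), sa)
          vec[present] <- m$density[present, i]
          recon[sa] <- recon[sa] + da * w[i] * as.numeric(cur %*% vec)
          cur <- cur %*% P
        }
      }
    }
    for (s in intersect(names(m$points), sa)) {
      pts <- m$points[[s]]
      if (is.null(pts) || !nrow(pts)) next
      for (r in seq_len(nrow(pts))) {
        vec <- setNames(rep(0, length(sa)), sa)
        vec[s] <- pts$weight[r]
        recon[sa] <- recon[sa] +
          as.numeric(expm_dense(pts$age[r] * Aaa) %*% vec)
      }
    }
  }
  res <- n0 - recon
  rn <- sqrt(sum(res^2))
  list(admissible = rn <= tol * max(1, sqrt(sum(n0^2))),
       residual = res, residual_norm = rn)
}
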