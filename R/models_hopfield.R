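#' Hopfield kinetic proofreading model
#'
#' Parameter container for the five-state proofreading network
#' \eqn{\{C, S, S^*, \emptyset, P\}}: a substrate--receptor complex \eqn{S}
#' and its phosphorylated form \eqn{S^*} interconvert with the free codon
#' \eqn{C}; \eqn{C} degrades to \eqn{\emptyset} at rate \eqn{\mu} and
#' \eqn{S^*} synthesizes the product \eqn{P} at rate \eqn{\lambda}.  Free
#' energies enter through their exponentials: `eE1` \eqn{= e^{E_1}}, `eE2`
#' \eqn{= e^{E_2}} (units \eqn{k_BT = 1}); `Q >= 1` measures how strongly the
#' phosphorylation step breaks detailed balance (`Q = 1` restores it).
#' A competing substrate uses barred energies with the discrimination factor
#' \eqn{\theta = e^{-(\bar E_1 - E_1)} \in (0,1]} and the same
#' \eqn{\eta = e^{E_2 - E_1} = e^{\bar E_2 - \bar E_1}}.
#'
#' @param k rate of \eqn{C \to S} (time-unit anchor; 1 by convention).
#' @param alpha rate of \eqn{S \to S^*}.
#' @param beta rate of \eqn{C \to S^*}.
#' @param mu degradation rate of \eqn{C}.
#' @param lambda production rate \eqn{S^* \to P}.
#' @param Q detailed-balance violation factor of the phosphorylation step.
#' @param eE1,eE2 exponentials of the binding and phosphorylation energies.
#' @return Object of class `hopfield_params`; derived quantities `xi`
#'   (\eqn{e^{E_1}}) and `eta` (\eqn{e^{E_2-E_1}}) are attached.
#' @export
hopfield_params <- function(k = 1, alpha, beta, mu, lambda, Q, eE1, eE2) {
  stopifnot(k > 0, alpha > 0, beta > 0, mu >= 0, lambda >= 0, Q > 0,
            eE1 > 0, eE2 > 0)
  structure(list(k = k, alpha = alpha, beta = beta, mu = mu,
                 lambda = lambda, Q = Q, eE1 = eE1, eE2 = eE2,
                 xi = eE1, eta = eE2 / eE1),
            class = "hopfield_params")
}

#' Preset used for the proofreading response-function figure
#'
#' The scaling family \eqn{\alpha = \mu = \varepsilon},
#' \eqn{\beta = \varepsilon^2}, \eqn{Q = \varepsilon^{-2}},
#' \eqn{\lambda = 2\varepsilon^2}, \eqn{e^{E_1} = 2},
#' \eqn{e^{E_2} = 4/\varepsilon^s}, and for the competing substrate
#' \eqn{e^{\bar E_1} = 8}, \eqn{e^{\bar E_2} = 16/\varepsilon^s}
#' (so \eqn{\theta = 1/4}).
#'
#' @param eps scale parameter \eqn{\varepsilon} (default 0.01).
#' @param s exponent \eqn{s \in (0, 1]} (default 1/2).
#' @param barred use the competing substrate's energies.
#' @return A `hopfield_params`.
#' @export
hopfield_preset <- function(eps = 0.01, s = 0.5, barred = FALSE) {
  hopfield_params(k = 1, alpha = eps, beta = eps^2, mu = eps,
                  lambda = 2 * eps^2, Q = eps^-2,
                  eE1 = if (barred) 8 else 2,
                  eE2 = (if (barred) 16 else 4) / eps^s)
}

# 3x3 generator of the (C, S, S*) subsystem, dn/dt = A3 n, including the
# loss channels mu (C -> sink) and lambda (S* -> P).
hopfield_core_generator <- function(p) {
  rev_phos <- p$alpha / p$Q * p$eta
  A3 <- rbind(
    c(-(p$k + p$beta + p$mu), p$k * p$eE1,            p$beta * p$eE2),
    c(p$k,                    -(p$k * p$eE1 + p$alpha), rev_phos),
    c(p$beta,                 p$alpha,
      -(rev_phos + p$beta * p$eE2 + p$lambda)))
  dimnames(A3) <- list(c("C", "S", "Sstar"), c("C", "S", "Sstar"))
  A3
}

#' Build the proofreading network as a compartment network
#'
#' Five states \eqn{\{C, S, S^*, \emptyset, P\}} with the rates of the
#' proofreading scheme; reverse rates follow from the energies
#' (\eqn{k e^{E_1}}, \eqn{\beta e^{E_2}}, \eqn{\alpha e^{E_2-E_1}/Q}).
#' The default partition groups the reaction core with the degradation sink,
#' `core` \eqn{= \{C, S, S^*, \emptyset\}}, against the product `product`
#' \eqn{= \{P\}}, whose single entrance point is \eqn{P} itself.
#'
#' @param p `hopfield_params`.
#' @return A `compartment_network`.
#' @export
hopfield_network <- function(p) {
  st <- c("C", "S", "Sstar", "sink", "P")
  A <- matrix(0, 5L, 5L, dimnames = list(st, st))
  add <- function(from, to, r) A[to, from] <<- A[to, from] + r
  add("C", "S", p$k);          add("S", "C", p$k * p$eE1)
  add("C", "Sstar", p$beta);   add("Sstar", "C", p$beta * p$eE2)
  add("S", "Sstar", p$alpha);  add("Sstar", "S", p$alpha / p$Q * p$eta)
  if (p$mu > 0) add("C", "sink", p$mu)
  if (p$lambda > 0) add("Sstar", "P", p$lambda)
  diag(A) <- -colSums(A)
  build_compartment_network(
    validate_rate_matrix(A),
    list(core = c("C", "S", "Sstar", "sink"), product = "P"))
}

#' Proofreading response function
#'
#' The waiting-time density of product formation under a unit impulse of the
#' codon, \eqn{\Phi(t) = \lambda S^*(t)} with \eqn{C(0) = 1},
#' \eqn{S(0) = S^*(0) = 0}, computed by propagating the 3x3 core generator
#' with one matrix exponential per step.
#'
#' @param p `hopfield_params`.
#' @param grid `time_grid`.
#' @return List with `t`, `Phi`, the state trajectories `C`, `S`, `Sstar`,
#'   and `mass` (grid integral of `Phi`).
#' @export
hopfield_response <- function(p, grid) {
  A3 <- hopfield_core_generator(p)
  P <- expm_dense(grid$dt * A3)
  np <- grid$n_points
  traj <- matrix(0, 3L, np, dimnames = list(rownames(A3), NULL))
  cur <- c(1, 0, 0)
  traj[, 1L] <- cur
  for (m in 2L:np) {
    cur <- P %*% cur
    traj[, m] <- cur
  }
  Phi <- p$lambda * traj["Sstar", ]
  list(t = grid$t, Phi = Phi, C = traj["C", ], S = traj["S", ],
       Sstar = traj["Sstar", ], mass = trapz(Phi, grid$dt))
}

#' Total product from a unit impulse of codon
#'
#' \eqn{P_\infty = \lambda \int_0^\infty S^*(t)\,dt} computed by trapezoid
#' quadrature of the response on the grid plus a spectral tail correction:
#' the remaining integral \eqn{\lambda\,[(-A_3)^{-1} n(t_{end})]_{S^*}}
#' obtained from the resolvent applied to the final state (dominated by the
#' slowest eigenvalue of the core generator).  Without degradation
#' (\eqn{\mu = 0}) every codon eventually makes product, so
#' \eqn{P_\infty = C(0) = 1}.
#'
#' @param p `hopfield_params`.
#' @param grid `time_grid`; default covers several slowest-decay times.
#' @return List with `P_inf`, `grid_part`, `tail_part`.
#' @export
hopfield_total_production <- function(p, grid = NULL) {
  A3 <- hopfield_core_generator(p)
  if (is.null(grid)) {
    ev <- abs(Re(eigen(A3, only.values = TRUE)$values))
    # resolve the fast transient on the grid; the resolvent tail (exact,
    # asymptotically the slowest mode) carries the remaining slow decay
    fast <- max(ev)
    grid <- time_grid(60 / fast, 24001L)
  }
  resp <- hopfield_response(p, grid)
  nT <- c(resp$C[grid$n_points], resp$S[grid$n_points],
          resp$Sstar[grid$n_points])
  tail <- unname(p$lambda * solve(-A3, nT)[3L])
  list(P_inf = resp$mass + tail, grid_part = resp$mass, tail_part = tail)
}

#' Laplace transform at zero of the core occupancies
#'
#' \eqn{(\hat C(0), \hat S(0), \hat S^*(0)) = (-A_3)^{-1} e_C}; the building
#' block of the production and timing formulas.
#' @param p `hopfield_params`.
#' @return Named numeric vector.
#' @export
hopfield_laplace0 <- function(p) {
  A3 <- hopfield_core_generator(p)
  setNames(solve(-A3, c(1, 0, 0)), c("C", "S", "Sstar"))
}

#' Discrimination ratio of total production
#'
#' Ratio \eqn{\bar P_\infty / P_\infty} of total product generated by the
#' competing (weaker-binding) substrate versus the cognate one, computed two
#' ways and cross-checked: (a) numerically, from the Laplace transforms at
#' zero of both linear systems; (b) from the closed-form expression in
#' \eqn{\theta = e^{-(\bar E_1 - E_1)}}, \eqn{\xi = e^{E_1}},
#' \eqn{\eta = e^{E_2 - E_1}} (valid for `k = 1` and shared
#' \eqn{\alpha,\beta,\mu,\lambda,Q,\eta}).  Proofreading guarantees
#' ratio \eqn{\ge \theta^2}, with equality approached in the scaling limit.
#'
#' @param p cognate `hopfield_params`.
#' @param pbar competing `hopfield_params` (same rates, barred energies), or
#'   `NULL` to derive it from `theta`.
#' @param theta discrimination factor used when `pbar` is `NULL`.
#' @return List with `ratio` (numeric route), `ratio_closed_form` (or `NA`
#'   when the parameter pattern does not match the formula), `theta`,
#'   `theta2`, `P_inf`, `Pbar_inf`.
#' @export
production_ratio <- function(p, pbar = NULL, theta = NULL) {
  if (is.null(pbar)) {
    stopifnot(!is.null(theta), theta > 0)
    pbar <- hopfield_params(k = p$k, alpha = p$alpha, beta = p$beta,
                            mu = p$mu, lambda = p$lambda, Q = p$Q,
                            eE1 = p$eE1 / theta, eE2 = p$eE2 / theta)
  }
  theta <- p$eE1 / pbar$eE1
  P_inf <- p$lambda * hopfield_laplace0(p)[["Sstar"]]
  Pbar_inf <- pbar$lambda * hopfield_laplace0(pbar)[["Sstar"]]
  ratio <- Pbar_inf / P_inf

  cf <- NA_real_
  same <- isTRUE(all.equal(c(p$alpha, p$beta, p$mu, p$lambda, p$Q, p$eta),
                           c(pbar$alpha, pbar$beta, pbar$mu, pbar$lambda,
                             pbar$Q, pbar$eta))) && abs(p$k - 1) < 1e-12
  if (same) {
    al <- p$alpha; be <- p$beta; mu <- p$mu; la <- p$lambda; Q <- p$Q
    xi <- p$xi; eta <- p$eta
    u <- (be + mu) * la / (mu * be * eta) + al / (be * Q) + al
    w <- (1 + be + mu) * al * la / (mu * be * eta)
    cf <- theta^2 *
      (1 + be + be * xi / (al * theta)) / (1 + be + be * xi / al) *
      (xi^2 + xi * u + w) / (xi^2 + theta * xi * u + theta^2 * w)
  }
  list(ratio = unname(ratio), ratio_closed_form = cf, theta = theta,
       theta2 = theta^2, P_inf = unname(P_inf), Pbar_inf = unname(Pbar_inf))
}

#' Mean time to product formation (no degradation)
#'
#' With \eqn{\mu = 0} the response function integrates to one and the mean
#' production time is its first moment,
#' \eqn{T = \int_0^\infty t\,\Phi(t)\,dt = \hat C(0) + \hat S(0) +
#' \hat S^*(0)}.  Both the printed closed form and the numeric first moment
#' \eqn{\lambda\,[A_3^{-2} e_C]_{S^*}} are returned.
#'
#' @param p `hopfield_params` with `mu = 0` (enforced).
#' @return List with `T_closed_form`, `T_moment`, `T_laplace`.
#' @export
mean_production_time <- function(p) {
  if (p$mu != 0) {
    p <- hopfield_params(k = p$k, alpha = p$alpha, beta = p$beta, mu = 0,
                         lambda = p$lambda, Q = p$Q, eE1 = p$eE1,
                         eE2 = p$eE2)
  }
  A3 <- hopfield_core_generator(p)
  hat0 <- solve(-A3, c(1, 0, 0))
  T_laplace <- sum(hat0)
  T_moment <- p$lambda * (solve(A3) %*% solve(A3, c(1, 0, 0)))[3L]
  k <- p$k; al <- p$alpha; be <- p$beta; la <- p$lambda; Q <- p$Q
  eta <- p$eta; eE1 <- p$eE1
  # exact rational form of C^(0) + S^(0) + S*^(0); note the final 1/lambda
  # sojourn-at-S* term
  T_cf <- ((la + be * eta * eE1) * (k * eE1 + al) +
             (al / Q) * eta * k * eE1 + (k + be) * (al * eta / Q) +
             k * (la + be * eta * eE1)) /
    (la * (be * k * eE1 + al * k + al * be)) + 1 / la
  list(T_closed_form = T_cf, T_moment = unname(T_moment),
       T_laplace = T_laplace)
}
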