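#' Completely monotone decomposition of a detailed-balance kernel
#'
#' For a network satisfying detailed balance with equilibrium \eqn{\mu}, the
#' scalar response kernel for exit from compartment `beta` towards `alpha`
#' is an exponential mixture
#' \deqn{\Phi_{\beta\alpha}(t) = \lambda_{i_\beta i_\alpha}
#'   \sum_j \kappa_j^2 e^{-\nu_j t}, \qquad \sum_j \kappa_j^2 = 1,}
#' obtained by symmetrizing the diagonal block \eqn{A_{\beta\beta}} with the
#' \eqn{\sqrt\mu} similarity and eigendecomposing: \eqn{\kappa_j} is the
#' entrance-point component of the \eqn{j}-th orthonormal eigenvector and
#' \eqn{\nu_j \ge 0} the negated eigenvalue.  All weights and decay rates are
#' nonnegative, so the kernel is completely monotone.
#'
#' @param net `compartment_network` passing [check_detailed_balance()].
#' @param beta source compartment name (the block that is decomposed).
#' @param alpha destination compartment name.
#' @param tol detailed-balance tolerance.
#' @return Object of class `cm_representation`: list with `prefactor`
#'   (\eqn{\lambda_{i_\beta i_\alpha}}), `weights` (\eqn{\kappa_j^2}),
#'   `decays` (\eqn{\nu_j}), `source`, `target`, and `density(t)` closure.
#' @export
cm_decompose <- function(net, beta, alpha, tol = 1e-8) {
  stopifnot(inherits(net, "compartment_network"))
  eq <- check_detailed_balance(net$A, tol = tol)
  if (!eq$has_detailed_balance) {
    stop("network does not satisfy detailed balance (status: ", eq$status,
         ", max violation ", signif(eq$max_violation, 4), ")")
  }
  ep <- net$entrance_points
  if (length(ep[[beta]]) != 1L || length(ep[[alpha]]) != 1L) {
    stop("cm_decompose requires single entrance points in both compartments")
  }
  ib <- ep[[beta]]
  ia <- ep[[alpha]]
  Abb <- net$E[[beta]] - net$C[[beta]]
  mu_b <- eq$mu[net$partition[[beta]]]
  Ms <- sqrt(mu_b)
  D <- sweep(sweep(Abb, 1L, Ms, `/`), 2L, Ms, `*`)  # M^{-1} A M
  D <- (D + t(D)) / 2
  ev <- eigen(D, symmetric = TRUE)
  i_b <- match(ib, net$partition[[beta]])
  weights <- ev$vectors[i_b, ]^2
  decays <- -ev$values
  prefactor <- unclass(net$A)[ia, ib]     # jump rate i_beta -> i_alpha
  structure(list(prefactor = prefactor, weights = weights, decays = decays,
                 source = beta, target = alpha,
                 density = function(t) {
                   prefactor * colSums(weights * exp(outer(-decays, t)))
                 }),
            class = "cm_representation")
}

#' @export
print.cm_representation <- function(x, ...) {
  cat("<cm_representation> Phi_{", x$source, " -> ", x$target, "}(t) = ",
      signif(x$prefactor, 5), " * sum_j kappa_j^2 exp(-nu_j t)\n",
      "  weights: ", paste(signif(x$weights, 4), collapse = ", "),
      " (sum = ", signif(sum(x$weights), 8), ")\n",
      "  decays:  ", paste(signif(x$decays, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Test a scalar kernel family for Markovianity
#'
#' The reduced compartment dynamics is Markovian iff every response kernel is
#' exponential with a shared per-source decay,
#' \eqn{\Phi_{\alpha\beta}(t) = \lambda_{\alpha\beta}
#' e^{-t\Lambda_\alpha}} with
#' \eqn{\Lambda_\alpha = \sum_\gamma \lambda_{\alpha\gamma}}.  Rates are
#' estimated from the kernel values at \eqn{t = 0} and the fit checked in
#' sup norm over the grid.
#'
#' @param k `kernel_family` with scalar kernels.
#' @param tol relative sup-norm tolerance of the exponential fit.
#' @return List with `is_markovian`, `rates` (|X| x |X| matrix,
#'   `rates[a, b]` = \eqn{\lambda_{\alpha\beta}}), `generator` (the induced
#'   compartment-level rate matrix in the column convention
#'   `A[i, j] = lambda_{ji}`), `max_misfit`.
#' @export
markovianity_test <- function(k, tol = 1e-6) {
  stopifnot(inherits(k, "kernel_family"))
  if (is.null(k$scalar)) stop("scalar kernels required")
  comp <- k$compartments
  nX <- length(comp)
  tt <- k$grid$t
  lam <- matrix(0, nX, nX, dimnames = list(comp, comp))
  for (a in comp) for (b in setdiff(comp, a)) {
    lam[a, b] <- k$scalar$Phi[a, b, 1L]
  }
  Lam <- rowSums(lam)
  misfit <- 0
  ok <- TRUE
  for (a in comp) for (b in setdiff(comp, a)) {
    model <- lam[a, b] * exp(-Lam[[a]] * tt)
    err <- max(abs(k$scalar$Phi[a, b, ] - model))
    scale <- if (lam[a, b] > 0) lam[a, b] else max(k$scalar$Phi[a, b, ], 1)
    misfit <- max(misfit, err / scale)
    if (err > tol * scale) ok <- FALSE
  }
  gen <- t(lam)               # A[i, j] = lambda_{ji}
  diag(gen) <- -colSums(gen)
  list(is_markovian = ok, rates = lam, generator = gen, max_misfit = misfit)
}

#' Root of the renewal characteristic equation
#'
#' Finds the unique real \eqn{r} with \eqn{\rho(M(r)) = 1}, where
#' \eqn{M(z)} is the Laplace-transformed kernel matrix ([laplace_kernel()]).
#' \eqn{\rho(M(z))} is strictly decreasing in \eqn{z}, so the root is located
#' by `uniroot` (Brent) on a bracket.  For conservative kernels with
#' irreducible \eqn{M} the root is \eqn{0}.
#'
#' @param k `kernel_family` with scalar kernels.
#' @param z_bracket search interval; the upper end must give
#'   \eqn{\rho < 1}.  By default the lower end is `-0.9` times the smallest
#'   positive decay rate of the kernels (for ODE-derived kernels, from the
#'   block spectra) and the upper end is `10`.
#' @param tol root tolerance.
#' @return Object of class `characteristic_solution`: `root`, `v` (right
#'   Perron vector, unit 1-norm), `rho_curve` (sampled `(z, rho)` pairs).
#' @export
characteristic_root <- function(k, z_bracket = NULL, tol = 1e-12) {
  stopifnot(inherits(k, "kernel_family"))
  if (is.null(k$scalar)) stop("scalar kernels required")
  comp <- k$compartments
  if (is.null(z_bracket)) {
    z_bracket <- c(-0.9 * min_kernel_decay(k), 10)
  }
  M0 <- laplace_kernel(k, max(0, z_bracket[1L]))$M
  g <- igraph::graph_from_adjacency_matrix(M0 > 0, mode = "directed",
                                           diag = FALSE)
  if (length(comp) > 1L && !igraph::is_connected(g, mode = "strong")) {
    stop("kernel matrix M(z) is reducible; the characteristic eigenproblem ",
         "requires a strongly connected compartment digraph")
  }
  rho_at <- function(z) spectral_radius(laplace_kernel(k, z)$M) - 1
  lo <- z_bracket[1L]
  hi <- z_bracket[2L]
  f_lo <- tryCatch(rho_at(lo), error = function(e) NA_real_)
  while (!is.finite(f_lo) && lo < hi - 1e-12) {
    lo <- lo / 2
    if (abs(lo) < 1e-12) lo <- 0
    f_lo <- tryCatch(rho_at(lo), error = function(e) NA_real_)
    if (abs(lo) < 1e-12) break
  }
  f_hi <- rho_at(hi)
  if (!is.finite(f_lo) || f_lo * f_hi > 0) {
    if (abs(f_hi) < 1e-10) {
      root <- hi
    } else if (is.finite(f_lo) && abs(f_lo) < 1e-10) {
      root <- lo
    } else {
      stop("bracket [", lo, ", ", hi, "] does not straddle rho(M(z)) = 1")
    }
  } else {
    root <- stats::uniroot(rho_at, c(lo, hi), tol = tol)$root
  }
  Mr <- laplace_kernel(k, root)$M
  v <- perron_vector(Mr)
  names(v) <- comp
  zs <- seq(lo, hi, length.out = 9L)
  curve <- cbind(z = zs, rho = vapply(zs, function(z) rho_at(z) + 1,
                                      numeric(1L)))
  structure(list(root = root, v = v, rho_curve = curve),
            class = "characteristic_solution")
}

#' @export
print.characteristic_solution <- function(x, ...) {
  cat("<characteristic_solution> root z* = ", signif(x$root, 8),
      "; v = (", paste(signif(x$v, 5), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Long-time profile of the renewal solution
#'
#' For conservative irreducible scalar kernels, the influx vector converges
#' exponentially to \eqn{c_0 v_0} where \eqn{v_0} is the Perron vector of
#' \eqn{M(0)} and \eqn{c_0} is the simple-pole residue of
#' \eqn{(I - M(z))^{-1}\hat B^0(z)} at \eqn{z = 0}, computed by the
#' eigenvector formula
#' \eqn{c_0 = u_0^\top \hat B^0(0)\,/\,(-u_0^\top M'(0) v_0)} with left/right
#' Perron vectors normalized to \eqn{u_0^\top v_0 = 1}.  The compartment
#' totals converge to
#' \eqn{N_\infty = c_0\, v_0 \odot \int_0^\infty s\,k_\alpha(s)\,ds}.
#' \eqn{M'(0)} has entries \eqn{-\int t\,\Phi_{\beta\alpha}(t)\,dt}, exact
#' for ODE-derived kernels via the squared-resolvent identity.
#'
#' @param k `kernel_family` with scalar kernels (conservative, irreducible).
#' @param f `forcing_set` carrying scalar `B0` (finite mass).
#' @return Object of class `asymptotic_profile`: `c0`, `v0`, `u0`,
#'   `N_inf`, `first_moments` (per-compartment \eqn{\int s\,k_\alpha}).
#' @export
asymptotic_profile <- function(k, f) {
  stopifnot(inherits(k, "kernel_family"), inherits(f, "forcing_set"))
  if (is.null(k$scalar)) stop("scalar kernels required")
  if (is.null(f$B0)) stop("forcing must carry scalar B0")
  comp <- k$compartments
  nX <- length(comp)
  M0 <- laplace_kernel(k, 0)$M
  v0 <- perron_vector(M0)
  u0 <- perron_vector(M0, left = TRUE)
  u0 <- u0 / sum(u0 * v0)           # u0^T v0 = 1

  Mp <- matrix(0, nX, nX, dimnames = list(comp, comp))
  mom_k <- setNames(numeric(nX), comp)
  if (k$provenance == "ode") {
    net <- k$net
    ep <- k$scalar$entrance
    for (b in comp) {
      ib <- ep[[b]]
      if (is.na(ib)) next
      Abb <- net$E[[b]] - net$C[[b]]
      Y2 <- block_first_moment_integral(Abb)   # int t e^{tA} dt
      e_ib <- as.numeric(net$partition[[b]] == ib)
      y2 <- Y2 %*% e_ib
      mom_k[[b]] <- sum(net_loss(net, b) * y2)
      for (a in setdiff(comp, b)) {
        ia <- ep[[a]]
        if (is.na(ia)) next
        Aab <- net_block(net, a, b)
        Mp[a, b] <- -(Aab %*% y2)[match(ia, net$partition[[a]])]
      }
    }
  } else {
    tt <- k$grid$t
    for (a in comp) {
      mom_k[[a]] <- trapz(tt * k$scalar$k_exit[a, ], k$grid$dt)
      for (b in setdiff(comp, a)) {
        Mp[b, a] <- -trapz(tt * k$scalar$Phi[a, b, ], k$grid$dt)
      }
    }
  }
  denom <- -sum(u0 * (Mp %*% v0))
  if (abs(denom) < 1e-12) {
    stop("pole of (I - M(z))^{-1} at z = 0 is not simple ",
         "(u0' M'(0) v0 ~ 0); asymptotic profile undefined")
  }
  if (k$provenance == "ode" && !is.null(f$n0)) {
    # exact B0hat(0): int B0_a = sum_b (A_ab Y_b n0_b)_{i_a}
    net <- k$net
    ep <- k$scalar$entrance
    B0hat <- setNames(numeric(nX), comp)
    for (a in comp) {
      ia <- ep[[a]]
      if (is.na(ia)) next
      acc <- 0
      for (b in setdiff(comp, a)) {
        Abb <- net$E[[b]] - net$C[[b]]
        Yb <- block_resolvent_integral(Abb)
        n0b <- f$n0[net$partition[[b]]]
        acc <- acc +
          (net_block(net, a, b) %*% Yb %*% n0b)[match(ia, net$partition[[a]])]
      }
      B0hat[[a]] <- acc
    }
  } else {
    B0hat <- apply(f$B0, 1L, trapz, dt = k$grid$dt)
  }
  c0 <- sum(u0 * B0hat) / denom
  N_inf <- c0 * v0 * mom_k
  structure(list(c0 = c0, v0 = setNames(v0, comp), u0 = setNames(u0, comp),
                 N_inf = N_inf, first_moments = mom_k),
            class = "asymptotic_profile")
}

#' @export
print.asymptotic_profile <- function(x, ...) {
  cat("<asymptotic_profile> c0 = ", signif(x$c0, 6), "\n  N_inf: ",
      paste(names(x$N_inf), signif(x$N_inf, 5), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Smallest positive decay rate of the kernel family: for ODE-derived kernels
# the least |Re eigenvalue| over exiting blocks; for tabulated kernels a
# log-slope fit over the tail of each kernel.
min_kernel_decay <- function(k) {
  decays <- numeric(0)
  if (k$provenance == "ode") {
    net <- k$net
    for (b in k$compartments) {
      if (all(net_loss(net, b) == 0)) next
      ev <- Re(eigen(net$E[[b]] - net$C[[b]], only.values = TRUE)$values)
      ev <- -ev[ev < -1e-12]
      if (length(ev)) decays <- c(decays, min(ev))
    }
  } else {
    tt <- k$grid$t
    for (a in k$compartments) for (b in setdiff(k$compartments, a)) {
      tf <- tail_mass(tt, k$scalar$Phi[a, b, ])
      if (isTRUE(tf$reliable) && is.finite(tf$rate) && tf$rate > 0) {
        decays <- c(decays, tf$rate)
      }
    }
  }
  if (!length(decays)) 0.25 else min(decays)
}
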