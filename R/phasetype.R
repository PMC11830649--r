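#' Erlang mixture distributions
#'
#' A mixture \eqn{f(t) = \sum_j q_j\,\gamma_{M,m_j}(t)} of Erlang densities
#' \eqn{\gamma_{M,m}(t) = M^{m+1} t^m e^{-Mt}/m!} (i.e. Gamma with shape
#' \eqn{m+1} and rate \eqn{M}), the dense constructive subclass of
#' phase-type distributions used to approximate arbitrary waiting-time laws.
#'
#' @param M common Erlang rate (> 0).
#' @param weights mixture weights \eqn{q_j > 0}, summing to 1.
#' @param shapes nonnegative integer shape parameters \eqn{m_j}.
#' @return Object of class `erlang_mixture` with `M`, `weights`, `shapes`,
#'   and closures `density(t)`, `cdf(t)`.
#' @export
erlang_mixture <- function(M, weights, shapes) {
  stopifnot(M > 0, length(weights) == length(shapes), all(weights > 0),
            all(shapes >= 0), all(shapes == round(shapes)))
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  weights <- weights / sum(weights)
  shapes <- as.integer(shapes)
  structure(list(
    M = M, weights = weights, shapes = shapes,
    density = function(t) {
      out <- 0 * t
      for (j in seq_along(weights)) {
        out <- out + weights[j] * stats::dgamma(t, shape = shapes[j] + 1L,
                                                rate = M)
      }
      out
    },
    cdf = function(t) {
      out <- 0 * t
      for (j in seq_along(weights)) {
        out <- out + weights[j] * stats::pgamma(t, shape = shapes[j] + 1L,
                                                rate = M)
      }
      out
    }), class = "erlang_mixture")
}

#' @export
print.erlang_mixture <- function(x, ...) {
  cat("<erlang_mixture> rate M = ", x$M, ", ", length(x$weights),
      " components\n  shapes m_j: ", paste(x$shapes, collapse = ", "),
      "\n  weights q_j: ", paste(signif(x$weights, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Erlangization fit of a waiting-time distribution
#'
#' Constructive approximation of a probability distribution on
#' \eqn{(0,\infty)} by an Erlang mixture: component \eqn{j} gets shape
#' \eqn{m_j = j - 1} and weight \eqn{q_j = F(j/M) - F((j-1)/M)} for
#' \eqn{j = 1, \dots, L-1}, with the remainder \eqn{q_L = 1 - F((L-1)/M)} on
#' the last component.  The mixture converges weakly to the target as
#' \eqn{M, L \to \infty}.  Components with zero weight are dropped.
#'
#' @param cdf target cumulative distribution function (vectorized,
#'   nondecreasing, \eqn{\to 1}).
#' @param M Erlang rate; the fit bins the target at resolution `1/M`.
#' @param L number of components (bins).
#' @return An `erlang_mixture`.  A warning is raised when the remainder bin
#'   holds more than half the mass (grid `L/M` does not cover the bulk).
#' @export
erlang_fit <- function(cdf, M, L) {
  stopifnot(M > 0, L >= 1L)
  j <- seq_len(L)
  Fr <- cdf(j / M)
  Fl <- cdf((j - 1) / M)
  q <- Fr - Fl
  q[L] <- 1 - Fl[L]
  if (q[L] > 0.5) {
    warning("remainder weight q_L = ", signif(q[L], 3),
            " > 0.5; increase L or decrease M to cover the target's bulk")
  }
  keep <- q > 0
  erlang_mixture(M, q[keep] / sum(q[keep]), (j - 1L)[keep])
}

#' Kolmogorov-Smirnov distance between an Erlang mixture and a target CDF
#'
#' Upper bound proxy for the Lévy-Prokhorov distance (LP <= KS for
#' distributions on the line); also returns a quadrature estimate of the
#' Wasserstein-1 distance \eqn{\int |F - G|}.
#' @param mix `erlang_mixture`.
#' @param cdf target CDF.
#' @param t_max,n evaluation grid.
#' @return List with `ks` and `w1`.
#' @export
mixture_distance <- function(mix, cdf, t_max = NULL, n = 2001L) {
  if (is.null(t_max)) t_max <- (max(mix$shapes) + 1 + 8) / mix$M * 2
  tt <- seq(0, t_max, length.out = n)
  d <- abs(mix$cdf(tt) - cdf(tt))
  list(ks = max(d), w1 = trapz(d, tt[2L] - tt[1L]))
}

#' Realize an Erlang mixture as a reaction chain network
#'
#' Builds the branching-chain network whose first-passage flux into the
#' terminal node reproduces the mixture density exactly: a start node
#' \eqn{\zeta} branches with rates \eqn{q_j M} into \eqn{L} chains of
#' \eqn{m_j} intermediate nodes traversed at uniform rate \eqn{M}, all
#' ending at a common absorbing node \eqn{\omega}.  Under a unit impulse at
#' \eqn{\zeta} the flux into \eqn{\omega} is
#' \eqn{M \sum_j x_{m_j,j}(t) = f(t)}.
#'
#' @param mix `erlang_mixture`.
#' @return `compartment_network` with compartments `chain`
#'   (\eqn{\{\zeta, x_{nj}\}}) and `end` (\eqn{\{\omega\}}).
#' @export
realize_chain <- function(mix) {
  M <- mix$M
  L <- length(mix$weights)
  nodes <- "zeta"
  for (j in seq_len(L)) {
    mj <- mix$shapes[j]
    if (mj > 0L) nodes <- c(nodes, paste0("x", seq_len(mj), "_", j))
  }
  nodes <- c(nodes, "omega")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  add_rate <- function(from, to, r) A[to, from] <<- A[to, from] + r
  for (j in seq_len(L)) {
    mj <- mix$shapes[j]
    qj <- mix$weights[j]
    if (mj == 0L) {
      add_rate("zeta", "omega", qj * M)
    } else {
      add_rate("zeta", paste0("x1_", j), qj * M)
      if (mj > 1L) for (nn in 2L:mj) {
        add_rate(paste0("x", nn - 1L, "_", j), paste0("x", nn, "_", j), M)
      }
      add_rate(paste0("x", mj, "_", j), "omega", M)
    }
  }
  diag(A) <- -colSums(A)
  build_compartment_network(
    validate_rate_matrix(A),
    list(chain = setdiff(nodes, "omega"), end = "omega"))
}

#' Realize a full kernel family as a conservative reaction network
#'
#' Assembles a single-entrance network whose scalar response kernels
#' \eqn{\Psi_{\alpha\beta}} equal \eqn{p_{\alpha\beta}} times the prescribed
#' Erlang mixture densities.  Each compartment \eqn{\alpha} consists of its
#' entrance point \eqn{i_\alpha} plus, for every \eqn{\beta} with
#' \eqn{p_{\alpha\beta} > 0}, the chains of the mixture `mixes[[a]][[b]]`;
#' the entrance point branches directly into chain \eqn{j} of the pair
#' \eqn{(\alpha,\beta)} with rate \eqn{M_\alpha p_{\alpha\beta} q_j}, chains
#' run at rate \eqn{M_\alpha} and end at \eqn{i_\beta}.  Merging the
#' branching into the entrance point makes the kernel reproduce the mixture
#' density exactly (the entrance sojourn supplies the first of the
#' \eqn{m_j + 1} Erlang stages); it requires all mixtures leaving one
#' compartment to share the same rate \eqn{M_\alpha}.
#'
#' @param p |X| x |X| matrix of routing weights with zero diagonal; every row
#'   must sum to 1 (within `1e-9`) or be identically zero (sink).
#' @param mixes nested list: `mixes[[a]][[b]]` an `erlang_mixture` for every
#'   pair with `p[a, b] > 0`.
#' @return `compartment_network` with compartments named by the rows of `p`.
#' @export
realize_network <- function(p, mixes) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p), all(p >= 0))
  comp <- rownames(p) %||% paste0("c", seq_len(nrow(p)))
  dimnames(p) <- list(comp, comp)
  rs <- rowSums(p)
  bad <- abs(rs - 1) > 1e-9 & abs(rs) > 1e-9
  if (any(bad)) {
    stop("rows of p must sum to 1 or 0; offending: ",
         paste(comp[bad], collapse = ", "))
  }
  nodes <- paste0("i_", comp)
  rate_list <- list()
  add_rate <- function(from, to, r) {
    rate_list[[length(rate_list) + 1L]] <<- list(from = from, to = to, r = r)
  }
  partition <- setNames(as.list(paste0("i_", comp)), comp)
  for (a in comp) {
    targets <- comp[p[a, ] > 0]
    if (!length(targets)) next
    Ms <- vapply(targets, function(b) mixes[[a]][[b]]$M, numeric(1L))
    if (length(unique(Ms)) != 1L) {
      stop("all mixtures leaving compartment ", a,
           " must share the same Erlang rate M (got ",
           paste(unique(Ms), collapse = ", "), ")")
    }
    M <- Ms[[1L]]
    for (b in targets) {
      mix <- mixes[[a]][[b]]
      for (j in seq_along(mix$weights)) {
        mj <- mix$shapes[j]
        qj <- mix$weights[j]
        rate0 <- M * p[a, b] * qj
        if (mj == 0L) {
          add_rate(paste0("i_", a), paste0("i_", b), rate0)
        } else {
          chain <- paste0("x", seq_len(mj), "_", a, ".", b, ".", j)
          nodes <- c(nodes, chain)
          partition[[a]] <- c(partition[[a]], chain)
          add_rate(paste0("i_", a), chain[1L], rate0)
          if (mj > 1L) for (nn in 2L:mj) {
            add_rate(chain[nn - 1L], chain[nn], M)
          }
          add_rate(chain[mj], paste0("i_", b), M)
        }
      }
    }
  }
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in rate_list) A[e$to, e$from] <- A[e$to, e$from] + e$r
  diag(A) <- -colSums(A)
  build_compartment_network(validate_rate_matrix(A), partition)
}

#' First-passage flux out of a compartment under an impulse
#'
#' Flux density of arrivals into `to_compartment` at time \eqn{t} given a
#' unit impulse placed at `from_state` at time zero:
#' \eqn{e^\top A_{\beta\alpha}\, e^{tA_{\alpha\alpha}}\, e_{i}}.
#' Used to verify that realized chains reproduce their mixture density.
#'
#' @param net `compartment_network`.
#' @param from_state state label receiving the impulse.
#' @param to_compartment destination compartment name.
#' @param grid `time_grid`.
#' @return Numeric vector of flux values on the grid.
#' @export
first_passage_flux <- function(net, from_state, to_compartment, grid) {
  a <- net$compartment_of[[from_state]]
  stopifnot(to_compartment %in% net$compartments, to_compartment != a)
  Aaa <- net$E[[a]] - net$C[[a]]
  Aba <- net_block(net, to_compartment, a)
  e_i <- as.numeric(net$partition[[a]] == from_state)
  P <- expm_dense(grid$dt * Aaa)
  cur <- e_i
  out <- numeric(grid$n_points)
  out[1L] <- sum(Aba %*% cur)
  for (m in 2L:grid$n_points) {
    cur <- P %*% cur
    out[m] <- sum(Aba %*% cur)
  }
  out
}
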