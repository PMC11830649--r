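#' Uniform time grid
#'
#' Closed uniform grid on `[0, t_end]` with `n_points` nodes,
#' `dt = t_end / (n_points - 1)`.
#' @param t_end final time (> 0).
#' @param n_points number of nodes (>= 2).
#' @return Object of class `time_grid` with `t`, `dt`, `t_end`, `n_points`.
#' @export
time_grid <- function(t_end, n_points) {
  stopifnot(t_end > 0, n_points >= 2)
  n_points <- as.integer(n_points)
  dt <- t_end / (n_points - 1L)
  structure(list(t = seq(0, t_end, length.out = n_points), dt = dt,
                 t_end = t_end, n_points = n_points), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> [0, ", x$t_end, "] with ", x$n_points,
      " nodes (dt = ", signif(x$dt, 4), ")\n", sep = "")
  invisible(x)
}

same_grid <- function(g1, g2, tol = 1e-12) {
  g1$n_points == g2$n_points && abs(g1$t_end - g2$t_end) <= tol * max(1, g1$t_end)
}

#' Generalized response kernels of a compartment network
#'
#' Tabulates the matrix-valued kernels of the compartment reduction on a time
#' grid: the cross kernels
#' \eqn{G_{\beta\alpha}(t) = A_{\alpha\beta}\, e^{t A_{\beta\beta}}}
#' (flux density into \eqn{\alpha} of elements that entered \eqn{\beta} a
#' time \eqn{t} ago) and the loss kernels
#' \eqn{K_\alpha(t) = C_\alpha\, e^{t A_{\alpha\alpha}}}.  One matrix
#' exponential `expm(dt * A_bb)` is computed per compartment block and the
#' time series is propagated by repeated multiplication, so the semigroup
#' property holds exactly on the grid.
#'
#' @param net a `compartment_network`.
#' @param grid a `time_grid`.
#' @return Object of class `kernel_family` with elements `grid`,
#'   `compartments`, `G` (list over "beta|alpha" keys of |alpha| x |beta| x
#'   n_points arrays), `K` (list over compartments of |alpha| x |alpha| x
#'   n_points arrays), `provenance = "ode"`, `net`.
#' @export
grfe_kernels <- function(net, grid) {
  stopifnot(inherits(net, "compartment_network"), inherits(grid, "time_grid"))
  comp <- net$compartments
  np <- grid$n_points

  # e^{t_m A_bb} series per compartment
  Eser <- list()
  for (b in comp) {
    Abb <- net$E[[b]] - net$C[[b]]
    nb <- nrow(Abb)
    P <- expm_dense(grid$dt * Abb)
    arr <- array(0, dim = c(nb, nb, np),
                 dimnames = list(rownames(Abb), colnames(Abb), NULL))
    cur <- diag(nb)
    arr[, , 1L] <- cur
    for (m in seq_len(np - 1L)) {
      cur <- cur %*% P
      arr[, , m + 1L] <- cur
    }
    Eser[[b]] <- arr
  }

  G <- list()
  K <- list()
  for (a in comp) {
    na <- length(net$partition[[a]])
    loss <- net_loss(net, a)
    Karr <- array(0, dim = c(na, na, np),
                  dimnames = list(net$partition[[a]], net$partition[[a]], NULL))
    for (m in seq_len(np)) Karr[, , m] <- loss * Eser[[a]][, , m]
    K[[a]] <- Karr
    for (b in setdiff(comp, a)) {
      Aab <- net_block(net, a, b)     # |a| x |b|, rates into a from b
      nb <- ncol(Aab)
      Garr <- array(0, dim = c(na, nb, np),
                    dimnames = list(net$partition[[a]], net$partition[[b]],
                                    NULL))
      for (m in seq_len(np)) Garr[, , m] <- Aab %*% Eser[[b]][, , m]
      G[[paste(b, a, sep = "|")]] <- Garr
    }
  }
  structure(list(grid = grid, compartments = comp, G = G, K = K,
                 provenance = "ode", net = net, scalar = NULL),
            class = "kernel_family")
}

#' @export
print.kernel_family <- function(x, ...) {
  cat("<kernel_family> ", length(x$compartments), " compartments, ",
      x$grid$n_points, " time nodes, provenance \"", x$provenance, "\"",
      if (!is.null(x$scalar)) ", scalar kernels populated" else "",
      "\n", sep = "")
  invisible(x)
}

#' Transient forcing functions from an initial state
#'
#' Tabulates the transient response of the initial occupancy `n0`:
#' \eqn{S^0_\alpha(t) = \sum_{\beta\ne\alpha} G_{\beta\alpha}(t)\, n^0_\beta}
#' and \eqn{J^0_\alpha(t) = K_\alpha(t)\, n^0_\alpha}, plus the initial
#' compartment totals \eqn{N^0_\alpha}.  When the kernel family carries
#' scalar kernels, the scalar forcings \eqn{B^0_\alpha = (S^0_\alpha)_{i_\alpha}}
#' and \eqn{D^0_\alpha = e^\top J^0_\alpha} are included.
#'
#' @param k a `kernel_family` from [grfe_kernels()] (optionally after
#'   [scalar_kernels()]).
#' @param n0 nonnegative numeric vector over states (named or in state order).
#' @return Object of class `forcing_set` with `grid`, `S0`, `J0` (lists of
#'   |alpha| x n_points matrices), `N0`, and scalar `B0`, `D0` matrices
#'   (|X| x n_points) when available.
#' @export
grfe_forcing <- function(k, n0) {
  stopifnot(inherits(k, "kernel_family"))
  net <- k$net
  if (is.null(net)) stop("forcing from initial states needs ODE-derived kernels")
  states <- net$states
  if (!is.null(names(n0))) n0 <- n0[states]
  if (length(n0) != length(states) || anyNA(n0)) {
    stop("n0 must assign a value to every state")
  }
  if (any(n0 < 0)) stop("n0 entries must be nonnegative")
  names(n0) <- states
  np <- k$grid$n_points
  comp <- k$compartments
  S0 <- J0 <- list()
  N0 <- setNames(numeric(length(comp)), comp)
  for (a in comp) {
    na <- length(net$partition[[a]])
    n0a <- n0[net$partition[[a]]]
    N0[[a]] <- sum(n0a)
    S0m <- matrix(0, na, np, dimnames = list(net$partition[[a]], NULL))
    for (b in setdiff(comp, a)) {
      Garr <- k$G[[paste(b, a, sep = "|")]]
      n0b <- n0[net$partition[[b]]]
      for (m in seq_len(np)) {
        S0m[, m] <- S0m[, m] +
          matrix(Garr[, , m], na, length(n0b)) %*% n0b
      }
    }
    J0m <- matrix(0, na, np, dimnames = list(net$partition[[a]], NULL))
    for (m in seq_len(np)) {
      J0m[, m] <- matrix(k$K[[a]][, , m], na, na) %*% n0a
    }
    S0[[a]] <- S0m
    J0[[a]] <- J0m
  }
  out <- structure(list(grid = k$grid, compartments = comp, S0 = S0, J0 = J0,
                        N0 = N0, B0 = NULL, D0 = NULL, n0 = n0),
                   class = "forcing_set")
  if (!is.null(k$scalar)) {
    ep <- k$scalar$entrance
    B0 <- D0 <- matrix(0, length(comp), np, dimnames = list(comp, NULL))
    for (a in comp) {
      if (!is.na(ep[[a]])) B0[a, ] <- S0[[a]][ep[[a]], ]
      D0[a, ] <- colSums(J0[[a]])
    }
    out$B0 <- B0
    out$D0 <- D0
  }
  out
}

#' Scalar response kernels for single-entrance partitions
#'
#' When every compartment has at most one entrance point \eqn{i_\alpha}, the
#' generalized kernels collapse to scalar response functions
#' \eqn{\Phi_{\alpha\beta}(t) = (G_{\alpha\beta}(t))_{i_\beta i_\alpha}}
#' (waiting-time density for exit from \eqn{\alpha} towards \eqn{\beta}) and
#' total exit kernels \eqn{k_\alpha(t) = \sum_j (K_\alpha(t))_{j i_\alpha}}.
#' Compartments with no entrance point get identically zero kernels.
#'
#' @param k a `kernel_family` from [grfe_kernels()] (ODE provenance), or a
#'   `compartment_network` (kernels are computed first).
#' @param grid `time_grid`, required when `k` is a network.
#' @return The `kernel_family` with a `scalar` element: `Phi` (|X| x |X| x
#'   n_points array, `Phi[a, b, ]` = \eqn{\Phi_{\alpha\beta}}), `k_exit`
#'   (|X| x n_points), `entrance` (named vector of entrance state labels,
#'   `NA` when absent).
#' @export
scalar_kernels <- function(k, grid = NULL) {
  if (inherits(k, "compartment_network")) {
    stopifnot(!is.null(grid))
    k <- grfe_kernels(k, grid)
  }
  stopifnot(inherits(k, "kernel_family"))
  net <- k$net
  if (is.null(net)) stop("scalar reduction requires ODE-derived kernels")
  nep <- lengths(net$entrance_points)
  if (any(nep > 1L)) {
    stop("compartments with multiple entrance points: ",
         paste(names(nep)[nep > 1L], collapse = ", "),
         "; the scalar reduction requires at most one entrance point each")
  }
  comp <- k$compartments
  np <- k$grid$n_points
  # entrance point; a singleton compartment that receives nothing still has
  # a well-defined entry pathway through its only state
  entrance <- vapply(comp, function(a) {
    ep <- net$entrance_points[[a]]
    if (length(ep)) ep
    else if (length(net$partition[[a]]) == 1L) net$partition[[a]]
    else NA_character_
  }, character(1L))
  Phi <- array(0, dim = c(length(comp), length(comp), np),
               dimnames = list(comp, comp, NULL))
  k_exit <- matrix(0, length(comp), np, dimnames = list(comp, NULL))
  for (a in comp) {
    ia <- entrance[[a]]
    if (is.na(ia)) next
    # exit kernel k_a(t) = e^T K_a(t) e_{i_a}
    k_exit[a, ] <- apply(k$K[[a]][, ia, , drop = FALSE], 3L, sum)
    for (b in setdiff(comp, a)) {
      ib <- entrance[[b]]
      if (is.na(ib)) next
      # Phi_{ab}(t) = (G_{ab}(t))_{i_b, i_a} with G_{ab} = A_{ba} e^{t A_aa}
      Phi[a, b, ] <- k$G[[paste(a, b, sep = "|")]][ib, ia, ]
    }
  }
  k$scalar <- list(Phi = Phi, k_exit = k_exit, entrance = entrance)
  k
}

#' Construct a kernel family from tabulated scalar kernels
#'
#' Wraps externally supplied scalar response kernels (e.g. measured, or
#' produced by [kernels_from_rates()]) into the container used by the
#' solvers and spectral analyses.
#'
#' @param Phi |X| x |X| x n_points array, `Phi[a, b, ]` the waiting-time
#'   density for exit from compartment `a` towards `b`; diagonal ignored.
#' @param grid `time_grid` matching the third dimension.
#' @param k_exit optional |X| x n_points matrix of total exit kernels;
#'   defaults to \eqn{k_\alpha = \sum_{\beta\ne\alpha} \Phi_{\alpha\beta}}.
#' @return A `kernel_family` with `provenance = "tabulated"`.
#' @export
tabulated_kernels <- function(Phi, grid, k_exit = NULL) {
  stopifnot(inherits(grid, "time_grid"), length(dim(Phi)) == 3L,
            dim(Phi)[1L] == dim(Phi)[2L], dim(Phi)[3L] == grid$n_points)
  comp <- dimnames(Phi)[[1L]] %||% paste0("c", seq_len(dim(Phi)[1L]))
  dimnames(Phi) <- list(comp, comp, NULL)
  for (a in comp) Phi[a, a, ] <- 0
  if (any(Phi < 0)) stop("kernel entries must be nonnegative")
  if (is.null(k_exit)) k_exit <- apply(Phi, c(1L, 3L), sum)
  dimnames(k_exit) <- list(comp, NULL)
  structure(list(grid = grid, compartments = comp, G = NULL, K = NULL,
                 provenance = "tabulated", net = NULL,
                 scalar = list(Phi = Phi, k_exit = k_exit,
                               entrance = setNames(rep(NA_character_,
                                                       length(comp)), comp))),
            class = "kernel_family")
}

#' Kernel masses, totals and sink diagnostics
#'
#' Computes the improper time-integrals \eqn{\int_0^\infty \Phi_{\alpha\beta}}
#' of the scalar kernels, their per-compartment totals, and the mass trapped
#' inside each compartment,
#' \eqn{\lim_{t\to\infty} e^\top e^{t A_{\alpha\alpha}} e_{i_\alpha}}.
#' For ODE-derived kernels the integrals are exact resolvent expressions
#' evaluated on the decaying invariant subspace
#' (\eqn{\int_0^\infty A_{\beta\alpha} e^{tA_{\alpha\alpha}}\,dt =
#' -A_{\beta\alpha} A_{\alpha\alpha}^{-1}} there); for tabulated kernels the
#' trapezoid on the grid is augmented by a single-exponential tail estimate
#' from the final decade of samples.
#'
#' @param k a `kernel_family` with scalar kernels.
#' @return List with `pair_mass` (|X| x |X| matrix, row = source compartment),
#'   `total_mass` (per source compartment), `limit_term` (trapped-mass limit,
#'   ODE provenance only), `tail` (tabulated provenance: list of tail fits),
#'   `sink` (logical: compartment emits no mass).
#' @export
kernel_mass <- function(k) {
  stopifnot(inherits(k, "kernel_family"))
  if (is.null(k$scalar)) stop("scalar kernels required; run scalar_kernels()")
  comp <- k$compartments
  nX <- length(comp)
  pm <- matrix(0, nX, nX, dimnames = list(comp, comp))
  limit_term <- setNames(rep(NA_real_, nX), comp)
  tails <- NULL
  if (k$provenance == "ode") {
    net <- k$net
    ep <- k$scalar$entrance
    for (a in comp) {
      ia <- ep[[a]]
      if (is.na(ia)) { limit_term[[a]] <- NA_real_; next }
      Aaa <- net$E[[a]] - net$C[[a]]
      Y <- block_resolvent_integral(Aaa)
      P0 <- block_limit_projection(Aaa)
      e_ia <- as.numeric(net$partition[[a]] == ia)
      limit_term[[a]] <- sum(P0 %*% e_ia)
      for (b in setdiff(comp, a)) {
        ib <- ep[[b]]
        if (is.na(ib)) next
        Aba <- net_block(net, b, a)   # rates into b from a
        pm[a, b] <- (Aba %*% Y %*% e_ia)[match(ib, net$partition[[b]])]
      }
    }
  } else {
    tails <- list()
    tt <- k$grid$t
    for (a in comp) for (b in setdiff(comp, a)) {
      y <- k$scalar$Phi[a, b, ]
      base <- trapz(y, k$grid$dt)
      tf <- tail_mass(tt, y)
      tails[[paste(a, b, sep = "|")]] <- tf
      pm[a, b] <- base + if (isTRUE(tf$reliable) && is.finite(tf$mass))
        tf$mass else 0
    }
  }
  total <- rowSums(pm)
  list(pair_mass = pm, total_mass = total,
       limit_term = limit_term, tail = tails,
       sink = total < 1e-12)
}

#' Laplace transform of the scalar kernel matrix
#'
#' Evaluates the renewal-equation matrices \eqn{M(z)} (with
#' \eqn{M(z)_{\alpha\beta} = \hat\Phi_{\beta\alpha}(z)} and zero diagonal)
#' and the diagonal \eqn{Q(z)} with \eqn{Q_{\alpha\alpha} = \hat k_\alpha(z)}.
#' ODE-derived kernels use the exact resolvent
#' \eqn{\hat\Phi_{\beta\alpha}(z) =
#' [A_{\alpha\beta}(zI - A_{\beta\beta})^{-1}]_{i_\alpha i_\beta}};
#' tabulated kernels are integrated by trapezoid quadrature of
#' \eqn{e^{-zt}\Phi(t)}.
#'
#' @param k `kernel_family` with scalar kernels.
#' @param z real transform variable.
#' @return List with matrices `M` and `Q`.
#' @export
laplace_kernel <- function(k, z) {
  stopifnot(inherits(k, "kernel_family"))
  if (is.null(k$scalar)) stop("scalar kernels required; run scalar_kernels()")
  comp <- k$compartments
  nX <- length(comp)
  M <- matrix(0, nX, nX, dimnames = list(comp, comp))
  Q <- matrix(0, nX, nX, dimnames = list(comp, comp))
  if (k$provenance == "ode") {
    net <- k$net
    ep <- k$scalar$entrance
    for (b in comp) {
      ib <- ep[[b]]
      if (is.na(ib)) next
      if (all(net_loss(net, b) == 0)) next  # no exits: zero column of M
      Abb <- net$E[[b]] - net$C[[b]]
      R <- zIminusA_solve(z, Abb, b)
      e_ib <- as.numeric(net$partition[[b]] == ib)
      rb <- R %*% e_ib
      Q[b, b] <- sum(net_loss(net, b) * rb)
      for (a in setdiff(comp, b)) {
        ia <- ep[[a]]
        if (is.na(ia)) next
        Aab <- net_block(net, a, b)
        M[a, b] <- (Aab %*% rb)[match(ia, net$partition[[a]])]
      }
    }
  } else {
    w <- exp(-z * k$grid$t)
    for (a in comp) {
      Q[a, a] <- trapz(k$scalar$k_exit[a, ] * w, k$grid$dt)
      for (b in setdiff(comp, a)) {
        M[b, a] <- trapz(k$scalar$Phi[a, b, ] * w, k$grid$dt)
      }
    }
  }
  list(M = M, Q = Q)
}

zIminusA_solve <- function(z, Abb, label) {
  nb <- nrow(Abb)
  Z <- z * diag(nb) - Abb
  d <- determinant(Z, logarithm = TRUE)
  if (!is.finite(d$modulus) || rcond(Z) < 1e-14) {
    stop("z = ", z, " makes (zI - A) singular for compartment block ", label)
  }
  solve(Z)
}

#' Export scalar or matrix kernels as a long-format data frame
#'
#' Columns `(t, from_compartment, to_compartment, row_state, col_state,
#' value)`; scalar kernels use empty `row_state`/`col_state`.
#' @param x a `kernel_family`.
#' @param ... unused.
#' @export
as.data.frame.kernel_family <- function(x, ...) {
  out <- list()
  tt <- x$grid$t
  if (!is.null(x$G)) {
    for (key in names(x$G)) {
      ba <- strsplit(key, "|", fixed = TRUE)[[1L]]
      arr <- x$G[[key]]
      dn <- dimnames(arr)
      for (i in seq_len(dim(arr)[1L])) for (j in seq_len(dim(arr)[2L])) {
        out[[length(out) + 1L]] <- data.frame(
          t = tt, from_compartment = ba[1L], to_compartment = ba[2L],
          row_state = dn[[1L]][i], col_state = dn[[2L]][j],
          value = arr[i, j, ], stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(x$scalar)) {
    comp <- x$compartments
    for (a in comp) for (b in setdiff(comp, a)) {
      out[[length(out) + 1L]] <- data.frame(
        t = tt, from_compartment = a, to_compartment = b,
        row_state = "", col_state = "",
        value = x$scalar$Phi[a, b, ], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Wrap scalar forcing functions into a forcing set
#'
#' @param grid `time_grid`.
#' @param B0 |X| x n_points matrix of influx forcings (rows named by
#'   compartment).
#' @param D0 |X| x n_points matrix of outflux forcings; defaults to zero.
#' @param N0 named vector of initial totals; defaults to zero.
#' @return A `forcing_set` carrying only the scalar fields.
#' @export
scalar_forcing <- function(grid, B0, D0 = NULL, N0 = NULL) {
  stopifnot(inherits(grid, "time_grid"), ncol(B0) == grid$n_points)
  comp <- rownames(B0) %||% paste0("c", seq_len(nrow(B0)))
  rownames(B0) <- comp
  if (is.null(D0)) D0 <- matrix(0, nrow(B0), grid$n_points,
                                dimnames = list(comp, NULL))
  if (is.null(N0)) N0 <- setNames(rep(0, nrow(B0)), comp)
  structure(list(grid = grid, compartments = comp, S0 = NULL, J0 = NULL,
                 B0 = B0, D0 = D0, N0 = N0),
            class = "forcing_set")
}

#' Markov-consistent forcing from initial compartment totals
#'
#' Builds the forcing pair \eqn{D^0_\alpha(t) = k_\alpha(t) N^0_\alpha},
#' \eqn{B^0_\alpha(t) = \sum_{\beta\ne\alpha}\Phi_{\beta\alpha}(t) N^0_\beta},
#' i.e. the transient response of a population that enters every compartment
#' exactly at time zero.  This is the forcing under which Markovianity of the
#' reduced dynamics is decidable from the kernels alone.
#'
#' @param k `kernel_family` with scalar kernels.
#' @param N0 named vector of initial compartment totals.
#' @return A `forcing_set`.
#' @export
consistency_forcing <- function(k, N0) {
  stopifnot(inherits(k, "kernel_family"), !is.null(k$scalar))
  comp <- k$compartments
  if (!is.null(names(N0))) N0 <- N0[comp]
  stopifnot(length(N0) == length(comp), !anyNA(N0))
  N0 <- setNames(as.numeric(N0), comp)
  np <- k$grid$n_points
  B0 <- D0 <- matrix(0, length(comp), np, dimnames = list(comp, NULL))
  for (a in comp) {
    D0[a, ] <- k$scalar$k_exit[a, ] * N0[[a]]
    for (b in setdiff(comp, a)) {
      B0[a, ] <- B0[a, ] + k$scalar$Phi[b, a, ] * N0[[b]]
    }
  }
  scalar_forcing(k$grid, B0, D0, N0)
}
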