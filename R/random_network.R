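#' Generate a random conservative compartment network
#'
#' Fixture generator for conservative linear reaction networks with a
#' compartment partition.  Structural options are imposed by construction
#' where possible and always verified post hoc; the generator resamples (with
#' derived seeds) a bounded number of times before failing.
#'
#' With `detailed_balance = TRUE` rates are constructed as
#' \eqn{\lambda_{ji} = s_{ij}/\mu_i} (i.e. `A[i,j] = s_ij / mu_j`) from a
#' symmetric nonnegative matrix \eqn{s} and a random strictly positive
#' equilibrium \eqn{\mu}, which guarantees \eqn{A_{ij}\mu_j = A_{ji}\mu_i}.
#' With `single_entrance = TRUE` every cross-compartment edge targets one
#' designated entrance state per compartment.  With
#' `strongly_connected = TRUE` compartments are linked in a directed ring
#' (plus random extras) and each compartment's internal graph contains a
#' cycle through all its states, so the full state digraph -- and hence the
#' compartment digraph -- is strongly connected and no compartment hides an
#' internal sink.
#'
#' @param n_states total number of states (>= `n_compartments`).
#' @param n_compartments number of compartments (>= 1).
#' @param seed integer seed.
#' @param single_entrance logical; at most one entrance point per compartment.
#' @param detailed_balance logical; construct reversible rates.
#' @param strongly_connected logical; strongly connected compartment digraph.
#' @param rate_scale positive multiplier applied to all rates.
#' @param max_retries resampling budget before giving up.
#' @return A `compartment_network`.
#' @export
random_conservative_network <- function(n_states, n_compartments, seed = 1L,
                                        single_entrance = FALSE,
                                        detailed_balance = FALSE,
                                        strongly_connected = FALSE,
                                        rate_scale = 1,
                                        max_retries = 25L) {
  stopifnot(n_states >= n_compartments, n_compartments >= 1L, rate_scale > 0)
  for (try in seq_len(max_retries)) {
    set.seed(seed + 7919L * (try - 1L))
    net <- try(generate_network_once(n_states, n_compartments,
                                     single_entrance, detailed_balance,
                                     strongly_connected, rate_scale),
               silent = TRUE)
    if (inherits(net, "try-error")) next
    if (network_satisfies(net, single_entrance, detailed_balance,
                          strongly_connected)) {
      return(net)
    }
  }
  stop("could not generate a network satisfying the requested options in ",
       max_retries, " attempts (n_states=", n_states,
       ", n_compartments=", n_compartments, ")")
}

generate_network_once <- function(n_states, n_compartments, single_entrance,
                                  detailed_balance, strongly_connected,
                                  rate_scale) {
  states <- paste0("s", seq_len(n_states))
  # random partition with at least one state per compartment
  sizes <- rep(1L, n_compartments)
  extra <- n_states - n_compartments
  if (extra > 0L) {
    add <- table(factor(sample.int(n_compartments, extra, replace = TRUE),
                        levels = seq_len(n_compartments)))
    sizes <- sizes + as.integer(add)
  }
  comp_names <- paste0("c", seq_len(n_compartments))
  partition <- split(states, rep(comp_names, sizes))[comp_names]
  entrance <- vapply(partition, function(s) sample(s, 1L), character(1L))

  sup <- matrix(FALSE, n_states, n_states,
                dimnames = list(states, states))  # sup[i,j]: edge i -> j
  add_edge <- function(i, j) sup[i, j] <<- TRUE

  # internal support: cycle through each compartment's states (strong
  # internal connectivity, no internal sinks) plus random chords
  for (a in comp_names) {
    s <- partition[[a]]
    m <- length(s)
    if (m >= 2L) {
      ord <- sample(s)
      for (k in seq_len(m)) add_edge(ord[k], ord[k %% m + 1L])
      n_chord <- sample.int(m, 1L) - 1L
      for (k in seq_len(n_chord)) {
        ij <- sample(s, 2L)
        add_edge(ij[1L], ij[2L])
      }
    }
  }

  # cross support
  cross_target <- function(b) {
    if (single_entrance) entrance[[b]] else sample(partition[[b]], 1L)
  }
  if (n_compartments >= 2L) {
    if (strongly_connected) {
      for (k in seq_len(n_compartments)) {
        a <- comp_names[k]
        b <- comp_names[k %% n_compartments + 1L]
        add_edge(sample(partition[[a]], 1L), cross_target(b))
      }
    }
    n_extra <- n_compartments + sample.int(n_compartments, 1L)
    for (k in seq_len(n_extra)) {
      ab <- sample(comp_names, 2L)
      add_edge(sample(partition[[ab[1L]]], 1L), cross_target(ab[2L]))
    }
  }
  diag(sup) <- FALSE

  A <- matrix(0, n_states, n_states, dimnames = list(states, states))
  if (detailed_balance) {
    # symmetric support; with single entrance, cross edges must pair the
    # entrance points of both compartments
    if (single_entrance && n_compartments >= 2L) {
      comp_of <- setNames(rep(comp_names, lengths(partition)),
                          unlist(partition))[states]
      for (i in states) for (j in states) {
        if (sup[i, j] && comp_of[[i]] != comp_of[[j]]) {
          sup[i, j] <- FALSE
          sup[entrance[[comp_of[[i]]]], entrance[[comp_of[[j]]]]] <- TRUE
        }
      }
    }
    supsym <- sup | t(sup)
    s_mat <- matrix(0, n_states, n_states)
    s_mat[supsym] <- stats::runif(sum(supsym), 0.2, 1)
    s_mat <- (s_mat + t(s_mat)) / 2
    s_mat[!supsym] <- 0
    mu <- stats::runif(n_states, 0.2, 1)
    mu <- mu / sum(mu)
    A <- rate_scale * sweep(s_mat, 2L, mu, `/`)  # A[i,j] = s_ij / mu_j
  } else {
    # A[i,j] = lambda_{ji}: jump j -> i, i.e. support edge (j, i)
    rates <- matrix(0, n_states, n_states)
    rates[t(sup)] <- stats::runif(sum(sup), 0.2, 1) * rate_scale
    A <- rates
    dimnames(A) <- list(states, states)
  }
  diag(A) <- 0
  diag(A) <- -colSums(A)
  build_compartment_network(validate_rate_matrix(A), partition)
}

network_satisfies <- function(net, single_entrance, detailed_balance,
                              strongly_connected) {
  if (single_entrance &&
      any(lengths(net$entrance_points) > 1L)) return(FALSE)
  if (detailed_balance &&
      !check_detailed_balance(net$A, tol = 1e-8)$has_detailed_balance) {
    return(FALSE)
  }
  if (strongly_connected && length(net$compartments) >= 2L) {
    g <- compartment_digraph(net)
    if (!igraph::is_connected(g, mode = "strong")) return(FALSE)
    gs <- igraph::graph_from_adjacency_matrix(
      t(unclass(net$A)) > 0, mode = "directed", diag = FALSE)
    if (!igraph::is_connected(gs, mode = "strong")) return(FALSE)
  }
  TRUE
}
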