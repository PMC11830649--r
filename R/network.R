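#' Decompose a rate matrix into compartments
#'
#' Partitions the state set of a conservative rate matrix into named
#' compartments and precomputes the block decomposition used throughout the
#' package: cross blocks \eqn{A_{\alpha\beta}} (rates into \eqn{\alpha} from
#' \eqn{\beta}), internal conservative blocks \eqn{E_{\alpha\alpha}} and
#' diagonal loss matrices \eqn{C_\alpha} with
#' \eqn{A_{\alpha\alpha} = E_{\alpha\alpha} - C_\alpha}, the directed edge set
#' \eqn{\{(i,j): \lambda_{ij} > 0\}}, and the entrance points of every
#' compartment (states receiving at least one jump from outside their
#' compartment).
#'
#' @param A a `rate_matrix` (see [validate_rate_matrix()]).
#' @param partition named list of character vectors of state labels; the sets
#'   must be non-empty, disjoint, and cover all states.
#' @return An object of class `compartment_network` with elements `A`,
#'   `states`, `partition`, `blocks` (list over "alpha|beta" keys), `E`, `C`
#'   (lists over compartments), `edges` (two-column character matrix,
#'   from/to in jump direction), `entrance_points`.
#' @examples
#' A <- validate_rate_matrix(rbind(c(-1, 0), c(1, 0)))
#' net <- build_compartment_network(A, list(a = "s1", b = "s2"))
#' net$entrance_points
#' @export
build_compartment_network <- function(A, partition) {
  A <- validate_rate_matrix(A)
  states <- attr(A, "states")
  if (is.null(names(partition)) || anyDuplicated(names(partition)) ||
      any(!nzchar(names(partition)))) {
    stop("partition must be a list with unique non-empty names")
  }
  partition <- lapply(partition, as.character)
  if (any(lengths(partition) == 0L)) stop("compartments must be non-empty")
  all_states <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_states)) stop("compartments must be disjoint")
  if (!setequal(all_states, states)) {
    stop("partition does not cover the states of the rate matrix; missing: ",
         paste(setdiff(states, all_states), collapse = ", "),
         "; extra: ", paste(setdiff(all_states, states), collapse = ", "))
  }

  comp_names <- names(partition)
  idx <- lapply(partition, function(s) match(s, states))
  comp_of <- setNames(rep(comp_names, lengths(partition)), all_states)[states]

  Au <- unclass(A)
  blocks <- list()
  E <- C <- list()
  for (a in comp_names) {
    ia <- idx[[a]]
    for (b in comp_names) {
      blocks[[paste(a, b, sep = "|")]] <-
        Au[ia, idx[[b]], drop = FALSE]
    }
    # loss rates out of the compartment: (C_a)_{ii} = sum_{j notin a} lambda_{ij}
    out_idx <- setdiff(seq_along(states), ia)
    loss <- if (length(out_idx)) colSums(Au[out_idx, ia, drop = FALSE]) else
      rep(0, length(ia))
    Eaa <- Au[ia, ia, drop = FALSE]
    # E's diagonal is defined so that E - C reproduces the A block bit-exactly
    diag(Eaa) <- diag(Eaa) + loss
    E[[a]] <- Eaa
    Ca <- diag(loss, nrow = length(ia))
    dimnames(Ca) <- dimnames(Eaa)
    C[[a]] <- Ca
  }

  # edges in jump direction: lambda_{ij} > 0 is A[j, i] > 0
  pos <- which(Au > 0 & row(Au) != col(Au), arr.ind = TRUE)
  edges <- cbind(from = states[pos[, 2L]], to = states[pos[, 1L]])

  entrance_points <- lapply(comp_names, function(a) {
    members <- partition[[a]]
    hit <- edges[, "to"] %in% members & !(edges[, "from"] %in% members)
    sort(unique(edges[hit, "to"]))
  })
  names(entrance_points) <- comp_names

  structure(list(A = A, states = states, partition = partition,
                 compartments = comp_names, state_index = idx,
                 compartment_of = comp_of, blocks = blocks, E = E, C = C,
                 edges = edges, entrance_points = entrance_points),
            class = "compartment_network")
}

#' @export
print.compartment_network <- function(x, ...) {
  cat("<compartment_network> ", length(x$states), " states in ",
      length(x$compartments), " compartments\n", sep = "")
  for (a in x$compartments) {
    ep <- x$entrance_points[[a]]
    cat("  ", a, ": {", paste(x$partition[[a]], collapse = ", "),
        "}  entrance: ",
        if (length(ep)) paste(ep, collapse = ", ") else "(none)", "\n",
        sep = "")
  }
  invisible(x)
}

# Cross block A_{alpha beta} (rates into alpha from beta).
net_block <- function(net, a, b) net$blocks[[paste(a, b, sep = "|")]]

# Diagonal loss-rate vector of compartment a.
net_loss <- function(net, a) diag(net$C[[a]])

#' Reassemble the rate matrix from its blocks
#'
#' Inverse of the block decomposition; used to verify that decomposition is
#' lossless.
#' @param net a `compartment_network`.
#' @return The reassembled rate matrix (plain matrix, state order of `net`).
#' @export
assemble_rate_matrix <- function(net) {
  n <- length(net$states)
  A <- matrix(0, n, n, dimnames = list(net$states, net$states))
  for (a in net$compartments) {
    ia <- net$state_index[[a]]
    for (b in net$compartments) {
      blk <- net_block(net, a, b)
      if (a == b) blk <- net$E[[a]] - net$C[[a]]
      A[ia, net$state_index[[b]]] <- blk
    }
  }
  A
}

#' Compartment-level reachability digraph
#'
#' Directed graph on compartments with an edge \eqn{\alpha \to \beta} whenever
#' some state of \eqn{\alpha} jumps directly to a state of \eqn{\beta}.
#' @param net a `compartment_network`.
#' @return An `igraph` graph.
#' @export
compartment_digraph <- function(net) {
  from <- net$compartment_of[net$edges[, "from"]]
  to <- net$compartment_of[net$edges[, "to"]]
  keep <- from != to
  el <- unique(cbind(from[keep], to[keep]))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(net$compartments),
                            name = net$compartments)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  g
}

#' Read / write the network JSON interchange format
#'
#' The on-disk format stores the edge list in jump direction so the matrix
#' orientation convention is unambiguous:
#' `{"states": [...], "edges": [{"from": i, "to": j, "rate": x}, ...],
#'   "compartments": {"name": [states...]}}`.
#'
#' @param net a `compartment_network`.
#' @param path file path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` returns a `compartment_network`.
#' @export
write_network_json <- function(net, path) {
  Au <- unclass(net$A)
  rates <- apply(net$edges, 1L, function(e) Au[e[["to"]], e[["from"]]])
  obj <- list(
    states = net$states,
    edges = data.frame(from = net$edges[, "from"], to = net$edges[, "to"],
                       rate = as.numeric(rates), stringsAsFactors = FALSE),
    compartments = net$partition
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- as.character(obj$states)
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  ed <- obj$edges
  if (!is.null(ed) && NROW(ed)) {
    for (k in seq_len(nrow(ed))) {
      A[ed$to[k], ed$from[k]] <- ed$rate[k]
    }
  }
  diag(A) <- -colSums(A)
  build_compartment_network(validate_rate_matrix(A),
                            as.list(obj$compartments))
}
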