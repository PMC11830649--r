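#' Validate a reaction-rate matrix
#'
#' A conservative linear reaction network on states \eqn{\Omega} is encoded by
#' a square matrix \eqn{A} with \eqn{A_{ij} = \lambda_{ji} \ge 0} for
#' \eqn{i \ne j} (the jump rate from state \eqn{j} to state \eqn{i} is stored
#' at row \eqn{i}, column \eqn{j}, so that \eqn{dn/dt = A n} without a
#' transpose) and \eqn{A_{ii} = -\sum_{k \ne i} \lambda_{ik}}, i.e. every
#' column sums to zero.  `validate_rate_matrix()` checks these conditions and
#' returns a `rate_matrix` object whose diagonal has been recomputed exactly
#' from the off-diagonal entries.
#'
#' @param A square numeric matrix; row/column names are used as state labels,
#'   otherwise labels `s1, s2, ...` are generated.
#' @param tol absolute tolerance for negative off-diagonal entries and nonzero
#'   column sums; defaults to `1e-9 * max(abs(A))`.
#' @return An object of class `rate_matrix`: the validated matrix with state
#'   labels as dimnames and attribute `states`.
#' @examples
#' A <- rbind(c(-1, 2), c(1, -2))
#' validate_rate_matrix(A)
#' @export
validate_rate_matrix <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("rate matrix must be square, got ", nrow(A), " x ", ncol(A))
  }
  if (!all(is.finite(A))) stop("rate matrix contains non-finite entries")
  n <- nrow(A)
  states <- rownames(A) %||% colnames(A) %||% paste0("s", seq_len(n))
  if (anyDuplicated(states)) stop("state labels must be unique")
  dimnames(A) <- list(states, states)
  if (is.null(tol)) tol <- 1e-9 * max(1, max(abs(A)))

  off <- A
  diag(off) <- 0
  bad <- which(off < -tol, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative off-diagonal rate at state pair (",
         states[bad[1L, 2L]], " -> ", states[bad[1L, 1L]], "): ",
         off[bad[1L, , drop = FALSE]])
  }
  off[off < 0] <- 0

  cs <- colSums(A)
  if (any(abs(cs) > tol)) {
    j <- which.max(abs(cs))
    stop("column sum nonzero at ", states[j], " (", signif(cs[j], 6),
         "); matrix is not conservative")
  }
  # diagonal is authoritative: recompute exact column-sum-zero
  diag(off) <- 0
  diag(off) <- -colSums(off)
  structure(off, class = "rate_matrix", states = states)
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> ", nrow(x), " states: ",
      paste(utils::head(attr(x, "states"), 8L), collapse = ", "),
      if (nrow(x) > 8L) ", ..." else "", "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Test a rate matrix for detailed balance
#'
#' Computes the equilibrium distribution \eqn{\mu} (normalized null vector of
#' \eqn{A}) and the largest violation of the pairwise balance conditions
#' \eqn{A_{ij}\mu_j = A_{ji}\mu_i}.  Detailed balance holds iff the null space
#' is one-dimensional, \eqn{\mu} is strictly positive and the violation is
#' below `tol` (relative to the largest flux).  A reducible matrix with a
#' multi-dimensional null space is reported with status
#' `"non-unique equilibrium"` rather than raising an error.
#'
#' @param A a `rate_matrix` (or coercible matrix).
#' @param tol relative tolerance on the balance violation (default `1e-8`).
#' @return A list of class `equilibrium_report` with elements
#'   `has_detailed_balance`, `mu` (or `NULL`), `max_violation`, `status`.
#' @examples
#' A <- validate_rate_matrix(rbind(c(-1, 2), c(1, -2)))
#' check_detailed_balance(A)  # mu = (2/3, 1/3)
#' @export
check_detailed_balance <- function(A, tol = 1e-8) {
  A <- validate_rate_matrix(A)
  n <- nrow(A)
  states <- attr(A, "states")
  sv <- svd(unclass(A))
  scale <- max(sv$d)
  null_dim <- sum(sv$d < 1e-10 * max(1, scale))
  if (null_dim != 1L) {
    return(structure(list(has_detailed_balance = FALSE, mu = NULL,
                          max_violation = NA_real_,
                          status = "non-unique equilibrium"),
                     class = "equilibrium_report"))
  }
  mu <- sv$v[, n]
  if (sum(mu) < 0) mu <- -mu
  positive <- all(mu > 1e-12 * max(mu))
  mu <- mu / sum(mu)
  names(mu) <- states
  F1 <- sweep(unclass(A), 2L, mu, `*`)  # A_{ij} mu_j
  viol <- max(abs(F1 - t(F1)))
  pos_flux <- F1[F1 > 0]
  rel <- if (length(pos_flux)) viol / max(pos_flux) else 0
  ok <- positive && rel <= tol
  structure(list(has_detailed_balance = ok,
                 mu = if (positive) mu else NULL,
                 max_violation = viol,
                 status = if (ok) "detailed balance" else if (!positive)
                   "equilibrium not strictly positive" else "balance violated"),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report> ", x$status,
      "; max pairwise violation = ", signif(x$max_violation, 4), "\n", sep = "")
  invisible(x)
}
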