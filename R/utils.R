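# Internal numerical helpers shared across modules.

#' @importFrom Matrix expm
#' @importFrom stats setNames
NULL

# Dense matrix exponential (scaling-and-squaring via Matrix).
expm_dense <- function(A) {
  if (length(A) == 1L) return(matrix(exp(A[1L]), 1L, 1L, dimnames = dimnames(A)))
  out <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
  dimnames(out) <- dimnames(A)
  out
}

# Spectral (oblique) projector onto ker(A) along range(A).  For the
# sub-generator blocks used here the zero eigenvalue is semisimple
# (lim e^{tA} exists), so the projector is V0 (U0^T V0)^{-1} U0^T with V0 /
# U0 orthonormal bases of the right / left null spaces (from the SVD).
block_null_projector <- function(A, ztol = NULL) {
  n <- nrow(A)
  if (is.null(ztol)) ztol <- 1e-10 * max(1, max(abs(A)))
  s <- svd(A)
  r0 <- which(s$d < ztol)
  if (!length(r0)) return(matrix(0, n, n, dimnames = dimnames(A)))
  V0 <- s$v[, r0, drop = FALSE]
  U0 <- s$u[, r0, drop = FALSE]
  P0 <- V0 %*% solve(crossprod(U0, V0), t(U0))
  dimnames(P0) <- dimnames(A)
  P0
}

# integral_0^inf (e^{tA} - P0) dt on the decaying subspace; equals the
# negated Drazin inverse -(A + P0)^{-1}(I - P0), exact also for defective
# blocks (Jordan chains), unlike an eigendecomposition route.
block_resolvent_integral <- function(A) {
  P0 <- block_null_projector(A)
  -solve(A + P0, diag(nrow(A)) - P0)
}

# integral_0^inf t e^{tA} dt on the decaying subspace: (A + P0)^{-2}(I - P0).
block_first_moment_integral <- function(A) {
  P0 <- block_null_projector(A)
  B <- solve(A + P0)
  B %*% B %*% (diag(nrow(A)) - P0)
}

# lim_{t->inf} e^{tA}: the spectral projection onto ker(A).
block_limit_projection <- function(A) {
  block_null_projector(A)
}

# Spectral radius of a (small, dense) nonnegative matrix.
spectral_radius <- function(M) {
  if (length(M) == 1L) return(abs(M[1L]))
  max(Mod(eigen(M, only.values = TRUE)$values))
}

# Right Perron eigenvector of an irreducible nonnegative matrix, 1-norm
# normalized and nonnegative.
perron_vector <- function(M, left = FALSE) {
  if (left) M <- t(M)
  if (length(M) == 1L) return(1)
  ev <- eigen(M)
  i <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, i])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sum(v)
}

# Trapezoid cumulative integral of a sampled function (vector y on a uniform
# grid with step dt); returns vector of same length starting at 0.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  c(0, cumsum((y[-n] + y[-1L]) / 2) * dt)
}

trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-n] + y[-1L]) / 2) * dt
}

# Exponential tail mass estimate from the final decade of samples:
# fit log y ~ t on the last fraction of the grid, return integral_{t_end}^inf.
tail_mass <- function(t, y, frac = 0.1) {
  n <- length(y)
  i <- seq.int(max(1L, floor(n * (1 - frac))), n)
  yi <- y[i]
  if (all(yi <= 0)) return(list(mass = 0, rate = NA_real_, reliable = TRUE))
  pos <- yi > 0
  if (sum(pos) < 3L) return(list(mass = 0, rate = NA_real_, reliable = FALSE))
  fit <- stats::lm.fit(cbind(1, t[i][pos]), log(yi[pos]))
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope >= 0) {
    return(list(mass = NA_real_, rate = NA_real_, reliable = FALSE))
  }
  list(mass = y[n] / (-slope), rate = -slope, reliable = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Composite Simpson rule on a uniform grid (n_points odd preferred; a
# trapezoid patch covers a trailing even interval).
simpson <- function(y, dt) {
  n <- length(y)
  if (n < 3L) return(trapz(y, dt))
  m <- if (n %% 2L == 1L) n else n - 1L
  i <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1L] <- 1; w[m] <- 1
  s <- sum(w * y[i]) * dt / 3
  if (m < n) s <- s + (y[n - 1L] + y[n]) / 2 * dt
  s
}
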