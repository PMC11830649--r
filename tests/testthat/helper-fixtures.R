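# Shared fixtures, all built in code.

# Two states, single jump s1 -> s2 at unit rate; compartments {s1}, {s2}.
two_state_chain <- function() {
  A <- matrix(0, 2L, 2L)
  A[2L, 1L] <- 1
  diag(A) <- -colSums(A)
  build_compartment_network(validate_rate_matrix(A),
                            list(a = "s1", b = "s2"))
}

# Irreversible 3-cycle s1 -> s2 -> s3 -> s1 (fails detailed balance by the
# Kolmogorov cycle criterion).
three_cycle <- function() {
  A <- matrix(0, 3L, 3L)
  A[2L, 1L] <- 1; A[3L, 2L] <- 1; A[1L, 3L] <- 1
  diag(A) <- -colSums(A)
  validate_rate_matrix(A)
}

# Compartment with an internal sink: i_a = s1 feeds s2 (absorbing inside a)
# and s3 -> b; mass entering at s1 partly never leaves a.
sink_inside_compartment <- function() {
  st <- c("s1", "s2", "s3", "s4")
  A <- matrix(0, 4L, 4L, dimnames = list(st, st))
  A["s2", "s1"] <- 1      # s1 -> s2 (internal trap)
  A["s3", "s1"] <- 1      # s1 -> s3
  A["s4", "s3"] <- 2      # s3 -> b
  A["s1", "s4"] <- 0.5    # b -> i_a, so a has entrance point s1
  diag(A) <- -colSums(A)
  build_compartment_network(validate_rate_matrix(A),
                            list(a = c("s1", "s2", "s3"), b = "s4"))
}

# Two symmetric compartments with exponential cross kernels e^{-t}
# (realized exactly as a 2-state network so Laplace transforms are closed
# form).
symmetric_exponential_pair <- function(grid) {
  A <- matrix(0, 2L, 2L)
  A[2L, 1L] <- 1; A[1L, 2L] <- 1
  diag(A) <- -colSums(A)
  net <- build_compartment_network(validate_rate_matrix(A),
                                   list(a = "s1", b = "s2"))
  scalar_kernels(net, grid)
}

# Tabulated Erlang-2 kernels t e^{-t} in both directions.
erlang2_pair <- function(grid) {
  Phi <- array(0, dim = c(2L, 2L, grid$n_points),
               dimnames = list(c("a", "b"), c("a", "b"), NULL))
  Phi["a", "b", ] <- grid$t * exp(-grid$t)
  Phi["b", "a", ] <- grid$t * exp(-grid$t)
  tabulated_kernels(Phi, grid)
}

random_n0 <- function(net, seed = 1L) {
  set.seed(seed)
  setNames(stats::runif(length(net$states), 0.1, 1), net$states)
}

expm_ref <- function(M) as.matrix(Matrix::expm(M))
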