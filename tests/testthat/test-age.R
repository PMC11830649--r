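test_that("pure transport shifts the initial profile along characteristics", {
  comp <- c("a", "b")
  rates <- age_rates(list(a = list(b = 0), b = list(a = 0)), comp)
  g <- time_grid(1, 101)
  ages <- seq(0, 1, by = g$dt)
  prof <- sin(ages) + 1
  m <- age_history(density = rbind(a = prof, b = rep(0, length(ages))),
                   ages = ages, compartments = comp)
  f <- spe_solve(rates, m, g)
  expect_equal(f$f["a", 101, 101:201], prof, tolerance = 1e-12)
})

test_that("constant rates collapse to the Markov ODE and conserve mass", {
  comp <- c("a", "b")
  rates <- age_rates(list(a = list(b = 0.7), b = list(a = 0.4)), comp)
  Lam <- rbind(c(-0.7, 0.4), c(0.7, -0.4))
  m <- age_history(points = list(a = data.frame(age = 0, weight = 2),
                                 b = data.frame(age = 0, weight = 1)),
                   compartments = comp)
  g <- time_grid(4, 801)
  N <- aggregate_age_density(spe_solve(rates, m, g))
  N_ref <- vapply(g$t, function(t) as.numeric(expm_ref(t * Lam) %*% c(2, 1)),
                  numeric(2L))
  expect_lt(max(abs(N - N_ref)), 2e-5)
  expect_lt(max(abs(colSums(N) - 3)), 3e-5)

  # quadratic convergence under step halving
  g2 <- time_grid(4, 1601)
  N2 <- aggregate_age_density(spe_solve(rates, m, g2))
  N2_ref <- vapply(g2$t, function(t)
    as.numeric(expm_ref(t * Lam) %*% c(2, 1)), numeric(2L))
  expect_gt(max(abs(N - N_ref)) / max(abs(N2 - N2_ref)), 3)
})

test_that("kernels from rates: exponential case and the survival identity", {
  comp <- c("a", "b")
  rates <- age_rates(list(a = list(b = 0.7), b = list(a = 0.4)), comp)
  g <- time_grid(10, 2001)
  k <- kernels_from_rates(rates, g)
  expect_equal(k$scalar$Phi["a", "b", ], 0.7 * exp(-0.7 * g$t),
               tolerance = 1e-12)
  expect_lt(attr(k, "survival_identity_dev"), 5e-6)

  # zero rates give zero kernels
  r0 <- age_rates(list(a = list(b = 0), b = list(a = 0)), comp)
  k0 <- kernels_from_rates(r0, time_grid(2, 51))
  expect_equal(max(abs(k0$scalar$Phi)), 0)
})

test_that("rates from kernels: closed-form examples and round trip", {
  comp <- c("a", "b")
  g <- time_grid(4, 1601)
  Phi <- array(0, dim = c(2L, 2L, g$n_points),
               dimnames = list(comp, comp, NULL))
  Phi["a", "b", ] <- g$t * exp(-g$t)          # Erlang-2
  Phi["b", "a", ] <- 0.5 * exp(-0.5 * g$t)    # exponential
  k <- tabulated_kernels(Phi, g)
  rr <- rates_from_kernels(k)
  # Erlang-2 kernel has hazard t/(1+t); exponential has constant hazard
  expect_lt(max(abs(rr$lambda("a", "b", g$t) - g$t / (1 + g$t))), 1e-5)
  expect_lt(max(abs(rr$lambda("b", "a", g$t) - 0.5)), 1e-5)
  # round trip back to kernels
  k2 <- kernels_from_rates(rr, g)
  expect_lt(max(abs(k2$scalar$Phi - Phi)), 1e-5)
})

test_that("exhausted survival is reported as an error", {
  comp <- c("a", "b")
  g <- time_grid(30, 601)
  Phi <- array(0, dim = c(2L, 2L, g$n_points),
               dimnames = list(comp, comp, NULL))
  Phi["a", "b", ] <- 2 * exp(-2 * g$t)   # mass 1 - e^{-60}: gone inside grid
  Phi["b", "a", ] <- 2 * exp(-2 * g$t)
  expect_error(rates_from_kernels(tabulated_kernels(Phi, g)),
               "survival exhausted")
})

test_that("history forcing: zero history, impulse-at-zero consistency, smoothing", {
  comp <- c("a", "b")
  net <- random_conservative_network(6, 2, seed = 3, single_entrance = TRUE,
                                     strongly_connected = TRUE)
  g <- time_grid(6, 601)
  k <- scalar_kernels(net, g)

  m0 <- age_history(compartments = net$compartments)
  f0 <- forcing_from_history(k, m0)
  expect_equal(max(abs(f0$B0)), 0)
  expect_equal(max(abs(f0$D0)), 0)

  # point mass at age zero reproduces the Markov-consistent forcing
  N0 <- c(1.2, 0.8)
  mp <- age_history(points = setNames(list(
    data.frame(age = 0, weight = N0[1L]),
    data.frame(age = 0, weight = N0[2L])), net$compartments),
    compartments = net$compartments)
  fp <- forcing_from_history(k, mp)
  fc <- consistency_forcing(k, setNames(N0, net$compartments))
  expect_lt(max(abs(fp$B0 - fc$B0)), 1e-10)
  expect_lt(max(abs(fp$D0 - fc$D0)), 1e-10)
  expect_equal(unname(fp$N0), N0, tolerance = 1e-6)

  # spread history smooths the forcing (smaller total variation than the
  # kernel-induced impulse response)
  ages <- seq(0, 2, by = g$dt)
  dens <- matrix(0.5, 2L, length(ages),
                 dimnames = list(net$compartments, NULL))
  ms <- age_history(density = dens, ages = ages,
                    compartments = net$compartments)
  fs <- forcing_from_history(k, ms)
  tv <- function(x) sum(abs(diff(x)))
  expect_lt(tv(fs$B0[1L, ]), tv(fc$B0[1L, ]) + 1e-8)
})

test_that("age-structure and renewal descriptions agree in both directions", {
  comp <- c("a", "b")
  rates <- age_rates(list(a = list(b = function(x) 0.5 + 0.3 * x / (1 + x)),
                          b = list(a = function(x) 0.8 * exp(-0.2 * x))),
                     comp)
  g <- time_grid(5, 1001)
  m <- age_history(points = list(a = data.frame(age = 0, weight = 1.5),
                                 b = data.frame(age = 0, weight = 0.5)),
                   compartments = comp)
  # forward: aggregate the SPE solution
  N_spe <- aggregate_age_density(spe_solve(rates, m, g))
  # renewal route with the induced kernels and history forcing
  k <- kernels_from_rates(rates, g)
  sol <- solve_rfe(k, forcing_from_history(k, m))
  expect_lt(max(abs(N_spe - sol$N)), 1e-4)

  # reverse: start from the kernels, recover rates, re-solve the SPE
  rr <- rates_from_kernels(k)
  N_spe2 <- aggregate_age_density(spe_solve(rr, m, g))
  expect_lt(max(abs(N_spe2 - sol$N)), 1e-4)

  # refinement shrinks the gap roughly quadratically
  g2 <- time_grid(5, 2001)
  N_spe_f <- aggregate_age_density(spe_solve(rates, m, g2))
  k2 <- kernels_from_rates(rates, g2)
  sol2 <- solve_rfe(k2, forcing_from_history(k2, m))
  gap1 <- max(abs(N_spe - sol$N))
  gap2 <- max(abs(N_spe_f - sol2$N))
  expect_gt(gap1 / gap2, 3)
})

test_that("admissible histories satisfy the initial-state compatibility condition", {
  net <- random_conservative_network(5, 2, seed = 8)
  set.seed(8)
  n0 <- setNames(stats::runif(5), net$states)
  # point mass at age zero is always admissible
  pts <- setNames(lapply(net$states, function(s)
    data.frame(age = 0, weight = n0[[s]])), net$states)
  m <- age_history(points = pts, compartments = net$states)
  res <- admissible_history(net, n0, m)
  expect_true(res$admissible)
  expect_lt(res$residual_norm, 1e-12)

  # generic mismatched history is inadmissible
  pts2 <- setNames(lapply(net$states, function(s)
    data.frame(age = 1, weight = n0[[s]])), net$states)
  m2 <- age_history(points = pts2, compartments = net$states)
  expect_false(admissible_history(net, n0, m2)$admissible)

  # scalar block: exponentially tilted history reproduces n0 exactly
  A <- validate_rate_matrix(rbind(c(-1, 0), c(1, 0)))
  net1 <- build_compartment_network(A, list(a = "s1", b = "s2"))
  # m_a(da) = c e^{-a} da on block A_aa = -1: integral of e^{a A} m =
  # c int e^{-2a} da = c / 2, so c = 2 n0 reproduces n0
  ages <- seq(0, 40, by = 0.01)
  dens <- matrix(0, 2L, length(ages), dimnames = list(c("s1", "s2"), NULL))
  dens["s1", ] <- 2 * 0.7 * exp(-ages)
  m3 <- age_history(density = dens, ages = ages,
                    compartments = c("s1", "s2"))
  res3 <- admissible_history(net1, c(s1 = 0.7, s2 = 0), m3)
  expect_lt(abs(res3$residual[["s1"]]), 1e-4)
})
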