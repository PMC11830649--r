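test_that("two-state chain has the closed-form exponential kernel", {
  net <- two_state_chain()
  g <- time_grid(10, 501)
  k <- scalar_kernels(net, g)
  expect_equal(k$scalar$Phi["a", "b", ], exp(-g$t), tolerance = 1e-12)
  expect_equal(k$scalar$k_exit["a", ], exp(-g$t), tolerance = 1e-12)
  # G_{ab}(t) is the 1x1 matrix e^{-t}
  expect_equal(as.numeric(k$G[["a|b"]][1, 1, ]), exp(-g$t),
               tolerance = 1e-12)
})

test_that("compartments without outgoing edges have identically zero loss kernels", {
  net <- two_state_chain()           # compartment b = {s2} is a sink
  k <- scalar_kernels(net, time_grid(5, 101))
  expect_equal(max(abs(k$K$b)), 0)
  expect_equal(max(abs(k$scalar$k_exit["b", ])), 0)
  expect_equal(max(abs(k$scalar$Phi["b", , ])), 0)
})

test_that("kernel masses: normalization, sinks, and trapped internal mass", {
  net <- two_state_chain()
  k <- scalar_kernels(net, time_grid(5, 101))
  km <- kernel_mass(k)
  expect_equal(unname(km$pair_mass["a", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(km$total_mass[["b"]]), 0)
  expect_true(km$sink[["b"]])

  # internal sink: part of the mass entering never exits (Remark-style)
  nets <- sink_inside_compartment()
  ks <- scalar_kernels(nets, time_grid(5, 101))
  kms <- kernel_mass(ks)
  expect_lt(kms$total_mass[["a"]], 1 - 1e-3)
  expect_gt(kms$limit_term[["a"]], 1e-3)
  # closed form: exit prob from s1 is 1/2 (s1 splits evenly, s3 always exits)
  expect_equal(unname(kms$total_mass[["a"]]), 0.5, tolerance = 1e-10)
  expect_equal(unname(kms$limit_term[["a"]]), 0.5, tolerance = 1e-10)
})

test_that("strongly connected single-entrance networks have unit kernel mass", {
  for (seed in c(1, 5, 9)) {
    net <- random_conservative_network(8, 3, seed = seed,
                                       single_entrance = TRUE,
                                       strongly_connected = TRUE)
    k <- scalar_kernels(net, time_grid(1, 11))
    km <- kernel_mass(k)
    expect_equal(unname(km$total_mass), rep(1, 3), tolerance = 1e-10)
    expect_equal(unname(km$limit_term), rep(0, 3), tolerance = 1e-10)
  }
})

test_that("cumulative loss-kernel integral matches the semigroup identity", {
  # int_0^T e^T K_a(r) dr = e^T (I - e^{T A_aa}), per column
  net <- random_conservative_network(7, 2, seed = 6)
  Tend <- 6
  g <- time_grid(Tend, 2001)
  k <- grfe_kernels(net, g)
  for (a in net$compartments) {
    Aaa <- net$E[[a]] - net$C[[a]]
    lhs <- vapply(seq_len(nrow(Aaa)), function(j)
      rfekit:::trapz(apply(k$K[[a]][, j, , drop = FALSE], 3L, sum), g$dt),
      numeric(1L))
    rhs <- colSums(diag(nrow(Aaa)) - expm_ref(Tend * Aaa))
    expect_equal(lhs, unname(rhs), tolerance = 1e-6)
  }
})

test_that("flux-balance identity holds at every node for ODE-derived kernels", {
  # sum_b e^T G_{ab}(t) = e^T K_a(t)
  net <- random_conservative_network(6, 3, seed = 8)
  g <- time_grid(4, 201)
  k <- grfe_kernels(net, g)
  for (a in net$compartments) {
    acc <- -apply(k$K[[a]], c(2L, 3L), sum)
    for (b in setdiff(net$compartments, a)) {
      acc <- acc + apply(k$G[[paste(a, b, sep = "|")]], c(2L, 3L), sum)
    }
    expect_lt(max(abs(acc)), 1e-10)
  }
  expect_true(all(unlist(lapply(k$G, min)) >= 0))
  expect_true(all(unlist(lapply(k$K, min)) >= 0))
})

test_that("exit kernel equals the sum of pair kernels for single-entrance nets", {
  net <- random_conservative_network(8, 3, seed = 5, single_entrance = TRUE,
                                     strongly_connected = TRUE)
  k <- scalar_kernels(net, time_grid(5, 301))
  for (a in net$compartments) {
    tot <- apply(k$scalar$Phi[a, , , drop = FALSE], 3L, sum)
    expect_equal(tot, unname(k$scalar$k_exit[a, ]), tolerance = 1e-10)
  }
})

test_that("forcing functions follow the transient-response formulas", {
  net <- two_state_chain()
  k <- scalar_kernels(net, time_grid(5, 201))

  f0 <- grfe_forcing(k, c(s1 = 0, s2 = 0))
  expect_equal(max(abs(f0$S0$a)), 0)
  expect_equal(max(abs(f0$J0$b)), 0)

  # mass concentrated in the sink compartment: no outflux forcing
  fb <- grfe_forcing(k, c(s1 = 0, s2 = 3))
  expect_equal(max(abs(fb$J0$b)), 0)
  expect_equal(fb$N0[["b"]], 3)

  expect_error(grfe_forcing(k, c(s1 = -1, s2 = 0)), "nonnegative")
})

test_that("initial mass at the entrance point gives Markov-consistent forcing", {
  net <- random_conservative_network(7, 3, seed = 10,
                                     single_entrance = TRUE,
                                     strongly_connected = TRUE)
  g <- time_grid(5, 301)
  k <- scalar_kernels(net, g)
  ep <- k$scalar$entrance
  n0 <- setNames(rep(0, length(net$states)), net$states)
  weights <- c(1.5, 0.5, 2)
  for (i in seq_along(net$compartments)) {
    n0[ep[[net$compartments[i]]]] <- weights[i]
  }
  f <- grfe_forcing(k, n0)
  fc <- consistency_forcing(k, setNames(weights, net$compartments))
  expect_equal(f$B0, fc$B0, tolerance = 1e-12)
  expect_equal(f$D0, fc$D0, tolerance = 1e-12)
})

test_that("scalar reduction refuses multiple entrance points, naming them", {
  # two cross edges into different states of b
  st <- c("s1", "s2", "s3")
  A <- matrix(0, 3L, 3L, dimnames = list(st, st))
  A["s2", "s1"] <- 1; A["s3", "s1"] <- 1
  diag(A) <- -colSums(A)
  net <- build_compartment_network(validate_rate_matrix(A),
                                   list(a = "s1", b = c("s2", "s3")))
  expect_error(scalar_kernels(net, time_grid(1, 11)),
               "multiple entrance points: b")
})

test_that("Laplace transforms: closed forms, mass identity at z = 0, Markov form", {
  net <- two_state_chain()
  k <- scalar_kernels(net, time_grid(5, 101))
  # exponential kernel e^{-t}: transform 1/(z+1)
  for (z in c(0, 0.5, 2)) {
    expect_equal(unname(laplace_kernel(k, z)$M["b", "a"]), 1 / (z + 1),
                 tolerance = 1e-12)
  }
  # z = 0 equals the kernel masses for any single-entrance fixture
  net2 <- random_conservative_network(8, 3, seed = 5,
                                      single_entrance = TRUE,
                                      strongly_connected = TRUE)
  k2 <- scalar_kernels(net2, time_grid(1, 11))
  M0 <- laplace_kernel(k2, 0)$M
  km <- kernel_mass(k2)
  expect_equal(t(M0), km$pair_mass, tolerance = 1e-10)

  # Markovian (one state per compartment) kernels: z Phi^(z) = z l / (z + L)
  st <- c("x", "y")
  A <- matrix(c(-1, 1, 2, -2), 2, 2, dimnames = list(st, st))
  netm <- build_compartment_network(validate_rate_matrix(A),
                                    list(X = "x", Y = "y"))
  km2 <- scalar_kernels(netm, time_grid(5, 101))
  z <- 1.3
  expect_equal(unname(laplace_kernel(km2, z)$M["Y", "X"]), 1 / (z + 1),
               tolerance = 1e-12)

  # singular resolvent is reported
  expect_error(laplace_kernel(k, -1), "singular")
})

test_that("tabulated kernels integrate with a tail estimate", {
  g <- time_grid(20, 2001)
  kt <- erlang2_pair(g)
  km <- kernel_mass(kt)
  expect_equal(unname(km$pair_mass["a", "b"]), 1, tolerance = 1e-3)
  expect_true(km$tail[["a|b"]]$reliable)
})
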