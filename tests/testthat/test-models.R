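test_that("proofreading network is a valid 5-state system with the expected structure", {
  p <- hopfield_preset(0.01, 0.5)
  net <- hopfield_network(p)
  expect_s3_class(validate_rate_matrix(unclass(net$A)), "rate_matrix")
  expect_equal(net$entrance_points$product, "P")
  # sink and product are absorbing
  expect_equal(sum(unclass(net$A)[, "P"] != 0), 0L)
  expect_equal(sum(unclass(net$A)[, "sink"] != 0), 0L)
})

test_that("Q = 1 restores detailed balance on the reaction core; Q > 1 breaks it", {
  p1 <- hopfield_params(k = 1, alpha = 0.3, beta = 0.2, mu = 0, lambda = 0,
                        Q = 1, eE1 = 2, eE2 = 5)
  A1 <- rfekit:::hopfield_core_generator(p1)
  expect_true(check_detailed_balance(validate_rate_matrix(A1))$has_detailed_balance)
  p2 <- hopfield_params(k = 1, alpha = 0.3, beta = 0.2, mu = 0, lambda = 0,
                        Q = 7, eE1 = 2, eE2 = 5)
  A2 <- rfekit:::hopfield_core_generator(p2)
  expect_false(check_detailed_balance(validate_rate_matrix(A2))$has_detailed_balance)
})

test_that("response function decays and integrates to one without degradation", {
  p0 <- hopfield_params(k = 1, alpha = 0.01, beta = 1e-4, mu = 0,
                        lambda = 2e-4, Q = 1e4, eE1 = 2, eE2 = 400)
  tp <- hopfield_total_production(p0)
  expect_equal(tp$P_inf, 1, tolerance = 1e-6)

  # with the figure preset (mu > 0) the response decays and mass is < 1
  resp <- hopfield_response(hopfield_preset(0.01, 0.5), time_grid(2000, 2001))
  expect_gt(resp$Phi[50], resp$Phi[2001])
  expect_true(all(resp$Phi >= 0))

  # lambda = 0 means no product channel
  p_nl <- hopfield_params(k = 1, alpha = 0.01, beta = 1e-4, mu = 0.01,
                          lambda = 0, Q = 1e4, eE1 = 2, eE2 = 400)
  expect_equal(max(abs(hopfield_response(p_nl, time_grid(10, 101))$Phi)), 0)
})

test_that("production ratio: closed form matches the Laplace route and obeys the proofreading bound", {
  set.seed(5)
  for (rep in 1:5) {
    p <- hopfield_params(k = 1, alpha = stats::runif(1, 0.01, 1),
                         beta = stats::runif(1, 0.01, 1),
                         mu = stats::runif(1, 0.01, 1),
                         lambda = stats::runif(1, 0.01, 1),
                         Q = stats::runif(1, 1, 100),
                         eE1 = stats::runif(1, 1, 5),
                         eE2 = stats::runif(1, 1, 50))
    theta <- stats::runif(1, 0.1, 0.9)
    pr <- production_ratio(p, theta = theta)
    expect_equal(pr$ratio, pr$ratio_closed_form,
                 tolerance = 1e-8)
    expect_gte(pr$ratio, pr$theta2)
  }
  # identical substrates give ratio one
  p <- hopfield_preset(0.01, 0.5)
  expect_equal(production_ratio(p, p)$ratio, 1, tolerance = 1e-12)
})

test_that("discrimination approaches theta^2 along the scaling family", {
  devs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    pr <- production_ratio(hopfield_preset(eps, 0.5),
                           hopfield_preset(eps, 0.5, barred = TRUE))
    pr$ratio / pr$theta2 - 1
  }, numeric(1L))
  expect_true(all(devs > 0))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3L], 0.01)
})

test_that("production ratio is invariant under a change of time unit", {
  p <- hopfield_params(k = 1, alpha = 0.05, beta = 0.01, mu = 0.02,
                       lambda = 0.03, Q = 50, eE1 = 2, eE2 = 40)
  scale <- 3.7
  p_s <- hopfield_params(k = scale, alpha = 0.05 * scale,
                         beta = 0.01 * scale, mu = 0.02 * scale,
                         lambda = 0.03 * scale, Q = 50, eE1 = 2, eE2 = 40)
  r1 <- production_ratio(p, theta = 0.3)$ratio
  r2 <- production_ratio(p_s, theta = 0.3)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("mean production time: closed form, Laplace sum and first moment agree", {
  p0 <- hopfield_params(k = 1, alpha = 0.01, beta = 1e-4, mu = 0,
                        lambda = 2e-4, Q = 1e4, eE1 = 2, eE2 = 400)
  mt <- mean_production_time(p0)
  expect_equal(mt$T_closed_form, mt$T_moment, tolerance = 1e-6)
  expect_equal(mt$T_closed_form, mt$T_laplace, tolerance = 1e-6)

  # symmetric parameters give unit timing ratio
  expect_equal(mt$T_moment / mean_production_time(p0)$T_moment, 1)

  # under the stated rate orderings the timing ratio approaches theta^2
  p_g <- hopfield_params(k = 1, alpha = 1e-2, beta = 1e-6, mu = 0,
                         lambda = 1e-5, Q = 1e6, eE1 = 50, eE2 = 5000)
  p_b <- hopfield_params(k = 1, alpha = 1e-2, beta = 1e-6, mu = 0,
                         lambda = 1e-5, Q = 1e6, eE1 = 200, eE2 = 20000)
  Tr <- mean_production_time(p_g)$T_moment / mean_production_time(p_b)$T_moment
  expect_equal(Tr, (50 / 200)^2, tolerance = 0.1)
})

test_that("adaptation kernel: explicit eigenstructure and zero total mass", {
  m <- adaptation_response(2, 3)
  expect_equal(m$lambda_plus, -1)
  expect_equal(m$lambda_minus, -2)
  tt <- seq(0, 20, by = 0.01)
  expect_equal(m$Phi(tt), -3 * exp(-tt) + 6 * exp(-2 * tt),
               tolerance = 1e-12)
  expect_equal(m$Phi(0), 3)          # Phi(0) = b
  expect_equal(m$mass_analytic, 0)
  expect_lt(abs(m$mass_numeric(50, 1e-3)), 1e-10)

  # generator route: Phi(t) = (b, 0) e^{At} e_1
  A <- rbind(c(-3, 2), c(-1, 0))
  expect_equal(m$Phi(0.37), 3 * expm_ref(0.37 * A)[1L, 1L],
               tolerance = 1e-12)

  # random parameter draws with b^2 > 4a
  set.seed(2)
  for (rep in 1:5) {
    b <- stats::runif(1, 1, 5)
    a <- stats::runif(1, 0.05, 0.9) * b^2 / 4
    mm <- adaptation_response(a, b)
    expect_equal(mm$mass_analytic, 0, tolerance = 1e-12)
    expect_lt(abs(mm$mass_numeric(80 / min(abs(mm$lambda_plus), 1), 1e-3)),
              1e-10)
    expect_equal(mm$Phi(0), b, tolerance = 1e-12)
  }
  expect_error(adaptation_response(3, 2), "b\\^2 > 4a")
})

test_that("adaptation output returns to baseline under an eventually constant signal", {
  m <- adaptation_response(2, 3)
  g <- time_grid(30, 3001)
  X <- m$response(signal_constant(5), g)
  expect_lt(abs(X[g$n_points] - 1), 1e-3)
})

test_that("linear polymerization develops a traveling front at speed 1/mu", {
  g <- time_grid(40, 4001)
  Psi <- function(t) stats::dgamma(t, shape = 8, rate = 8)   # mean 1
  lp <- linear_polymerization(Psi, L_max = 22, grid = g)
  expect_equal(lp$mu, 1, tolerance = 1e-6)
  # plateau at mu for sizes well behind the front
  expect_equal(lp$n[5, g$n_points], lp$mu, tolerance = 1e-3)
  # front speed at l = 20 within 5% of 1/mu
  expect_lt(abs(lp$front_speed[20] * lp$mu - 1), 0.05)

  # narrow kernel: sharp half-height crossing between the arrival times of
  # the (l-1)-th and l-th elongation step, i.e. near (l - 1/2) * mu
  Psi_n <- function(t) stats::dgamma(t, shape = 400, rate = 400)
  lp_n <- linear_polymerization(Psi_n, L_max = 12, grid = time_grid(15, 3001))
  expect_lt(abs(lp_n$front_time[10] - 9.5), 0.1)
})

test_that("C1FFL: ODE and double-convolution routes agree and refine together", {
  g <- time_grid(3, 151)
  S <- signal_step_on(0, 1)
  r <- c1ffl_response(5, 1, 5, S, g)
  expect_lt(r$max_route_gap, 1e-4)
  r2 <- c1ffl_response(5, 1, 5, S, time_grid(3, 301))
  expect_lt(r2$max_route_gap, r$max_route_gap / 2)
  # zero signal gives zero response on both routes
  r0 <- c1ffl_response(5, 1, 5, signal_constant(0), g)
  expect_equal(max(abs(r0$Z_ode)), 0)
  expect_equal(max(abs(r0$Z_kernel)), 0)
  expect_error(c1ffl_response(2, 2, 5, S, g), "b != a")
})

test_that("C1FFL limit model is a sign-sensitive delay", {
  g <- time_grid(8, 801)
  # ON step: saturation at 1 on a time of order one
  on <- c1ffl_limit_response(signal_step_on(0, 1), g)
  expect_lt(abs(on$xi[g$n_points] - 1), 1e-3)
  expect_lt(on$xi[which.min(abs(g$t - 0.2))], 0.25)  # delayed rise
  # OFF step: response vanishes immediately after switch-off
  off <- c1ffl_limit_response(signal_step_off(2, 1), g)
  expect_equal(max(abs(off$xi[g$t > 2])), 0)
  expect_gt(off$xi[max(which(g$t <= 2))], 0.9)
})

test_that("nonlinear polymerization conserves monomer mass and logs boundary flux", {
  g <- time_grid(5, 1001)
  Psi <- function(t) stats::dgamma(t, shape = 3, rate = 6)
  np <- nonlinear_polymerization(Psi, signal_constant(1), L_max = 12,
                                 grid = g, n1_0 = 0.5)
  expect_lt(np$max_balance_residual, 1e-6)
  expect_true(all(np$n >= 0))
  # zero data and zero source stay zero
  np0 <- nonlinear_polymerization(Psi, signal_constant(0), L_max = 4,
                                  grid = time_grid(1, 101), n1_0 = 0)
  expect_equal(max(abs(np0$n)), 0)
  expect_equal(max(abs(np0$w)), 0)
})

test_that("a narrow maturation kernel recovers Markovian aggregation kinetics", {
  g <- time_grid(3, 3001)
  Psi <- function(t) stats::dgamma(t, shape = 64, rate = 6400)  # mean 0.01
  np <- nonlinear_polymerization(Psi, signal_constant(0), L_max = 5,
                                 grid = g, n1_0 = 1)
  # oracle: instantaneous-maturation mass-action ODE integrated with Heun
  f <- function(n) {
    L <- 5L
    dn <- numeric(L)
    att <- n[1L] * n
    att[L] <- 0
    for (l in 2L:L) {
      dn[l] <- -att[l] + (if (l < L) n[l + 1L] else 0) - n[l] +
        (if (l == 2L) n[1L]^2 else n[1L] * n[l - 1L])
    }
    dn[1L] <- 2 * n[2L] - sum(att[2L:L]) - 2 * n[1L]^2 + sum(n[3L:L])
    dn
  }
  n <- c(1, numeric(4L))
  for (m in 2L:g$n_points) {
    k1 <- f(n)
    k2 <- f(n + g$dt * k1)
    n <- n + g$dt / 2 * (k1 + k2)
  }
  expect_lt(max(abs(np$n[, g$n_points] - n)), 5e-3)
})
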