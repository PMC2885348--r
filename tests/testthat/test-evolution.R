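# Mutation-selection state-transition model: grid mapping, mutation
# fluxes, coupling to growth, conservation, and the small-instance oracle.

test_that("state grid maps index to AR expression", {
  grid <- build_state_grid()
  expect_equal(grid$Rt_values[50], 64)   # state 50 carries R_t = 64 nM
  expect_equal(grid$Rt_values[1], 15)
  expect_equal(grid$Rt_values[100], 114)
  expect_error(build_state_grid(Q = 1), "invalid-grid")
  expect_error(build_state_grid(step = 0), "invalid-grid")
})

test_that("per-state environment follows the kinetics model", {
  grid <- build_state_grid(Q = 10, Rt_min = 15, step = 10)
  kp <- kinetic_params()
  g <- growth_params()

  env <- per_state_environment(grid, kp, T_S = 5, eta = 1, g = g)
  expect_length(env$C_t, 10)
  expect_true(all(diff(env$C_t) > 0))  # C_t increases with R_t

  # no enzyme: the signal is T:AR only
  env0 <- per_state_environment(grid, kinetic_params(alpha = 0), 5, 1, g)
  ctr_only <- vapply(grid$Rt_values, function(Rt) {
    kp0 <- kinetic_params(alpha = 0, R_t = Rt)
    kinetics_steady_state(kp0, 5)[["C_TR"]]
  }, numeric(1))
  expect_equal(env0$C_t, ctr_only, tolerance = 1e-9)

  # no serum T: zero signal everywhere, background-plus-low-androgen ROS
  envz <- per_state_environment(grid, kp, 0, 1, g)
  expect_equal(envz$C_t, rep(0, 10))
  expect_equal(envz$S, rep(g$mu + 1, 10))
})

test_that("mutation fluxes conserve cells with reflecting boundaries", {
  expect_equal(mutation_fluxes(rep(7, 10), 1e-4), rep(0, 10))
  expect_equal(mutation_fluxes(c(1, 5, 2), 0), rep(0, 3))

  # point mass in an interior state spreads evenly to both neighbours
  P <- c(0, 0, 10, 0, 0)
  fl <- mutation_fluxes(P, 2e-3)
  expect_equal(fl, c(0, 2e-2, -4e-2, 2e-2, 0))

  set.seed(13)
  for (i in 1:10) {
    P <- runif(sample(2:50, 1), 0, 1e8)
    expect_equal(sum(mutation_fluxes(P, 10^runif(1, -6, -3))), 0,
                 tolerance = 1e-8)
  }
})

test_that("evolution RHS reduces to shared-crowding growth when gamma = 0", {
  grid <- build_state_grid(Q = 5, Rt_min = 25, step = 10)
  g <- growth_params()
  env <- per_state_environment(grid, kinetic_params(), 5, 1, g)
  P <- c(1e6, 2e7, 3e7, 1e7, 5e5)
  d <- evolution_rhs(P, env, g, gamma = 0)
  for (i in 1:5) {
    S <- ros_level(env$C_t[i], g)
    expect_equal(d[i], P[i] * (proliferation_signal(env$C_t[i], S, g) -
                                 g$sigma * sum(P) -
                                 death_rate(env$C_t[i], S, g)),
                 tolerance = 1e-12)
  }
  expect_error(evolution_rhs(P[1:3], env, g, 0), "invalid-input")
})

test_that("two-state system matches a hand-written ODE oracle", {
  grid <- build_state_grid(Q = 2, Rt_min = 40, step = 20)
  g <- growth_params()
  env <- per_state_environment(grid, kinetic_params(), 5, 1, g)
  gamma <- 1e-4
  # net per-capita growth of each strain, written out by hand
  hand_net <- vapply(1:2, function(i) {
    C <- env$C_t[i]
    S <- 0.05 + 30^4 / (30^4 + C^4) + C^4 / (225^4 + C^4)
    M0 <- (log(2) / 48) * (C^2 / (110^2 + C^2) + 4 * S * exp(1 - 4 * S))
    N <- 0.004 + (log(2) / 48) * (40^2 / (40^2 + C^2) + S^8 / (1 + S^8))
    M0 - N
  }, numeric(1))
  f <- function(t, P) {
    c(P[1] * (hand_net[1] - 1.5e-10 * (P[1] + P[2])) +
        gamma * (P[2] - P[1]),
      P[2] * (hand_net[2] - 1.5e-10 * (P[1] + P[2])) +
        gamma * (P[1] - P[2]))
  }
  ref <- oracle_rk4(f, c(1e7, 1e4), 5000, dt = 0.5)

  ep <- evolution_params(gamma = gamma, t_end = 5000, output_stride = 5000)
  sim <- simulate_evolution(grid, env, g, ep, init = c(1e7, 1e4),
                            rtol = 1e-9, atol = 1e-9)
  expect_equal(unname(sim$P[nrow(sim$P), ]), unname(ref),
               tolerance = 1e-6)
})

test_that("mutation conserves cells; gamma = 0 pins the average", {
  grid <- build_state_grid(Q = 20, Rt_min = 15, step = 5)
  kp <- kinetic_params()
  gq <- growth_params(r = 0, delta = 0, delta0 = 0, sigma = 0)
  env <- per_state_environment(grid, kp, 5, 1, gq)
  init <- c(rep(0, 9), 1e7, rep(0, 10))
  for (gamma in c(1e-5, 1e-3)) {
    ep <- evolution_params(gamma = gamma, t_end = 20000,
                           output_stride = 5000)
    sim <- simulate_evolution(grid, env, gq, ep, init = init)
    expect_equal(sim$total_cells / 1e7, rep(1, length(sim$time_h)),
                 tolerance = 1e-7)
    expect_true(all(sim$P >= 0))
    expect_true(all(sim$avg_Rt_nM >= 15 & sim$avg_Rt_nM <= 110))
  }

  # gamma = 0 with a point initial condition: average R_t never moves
  g <- growth_params()
  env5 <- per_state_environment(grid, kp, 5, 1, g)
  ep0 <- evolution_params(gamma = 0, t_end = 20000, output_stride = 5000)
  i0 <- 7
  init0 <- numeric(20); init0[i0] <- 1e6
  sim0 <- simulate_evolution(grid, env5, g, ep0, init = init0)
  expect_equal(sim0$avg_Rt_nM, rep(grid$Rt_values[i0], length(sim0$time_h)))
})

test_that("symmetric environments keep the average at the grid midpoint", {
  grid <- build_state_grid(Q = 6, Rt_min = 10, step = 10)
  g <- growth_params()
  env <- structure(list(C_t = rep(100, 6), S = rep(ros_level(100, g), 6),
                        Rt_values = grid$Rt_values, T_S = NA, eta = 1),
                   class = "strain_environment")
  ep <- evolution_params(gamma = 1e-4, t_end = 50000,
                         output_stride = 10000)
  sim <- simulate_evolution(grid, env, g, ep, init = rep(1e6, 6))
  expect_equal(sim$avg_Rt_nM, rep(35, length(sim$time_h)),
               tolerance = 1e-9)
})

test_that("population-weighted average AR expression", {
  grid <- build_state_grid()
  P <- numeric(100); P[50] <- 3e7
  expect_equal(average_ar(P, grid), 64)
  expect_equal(average_ar(rep(1, 100), grid), 64.5)
  P2 <- numeric(100); P2[83] <- 12
  expect_equal(average_ar(P2, grid), grid$Rt_values[83])
  expect_error(average_ar(numeric(100), grid), "undefined-average")
})

test_that("threshold crossing times interpolate linearly", {
  df <- data.frame(time_h = 0:10, avg_Rt_nM = seq(60, 70, by = 1))
  expect_equal(time_to_threshold(df, 64), 4)
  expect_equal(time_to_threshold(df, 60), 0)
  expect_true(is.na(time_to_threshold(
    data.frame(time_h = 0:5, avg_Rt_nM = rep(50, 6)), 64)))
  expect_error(time_to_threshold(
    data.frame(time_h = numeric(0), avg_Rt_nM = numeric(0)), 1),
    "invalid-input")
})
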