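# AR kinetics: unit operations, dynamics, steady state, and the module
# invariants (non-negativity, pool conservation, saturation, linearity in
# R_t, inhibition monotonicity).

test_that("dissociation constants match the measured binding rates", {
  expect_equal(dissociation_constant(0.14, 0.069), 0.49, tolerance = 0.01)
  expect_equal(dissociation_constant(0.053, 0.018), 0.34, tolerance = 0.01)
  expect_identical(dissociation_constant(1, 1), 1)
  expect_error(dissociation_constant(0, 1), "invalid-parameter")
  expect_error(dissociation_constant(-0.1, 1), "invalid-parameter")
})

test_that("competitive inhibition scales the Michaelis constant", {
  expect_equal(as.numeric(effective_km(75, 0, 0.46)), 75)
  expect_equal(as.numeric(effective_km(75, 0.46, 0.46)), 150)
  expect_equal(as.numeric(effective_km(75, 4.6, 0.46)), 825)
  expect_equal(attr(effective_km(75, 4.6, 0.46), "eta"), 11)
  expect_error(effective_km(75, 1, 0), "invalid-parameter")
  expect_error(effective_km(75, -1, 0.46), "invalid-parameter")
})

test_that("reductase rate is Michaelis-Menten in free T", {
  expect_equal(reductase_rate(0, 5, 18, 75), 0)
  expect_equal(reductase_rate(75, 5, 18, 75), 45)  # half of Vmax = 90
  expect_equal(reductase_rate(1e9, 5, 18, 75), 90, tolerance = 1e-6)
  expect_error(reductase_rate(1, 5, 18, 0), "invalid-parameter")
})

test_that("influx vanishes at zero serum T and saturates", {
  p <- influx_params(u_max = 1, u_half = 1)
  expect_equal(influx(0, p), 0)
  expect_equal(influx(1, p), 0.5)
  expect_error(influx(-1, p), "invalid-input")

  # tabulated form: monotone interpolation, flat extrapolation, U(0) = 0
  tab <- influx_params(form = "tabulated",
                       table = data.frame(T_S = c(1, 2, 4),
                                          U = c(0.2, 0.4, 0.5)))
  expect_equal(influx(0, tab), 0)
  expect_equal(influx(1.5, tab), 0.3)
  expect_equal(influx(50, tab), 0.5)   # flat beyond the table
  expect_error(
    influx_params(form = "tabulated",
                  table = data.frame(T_S = c(1, 2), U = c(0.4, 0.2))),
    "non-decreasing")
})

test_that("homeostatic AR production balances the bound pool", {
  b <- log(2) / 3
  expect_equal(ar_production_rate(45, 0, 0, b), 45 * b)
  expect_equal(ar_production_rate(45, 20, 25, b), 0)
  expect_equal(ar_production_rate(45, 10, 30, b), 5 * b)
  # clamped when bound receptor transiently exceeds the set point
  expect_equal(ar_production_rate(45, 30, 30, b), 0)
})

test_that("kinetics right-hand side matches term-by-term hand evaluation", {
  p <- kinetic_params()

  # all-zero state: only AR production and influx fire
  d0 <- kinetics_rhs(kinetic_state(), p, T_S = 5)
  u <- 1.4078 * 5 / 9
  expect_equal(unname(d0),
               c(p$beta_R_norm * 45, u, 0, 0, 0), tolerance = 1e-12)

  # generic state: every term written out independently
  s <- kinetic_state(R = 45, T = 1, D = 1, C_TR = 0, C_DR = 0)
  d <- kinetics_rhs(s, p, T_S = 5)
  v <- 5 * 18 * 1 / (75 + 1)
  bindT <- 0.14 * 1 * 45 - 0.069 * 0
  bindD <- 0.053 * 1 * 45 - 0.018 * 0
  lam <- p$beta_R_norm * (45 - 0 - 0)
  expect_equal(unname(d), c(
    lam - p$beta_R * 45 - bindT - bindD,
    u - p$beta_T * 1 - v - bindT,
    v - p$beta_D * 1 - bindD,
    bindT,
    bindD
  ), tolerance = 1e-12)

  expect_error(kinetics_rhs(c(R = -1, T = 0, D = 0, C_TR = 0, C_DR = 0),
                            p, 5), "invalid-state")
})

test_that("AR pool balance: binding fluxes cancel in d(R + C_TR + C_DR)/dt", {
  p <- kinetic_params()
  set.seed(7)
  for (i in 1:20) {
    s <- kinetic_state(R = runif(1, 0, 50), T = runif(1, 0, 10),
                       D = runif(1, 0, 30), C_TR = runif(1, 0, 20),
                       C_DR = runif(1, 0, 40))
    d <- kinetics_rhs(s, p, T_S = runif(1, 0, 10))
    lam <- ar_production_rate(p$R_t, s[["C_TR"]], s[["C_DR"]],
                              p$beta_R_norm)
    expect_equal(d[["R"]] + d[["C_TR"]] + d[["C_DR"]],
                 lam - p$beta_R * s[["R"]], tolerance = 1e-12)
  }
})

test_that("time-dependent dynamics: transient T:AR peak, DHT:AR dominance", {
  p <- kinetic_params()

  # no serum source: pure relaxation of free AR to the set point
  tr0 <- simulate_kinetics(p, T_S = 0, t_end = 200)
  final0 <- unlist(tr0[nrow(tr0), c("R_nM", "T_nM", "D_nM", "CTR_nM",
                                    "CDR_nM")])
  expect_equal(unname(final0), c(45, 0, 0, 0, 0), tolerance = 1e-7)

  tr <- simulate_kinetics(p, T_S = 5, t_end = 2000)
  # T:AR complex peaks early, then the DHT:AR complex overtakes it
  expect_lt(tr$time_h[which.max(tr$CTR_nM)],
            tr$time_h[which.max(tr$CDR_nM)])
  expect_gt(tr$CDR_nM[nrow(tr)], tr$CTR_nM[nrow(tr)])
  expect_true(all(tr[-1] >= 0))
  # homeostatic production pins total AR to R_t at steady state
  expect_equal(tr$totalAR_nM[nrow(tr)], 45, tolerance = 1e-5)

  # piecewise-constant serum schedule: androgen withdrawal at 500 h
  # drains the DHT pool (slowly -- receptor rebinding shelters bound DHT)
  sched <- data.frame(time_h = c(0, 500), T_S = c(5, 0))
  tr2 <- simulate_kinetics(p, sched, t_end = 3000)
  after <- tr2$totalDHT_nM[tr2$time_h > 600]
  expect_true(all(diff(after) < 0))
  expect_lt(tr2$totalDHT_nM[nrow(tr2)], 0.15 * max(tr2$totalDHT_nM))
})

test_that("steady state: androgen mostly DHT and bound to AR at baseline", {
  p <- kinetic_params()
  expect_equal(unname(unclass(kinetics_steady_state(p, 0))),
               c(45, 0, 0, 0, 0))

  ss <- kinetics_steady_state(p, 5)
  expect_gt(ss[["C_DR"]] / p$R_t, 0.8)   # nearly all receptor DHT-bound
  expect_gt(ss[["C_DR"]], 5 * ss[["C_TR"]])
  expect_lt(ss[["T"]], 1)                 # free T stays small
  tot <- state_totals(ss)
  expect_equal(tot[["total_AR"]], 45, tolerance = 1e-9)
  expect_true(tot[["total_DHT"]] >= 40 && tot[["total_DHT"]] <= 60)

  # detailed balance of both binding reactions
  expect_lt(abs(p$ka_T * ss[["T"]] * ss[["R"]] - p$kd_T * ss[["C_TR"]]),
            1e-9)
  expect_lt(abs(p$ka_D * ss[["D"]] * ss[["R"]] - p$kd_D * ss[["C_DR"]]),
            1e-9)
})

test_that("root-found steady state agrees with long integration", {
  set.seed(11)
  for (i in 1:3) {
    p <- rand_kinetic_params()
    for (TS in c(0.5, 5)) {
      ss <- kinetics_steady_state(p, TS)
      endp <- simulate_kinetics(p, TS, t_end = 5000, n_out = 2)
      endv <- unlist(endp[2, c("R_nM", "T_nM", "D_nM", "CTR_nM",
                               "CDR_nM")])
      expect_equal(unname(endv), unname(unclass(ss)), tolerance = 1e-6)
    }
  }
})

test_that("non-negativity from arbitrary non-negative initial states", {
  p <- kinetic_params()
  set.seed(3)
  for (i in 1:5) {
    init <- kinetic_state(R = runif(1, 0, 60), T = runif(1, 0, 20),
                          D = runif(1, 0, 40), C_TR = runif(1, 0, 25),
                          C_DR = runif(1, 0, 25))
    tr <- simulate_kinetics(p, runif(1, 0, 10), t_end = 300, init = init)
    expect_true(all(tr[-1] >= 0))
  }
})

test_that("saturation: complexes level off with serum T while free DHT rises", {
  p <- kinetic_params()
  TS <- c(0.5, 1, 2, 5, 10, 20, 50)
  ss <- lapply(TS, kinetics_steady_state, p = p)
  bound <- vapply(ss, function(s) s[["C_TR"]] + s[["C_DR"]], numeric(1))
  freeD <- vapply(ss, function(s) s[["D"]], numeric(1))
  expect_true(all(diff(bound) > 0))
  expect_true(all(bound <= p$R_t))
  expect_true(all(diff(freeD) > 0))
  # complexes saturate: the marginal bound gain per nM serum T collapses
  expect_lt((bound[7] - bound[5]) / 30, 0.05 * (bound[4] - bound[1]) / 4.5)
})

test_that("bound androgen scales linearly with the AR set point", {
  p30 <- kinetic_params(R_t = 30)
  p60 <- kinetic_params(R_t = 60)
  s30 <- kinetics_steady_state(p30, 5)
  s60 <- kinetics_steady_state(p60, 5)
  expect_equal(s60[["C_TR"]] / s30[["C_TR"]], 2, tolerance = 1e-9)
  expect_equal(s60[["C_DR"]] / s30[["C_DR"]], 2, tolerance = 1e-9)
  # free concentrations do not depend on R_t
  expect_equal(s60[["T"]], s30[["T"]], tolerance = 1e-9)
  expect_equal(s60[["D"]], s30[["D"]], tolerance = 1e-9)
})

test_that("inhibition: total DHT falls with eta; no enzyme, no DHT", {
  etas <- c(1, 2, 5, 10, 50)
  totD <- vapply(etas, function(e) {
    p <- kinetic_params(inhibitor_I = (e - 1) * 0.46)  # eta = 1 + I/K_I
    state_totals(kinetics_steady_state(p, 5))[["total_DHT"]]
  }, numeric(1))
  expect_true(all(diff(totD) < 0))

  ss0 <- kinetics_steady_state(kinetic_params(alpha = 0), 5)
  expect_identical(ss0[["D"]], 0)
  expect_identical(ss0[["C_DR"]], 0)
})

test_that("effective AR pool turnover rises as serum T falls", {
  p <- kinetic_params()
  # androgen-free pool turns over at the normal rate; bound pool slower
  expect_equal(effective_ar_turnover(kinetics_steady_state(p, 0), p),
               p$beta_R_norm)
  expect_equal(
    effective_ar_turnover(kinetic_state(R = 0, C_TR = 20, C_DR = 25), p),
    0)
  turn <- vapply(c(0.5, 1, 2, 5, 10), function(TS)
    effective_ar_turnover(kinetics_steady_state(p, TS), p), numeric(1))
  expect_true(all(diff(turn) < 0))
})

test_that("trajectory CSV round-trips", {
  tr <- simulate_kinetics(kinetic_params(), 5, t_end = 10, n_out = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_named(back, c("time_h", "R_nM", "T_nM", "D_nM", "CTR_nM",
                       "CDR_nM", "totalT_nM", "totalDHT_nM", "totalAR_nM"))
  expect_equal(back$CDR_nM, tr$CDR_nM, tolerance = 1e-12)
})
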