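# Shared test utilities: an independent fixed-step RK4 integrator used as
# an oracle against the package's adaptive solver, and random parameter
# draws around the baseline tables.

# classic fixed-step RK4; deliberately independent of the package solver
oracle_rk4 <- function(f, y0, t_end, dt) {
  y <- y0
  t <- 0
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  y
}

# kinetic parameters drawn uniformly within +/-50% of the baseline values
rand_kinetic_params <- function() {
  j <- function(x) x * stats::runif(1, 0.5, 1.5)
  kinetic_params(
    ka_T = j(0.14), kd_T = j(0.069), ka_D = j(0.053), kd_D = j(0.018),
    beta_R = j(log(2) / 3), beta_T = j(log(2) / 3), beta_D = j(log(2) / 9),
    alpha = j(5), k_cat = j(18), K_M = j(75), K_I = j(0.46),
    R_t = j(45), beta_R_norm = j(log(2) / 3),
    influx = influx_params(u_max = j(1.4078), u_half = j(4))
  )
}

# growth parameters with every value scaled by an independent factor in
# [1 - spread, 1 + spread] (theta2 > theta1 is preserved for spread <= .25
# since their baseline ratio is 7.5)
perturbed_growth_params <- function(spread = 0.25) {
  j <- function(x) x * stats::runif(1, 1 - spread, 1 + spread)
  growth_params(theta1 = j(30), theta2 = j(225), mu = j(0.05),
                phi1 = j(110), phi2 = j(40), varphi = j(4),
                omega = j(1), sigma = j(1.5e-10), delta0 = j(0.004),
                delta = j(log(2) / 24), r = j(log(2) / 24))
}

# effective signal C_t at the kinetics steady state for a given R_t and
# serum T (eta scales the Michaelis constant)
ss_ct <- function(Rt, TS, eta = 1, kp = kinetic_params(),
                  g = growth_params()) {
  kp$K_M <- kp$K_M * eta
  kp$R_t <- Rt
  ss <- kinetics_steady_state(kp, TS)
  effective_complex(ss[["C_TR"]], ss[["C_DR"]], g$w_dht)
}
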