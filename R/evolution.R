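## Deterministic mutation-selection dynamics over Q epithelial strains that
## differ only in homeostatic AR expression R_t. Each strain's androgen
## environment (C_t, S) comes from the kinetics steady state at its R_t;
## strains grow by the tissue model with crowding through the total cell
## count, and nearest-neighbour mutation moves cells between adjacent
## states at first-order rate gamma.
##
## Quasi-steady-state coupling: the kinetics equilibrate in days while
## selection plays out over years, and the kinetics do not depend on P, so
## per-state (C_t, S) are computed once per (T_S, eta) scenario.

#' Build the strain state grid
#'
#' State `i` carries homeostatic AR `Rt_values[i] = Rt_min + (i-1)*step`.
#' The defaults give 100 states with `R_t` from 15 to 114 nM (state `i`
#' has `R_t = 14 + i` nM; state 50 has 64 nM).
#'
#' @param Q number of states, >= 2.
#' @param Rt_min `R_t` of state 1 (nM).
#' @param step grid spacing (nM), > 0.
#' @return object of class `state_grid` with fields `Q` and `Rt_values`.
#' @export
build_state_grid <- function(Q = 100, Rt_min = 15, step = 1) {
  if (!is.numeric(Q) || length(Q) != 1 || Q < 2 || Q != round(Q)) {
    stop("invalid-grid: Q must be an integer >= 2", call. = FALSE)
  }
  if (step <= 0) stop("invalid-grid: step must be > 0", call. = FALSE)
  if (Rt_min <= 0) stop("invalid-grid: Rt_min must be > 0", call. = FALSE)
  structure(list(Q = as.integer(Q),
                 Rt_values = Rt_min + (seq_len(Q) - 1) * step),
            class = "state_grid")
}

#' Evolution run parameters
#'
#' @param gamma nearest-neighbour mutation transition rate (h^-1), >= 0.
#' @param t_end simulated horizon (h), > 0; default 20 years.
#' @param init_mode `"point"` (whole population in the state nearest
#'   `init_state_Rt`) or `"uniform"`.
#' @param init_state_Rt target `R_t` (nM) for the point initial condition;
#'   default the normal homeostatic level, 45 nM.
#' @param output_stride spacing of output times (h).
#' @return object of class `evolution_params`.
#' @export
evolution_params <- function(gamma = 1e-5, t_end = 175200,
                             init_mode = c("point", "uniform"),
                             init_state_Rt = 45, output_stride = 720) {
  init_mode <- match.arg(init_mode)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0) {
    stop("invalid-parameter: gamma must be a single number >= 0",
         call. = FALSE)
  }
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0) {
    stop("invalid-parameter: t_end must be > 0", call. = FALSE)
  }
  if (output_stride <= 0) {
    stop("invalid-parameter: output_stride must be > 0", call. = FALSE)
  }
  structure(list(gamma = gamma, t_end = t_end, init_mode = init_mode,
                 init_state_Rt = init_state_Rt,
                 output_stride = output_stride),
            class = "evolution_params")
}

#' Per-state androgen environment from the kinetics model
#'
#' For each grid state, solves the kinetics steady state with that state's
#' `R_t` and an effective Michaelis constant scaled by `eta`, then maps the
#' bound complexes to the effective signal `C_t` and ROS level `S`. Since
#' steady-state free T and DHT do not depend on `R_t`, `C_t` is linear in
#' `R_t` at fixed serum testosterone.
#'
#' @param grid a [build_state_grid()] object.
#' @param kp a [kinetic_params()] object (its `R_t` is overridden per
#'   state).
#' @param T_S serum testosterone (nM).
#' @param eta effective Michaelis-constant multiplier for 5-alpha-reductase
#'   inhibition (1 = uninhibited), applied on top of any `inhibitor_I` in
#'   `kp`.
#' @param g a [growth_params()] object (supplies `w_dht` and ROS shape).
#' @return object of class `strain_environment` with fields `C_t`, `S`
#'   (length-`Q` vectors), `Rt_values`, `T_S`, `eta`.
#' @export
per_state_environment <- function(grid, kp, T_S, eta = 1,
                                  g = growth_params()) {
  stopifnot(inherits(grid, "state_grid"), inherits(kp, "kinetic_params"),
            inherits(g, "growth_params"))
  if (!is.numeric(eta) || length(eta) != 1 || eta < 1) {
    stop("invalid-parameter: eta must be a single number >= 1",
         call. = FALSE)
  }
  kp_eta <- kp
  kp_eta$K_M <- kp$K_M * eta
  C_t <- vapply(grid$Rt_values, function(Rt) {
    kp_i <- kp_eta
    kp_i$R_t <- Rt
    ss <- tryCatch(kinetics_steady_state(kp_i, T_S),
                   error = function(e) {
                     stop("steady-state failure at state R_t = ", Rt,
                          " nM: ", conditionMessage(e), call. = FALSE)
                   })
    effective_complex(ss[["C_TR"]], ss[["C_DR"]], g$w_dht)
  }, numeric(1))
  structure(list(C_t = C_t, S = ros_level(C_t, g),
                 Rt_values = grid$Rt_values, T_S = T_S, eta = eta),
            class = "strain_environment")
}

#' Nearest-neighbour mutation fluxes
#'
#' Interior state `i` loses cells at rate `2*gamma` (evenly to its two
#' neighbours) and gains `gamma` times each neighbour's count. Boundary
#' states exchange with their single neighbour only (reflecting
#' boundaries), so the fluxes sum to zero exactly and mutation conserves
#' cells.
#'
#' @param P population vector (cells per state), length >= 2.
#' @param gamma mutation rate (h^-1), >= 0.
#' @return flux vector (cells/h), same length as `P`, summing to 0.
#' @export
mutation_fluxes <- function(P, gamma) {
  if (gamma < 0) stop("invalid-parameter: gamma must be >= 0",
                      call. = FALSE)
  Q <- length(P)
  if (Q < 2) stop("invalid-input: need at least 2 states", call. = FALSE)
  inflow <- c(0, P[-Q]) + c(P[-1], 0)
  outflow <- P * c(1, rep(2, Q - 2), 1)
  gamma * (inflow - outflow)
}

#' Evolution ODE right-hand side
#'
#' `dP_i/dt = P_i * (M0(C_t_i, S_i) - sigma * sum(P) - N(C_t_i, S_i)) +`
#' mutation fluxes. Strains grow independently except for crowding through
#' the shared total cell count.
#'
#' @param P population vector (cells per state).
#' @param env a [per_state_environment()] object.
#' @param g a [growth_params()] object.
#' @param gamma mutation rate (h^-1).
#' @return derivative vector (cells/h).
#' @export
evolution_rhs <- function(P, env, g, gamma) {
  stopifnot(inherits(env, "strain_environment"),
            inherits(g, "growth_params"))
  if (length(P) != length(env$C_t)) {
    stop("invalid-input: length of P must match the environment",
         call. = FALSE)
  }
  M0 <- proliferation_signal(env$C_t, env$S, g)
  N <- death_rate(env$C_t, env$S, g)
  P * (M0 - g$sigma * sum(P) - N) + mutation_fluxes(P, gamma)
}

#' Default initial population
#'
#' Point mode: the whole population, at its single-strain equilibrium
#' count, in the state nearest `init_state_Rt`. Uniform mode: the same
#' total spread evenly over all states.
#'
#' @param grid a [build_state_grid()] object.
#' @param env a [per_state_environment()] object.
#' @param g a [growth_params()] object.
#' @param ep an [evolution_params()] object.
#' @return population vector (cells per state).
#' @export
initial_population <- function(grid, env, g, ep) {
  i0 <- which.min(abs(grid$Rt_values - ep$init_state_Rt))
  P0 <- growth_steady_state(env$C_t[i0], g)
  if (P0 <= 0) {
    stop("invalid-input: the initial state (R_t = ",
         grid$Rt_values[i0], " nM) is nonviable in this environment",
         call. = FALSE)
  }
  P <- numeric(grid$Q)
  if (ep$init_mode == "point") P[i0] <- P0 else P[] <- P0 / grid$Q
  P
}

#' Simulate mutation-selection dynamics of AR expression
#'
#' Integrates the state-transition model and reports the population of
#' every strain plus the population-weighted average `R_t` through time.
#'
#' @param grid a [build_state_grid()] object.
#' @param env a [per_state_environment()] object for the scenario's
#'   `(T_S, eta)`.
#' @param g a [growth_params()] object.
#' @param ep an [evolution_params()] object.
#' @param init optional population vector; default [initial_population()].
#' @param rtol,atol solver tolerances (cells are O(1e7-1e8), so the
#'   defaults resolve per-state counts to well below one cell in relative
#'   terms).
#' @return object of class `evolution_sim`: list with `time_h`, `P`
#'   (times x states matrix, clipped to 0 on output), `avg_Rt_nM`,
#'   `total_cells`, `grid`, `gamma`, `T_S`, `eta`.
#' @export
simulate_evolution <- function(grid, env, g, ep, init = NULL,
                               rtol = 1e-6, atol = 1e-6) {
  stopifnot(inherits(grid, "state_grid"),
            inherits(env, "strain_environment"),
            inherits(ep, "evolution_params"))
  if (is.null(init)) init <- initial_population(grid, env, g, ep)
  if (length(init) != grid$Q || any(init < 0) || sum(init) == 0) {
    stop("invalid-input: init must be a non-negative, not-all-zero ",
         "vector of length Q", call. = FALSE)
  }
  ## precompute per-state net growth terms; only crowding couples states
  M0 <- proliferation_signal(env$C_t, env$S, g)
  N <- death_rate(env$C_t, env$S, g)
  net <- M0 - N
  sigma <- g$sigma
  gamma <- ep$gamma
  Q <- grid$Q
  two_int <- c(1, rep(2, Q - 2), 1)
  f <- function(t, P) {
    P * (net - sigma * sum(P)) +
      gamma * (c(0, P[-Q]) + c(P[-1], 0) - P * two_int)
  }
  times <- unique(c(seq(0, ep$t_end, by = ep$output_stride), ep$t_end))
  sol <- ode_rk45(f, init, times, rtol = rtol, atol = atol)
  sol <- pmax(sol, 0)
  tot <- rowSums(sol)
  avg <- as.numeric(sol %*% grid$Rt_values) / tot
  structure(list(time_h = times, P = sol, avg_Rt_nM = avg,
                 total_cells = tot, grid = grid, gamma = gamma,
                 T_S = env$T_S, eta = env$eta),
            class = "evolution_sim")
}

#' Population-weighted average AR expression
#'
#' @param P population vector (cells per state), with `sum(P) > 0`.
#' @param grid a [build_state_grid()] object.
#' @return average `R_t` (nM), within the grid extremes.
#' @export
average_ar <- function(P, grid) {
  stopifnot(inherits(grid, "state_grid"))
  if (length(P) != grid$Q) {
    stop("invalid-input: length of P must equal Q", call. = FALSE)
  }
  if (any(P < 0) || sum(P) <= 0) {
    stop("undefined-average: population must be non-negative with a ",
         "positive total", call. = FALSE)
  }
  sum(P * grid$Rt_values) / sum(P)
}

#' First time the average AR expression reaches a threshold
#'
#' Linearly interpolates between output times; `NA` if the threshold is
#' never reached.
#'
#' @param x an `evolution_sim`, or a data.frame with columns `time_h` and
#'   `avg_Rt_nM` (time-ordered).
#' @param threshold average `R_t` threshold (nM).
#' @return crossing time (h), or `NA_real_`.
#' @export
time_to_threshold <- function(x, threshold) {
  if (inherits(x, "evolution_sim")) {
    tt <- x$time_h; v <- x$avg_Rt_nM
  } else if (is.data.frame(x) && all(c("time_h", "avg_Rt_nM") %in%
                                       names(x))) {
    tt <- x$time_h; v <- x$avg_Rt_nM
  } else {
    stop("invalid-input: need an evolution_sim or a data.frame with ",
         "time_h and avg_Rt_nM", call. = FALSE)
  }
  if (length(tt) == 0) stop("invalid-input: empty series", call. = FALSE)
  if (is.unsorted(tt)) {
    stop("invalid-input: series must be time-ordered", call. = FALSE)
  }
  hit <- which(v >= threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(tt[1])
  ## linear interpolation across the bracketing interval
  t0 <- tt[i - 1]; t1 <- tt[i]; v0 <- v[i - 1]; v1 <- v[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Tidy data.frame view of an evolution simulation
#'
#' @param x an `evolution_sim`.
#' @param wide if `TRUE`, one column per state (`P_state_001`, ...);
#'   otherwise a tidy (time, state, Rt, cells) layout.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.evolution_sim <- function(x, wide = TRUE, ...) {
  if (wide) {
    df <- data.frame(time_h = x$time_h, avg_Rt_nM = x$avg_Rt_nM,
                     total_cells = x$total_cells)
    pm <- as.data.frame(x$P)
    names(pm) <- sprintf("P_state_%03d", seq_len(x$grid$Q))
    cbind(df, pm)
  } else {
    data.frame(
      time_h = rep(x$time_h, times = x$grid$Q),
      state = rep(seq_len(x$grid$Q), each = length(x$time_h)),
      Rt_nM = rep(x$grid$Rt_values, each = length(x$time_h)),
      cells = as.vector(x$P)
    )
  }
}
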