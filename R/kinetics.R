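## Intracellular AR chemical kinetics: testosterone influx, 5-alpha-reductase
## conversion to DHT, mass-action binding of T and DHT to the androgen
## receptor, first-order degradation of the free species, and homeostatic AR
## production. Concentrations in nM, time in hours throughout.

#' Testosterone influx parameters
#'
#' The rate `U(T_S)` at which free testosterone enters the intracellular
#' prostate compartment, as a function of serum testosterone `T_S` (nM).
#' Two forms are supported: a two-parameter saturating curve
#' `U = u_max * T_S / (u_half + T_S)`, and a tabulated form that linearly
#' interpolates user-supplied `(T_S, U)` pairs (flat extrapolation beyond
#' the table). Both satisfy `U(0) = 0` and are non-decreasing.
#'
#' The default `u_max`/`u_half` were calibrated once (see
#' `scripts/calibrate_influx.R`) so that the baseline steady state at serum
#' T = 5 nM and homeostatic AR `R_t` = 45 nM yields a total intraprostatic
#' DHT of 50 nM, the midpoint of the normal 40-60 nM range.
#'
#' @param form `"saturating"` or `"tabulated"`.
#' @param u_max maximum influx rate (nM/h), saturating form.
#' @param u_half serum T at half-maximal influx (nM), saturating form.
#' @param table data.frame with columns `T_S` and `U` (tabulated form);
#'   `T_S` strictly increasing, `U` non-negative and non-decreasing. A
#'   leading `(0, 0)` row is prepended if absent so that `U(0) = 0`.
#' @return an object of class `influx_params`.
#' @export
#' @examples
#' p <- influx_params()
#' influx(5, p)
influx_params <- function(form = c("saturating", "tabulated"),
                          u_max = 1.4078, u_half = 4, table = NULL) {
  form <- match.arg(form)
  if (form == "saturating") {
    if (!is.numeric(u_max) || length(u_max) != 1 || u_max < 0) {
      stop("invalid-parameter: u_max must be a single non-negative number",
           call. = FALSE)
    }
    if (!is.numeric(u_half) || length(u_half) != 1 || u_half <= 0) {
      stop("invalid-parameter: u_half must be a single positive number",
           call. = FALSE)
    }
    out <- list(form = form, u_max = u_max, u_half = u_half, table = NULL)
  } else {
    if (is.null(table) || !is.data.frame(table) ||
        !all(c("T_S", "U") %in% names(table)) || nrow(table) < 1) {
      stop("invalid-parameter: tabulated influx requires a data.frame ",
           "with columns T_S and U", call. = FALSE)
    }
    tab <- table[order(table$T_S), c("T_S", "U")]
    if (any(tab$T_S < 0) || any(tab$U < 0)) {
      stop("invalid-parameter: influx table entries must be non-negative",
           call. = FALSE)
    }
    if (anyDuplicated(tab$T_S)) {
      stop("invalid-parameter: influx table T_S values must be unique",
           call. = FALSE)
    }
    if (is.unsorted(tab$U)) {
      stop("invalid-parameter: influx must be non-decreasing in T_S",
           call. = FALSE)
    }
    if (tab$T_S[1] > 0) tab <- rbind(data.frame(T_S = 0, U = 0), tab)
    if (tab$U[1] != 0) {
      stop("invalid-parameter: influx table must satisfy U(0) = 0",
           call. = FALSE)
    }
    out <- list(form = form, u_max = NA_real_, u_half = NA_real_,
                table = tab)
  }
  structure(out, class = "influx_params")
}

#' Testosterone influx rate
#'
#' @param T_S serum testosterone (nM); may be a vector.
#' @param p an [influx_params()] object.
#' @return influx `U` (nM/h), same length as `T_S`.
#' @export
influx <- function(T_S, p) {
  stopifnot(inherits(p, "influx_params"))
  if (any(!is.finite(T_S)) || any(T_S < 0)) {
    stop("invalid-input: serum testosterone must be finite and >= 0",
         call. = FALSE)
  }
  if (p$form == "saturating") {
    p$u_max * T_S / (p$u_half + T_S)
  } else {
    stats::approx(p$table$T_S, p$table$U, xout = T_S, rule = 2,
                  ties = "ordered")$y
  }
}

#' AR kinetics parameters
#'
#' Rate constants and concentrations for the intracellular androgen/AR
#' kinetics model. Defaults are the baseline literature values: mass-action
#' association/dissociation rates for T:AR and DHT:AR, first-order
#' degradation rates for free AR, T, and DHT, Michaelis-Menten parameters
#' for 5-alpha-reductase, the competitive-inhibitor (finasteride)
#' dissociation constant, and the homeostatic total AR set point `R_t`.
#'
#' @param ka_T,kd_T T:AR association (nM^-1 h^-1) / dissociation (h^-1).
#' @param ka_D,kd_D DHT:AR association (nM^-1 h^-1) / dissociation (h^-1).
#' @param beta_R free AR degradation rate (h^-1).
#' @param beta_T free T degradation rate (h^-1).
#' @param beta_D free DHT degradation rate (h^-1).
#' @param alpha 5-alpha-reductase concentration (mg/L).
#' @param k_cat reductase turnover number (nmol h^-1 mg^-1).
#' @param K_M reductase Michaelis constant (nM).
#' @param K_I finasteride dissociation constant (nM).
#' @param inhibitor_I inhibitor concentration I (nM); raises the effective
#'   Michaelis constant by the factor `eta = 1 + I/K_I`.
#' @param R_t homeostatic total AR concentration (nM).
#' @param beta_R_norm normal AR turnover rate (h^-1) entering the
#'   homeostatic production law; equal to `beta_R` at baseline.
#' @param influx an [influx_params()] object.
#' @return an object of class `kinetic_params` (a validated list).
#' @export
kinetic_params <- function(ka_T = 0.14, kd_T = 0.069,
                           ka_D = 0.053, kd_D = 0.018,
                           beta_R = log(2) / 3, beta_T = log(2) / 3,
                           beta_D = log(2) / 9,
                           alpha = 5, k_cat = 18, K_M = 75, K_I = 0.46,
                           inhibitor_I = 0, R_t = 45,
                           beta_R_norm = log(2) / 3,
                           influx = influx_params()) {
  p <- list(ka_T = ka_T, kd_T = kd_T, ka_D = ka_D, kd_D = kd_D,
            beta_R = beta_R, beta_T = beta_T, beta_D = beta_D,
            alpha = alpha, k_cat = k_cat, K_M = K_M, K_I = K_I,
            inhibitor_I = inhibitor_I, R_t = R_t,
            beta_R_norm = beta_R_norm, influx = influx)
  num <- p[setdiff(names(p), "influx")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    stop("invalid-parameter: ", paste(bad, collapse = ", "),
         " must be single non-negative finite numbers", call. = FALSE)
  }
  if (ka_T <= 0 || ka_D <= 0) {
    stop("invalid-parameter: association rates ka_T, ka_D must be > 0",
         call. = FALSE)
  }
  if (R_t <= 0) stop("invalid-parameter: R_t must be > 0", call. = FALSE)
  if (K_M <= 0) stop("invalid-parameter: K_M must be > 0", call. = FALSE)
  if (K_I <= 0) stop("invalid-parameter: K_I must be > 0", call. = FALSE)
  if (!inherits(influx, "influx_params")) {
    stop("invalid-parameter: influx must be an influx_params object",
         call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("AR kinetics parameters (nM, h)\n")
  cat(sprintf("  K_D(T)   = %.4f nM   K_D(DHT) = %.4f nM\n",
              x$kd_T / x$ka_T, x$kd_D / x$ka_D))
  cat(sprintf("  R_t = %g nM, beta_R = %.4g, beta_T = %.4g, beta_D = %.4g\n",
              x$R_t, x$beta_R, x$beta_T, x$beta_D))
  cat(sprintf("  reductase: alpha = %g mg/L, k_cat = %g, K_M = %g nM",
              x$alpha, x$k_cat, x$K_M))
  eta <- 1 + x$inhibitor_I / x$K_I
  cat(sprintf(" (effective %g nM, eta = %.3g)\n", x$K_M * eta, eta))
  cat(sprintf("  influx: %s\n", x$influx$form))
  invisible(x)
}

#' Kinetic state vector
#'
#' Concentrations (nM) of the five intracellular species: free AR `R`,
#' free testosterone `T`, free DHT `D`, and the two receptor complexes
#' `C_TR` (T:AR) and `C_DR` (DHT:AR).
#'
#' @param R,T,D,C_TR,C_DR non-negative concentrations (nM).
#' @return named numeric vector of class `kinetic_state`.
#' @export
kinetic_state <- function(R = 0, T = 0, D = 0, C_TR = 0, C_DR = 0) {
  s <- c(R = unname(R), T = unname(T), D = unname(D),
         C_TR = unname(C_TR), C_DR = unname(C_DR))
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("invalid-state: all concentrations must be finite and >= 0",
         call. = FALSE)
  }
  structure(s, class = c("kinetic_state", "numeric"))
}

#' Equilibrium dissociation constant
#'
#' `K_D = kd / ka` for a mass-action binding pair. With the baseline T:AR
#' rates this gives 0.49 nM, and 0.34 nM for DHT:AR.
#'
#' @param ka association rate (nM^-1 h^-1), > 0.
#' @param kd dissociation rate (h^-1), >= 0.
#' @return `K_D` in nM.
#' @export
#' @examples
#' dissociation_constant(0.14, 0.069) # testosterone, ~0.49 nM
dissociation_constant <- function(ka, kd) {
  if (any(!is.finite(ka)) || any(ka <= 0)) {
    stop("invalid-parameter: ka must be > 0", call. = FALSE)
  }
  if (any(!is.finite(kd)) || any(kd < 0)) {
    stop("invalid-parameter: kd must be >= 0", call. = FALSE)
  }
  kd / ka
}

#' Effective Michaelis constant under competitive inhibition
#'
#' A competitive inhibitor at concentration `I` with dissociation constant
#' `K_I` raises the Michaelis constant to `K_M * eta`, `eta = 1 + I/K_I`.
#'
#' @param K_M uninhibited Michaelis constant (nM), > 0.
#' @param I inhibitor concentration (nM), >= 0.
#' @param K_I inhibitor dissociation constant (nM), > 0.
#' @return effective `K_M` (nM), with attribute `eta`.
#' @export
effective_km <- function(K_M, I, K_I) {
  if (any(!is.finite(K_M)) || any(K_M <= 0)) {
    stop("invalid-parameter: K_M must be > 0", call. = FALSE)
  }
  if (any(!is.finite(K_I)) || any(K_I <= 0)) {
    stop("invalid-parameter: K_I must be > 0", call. = FALSE)
  }
  if (any(!is.finite(I)) || any(I < 0)) {
    stop("invalid-parameter: inhibitor concentration must be >= 0",
         call. = FALSE)
  }
  eta <- 1 + I / K_I
  structure(K_M * eta, eta = eta)
}

#' 5-alpha-reductase conversion rate
#'
#' Michaelis-Menten rate at which free testosterone is converted to DHT:
#' `alpha * k_cat * T / (K_M_eff + T)`. Units: mg/L x nmol h^-1 mg^-1 =
#' nM/h.
#'
#' @param T_free free testosterone (nM), >= 0.
#' @param alpha enzyme concentration (mg/L), >= 0.
#' @param k_cat turnover number (nmol h^-1 mg^-1), >= 0.
#' @param K_M_eff (effective) Michaelis constant (nM), > 0.
#' @return conversion rate (nM/h).
#' @export
reductase_rate <- function(T_free, alpha, k_cat, K_M_eff) {
  if (any(!is.finite(T_free)) || any(T_free < 0)) {
    stop("invalid-parameter: T_free must be >= 0", call. = FALSE)
  }
  if (any(alpha < 0) || any(k_cat < 0)) {
    stop("invalid-parameter: alpha and k_cat must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(K_M_eff)) || any(K_M_eff <= 0)) {
    stop("invalid-parameter: K_M_eff must be > 0", call. = FALSE)
  }
  alpha * k_cat * T_free / (K_M_eff + T_free)
}

#' Homeostatic AR production rate
#'
#' Production `lambda = beta_R_norm * max(0, R_t - C_TR - C_DR)`: the cell
#' replaces exactly the receptor mass needed to hold the total pool at its
#' set point `R_t`, at the normal turnover rate. The clamp keeps production
#' non-negative if bound receptor transiently exceeds the set point.
#'
#' @param R_t homeostatic total AR (nM).
#' @param C_TR,C_DR bound complex concentrations (nM).
#' @param beta_R_norm normal AR turnover rate (h^-1).
#' @return production rate `lambda` (nM/h).
#' @export
ar_production_rate <- function(R_t, C_TR, C_DR, beta_R_norm) {
  if (any(c(R_t, C_TR, C_DR, beta_R_norm) < 0)) {
    stop("invalid-parameter: all arguments must be >= 0", call. = FALSE)
  }
  beta_R_norm * pmax(0, R_t - C_TR - C_DR)
}

## fast unchecked right-hand side; y = c(R, T, D, C_TR, C_DR)
.kin_rhs <- function(y, p, U, km_eff) {
  R <- y[1]; Tf <- y[2]; D <- y[3]; Ctr <- y[4]; Cdr <- y[5]
  v <- p$alpha * p$k_cat * Tf / (km_eff + Tf)
  bT <- p$ka_T * Tf * R - p$kd_T * Ctr
  bD <- p$ka_D * D * R - p$kd_D * Cdr
  lam <- p$beta_R_norm * max(0, p$R_t - Ctr - Cdr)
  c(lam - p$beta_R * R - bT - bD,
    U - p$beta_T * Tf - v - bT,
    v - p$beta_D * D - bD,
    bT,
    bD)
}

#' Right-hand side of the kinetics ODE system
#'
#' Time derivatives of (R, T, D, C_TR, C_DR) given serum testosterone
#' `T_S`: influx and first-order degradation of free T, Michaelis-Menten
#' conversion of T to DHT (with competitive inhibition raising the
#' effective Michaelis constant), mass-action binding of both ligands to
#' free AR, first-order degradation of free AR and homeostatic AR
#' production. Bound complexes do not degrade.
#'
#' @param s a [kinetic_state()] (or named non-negative vector).
#' @param p a [kinetic_params()] object.
#' @param T_S serum testosterone (nM).
#' @return named numeric vector of derivatives (nM/h).
#' @export
kinetics_rhs <- function(s, p, T_S) {
  stopifnot(inherits(p, "kinetic_params"))
  s <- s[c("R", "T", "D", "C_TR", "C_DR")]
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("invalid-state: state fields must be finite and >= 0",
         call. = FALSE)
  }
  U <- influx(T_S, p$influx)
  km_eff <- as.numeric(effective_km(p$K_M, p$inhibitor_I, p$K_I))
  d <- .kin_rhs(as.numeric(s), p, U, km_eff)
  names(d) <- c("R", "T", "D", "C_TR", "C_DR")
  d
}

#' Simulate the kinetics model through time
#'
#' Integrates the kinetics ODE from `init` to `t_end` under a constant or
#' piecewise-constant serum testosterone schedule and returns a trajectory
#' with derived totals (total T, total DHT, total AR).
#'
#' @param p a [kinetic_params()] object.
#' @param T_S serum testosterone: a single value (nM) held constant, or a
#'   data.frame with columns `time_h` and `T_S` giving a piecewise-constant
#'   schedule (each level applies from its `time_h` onward; the first
#'   `time_h` must be 0).
#' @param t_end final time (h), > 0.
#' @param init initial [kinetic_state()]; default: free AR at `R_t`, all
#'   other species 0.
#' @param n_out number of output points (evenly spaced, including 0).
#' @param rtol,atol solver tolerances.
#' @return a data.frame of class `kinetic_trajectory` with columns
#'   `time_h`, `R_nM`, `T_nM`, `D_nM`, `CTR_nM`, `CDR_nM`, `totalT_nM`,
#'   `totalDHT_nM`, `totalAR_nM`. Concentrations are clipped to 0 at
#'   solver-tolerance level on output.
#' @export
simulate_kinetics <- function(p, T_S, t_end = 2000, init = NULL,
                              n_out = 201, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0) {
    stop("invalid-input: t_end must be a single positive number",
         call. = FALSE)
  }
  if (is.null(init)) init <- kinetic_state(R = p$R_t)
  init <- init[c("R", "T", "D", "C_TR", "C_DR")]
  if (any(init < 0)) {
    stop("invalid-state: initial state must be non-negative", call. = FALSE)
  }

  sched <- if (is.data.frame(T_S)) {
    if (!all(c("time_h", "T_S") %in% names(T_S)) || T_S$time_h[1] != 0 ||
        is.unsorted(T_S$time_h, strictly = TRUE)) {
      stop("invalid-input: T_S schedule needs columns time_h (starting ",
           "at 0, strictly increasing) and T_S", call. = FALSE)
    }
    T_S
  } else {
    data.frame(time_h = 0, T_S = as.numeric(T_S))
  }
  km_eff <- as.numeric(effective_km(p$K_M, p$inhibitor_I, p$K_I))
  times <- seq(0, t_end, length.out = max(2, n_out))

  ## integrate segment by segment over the piecewise-constant schedule
  brks <- c(sched$time_h, t_end)
  y <- as.numeric(init)
  rows <- matrix(NA_real_, nrow = length(times), ncol = 5)
  rows[1, ] <- y
  for (seg in seq_len(nrow(sched))) {
    t0 <- brks[seg]; t1 <- brks[seg + 1]
    if (t1 <= t0) next
    U <- influx(sched$T_S[seg], p$influx)
    f <- function(t, y) .kin_rhs(y, p, U, km_eff)
    idx <- which(times > t0 & times <= t1)
    seg_times <- unique(c(t0, times[idx], t1))
    sol <- ode_rk45(f, y, seg_times, rtol = rtol, atol = atol)
    if (length(idx)) rows[idx, ] <- sol[match(times[idx], seg_times), ]
    y <- sol[nrow(sol), ]
  }
  rows <- pmax(rows, 0)  # clip solver-tolerance negatives

  out <- data.frame(
    time_h = times,
    R_nM = rows[, 1], T_nM = rows[, 2], D_nM = rows[, 3],
    CTR_nM = rows[, 4], CDR_nM = rows[, 5]
  )
  out$totalT_nM <- out$T_nM + out$CTR_nM
  out$totalDHT_nM <- out$D_nM + out$CDR_nM
  out$totalAR_nM <- out$R_nM + out$CTR_nM + out$CDR_nM
  class(out) <- c("kinetic_trajectory", "data.frame")
  attr(out, "params") <- p
  attr(out, "T_S") <- sched
  out
}

#' Steady state of the kinetics model
#'
#' At steady state both complex equations force the binding fluxes to net
#' zero, so free testosterone solves the scalar balance
#' `U(T_S) = beta_T * T + v_red(T)` (monotone in `T`); free DHT, free AR
#' and the complexes then follow in closed form. The scalar balance is
#' solved by damped bisection/Brent root-finding and the full right-hand
#' side residual is verified against `tol`.
#'
#' @param p a [kinetic_params()] object.
#' @param T_S serum testosterone (nM), >= 0.
#' @param tol residual tolerance (nM/h) on the full right-hand side.
#' @return a [kinetic_state()] at steady state.
#' @export
#' @examples
#' ss <- kinetics_steady_state(kinetic_params(), T_S = 5)
#' sum(ss[c("R", "C_TR", "C_DR")])  # total AR = R_t = 45 nM
kinetics_steady_state <- function(p, T_S, tol = 1e-9) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!is.numeric(T_S) || length(T_S) != 1 || !is.finite(T_S) || T_S < 0) {
    stop("invalid-input: T_S must be a single non-negative number",
         call. = FALSE)
  }
  U <- influx(T_S, p$influx)
  km_eff <- as.numeric(effective_km(p$K_M, p$inhibitor_I, p$K_I))
  vmax <- p$alpha * p$k_cat

  if (U == 0) {
    Tf <- 0
  } else if (vmax == 0) {
    if (p$beta_T <= 0) {
      stop("steady-state error: free T has no sink (beta_T = 0, alpha = 0)",
           call. = FALSE)
    }
    Tf <- U / p$beta_T
  } else {
    g <- function(Tf) U - p$beta_T * Tf - vmax * Tf / (km_eff + Tf)
    upper <- if (p$beta_T > 0) U / p$beta_T else km_eff * U / max(vmax - U, tol)
    if (p$beta_T == 0 && U >= vmax) {
      stop("steady-state error: influx exceeds reductase capacity with ",
           "no first-order T sink", call. = FALSE)
    }
    Tf <- stats::uniroot(g, c(0, upper * (1 + 1e-12)), tol = 1e-14,
                         maxiter = 1000)$root
  }
  v <- vmax * Tf / (km_eff + Tf)
  if (v > 0 && p$beta_D <= 0) {
    stop("steady-state error: DHT is produced but beta_D = 0 gives it no ",
         "sink", call. = FALSE)
  }
  D <- if (v > 0) v / p$beta_D else 0
  KD_T <- p$kd_T / p$ka_T
  KD_D <- p$kd_D / p$ka_D
  R <- p$R_t / (p$beta_R / p$beta_R_norm + Tf / KD_T + D / KD_D)
  ss <- kinetic_state(R = R, T = Tf, D = D,
                      C_TR = R * Tf / KD_T, C_DR = R * D / KD_D)
  resid <- max(abs(kinetics_rhs(ss, p, T_S)))
  if (!is.finite(resid) || resid > max(tol, 1e-10 * max(U, 1))) {
    stop("steady-state error: residual norm ", signif(resid, 4),
         " nM/h exceeds tolerance", call. = FALSE)
  }
  ss
}

#' Totals of a kinetic state
#'
#' @param s a [kinetic_state()].
#' @return named vector `total_T` (T + C_TR), `total_DHT` (D + C_DR), and
#'   `total_AR` (R + C_TR + C_DR), in nM.
#' @export
state_totals <- function(s) {
  c(total_T = unname(s[["T"]] + s[["C_TR"]]),
    total_DHT = unname(s[["D"]] + s[["C_DR"]]),
    total_AR = unname(s[["R"]] + s[["C_TR"]] + s[["C_DR"]]))
}

#' Effective turnover rate of the total AR pool
#'
#' Only free AR degrades, so at steady state the whole pool turns over at
#' `beta_R_norm * R_ss / R_t` -- the normal turnover rate scaled by the
#' free fraction. Androgen binding therefore slows pool turnover, and
#' turnover rises nonlinearly as serum testosterone falls toward 0.
#'
#' @param ss steady-state [kinetic_state()].
#' @param p a [kinetic_params()] object.
#' @return effective turnover rate (h^-1).
#' @export
effective_ar_turnover <- function(ss, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (p$R_t <= 0) {
    stop("invalid-parameter: R_t must be > 0", call. = FALSE)
  }
  p$beta_R_norm * ss[["R"]] / p$R_t
}

#' Write a kinetic trajectory to CSV
#'
#' @param traj a `kinetic_trajectory` from [simulate_kinetics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
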