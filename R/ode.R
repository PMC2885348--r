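## Internal adaptive ODE integrator (Dormand-Prince 5(4), FSAL).
##
## The pre-installed stack provides no ODE solver package, so simulation
## routines use this integrator. It is validated against closed-form
## solutions in the test suite. Right-hand sides are plain R functions
## f(t, y) returning dy/dt; no events, no root-finding.

## Dormand-Prince coefficients
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
## 5th-order weights (row 7 of a; FSAL)
.dp_b <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
## error weights b - bhat
.dp_e <- c(71 / 57600, 0, -71 / 16695, 71 / 1920, -17253 / 339200,
           22 / 525, -1 / 40)

#' Integrate an ODE system with an adaptive Runge-Kutta 5(4) scheme
#'
#' Dormand-Prince embedded pair with PI-free standard step-size control and
#' first-same-as-last reuse. Intended for the moderately stiff mass-action
#' and population systems in this package; tolerances default to the tight
#' values used by the kinetics simulator.
#'
#' @param rhs function `f(t, y)` returning the derivative vector.
#' @param y0 numeric initial state.
#' @param times strictly increasing numeric vector of output times; the
#'   first element is the initial time.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param hmax maximum step size.
#' @param max_steps safety cap on accepted + rejected steps.
#' @return matrix with `length(times)` rows and `length(y0)` columns
#'   (column names from `names(y0)`).
#' @keywords internal
#' @noRd
ode_rk45 <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                     hmax = Inf, max_steps = 5e6) {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n,
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  t <- times[1]
  y <- as.numeric(y0)
  f0 <- rhs(t, y)
  if (length(f0) != n || any(!is.finite(f0))) {
    stop("integration error: right-hand side returned a non-finite or ",
         "mis-sized derivative at the initial state", call. = FALSE)
  }

  ## initial step size: crude norm-based guess, refined by the controller
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y / sc)^2))
  d1 <- sqrt(mean((f0 / sc)^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else (times[2] - times[1]) * 1e-4
  h <- min(h, hmax, times[length(times)] - t)
  if (h <= 0) h <- .Machine$double.eps^0.5

  k <- vector("list", 7)
  k[[1]] <- f0
  next_out <- 2L
  steps <- 0L

  while (next_out <= length(times)) {
    t_target <- times[next_out]
    hit <- FALSE
    if (t + h >= t_target - 1e-12 * max(1, abs(t_target))) {
      h_try <- t_target - t
      hit <- TRUE
    } else {
      h_try <- h
    }

    ## stages 2..7 (stage 7 doubles as the FSAL derivative)
    ytmp <- y + h_try * .dp_a[[1]][1] * k[[1]]
    k[[2]] <- rhs(t + .dp_c[2] * h_try, ytmp)
    for (s in 3:7) {
      a <- .dp_a[[s - 1]]
      acc <- a[1] * k[[1]]
      for (j in 2:(s - 1)) acc <- acc + a[j] * k[[j]]
      k[[s]] <- rhs(t + .dp_c[s] * h_try, y + h_try * acc)
    }
    ynew <- y + h_try * (.dp_b[1] * k[[1]] + .dp_b[3] * k[[3]] +
                           .dp_b[4] * k[[4]] + .dp_b[5] * k[[5]] +
                           .dp_b[6] * k[[6]])
    errv <- h_try * (.dp_e[1] * k[[1]] + .dp_e[3] * k[[3]] +
                       .dp_e[4] * k[[4]] + .dp_e[5] * k[[5]] +
                       .dp_e[6] * k[[6]] + .dp_e[7] * k[[7]])
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    err <- sqrt(mean((errv / sc)^2))

    if (!is.finite(err)) {
      ## blow-up inside a trial step: shrink hard and retry
      h <- h_try / 10
      steps <- steps + 1L
    } else if (err <= 1) {
      t <- t + h_try
      y <- ynew
      k[[1]] <- k[[7]]
      if (hit) {
        out[next_out, ] <- y
        next_out <- next_out + 1L
      }
      fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
      h <- min(max(h_try * fac, .Machine$double.eps^0.5), hmax)
      steps <- steps + 1L
    } else {
      h <- h_try * max(0.1, 0.9 * err^(-0.2))
      ## recompute k1 not needed: step rejected, state unchanged
      steps <- steps + 1L
    }
    if (steps > max_steps) {
      stop("integration error: step limit exceeded at t = ",
           signif(t, 6), " (residual step size ", signif(h, 3), ")",
           call. = FALSE)
    }
  }
  out
}
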