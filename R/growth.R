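## Androgen- and ROS-driven prostate epithelial growth. The effective
## AR:ligand signal C_t (nM of AR:T equivalents) drives an oxidative-stress
## index S (dimensionless, U-shaped in C_t), a summed proliferation signal
## M0 and a summed death signal N; cell count P follows
## dP/dt = P (M0 - sigma P - N), giving a finite equilibrium for any C_t.
##
## The printed forms of the proliferation and death signals are
## reconstructed additively from their stated components, with a 1/2
## normalization on each summed pair so the stated maxima (r and
## delta0 + delta) hold exactly. The reconstruction is isolated behind
## proliferation_signal() and death_rate() so an alternative form is a
## one-line swap.

#' Growth model parameters
#'
#' Shape and rate parameters for the tissue growth model. Defaults are the
#' baseline set: ROS induction thresholds `theta1`/`theta2` (nM) with Hill
#' coefficients `n`/`m`, background ROS `mu`, proliferation half-maximum
#' `phi1` (nM), apoptosis half-maximum `phi2` (nM), ROS-proliferation shape
#' `varphi`, ROS-death half-maximum `omega` with Hill coefficient `q`,
#' crowding coefficient `sigma` (cell^-1 h^-1), background death `delta0`
#' (h^-1), maximum androgen/ROS death `delta` (h^-1), and maximum
#' proliferation `r` (h^-1). `w_dht` is the potency of DHT:AR relative to
#' T:AR in the effective signal; `k_apop` is the Hill coefficient of the
#' low-androgen death signal (set to 2 like the mitotic signal).
#'
#' @param theta1,theta2 half-maximal `C_t` for low/high androgen induced
#'   ROS (nM); `theta2 > theta1` required.
#' @param mu background ROS level (dimensionless).
#' @param n,m Hill coefficients for the two ROS induction terms (>= 1).
#' @param phi1 half-maximal `C_t` for androgen-induced proliferation (nM).
#' @param phi2 half-maximal `C_t` for low-androgen apoptosis (nM).
#' @param varphi shape of the ROS-induced proliferation signal.
#' @param omega half-maximal `S` for ROS-induced death.
#' @param q Hill coefficient for ROS-induced death (>= 1).
#' @param sigma crowding (growth attenuation) coefficient (cell^-1 h^-1).
#' @param delta0 background per-capita death rate (h^-1).
#' @param delta maximum androgen/ROS per-capita death rate (h^-1).
#' @param r maximum per-capita proliferation rate (h^-1).
#' @param w_dht relative potency of DHT:AR in the effective signal.
#' @param k_apop Hill coefficient of the low-androgen death signal (>= 1).
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(theta1 = 30, theta2 = 225, mu = 0.05,
                          n = 4, m = 4, phi1 = 110, phi2 = 40,
                          varphi = 4, omega = 1, q = 8,
                          sigma = 1.5e-10, delta0 = 0.004,
                          delta = log(2) / 24, r = log(2) / 24,
                          w_dht = 2.4, k_apop = 2) {
  g <- list(theta1 = theta1, theta2 = theta2, mu = mu, n = n, m = m,
            phi1 = phi1, phi2 = phi2, varphi = varphi, omega = omega,
            q = q, sigma = sigma, delta0 = delta0, delta = delta, r = r,
            w_dht = w_dht, k_apop = k_apop)
  bad <- names(g)[!vapply(g, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    stop("invalid-parameter: ", paste(bad, collapse = ", "),
         " must be single non-negative finite numbers", call. = FALSE)
  }
  if (any(c(n, m, q, k_apop) < 1)) {
    stop("invalid-parameter: Hill coefficients n, m, q, k_apop must be ",
         ">= 1", call. = FALSE)
  }
  if (theta2 <= theta1) {
    stop("invalid-parameter: theta2 must exceed theta1", call. = FALSE)
  }
  structure(g, class = "growth_params")
}

#' Effective AR:ligand signal
#'
#' `C_t = C_TR + w_dht * C_DR`, the concentration of AR:T equivalents.
#' DHT:AR is weighted by its relative potency (default 2.4) in maintaining
#' prostate tissue.
#'
#' @param C_TR,C_DR complex concentrations (nM), >= 0.
#' @param w_dht relative DHT potency.
#' @return `C_t` in nM.
#' @export
effective_complex <- function(C_TR, C_DR, w_dht = 2.4) {
  if (any(C_TR < 0) || any(C_DR < 0) || any(w_dht < 0)) {
    stop("invalid-parameter: inputs must be >= 0", call. = FALSE)
  }
  C_TR + w_dht * C_DR
}

#' Oxidative stress level
#'
#' `S = mu + theta1^n / (theta1^n + C_t^n) + C_t^m / (theta2^m + C_t^m)`:
#' background ROS plus induction by both low and high androgen signal, so
#' `S` is U-shaped in `C_t` with `mu <= S <= mu + 2`.
#'
#' @param C_t effective AR:ligand signal (nM), >= 0; may be a vector.
#' @param g a [growth_params()] object.
#' @return dimensionless ROS level `S`.
#' @export
ros_level <- function(C_t, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(C_t < 0)) stop("invalid-input: C_t must be >= 0", call. = FALSE)
  g$mu + g$theta1^g$n / (g$theta1^g$n + C_t^g$n) +
    C_t^g$m / (g$theta2^g$m + C_t^g$m)
}

#' Per-capita proliferation signal
#'
#' `M0 = (r/2) * (C_t^2 / (phi1^2 + C_t^2) + varphi*S*exp(1 - varphi*S))`:
#' a sigmoidal androgen term plus a ROS term that rises from 0, peaks at
#' `S = 1/varphi`, and attenuates at high ROS (growth arrest). Bounded by
#' `0 <= M0 <= r`. Crowding is applied separately in [growth_rhs()].
#'
#' @param C_t effective AR:ligand signal (nM).
#' @param S ROS level, typically [ros_level()] of `C_t`.
#' @param g a [growth_params()] object.
#' @return proliferation signal (h^-1).
#' @export
proliferation_signal <- function(C_t, S, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(C_t < 0) || any(S < 0)) {
    stop("invalid-input: C_t and S must be >= 0", call. = FALSE)
  }
  (g$r / 2) * (C_t^2 / (g$phi1^2 + C_t^2) +
                 g$varphi * S * exp(1 - g$varphi * S))
}

#' Per-capita death rate
#'
#' `N = delta0 + (delta/2) * (phi2^k / (phi2^k + C_t^k) +
#' S^q / (omega^q + S^q))` with `k = k_apop`: background apoptosis plus a
#' low-androgen apoptotic Hill plus a high-ROS apoptotic Hill. Bounded by
#' `delta0 <= N <= delta0 + delta`.
#'
#' @inheritParams proliferation_signal
#' @return per-capita death rate (h^-1).
#' @export
death_rate <- function(C_t, S, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(C_t < 0) || any(S < 0)) {
    stop("invalid-input: C_t and S must be >= 0", call. = FALSE)
  }
  g$delta0 + (g$delta / 2) *
    (g$phi2^g$k_apop / (g$phi2^g$k_apop + C_t^g$k_apop) +
       S^g$q / (g$omega^g$q + S^g$q))
}

#' Growth ODE right-hand side
#'
#' `dP/dt = P * (M0(C_t, S(C_t)) - sigma * P - N(C_t, S(C_t)))`, with `S`
#' evaluated instantaneously from `C_t`.
#'
#' @param P cell count, >= 0.
#' @param C_t effective AR:ligand signal (nM).
#' @param g a [growth_params()] object.
#' @return `dP/dt` (cells/h).
#' @export
growth_rhs <- function(P, C_t, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(P < 0)) stop("invalid-input: P must be >= 0", call. = FALSE)
  S <- ros_level(C_t, g)
  P * (proliferation_signal(C_t, S, g) - g$sigma * P -
         death_rate(C_t, S, g))
}

#' Steady-state cell count
#'
#' The crowding term gives the logistic-type equilibrium
#' `P* = max(0, (M0 - N) / sigma)`.
#'
#' @param C_t effective AR:ligand signal (nM); may be a vector.
#' @param g a [growth_params()] object.
#' @return equilibrium cell count(s).
#' @export
growth_steady_state <- function(C_t, g) {
  stopifnot(inherits(g, "growth_params"))
  if (g$sigma <= 0) {
    stop("invalid-parameter: sigma must be > 0 (no crowding implies no ",
         "guaranteed finite equilibrium)", call. = FALSE)
  }
  S <- ros_level(C_t, g)
  pmax(0, (proliferation_signal(C_t, S, g) - death_rate(C_t, S, g)) /
         g$sigma)
}

#' Per-capita cell turnover at the tissue steady state
#'
#' At equilibrium per-capita birth equals per-capita death, so turnover is
#' the death rate `N(C_t, S(C_t))`. Lower androgen signal raises turnover,
#' which is read as a faster mutational/evolutionary tempo.
#'
#' @param C_t effective AR:ligand signal (nM); may be a vector.
#' @param g a [growth_params()] object.
#' @return per-capita turnover rate (h^-1).
#' @export
turnover_rate <- function(C_t, g) {
  death_rate(C_t, ros_level(C_t, g), g)
}
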