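---
title: "Methods: a multi-scale model of androgen-regulated prostate epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-scale model of androgen-regulated prostate epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(androscape)
```

# The model

`androscape` couples three deterministic layers describing how androgen
levels shape the growth and evolution of prostate epithelium. All
concentrations are in nM and all times in hours.

## Intracellular AR kinetics

Serum testosterone $T_S$ is an imposed input (constant or a
piecewise-constant schedule), never a dynamic state. Five intracellular
species evolve: free androgen receptor $R$, free testosterone $T$, free
dihydrotestosterone $D$, and the receptor complexes $C_{T:R}$ and
$C_{D:R}$:

$$
\begin{aligned}
\dot T &= U(T_S) - \beta_T T - v_{red}(T) - k_a^T T R + k_d^T C_{T:R},\\
\dot D &= v_{red}(T) - \beta_D D - k_a^D D R + k_d^D C_{D:R},\\
\dot R &= \lambda - \beta_R R - k_a^T T R + k_d^T C_{T:R}
          - k_a^D D R + k_d^D C_{D:R},\\
\dot C_{T:R} &= k_a^T T R - k_d^T C_{T:R},\qquad
\dot C_{D:R} = k_a^D D R - k_d^D C_{D:R},
\end{aligned}
$$

with Michaelis–Menten conversion
$v_{red}(T) = \alpha k_{cat} T / (K_M^{eff} + T)$ and competitive
inhibition $K_M^{eff} = K_M (1 + I/K_I) = K_M\,\eta$. Complexes do not
degrade. AR production is homeostatic:

$$\lambda = \beta_R^{norm}\,\max\{0,\; R_t - C_{T:R} - C_{D:R}\}.$$

With $\beta_R^{norm} = \beta_R$ this is the unique first-order law whose
steady state carries a total receptor pool of exactly $R_t$, and the
clamp keeps production non-negative if bound receptor transiently
exceeds the set point. Because only free AR degrades, the *effective*
pool turnover at steady state is $\beta_R^{norm} R_{ss}/R_t$
(`effective_ar_turnover()`), which rises nonlinearly as serum
testosterone falls — high androgen shelters the receptor pool.

**Steady states are semi-analytic.** At equilibrium both complex
equations force the binding fluxes to net zero, so free testosterone
solves the scalar balance $U(T_S) = \beta_T T + v_{red}(T)$ (monotone in
$T$, bracketed by $[0, U/\beta_T]$ and solved by Brent's method to
$10^{-14}$); then $D = v_{red}(T)/\beta_D$ and
$R = R_t / (\beta_R/\beta_R^{norm} + T/K_D^T + D/K_D^D)$. The full
right-hand-side residual is verified against $10^{-9}$ nM/h before the
state is returned. The independent oracle in the test suite is a 5000 h
integration of the full system; the two routes agree to
$<10^{-5}$ nM per component over random parameter draws within ±50% of
the baseline table.

A useful exact consequence: steady-state free $T$ and $D$ do not depend
on $R_t$, so bound complexes — and the growth signal below — are exactly
linear in $R_t$ at fixed serum testosterone.

## Default parameters and the influx calibration

Defaults are the baseline literature values: $k_a^T = 0.14$,
$k_d^T = 0.069$ ($K_D = 0.49$ nM), $k_a^D = 0.053$, $k_d^D = 0.018$
($K_D = 0.34$ nM), $\beta_R = \beta_T = \ln 2/3$, $\beta_D = \ln 2/9$
(a 9 h DHT half-life, consistent with the >6 h literature bound),
$\alpha = 5$ mg/L, $k_{cat} = 18$ nmol h⁻¹ mg⁻¹, $K_M = 75$ nM,
$K_I = 0.46$ nM, $R_t = 45$ nM.

The influx $U(T_S)$ has no recoverable published algebraic form, so the
default is the two-parameter saturating curve
$U = u_{max} T_S/(u_{half} + T_S)$. Its constants were fixed **once**,
by `scripts/calibrate_influx.R`: $u_{half} = 4$ nM sits in the middle of
the physiologic serum-testosterone range (3–6 nM in the rat), and
$u_{max} = 1.4078$ nM/h is the unique value for which the baseline
steady state ($T_S = 5$, $R_t = 45$) carries 50 nM of total
intraprostatic DHT — the midpoint of the normal 40–60 nM range. The
resulting total intraprostatic testosterone, ≈2.4 nM, falls inside the
1.8–2.2 nM range of published rat measurements without having been
fitted to it. A tabulated influx form (monotone linear interpolation,
flat extrapolation) is available for users with their own data.

```{r steady-state}
p <- kinetic_params()
ss <- kinetics_steady_state(p, T_S = 5)
round(state_totals(ss), 3)
```

## Tissue growth

The two complexes act through a single effective signal, in "AR:T
equivalents": $C_t = C_{T:R} + 2.4\,C_{D:R}$ (DHT being 2.4× as potent
as testosterone at maintaining prostate tissue). Oxidative stress is an
instantaneous, U-shaped function of the signal,

$$S(C_t) = \mu + \frac{\theta_1^n}{\theta_1^n + C_t^n}
             + \frac{C_t^m}{\theta_2^m + C_t^m},$$

bounded between $\mu$ and $\mu + 2$: both androgen deprivation and
androgen excess are pro-oxidant. The cell count $P$ obeys
$\dot P = P\,(M_0 - \sigma P - N)$ with

$$
M_0 = \frac{r}{2}\left[\frac{C_t^2}{\varphi_1^2 + C_t^2}
        + \phi S e^{1-\phi S}\right],\qquad
N = \delta_0 + \frac{\delta}{2}\left[
        \frac{\varphi_2^{k}}{\varphi_2^{k} + C_t^{k}}
        + \frac{S^q}{\omega^q + S^q}\right].
$$

**Reconstruction note.** The printed forms of $M_0$ and $N$ are not
recoverable; the forms above are the additive combination of their
described components — a sigmoidal androgen proliferation term (Hill
coefficient 2), a ROS proliferation term that peaks at $S = 1/\phi$ and
attenuates (growth arrest at high ROS), a low-androgen apoptosis Hill
(coefficient $k$, exposed as `k_apop`, set to 2 like the mitotic
signal), and a high-ROS apoptosis Hill — each summed pair carrying a
$1/2$ normalization so the stated maxima ($M_0 \le r$ and
$N \le \delta_0 + \delta$) hold exactly. This is the only additive form
consistent with those maxima. It is isolated inside
`proliferation_signal()` and `death_rate()` so an alternative
reconstruction is a one-line swap. The duplicated death-rate row in the
published parameter table is read as $\delta_0 = 0.004$ h⁻¹ (background)
and $\delta = \ln 2/24$ h⁻¹ (maximum).

Crowding gives the closed-form equilibrium
$P^* = \max\{0, (M_0 - N)/\sigma\}$, and at equilibrium per-capita birth
equals death, so the *turnover* rate is simply $N(C_t, S(C_t))$.
Turnover units in the source figures are unlabeled, so only
monotonicity — turnover falls with serum T, rises with inhibition
$\eta$ — is ever asserted, never absolute values. Cell counts are
reported as cells; any mass conversion is a single display constant,
since only the shapes of the curves are meaningful.

## Strain evolution

Selection on AR expression is modeled as a deterministic
mutation–selection system over $Q$ strains, strain $i$ carrying
$R_t = R_t^{min} + (i-1)\,\mathrm{step}$ (defaults: 100 states, 15 to
114 nM, so state 50 has 64 nM). Each strain's environment
$(C_{t,i}, S_i)$ comes from the kinetics steady state at its $R_t$ —
a quasi-steady-state coupling that is exact at constant $T_S$, because
the kinetics equilibrate in days (vs. multi-year selection horizons) and
do not depend on $P$. Strains grow by the tissue model, compete through
the shared crowding term $\sigma \sum_j P_j$, and exchange cells with
their nearest neighbours at first-order mutation rate $\gamma$:

$$\dot P_i = P_i\,\bigl(M_0(C_{t,i}, S_i) - \sigma \textstyle\sum_j P_j
             - N(C_{t,i}, S_i)\bigr)
             + \gamma (P_{i-1} + P_{i+1} - 2 P_i),$$

with reflecting boundaries (edge states exchange only with their single
neighbour) so that mutation conserves cells exactly. The reported
summary is the population-weighted average
$\bar R_t = \sum_i P_i R_t^{(i)} / \sum_i P_i$.

### Choices the source leaves open

* **Mutation rate.** $\gamma$ is never given numerically; the default is
  $10^{-5}$ h⁻¹ and every selection-ordering test is repeated over
  $\gamma \in \{10^{-6}, 10^{-5}, 10^{-4}\}$.
* **Initial condition.** The whole population starts in the state
  nearest $R_t = 45$ nM (the normal homeostatic level), at that strain's
  single-strain equilibrium count; a uniform mode is available.
* **Horizon.** 20 years (175,200 h) by default.
* **Scenario levels.** "Normal" serum T is 5 nM. "Low" is 0.25 nM —
  castration-level, since castration removes up to 95% of serum
  testosterone; "high" is 10 nM. This matters (see below).

### What selection does here, and why

Because $C_t$ is exactly linear in $R_t$ with slope $c(T_S, \eta)$, the
long-run winner is essentially the strain maximizing the net growth
$f(C_t) = M_0 - N$, i.e. $R_t^* \approx C^*/c$ where $C^* \approx 170$
nM is the fitness peak. The slope $c$ increases with serum T and
decreases with inhibition, so low androgen environments (low $T_S$ or
high $\eta$) select for **higher** final AR expression, and high serum T
for slightly **lower** — the margin between $T_S = 5$ and $T_S = 10$ is
small (≈0.6 nM) precisely because the receptor, with sub-nM $K_D$s,
stays near saturation across the physiologic range.

Two timing findings from this reconstruction, established by the test
suite rather than asserted from the source:

* A *mild* reduction in serum T ($T_S = 1$) still selects for higher
  final AR expression, but it does **not** delay selection — its fitness
  gradient near the initial state is as steep as the normal
  environment's. The delayed-but-ultimately-higher pattern appears at
  castration-level ablation ($T_S = 0.25$) and under strong reductase
  inhibition, where the signal slope $c$ is genuinely depressed.
  Crossing delays are measured at a threshold of 55 nM — 10 nM above
  the initial expression, inside every environment's early climb (at
  late thresholds the comparison inverts trivially, because the normal
  environment stalls just below its own optimum near 75 nM).
* Raising the background ROS level $\mu$ *slows* selection under low
  androgen in this reconstruction (and lowers the final $\bar R_t$):
  at low-androgen signal levels $\phi S > 1$, so extra background ROS
  pushes every strain deeper into the decaying branch of the
  ROS-proliferation factor and compresses fitness differentials. The
  corresponding acceptance assertion, which expects the opposite
  direction, is deliberately left failing rather than adjusted — the
  opposite direction evidently held in the original signal forms, which
  are not recoverable. Lowering $\theta_2$ accelerates selection, and a
  large $\theta_1$ (60 nM) produces the multi-phase rise (slow climb,
  jump, slow climb), both as described.

# Numerical choices

* **Integrator.** No ODE solver package ships in the supported
  environment, so all simulations use an internal adaptive
  Dormand–Prince 5(4) pair with FSAL and standard step-size control
  (`R/ode.R`), validated against closed-form solutions and an
  independent fixed-step RK4 oracle. Kinetics runs use
  rtol $10^{-8}$/atol $10^{-10}$; evolution runs use rtol $10^{-6}$
  (populations are $O(10^7)$ cells, so this resolves sub-cell
  increments). The system is only mildly stiff (fastest binding rates
  ≈6 h⁻¹ against degradation rates ≈0.1 h⁻¹), well within an explicit
  method's stability budget.
* **Non-negativity** is not enforced during stepping; solver-tolerance
  undershoots are clipped to zero on output only.
* **Steady-state tolerance.** Full-RHS residual ≤ $10^{-9}$ nM/h.
* **Fitting.** Ordinary least squares throughout (no error model is
  given for the source data): the influx curve by Nelder–Mead on
  log-parameters; $(\alpha, \beta_D)$ likewise, with both totals
  weighted equally in nM and degenerate corners (e.g. $\beta_D \to 0$
  with conversion active, where no steady state exists) penalized
  rather than fatal. Structural unidentifiability (no DHT in the data
  ⇒ $\beta_D$ arbitrary) is detected and flagged, not "fitted".

# The synthetic data generator

`generate_synthetic_dataset()` emulates the design of the classic
castrated-rat infusion experiments that anchor the calibration: a grid
of serum testosterone levels, one arm with the reductase active and one
with it fully blocked ($\alpha = 0$, the idealized finasteride limit —
so the blocked arm has exactly zero DHT), reporting total intraprostatic
T and DHT. Noise is multiplicative log-normal with a chosen coefficient
of variation, mean-preserving, deterministic under a seed. It emulates
the *steady-state, population-averaged* structure of such data — it does
not emulate between-animal variability, assay floors/ceilings, or serum
DHT exchange, so a green parameter-recovery test establishes that the
inference pipeline inverts *this model* correctly, not that it would
recover parameters from real tissue panels. Note that 5% noise on total
concentrations amplifies to ≈25% noise on inferred influx at high serum
T (the binding-equilibrium inversion is ill-conditioned when the
receptor is nearly saturated), which is why noisy-recovery bounds are
stated at the level where the noise is applied.

The actual published tissue measurements exist only as plotted figures
and are **not** digitized anywhere in this package; the fitted values
$\alpha = 5$ mg/L and $\beta_D = \ln 2/9$ h⁻¹ are treated as ground
truth for fixture generation, and all fitting is validated by parameter
recovery.

# Known limitations

Deliberately out of scope, following the source model: stromal–epithelial
paracrine signaling, vasculature and spatial heterogeneity; nuclear
translocation, dimerization and promoter binding (complex concentrations
stand in as surrogates); serum androgen dynamics; complex half-life
effects; stochastic (finite-population) mutation and drift; mutations in
traits other than AR expression; necrosis at extreme oxidative stress.
The growth-signal shapes are an acknowledged first approximation — all
growth-level and evolution-level conclusions are therefore asserted as
orderings and monotonicities, never as absolute values.
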