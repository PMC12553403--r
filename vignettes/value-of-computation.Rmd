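---
title: "Measuring whether thinking time tracks the value of computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring whether thinking time tracks the value of computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocchess)
```

## The question and the quantities

In clocked two-player games, every move poses a meta-decision: is this
position worth thinking about? Resource-rational accounts predict that
deliberation time should track the *value of computation* — spend time where
extra search would change the move for the better, and spend less when the
clock itself is the scarce resource. `vocchess` implements the quantitative
machinery for testing that prediction on move-level game data, and ships a
synthetic generator so the entire pipeline (and its parameter-recovery
properties) runs without any external dataset or engine.

Four layers of quantities are involved.

**Utility.** Raw engine-style evaluations (centipawns, or a signed
ply-distance to mate) are mapped to a *time-agnostic win probability*
$U \in [0,1]$ by one logistic regression per evaluation channel
(`fit_utility_map()`, `to_win_prob()`). Calibration uses decisive
(checkmate-ended) games with both clocks comfortably above a floor, so the
mapping reflects position strength rather than time trouble. The two
channels are fitted independently; where they meet, the discontinuity is
reported as a seam diagnostic rather than smoothed away. Playing-strength
ratings enter through the standard Elo expected-score curve
$1/(1+10^{-\Delta/400})$.

**Benefit of computation.** Each position carries a *consideration set* of
candidate moves, each with a shallow utility $U_{-C}(m)$ (no search) and a
deep utility $U_{C}(m)$ (treated as ground truth). The oracle benefit is

$$\Delta U_C \;=\; U_C(m_C) - U_C(m_{-C}),$$

the gain from playing the deep-search argmax $m_C$ instead of the shallow
argmax $m_{-C}$. It is zero exactly when the two argmaxes agree. The
*expected* benefit removes the oracle: each move's deep utility is modelled
as a Gaussian belief centred on its shallow value with standard deviation
$|U_C(m) - U_{-C}(m)|$ (the single-sample maximum-likelihood spread), and

$$E[\Delta U_C] \;=\; E\!\left[\max_m X_m\right] - \mu(m_{-C}),$$

with independent beliefs across moves. This is computable before the search
outcome is known, is non-negative because $m_{-C}$ maximizes the means, and
is strictly positive whenever beliefs overlap — even at $\Delta U_C = 0$.

**Cost of time.** For one time control, the empirical value function
$V(T, U)$ is the raw binned win proportion (draws count one half) over time
remaining ($3$ s bins) and advantage ($0.03$ utility bins). No functional
form is imposed. The cost of spending $\Delta T$ is
$V(T,U) - V(T - \Delta T, U)$, and the longest worthwhile deliberation is

$$\Delta T_{\max} = \max\{\Delta T : V(T - \Delta T,\, U + \Delta U_C) \ge V(T, U)\},$$

scanned over time-bin multiples. Analytic cost families (`linear`, `power`,
`power_timeleft`) give closed-form thresholds
$\Delta U_C/\rho$, $(\Delta U_C/a)^{1/b}$ and $T(\Delta U_C/a)^{1/b}$ for
comparison; the last is exactly homogeneous of degree 1 in $T$.

**Observables.** Move times are recovered from successive clock readings
and the increment, and related to the benefit scores through OLS
regressions (with centred Elo and its interaction), AIC comparison of the
$\sqrt{\cdot}$ versus identity transform (the concavity test), per-player
Spearman correlations summarized by Elo bin, and binned mean-move-time
curves. `implied_mean_move_times()` closes the loop: it marginalizes a
stopping policy over a distribution of states and computation offers to
produce the move-time-versus-benefit curve that policy would generate.

## Numerical choices

* **Expected max of Gaussians.** `expected_max_gaussians()` integrates the
  positive/negative-part identity
  $E[M] = a + \int_a^{hi}(1 - F) - \int_{lo}^{a} F$ with $F$ the product
  CDF, anchor $a = 0$ clamped into a bracket spanning
  $8\max\sigma$ beyond the extreme means, by adaptive quadrature split at
  point-mass locations (moves with zero spread are handled as exact point
  masses, not jittered). Absolute accuracy is about $10^{-6}$ utility; the
  result is floored at $\max\mu$, an exact lower bound, which also
  guarantees $E[\Delta U_C] \ge 0$ in floating point. A Monte-Carlo
  estimator (`mc_expected_benefit()`) serves as an independent oracle.
* **Ties.** Argmaxes break ties by set order (first listed wins),
  everywhere; ingested tables order moves by descending shallow value.
* **Beliefs are not truncated** to $[0,1]$: the Gaussian tails extend past
  the utility bounds. Truncation would complicate the quadrature for a
  second-order effect near saturated positions.
* **Inestimable grid cells.** Cells with fewer than `min_count` (default
  50) moves are `NA`. Non-strict lookups fall back to the nearest estimable
  cell along the time axis *within the same utility row* — preserving the
  $U$-conditioning that drives the stopping inequality — and only if the
  whole row is empty (advantages saturate near 0 and 1, where data thin
  out) to the nearest non-empty row. A strict mode errors instead, naming
  the cell.
* **Stopping scan.** `delta_t_max_empirical()` returns the *largest*
  satisfying time-bin multiple even when sampling noise breaks the
  satisfying set into pieces; a contiguous mode stops at the first failure.
  Single-cell thresholds are noisy on estimated grids; monotonicity
  analyses should average the surface over a lattice of states, as the
  worked analyses here do.
* **AIC convention.** $n\log(\mathrm{RSS}/n) + 2k$ with $k$ the number of
  coefficients, additive constants dropped — fixed across compared models,
  which must be fitted on identical rows.
* **Clock conventions.** The default `post_increment` convention assumes
  recorded clocks obey $\mathrm{after} = \mathrm{before} - t + I$, so
  $t = \Delta\mathrm{clock} + I$; `subtract_increment` subtracts the increment
  instead, for exports that record clocks before the increment is credited.
  Move times are clamped at zero with a logged count.

## What the synthetic generator emulates

`generate_dataset()` simulates a population of blitz games so that every
downstream stage — scoring, regression, value-grid estimation, policy
derivation, parameter recovery — can be exercised end to end. Its defaults
are the package's reference study conditions:

* **180+0 time control, games truncated at ply 140.** A no-increment blitz
  setting in which the clock genuinely binds: roughly half of the simulated
  games end by flagging, so time remaining carries real value.
* **Advantage dynamics.** The active player's advantage follows a reflected
  random walk on $[0,1]$ (innovation SD 0.03 per ply), giving the serial
  correlation that value-grid estimation sees in real games. Consideration
  sets are anchored on the current advantage: the best deep value equals
  it, alternatives sit an exponential gap (mean 0.08) below, and shallow
  values add heteroscedastic Gaussian noise (scale 0.1, per-move
  multipliers uniform on $(0.5, 1.5)$). The heteroscedasticity is
  deliberate: it creates variation in $E[\Delta U_C]$ at fixed
  $\Delta U_C$, the structure the expected-benefit analyses exploit.
* **Deliberation policy.** Players follow a power-family stopping rule
  (default $a = 0.005$, $b = 2$): each position offers a computation whose
  time cost is the policy threshold $\Delta T_{\max}$ times an independent
  lognormal factor (sdlog 0.75), accepted exactly when it is at most the
  threshold — computation is all-or-none, and a declined positive-benefit
  offer forfeits the benefit. Positions with zero true benefit receive a
  baseline offer that is never worthwhile. Because offered times are
  proportional to the threshold, the log of accepted deliberation time is
  linear in $\log \Delta U_C$ with slope exactly $1/b$, which is the
  package's headline parameter-recovery property
  (`recover_cost_exponent()` gets within $\pm 0.05$ of $1/2$ at the
  default conditions).
* **Noise and heterogeneity.** Deliberation times carry multiplicative
  lognormal noise (CV 0.25, mean one) on top of a 2 s motor baseline, and
  each player has a persistent lognormal deliberateness multiplier
  (sdlog 0.4) on deliberation within a game. The persistent component
  matters: with identical players, a mid-game clock reading predicts
  nothing about eventual flagging and the estimated $V(T,U)$ is flat in
  $T$. Persistent speed differences — very much a feature of real player
  populations — are what make time-left informative. The noise multiplies
  only the deliberation component, so declined offers cost exactly the
  motor time and the recovery regression stays unbiased.
* **Outcomes.** A mover whose clock would reach zero flags and loses (the
  flagging move never completes and is not emitted, so clock bookkeeping
  is exact on every emitted record: $\mathrm{after} - \mathrm{before} +
  t_{\mathrm{spent}} - I = 0$). Games reaching the truncation ply are
  scored by final advantage with a symmetric draw band of $\pm 0.05$.
* **What it does not emulate.** There is no board: moves are abstract
  utility bundles, so opening theory, position complexity, Elo-dependent
  skill or speed, and engine-specific evaluation artifacts are absent
  (ratings are drawn at 1500 ± 300 but drive nothing). Passing tests
  therefore show that the *machinery* is correct and that the analyses
  recover known generative structure — not that real players behave this
  way.

`generate_offer()` draws standalone offer pairs for policy marginalization:
lognormal times (median $10^{-4}$ s scaled by $s = 20{,}000$, so median 2 s)
and Beta(1.2, 10) benefits, coupled through a Gaussian copula with a
configurable Spearman correlation (default 0.5).

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_games = 500, seed = 1)
sim <- generate_dataset(cfg)
scored <- score_moves(sim$records)

# concavity: sqrt transform beats identity on AIC
fit_sqrt <- fit_movetime_regression(scored, "delta_uc", "sqrt")
fit_iden <- fit_movetime_regression(scored, "delta_uc", "identity")
aic_compare(fit_sqrt, fit_iden)

# cost structure and the stopping surface it implies
grid <- build_value_grid(scored, cfg$time_control, run_config())
delta_t_max_empirical(grid, t = 120, u = 0.5, delta_uc = 0.09)

# recovery of the generative cost exponent (true value 1/2)
recover_cost_exponent(scored, motor_time = cfg$motor_time)
```

The problem sizes used by the shipped analyses are deliberate choices:
3,000 games (about 200,000 moves) for value-grid and policy summaries,
600 games (about 25,000 accepted deliberations) for exponent recovery, and
50,000 sampled offers for policy marginalization. These are large enough
that the binned estimators are stable yet small enough to run comfortably
on a laptop.

## Known limitations

* The expected-benefit model assumes independent Gaussian beliefs with a
  single-sample spread estimate; correlated move values (common on a real
  board, where candidate moves share tactical motifs) are not represented.
* The empirical value function is a raw binned proportion. It needs large
  samples near the edges of the state space, and the largest-satisfying
  stopping scan inherits its noise; no smoothing is offered by design.
* The simulator's acceptance rule makes offer acceptance independent of
  the offer's size given the threshold, which is what makes exponent
  recovery exact; real deliberation is incremental rather than
  all-or-none.
* Ratings influence nothing in the generator, so expertise-interaction
  analyses run on it will correctly estimate (and should find) null
  effects; they are exercised against hand-constructed data in the tests.
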