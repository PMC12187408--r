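---
title: "Model tiers for transcriptional bursting: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model tiers for transcriptional bursting: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstsim)
```

## The model

`burstsim` simulates a single auto-repressed gene whose promoter behaves as
a telegraph switch. The promoter is ON or OFF; while ON, transcription
initiates at rate $\alpha_M$, and each initiated transcript enters the
system a fixed delay $\tau$ later (transcription plus nuclear export).
Protein is translated from mRNA at rate $\alpha_P$, and both species decay
with first-order rates $\mu_M$, $\mu_P$. The feedback closes through the
promoter: the ON$\to$OFF rate is $\lambda (P/P_0)^h$ and the OFF$\to$ON
rate is $\lambda$, so that the *mean* promoter activity at protein level
$P$ is the Hill function

$$ f(P) = \frac{1}{1 + (P/P_0)^h}, $$

independently of $\lambda$. The bursting parameter $\lambda$ therefore
moves the *timescale* of bursting without changing the average
transcription rate, which is what makes the model tiers comparable.

Two noise sources are controlled independently:

* **copy-number noise**, scaled by the system size $\Omega$ (molecule
  counts are $\Omega \times$ concentration; relative fluctuations scale as
  $\Omega^{-1/2}$);
* **bursting noise**, scaled by $\lambda$ (relative fluctuations scale as
  $\lambda^{-1/2}$).

Setting either scale to `Inf` switches that source off exactly, giving
four tiers:

| tier | $\Omega$ | $\lambda$ | function |
|------|----------|-----------|----------|
| full delayed SSA | finite | finite | `simulate_full()` |
| copy-number only | finite | `Inf` | `simulate_full()` (Hill-rate propensity) |
| piecewise-deterministic | `Inf` | finite | `simulate_pdmp()` |
| deterministic DDE | `Inf` | `Inf` | `integrate_dde()` |

On top of these sit the diffusion approximations: the extended chemical
Langevin equation (`simulate_cle()`), whose mRNA noise carries an explicit
bursting variance term of order $1/\lambda$ in addition to the classical
$1/\Omega$ term, and its linearisation about the deterministic fixed point
(`simulate_lna()`), for which the stationary power spectra are available
in closed form (`spectrum_analytic()`, `sigma_from_spectrum()`).

We represent the infinite sentinels with IEEE `Inf` rather than a large
float: arithmetic against `Inf` is exact, the corresponding noise
contributions are zeroed by an `is.finite()` test, and no overflow can
occur.

## Reference parameters

The package defaults are an experimentally informed set for an ultradian
oscillator in mouse neural progenitor cells:
$\alpha_M = 39.93$ cu/min, $\alpha_P = 21.56$/min,
$\mu_M = \ln 2/30$/min, $\mu_P = \ln 2/90$/min, $h = 4.78$,
$P_0 = 24201.01$ cu, $\tau = 33$ min. Concentrations are measured in
"cu", one molecule per reference nuclear volume (523 fL), so $\Omega = 1$
corresponds to the experimentally relevant copy numbers. At these
parameters the deterministic system spirals into a stable fixed point
(so any sustained oscillation in the stochastic tiers is noise-induced):

```{r fixed-point}
p <- feedback_params()
solve_fixed_point(p)
```

The toggle-switch defaults ($\alpha = 1$ cu/min, $\mu = 0.1$/min, $h = 2$,
$P_0 = 3$ cu, $\Omega = 100$, $\lambda = 100$/min) put the deterministic
system in its bistable regime:

```{r toggle}
toggle_fixed_points(toggle_params())
```

The asymmetric pair $(1, 9)$/$(9, 1)$ is exact by substitution; the
symmetric point is the positive root of $x^3 + 9x - 90$ and is unstable.

## Simulator design

**Delayed SSA.** Delay handling follows the scheduled-event scheme: an
initiation at time $t$ pushes an arrival at $t + \tau$ onto a FIFO queue
(constant delay keeps it ordered). Whenever the earliest arrival precedes
the next tentative reaction, time advances to the arrival, the mRNA count
increments, and the exponential clock is redrawn — valid by memorylessness
and necessary because propensities change at the arrival. An initiated
transcript is delivered regardless of later promoter switching, because
production is gated by the promoter state *at initiation*. The initial
promoter state is drawn Bernoulli$(f(P_\text{init}))$ — the stationary
conditional law at the initial protein level — to minimise equilibration
bias; `"fixed-point"` initialisation rounds $\Omega M^*$, $\Omega P^*$ to
counts. Sampling onto the output grid is zero-order hold, since the true
state is piecewise constant.

**Piecewise-deterministic process.** Between switches, $(M, P)$ follow the
linear cascade ODEs driven by the *delayed* promoter state
$\sigma(t-\tau)$, integrated with Heun's method at a fixed internal step
$\min(\text{sample\_dt}, 0.01)$ min. The ON$\to$OFF jump time inverts the
accumulated hazard $\int \lambda (P(s)/P_0)^h\,ds$ (trapezoid rule on the
integration grid, crossing located by linear interpolation within the
step); hazard inversion was chosen over thinning because $P$ has no
a-priori bound during transients. Steps are split exactly at the times
where the delayed drive changes. One numerical subtlety is worth
recording: the delayed state must be advanced with the *same*
floating-point expression (`switch_time + tau`) used to split the steps.
Computing `t - tau` and searching the switch history loses the boundary to
cancellation and systematically stretches delayed ON periods — an error
that grows with $\lambda$. Dwell times before $t = 0$ are governed by the
constant initial state, so runs started at the fixed point carry a
transient of roughly one damping time; all stationary statistics discard
an equilibration window.

**Extended CLE.** Euler–Maruyama with independent Gaussian increments per
channel (the reaction system has no reaction changing both counts, so the
cross-correlation vanishes). The mRNA variance per unit time is

$$ \frac{\alpha_M^2}{\lambda}\,
   \frac{2 (P_d/P_0)^h}{(1 + (P_d/P_0)^h)^3}
   + \frac{1}{\Omega}\left(\alpha_M f(P_d) + \mu_M M\right), $$

with $P_d = P(t - \tau)$ read from a ring buffer at lag
$\text{round}(\tau/\text{dt})$. States are clamped at zero after each
step; clamping (rather than reflection or rejection) preserves the
Gaussian increment in the interior and the model is used far from the
boundary in its validity regime. The default step is $0.01$ min; the
toggle-switch long runs use $1$ min, matching the regime where that
coarser step was established. A `sample_dt` argument thins what is
*stored* (statistics use the thinned stationary grid) without changing
the integration step — long ensembles cannot retain $10^7$ steps per
trajectory.

One genuine ambiguity in the source material is whether the mRNA drift
carries the prefactor $\alpha_M$ in front of $f$: the deterministic rate
equations and the $\alpha_M^2$ scale of the bursting noise both require
it, and the fast-switching limit only reduces correctly with it, so the
default drift is $\alpha_M f(P_d) - \mu_M M$. The literal alternative
(drift $f(P_d) - \mu_M M$) is preserved behind
`drift_alpha_m = FALSE` rather than silently resolved.

**LNA.** The linearisation uses the constant amplitudes
$\sigma_M^2, \sigma_P^2$ of `noise_amplitudes()` — the CLE variances
evaluated at the fixed point — and the feedback gain
$\alpha_M f'(P^*)$. Its two-sided power spectrum is evaluated exactly,
with the delay entering through $\cos \omega\tau$, $\sin \omega\tau$ terms
in the denominator.

## Spectral conventions and quadrature

All spectra are two-sided over angular frequency, normalised so that
$\Sigma^2 = \frac{1}{2\pi}\int S(\omega)\, d\omega$ holds exactly; the
discrete periodogram (`ensemble_periodogram()`) uses
$S(\omega_k) = \Delta t\,|X_k|^2/n$ with per-trajectory mean removal, which
makes the discrete Parseval identity exact for every input. Ensemble
$\Sigma$ estimates remove each trajectory's own mean and pool sums of
squares, which is identical to the variance of the mean-removed
concatenation and consistent with the periodogram convention. (Whether
the original analysis pooled trajectories or averaged per-trajectory
$\Sigma$ values is not stated; the pooled convention is documented here
and used throughout.)

`sigma_from_spectrum()` integrates the sharply resonant spectrum
piecewise: geometric segments bracket the resonance near the
characteristic frequency, the delay-induced oscillatory tail
($\mathcal{O}(1/\omega^2)$ decay modulated with period $2\pi/\tau$) is
integrated in half-period segments up to
$\omega_{\max} = 10^3 \max(\mu_M, \mu_P, 2\pi/\tau)$, and the remaining
tail is added in closed form as $\sigma_P^2/(\pi\,\omega_{\max})$, leaving
a residual of order $\omega_{\max}^{-3}$ — far below the $10^{-8}$
relative target.

```{r sigma}
sigma_from_spectrum(feedback_params(), noise_scales(omega = 100, lam = 10))
```

## Diagnostics

The central comparison statistic is the stationary protein standard
deviation $\Sigma_P$ and the relative error
$r_\Sigma = |\Sigma_P - \Sigma_{P,F}|/\Sigma_{P,F}$ of each approximate
tier against the full delayed SSA. `sweep_lambda()`/`sweep_grid()` run
these comparisons over $(\lambda, \Omega)$ grids with the reference
protocol (trajectories of $10^5$ min, 2000 min discarded, 2 trajectories
for $\lambda \le 0.1$ and 20 otherwise) and attach bootstrap confidence
intervals (1000 resamples over trajectories) so that scaled reruns can be
asserted honestly. Per-cell seeds derive deterministically from a base
seed and the cell indices (`derive_seed()`), so any cell can be reproduced
in isolation.

Toggle waiting times follow the reference procedure: both channels are
smoothed with a centred 1000-min moving average, dwells are contiguous
runs with the high channel above 4 cu and the low channel below it, the
undefined half-window edges are discarded (not padded), and
boundary-censored dwells are dropped — unbiased for the mean under
stationarity.

## Problem sizes used by the test suite

The package's tests verify the quantitative claims at problem sizes chosen
for a desk-scale run, with assertions widened by the Monte-Carlo
confidence interval of the measured quantity:

* slow-bursting CLE error at $(\Omega, \lambda) = (1, 0.1)$: the full
  reference protocol (2 trajectories $\times\,10^5$ min per tier). Note
  the 2-trajectory protocol carries an intrinsic standard error of
  several percentage points on $r_\Sigma$; converged runs (14
  trajectories) give $r_\Sigma \approx 35\%$.
* CLE error inside the validity region at $(1, 1)$: 8 trajectories
  $\times\ 2 \times 10^4$ min.
* LNA at $(100, 1)$: 4 trajectories $\times$ 1500 min; LNA bound at
  $(100, 0.01)$: 2 trajectories $\times$ 5000 min.
* toggle moments and waiting times at $\lambda = 1$: one run of
  $2 \times 10^6$ min per model (the reference analysis used $10^7$ min);
  dwell-moment tolerances use nonparametric bootstrap standard errors
  because dwell distributions are heavy-tailed.

## What the generators do and do not emulate

All test data are produced by the simulators themselves; there is no
external data. The synthetic regimes reproduce the structural features
the theory addresses — telegraph bursting, delayed feedback, finite copy
numbers, bistable switching — under time-homogeneous parameters and a
single promoter copy. They do not emulate extrinsic noise (cell-to-cell
parameter variability), cell division, multiple alleles, or measurement
noise, so passing tests validate the mathematical tiers against each
other, not the biological completeness of the model.

## Known limitations

* The Euler–Maruyama schemes are strong order 0.5; no Milstein or
  adaptive stepping is provided. The default 0.01-min step was adopted
  from the regime where it was established; halve it to check sensitivity
  in new parameter regions.
* The PDMP jump time is located by linear interpolation within one
  integration step ($\mathcal{O}(\text{dt}^2)$); no root polishing.
* Spectra are only available at stable fixed points; the solver reports
  an error on resonant grids rather than attempting analytic
  continuation.
* The toggle switch is simulated as SSA and CLE only (no PDMP tier), and
  spectra are not provided for it.
* Waiting-time extraction censors dwells at the series boundaries; for
  dwell distributions with means approaching the run length the censoring
  bias becomes material.
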