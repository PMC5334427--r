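---
title: "Methods: bilinear DCM of a three-region visual hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilinear DCM of a three-region visual hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`dcmbold` estimates directed ("effective") connectivity among three visual
regions -- V1, motion-sensitive V5, and posterior parietal cortex (PPC) --
from block-design fMRI time series. Neuronal population activity
$x \in \mathbb{R}^3$ follows the bilinear state equation

$$\dot{x} = \Big(A + \sum_{i=1}^{3} u_i B^{(i)}\Big)x + Cu,$$

where $A$ (Hz) holds the condition-independent couplings and
self-decays, each $B^{(i)}$ the change of those couplings induced by input
$u_i$, and $C$ the direct driving effects of the inputs on the regions.
The endogenous skeleton is fixed for all models considered here:
reciprocal V1&harr;V5 and V5&harr;PPC connections, no direct V1&harr;PPC edge,
and self-connections on the diagonal.

The three inputs are nested boxcars derived from the block schedule of a
visual-motion predictability paradigm: `MOTION` is on during every
experimental block, `UNPREDICTABLE` during the random and arbitrary blocks,
and `ARBITRARY` during the arbitrary blocks only. Nesting means each input
models the *increment* of unpredictability over the previous level, so a
modulation by `UNPREDICTABLE` reads as "what changes when motion stops being
predictable", on top of the common `MOTION` effect.

Neuronal activity is mapped to BOLD through the balloon--Windkessel model:
per region, a vasodilatory signal $s$ (decay $\kappa$, feedback $\gamma$),
inflow $f$, venous volume $v$ (transit time $\tau$, stiffness $\alpha$) and
deoxyhemoglobin $q$ (resting extraction $E_0$), with the BOLD signal the
standard nonlinear function of $(v, q)$ using 3 T constants and a 30 ms echo
time, expressed in percent signal change. Observation noise is i.i.d.
Gaussian per scan with one precision per region.

## Assumptions

* Subjects share one generating model structure (motivating fixed-effects
  group inference).
* Noise is white; real fMRI has autocorrelated noise and drifts, which the
  synthetic generator deliberately omits (see "What the simulator does and
  does not emulate").
* The system is dynamically stable: the parameter space is the set of
  $(A, B, C)$ with all eigenvalues of $A$ in the left half-plane. Priors
  are truncated to this support and the optimizer rejects unstable
  candidates.

# Estimation: variational Laplace

`dcm()` maximizes the free energy $F$, a lower bound on the log model
evidence, under a Gaussian posterior $q(\theta) = N(\mu, \Sigma)$:

$$F = \log p(y \mid \mu, h) - \tfrac12 (\mu - m)^\top P_0 (\mu - m)
      + \tfrac12 \log \lvert \Sigma \rvert
      - \tfrac12 \log \lvert C_0 \rvert + (\text{terms in } h),$$

i.e. accuracy minus a complexity (KL) penalty -- the currency of the model
comparison downstream. The E-step takes Gauss--Newton steps with
Levenberg--Marquardt damping (adapted per iteration) and step-halving until
$F$ increases; the M-step updates each region's log noise precision $h_r$ by
guarded Newton ascent under a standard-normal hyperprior. Gradients come
from central finite differences through the integrator; at three regions
this is cheap and avoids sensitivity equations. Convergence is declared when
$F$ changes by less than `tol = 1e-2` nats, well below the ~3-nat
differences that matter for model selection.

Two numerical details are worth knowing. First, step acceptance evaluates
$F$ with the curvature frozen at the current iterate; after the Jacobian is
refreshed the recorded $F$ can dip by a few hundredths of a nat near the
optimum. The engine therefore keeps the best iterate seen, treats a small
terminal dip as convergence, and aborts only on eight consecutive decreases
(which would signal a bug). Second, on a linear-Gaussian model with fixed
noise the scheme is exact: the test suite checks $F$ against the closed-form
evidence to $10^{-3}$ nats.

## Parameterization and priors

Self-connections are estimated as $A_{ii} = -0.5\,e^{\theta_{ii}}$, so every
decay is negative by construction. Default priors
(`dcm_priors()`, all overridable and recorded in the fit):

| class | prior | rationale |
|---|---|---|
| off-diagonal $A$, $B$, $C$, self log-scaling | $N(0, 1)$ | weakly informative; couplings of order 1 Hz recover without material shrinkage |
| hemodynamic log-scales (shared $\kappa$, per-region $\tau$) | $N(0, 1/256)$ | the conventional tight hemodynamic prior; looser values let transit time trade off against endogenous coupling and bias it |
| log noise precision per region | $N(0, 1)$ | weak regularization of the ReML-style update |

The priors are *truncated to the stable regime*. This is not cosmetic: for
any Gaussian prior of useful width, a substantial fraction of untruncated
draws yields an unstable $A$ (the test suite measures this on prior draws
at the default widths), because the negative self-decay bounds only the
diagonal. `draw_from_prior()` rejection-samples accordingly, and the same
support is enforced during optimization, so the stability property holds
for the prior actually used.

The width choice follows from a design-stage calibration of the
group-averaged estimate under the synthetic study conditions: tight
shrinkage priors on couplings bias connections of order 1 Hz by an amount
comparable to the recovery tolerance, and fixed-effects parameter averaging
cannot remove that bias because every subject carries the same prior.
Users fitting systems with much larger couplings should widen the priors
further.

# Group level: FFX BMS, Occam's window, BPA

`ffx_bms()` sums free energies over subjects (fixed effects) and converts
them to posterior model probabilities under a uniform model prior;
family probabilities are sums over members. `occams_window()` keeps models
above a posterior threshold (default 0.01, a configuration knob reported in
the output) and returns both raw and within-window renormalized
probabilities, since either normalization may be wanted when the window
holds more than one model.

`bayesian_parameter_average()` pools the winning model's per-session
posteriors by precision weighting: $P = \sum_i P_i$,
$\mu = P^{-1} \sum_i P_i \mu_i$. `corrected_intervals()` draws from the
averaged Gaussian and forms per-parameter empirical intervals at the
Bonferroni-corrected simultaneous level, by default $\alpha = 0.05$ over
$k = 13$ parameters (the free neural parameter count of the reference
model: 3 self + 4 couplings + 3 driving + 3 modulatory), flagging parameters
whose corrected interval contains zero. At the group-averaged values of the
passive response mode, one driving parameter ($0.11 \pm 0.04$,
$|z| \approx 2.75$) sits just inside the $k = 13$ two-sided critical value
($\approx 2.89$); with the printed two-decimal SDs it is therefore flagged
as containing zero alongside the three genuinely weak parameters, a
borderline case worth knowing about when comparing against published
two-decimal tables.

# The synthetic-data generator

The stimulus simulator reproduces the experiment's structure:

* **Geometry and kinematics.** A ball of 2 deg diameter moves at 6 deg/s
  inside a 24 x 16 deg frame; its centre lives in the 22 x 14 deg effective
  play area. Simulation is event-driven with exact event times;
  trajectories are exported at 100 Hz.
* **Reflection regimes.** `PREDICTABLE`: specular reflection.
  `RANDOM`: emergent angle uniform over the inward half-plane, excluding a
  5 deg grazing band (our choice, to avoid wall-sliding trajectories).
  `ARBITRARY`: additionally, mid-field direction changes as a Poisson
  process; the default hazard (0.208 /s) is fixed by `calibrate_hazard()`,
  which bisects on simulated sessions until arbitrary blocks show 1.6 times
  the direction changes of predictable blocks. Corner hits reflect both
  components as a single event.
* **Schedule.** 30 blocks per session, 10 per condition, pseudo-random
  order; durations {20, 20.5, 21.5} s, start jitters {0, 0.5, 1.5} s and
  baselines {8.5, 10, 11.5} s (mean exactly 10 s) counterbalanced with the
  10/3 remainder rotated across conditions so session totals match per
  level. The ball resumes each block from its last position.
* **Acquisition window.** 512 retained scans at TR 1.8 s. The full schedule
  (~940 s) slightly exceeds the 921.6 s window, so the tail of the session
  falls outside the scans; `build_inputs()` truncates and can warn. This
  mismatch is a property of the printed design itself (block, baseline and
  jitter totals cannot fit the retained-scan window exactly) and we chose to
  keep the schedule faithful rather than compress it.
* **Cohort.** Each synthetic subject receives an independently randomized
  schedule, the noiseless BOLD of the generating parameters, and white scan
  noise scaled per region to SNR 3 (SD of signal over SD of noise).

What passing recovery tests shows -- and what it does not: the generator
uses the same forward model as the estimator, white noise, and no
physiological or motion confounds. Recovery therefore validates the
*inference machinery* (identifiability at the design's information content),
not robustness to hemodynamic misspecification, autocorrelated noise, or
preprocessing artifacts of real data.

The generating values of `reference_params()` are the group-averaged
couplings of the winning model of the active response mode, used as ground
truth for all recovery experiments.

# Numerical choices

* **Microtime grid.** Inputs and states are integrated at
  `dt = TR/16 = 0.1125` s, the common sub-TR resolution for block designs.
* **Neuronal update.** The inputs are piecewise constant, so each bin is
  advanced with the exact affine update $e^{\bar{A}\,dt}$ of the augmented
  system $[[M, Cu],[0,0]]$; with at most four distinct input vectors per
  session, four matrix exponentials per model evaluation suffice. The test
  suite verifies agreement with a fine-step RK4 oracle to $10^{-8}$.
* **Hemodynamic update.** Classical RK4 within each bin, with the neuronal
  drive evaluated exactly at the bin start, midpoint and end (half-bin
  matrix exponential). $v^{1/\alpha}$ uses a sqrt-chain when $1/\alpha$ is a
  multiple of 1/8 (the default $\alpha = 0.32$ gives 3.125) -- an exact
  rewriting, not an approximation.
* **Degenerate inputs.** A zero-duration block yields an empty trajectory
  holding the initial state; a zero hazard makes `ARBITRARY` blocks
  reproduce `RANDOM` exactly under the same seed; with all inputs off the
  full system stays at rest identically.
* **Problem sizes in the test suite.** Oracle and property tests run on
  short 9-block sessions (about 190 s, 104 scans); replicate-level recovery
  uses 20 subjects at 256 scans; the headline recovery and model-selection
  checks use the full design (10 subjects, 512 scans, 16-model subspace).
  These sizes are the package's choices for a balanced default test run;
  all of them are functions of arguments, not constants.

# Known limitations

* Fixed-effects inference only; no random-effects BMS or hierarchical
  (empirical-Bayes) inversion across subjects.
* White observation noise; no AR modeling, drift terms or confound
  regressors in the observation model.
* The bilinear model is first-order: no nonlinear (second-order) modulation,
  no stochastic dynamics.
* Weakly identified directions (e.g. the baseline V1&rarr;V5 coupling versus
  its `MOTION` modulation, which co-occur whenever the ball moves) recover
  with visible posterior spread; the well-identified driving and modulatory
  parameters carry the scientific conclusions.
* The full 2304-model space is enumerable in well under a second, but
  inverting it for a cohort is a multi-hour computation; the pipeline
  gates it behind an explicit flag and defaults to a 16-model subspace
  containing the reference model.
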