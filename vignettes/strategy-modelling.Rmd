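---
title: "Modelling instantaneous strategies in a continuous penalty-shot game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling instantaneous strategies in a continuous penalty-shot game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penaltygp)
```

## The task and its physics

`penaltygp` analyses a continuous, zero-sum video game: a shooter steers a
puck that drifts rightward at constant horizontal speed toward a goal line,
while a goalie's vertical bar tries to intercept it. Both players control
only vertical velocity through a joystick input $u_t \in [-1, 1]$. In
normalised screen coordinates ($[-1,1]^2$, x rightward), the puck starts at
$(-0.75, 0)$, the goal line sits at $x = 0.77$, and the bar at $x = 0.75$.
Puck dynamics are

$$x_{t+1} = x_t + v_p, \qquad y_{t+1} = y_t + v_p u_t,$$

and the bar moves at $\tfrac{2}{3}\theta v_p u_t$, where the multiplier
$\theta$ accelerates by $0.85$ per step while the goalie holds near-maximal
input ($|u| \ge 0.8$) in a constant direction for at least three consecutive
steps (first applied on the third), and resets to $1$ otherwise.

The task fixes the start, the goal line, the bar-speed factor, the
$\theta$ increment, and the trial duration (roughly 1.5 s over 94–96
timepoints); the per-step speed, the bar's height, and the collision test
are implementation choices. The package's defaults, all configurable
through `game_config()`:

* $v_p = (0.77 + 0.75)/95$, so a trial lasts exactly 95 steps and
  $\Delta t = 1.5/95$ s;
* puck radius $1/64$ (diameter $1/64$ of the 2-unit screen width);
* `bar_half_height = 0.15`;
* the outcome is decided by 1-D vertical interval overlap at the step where
  the puck first reaches the bar's x position: the shot is blocked iff
  $|y_{\text{puck}} - y_{\text{bar}}| \le$ `bar_half_height + puck_radius`.

Inputs are sampled once per step (zero-order hold); positions are clamped so
both avatars stay on screen.

## From trajectories to change points

Shooter trajectories decompose into straight segments at near-maximal
joystick deflection separated by *change points* — reversals of the input's
sign. `extract_changepoints()` flags a reversal only when both sides exceed
a dead zone (`|u| >= 0.2` by default) so jitter around zero is not counted;
the threshold is configurable because "near-maximal" has no single
quantification.

`build_design()` turns trials into one labelled row per timepoint with seven
state predictors — puck x and y, bar y, both vertical velocities (first
differences of position), time since the last change point (normalised by
trial length, resetting after each change point), and opponent experience
(the per-opponent trial ordinal scaled to $[0,1]$) — plus the opponent
identity $\omega \in \{0, 1\}$ treated as a continuous eighth input. The
binary label $a_t$ marks whether a change point occurs at the *next* step.
Continuous predictors are standardised per participant by default, which
makes kernel length scales comparable across inputs for per-participant
policy models; pooled value models should use `standardize = "global"`,
which preserves cross-participant differences in positioning (a
per-participant z-score would make a timid, centre-hugging shooter's states
indistinguishable from a wide-ranging one's).

## The policy model

The switching policy is a GP probit classifier,
$a \sim \mathrm{Bernoulli}(\pi(\mathbf{s}, \omega))$ with
$\Phi^{-1}(\pi) = f \sim \mathcal{GP}(0, k)$ and the ARD-RBF kernel

$$k(\mathbf{x}, \mathbf{x}') = \sigma^2 \exp\!\Big(-\sum_i
\frac{(x_i - x_i')^2}{2\lambda_i^2}\Big),$$

one length scale per input: a large $\lambda_i$ means input $i$ barely
influences switching. `fit_svgp()` implements sparse variational inference:
the posterior is summarised at $M$ inducing points (k-means-initialised and
held fixed — optimising their locations buys little once $M$ covers the
input density and keeps the optimisation small), with a whitened variational
Gaussian over the inducing outputs. The expected Bernoulli log-likelihood is
integrated by 20-point Gauss–Hermite quadrature; the class probability at a
point uses the exact probit-Gaussian identity
$\mathbb{E}\,\Phi(f) = \Phi(\mu/\sqrt{1+s^2})$.

Kernel hyperparameters are learned by empirical Bayes — ascent on the same
evidence lower bound. Gradients with respect to the variational parameters
are analytic; the handful of kernel hyperparameters move by central finite
differences of the ELBO, refreshed (and stepped) every `hyper_every`
iterations. Optimisation is full-batch Adam by default (`batch_size` enables
minibatching); a few hundred to a thousand iterations suffice at these data
sizes, and the defaults (`n_inducing = 50`, `n_iters = 1000`,
`jitter = 1e-6`) are deliberately modest — model fits and sensitivities are
insensitive to pushing these further, which is why the package does not
default to the very large inducing-point counts and iteration budgets a
GPU-backed implementation would use. Held-out performance is measured by
AUC at a timepoint-level 80/20 split (`split_train_test()`), accepting
within-trial correlation, consistent with the model's assumption that
timepoints are independent given the state.

## Sensitivity indices

Because $f$ is a GP with a smooth kernel, its gradient is a GP too.
`latent_gradient()` returns the analytic gradient of the posterior mean and
the posterior covariance of the gradient (via first and second kernel
derivatives; for the ARD-RBF the prior gradient covariance at a point is
$\mathrm{diag}(\sigma^2/\lambda_i^2)$, to which the posterior reverts far
from data). Each input gets a per-timepoint index

$$\nu_i(\mathbf{x}) = \big(\nabla_i f(\mathbf{x}) / \sigma_i(\mathbf{x})\big)^2,$$

the squared gradient normalised by its own posterior standard deviation —
$\chi^2_1$ under the null of a pure-noise gradient, so uncertain gradients
are downweighted. The $\sigma_i$ here is the latent gradient's posterior
standard deviation only; no likelihood-level noise enters, since the probit
model has no separate noise parameter to propagate. Sensitivity to the
opponent's *actions* combines the bar-position and bar-velocity gradients:

$$\varsigma = \lVert L^{-1} \nabla_{\tilde{x}} f \rVert^2, \qquad
\tilde{x} = (y_{\text{bar}}, v_{\text{bar}}), \quad LL^\top = \Sigma_{\tilde{x}},$$

which equals whitening by PCA with equal weight per component (the package
tests both routes agree to $10^{-10}$). Credible intervals use the indices'
noncentral-$\chi^2$ distributions. Indices aggregate by trial and
participant (`aggregate_sensitivity()`); the early/late opponent contrast
(`opponent_phase_contrast()`) splits trials at half their steps — the task
description never defines the phase boundary, so it is a configurable
fraction.

## Variance decomposition

`decompose_variance()` partitions per-timepoint index values into
participant, trial, and residual components by the exact sum-of-squares
identity (participant means about the grand mean, trial means about their
participant means, within-trial residuals, each weighted by group size), so
the three proportions sum to one to machine precision on any input —
"appropriately weighted" is resolved in favour of exact additivity rather
than unbiased mixed-model components. The permutation null
(`permutation_test()`) jointly shuffles the (participant, trial) label pair
across points; the total sum of squares is permutation-invariant, and the
null proportions concentrate near the small df-driven floor
$(\text{groups}-1)/(N-1)$, i.e. near zero at these problem sizes.

## Value models and final-move timing

Two complementary value functions are estimated with the same GP machinery.
The *empirical action value* `fit_empirical_q()` predicts the trial's
win/loss from state, opponent, and the observed action (nine inputs) — the
value of acting under both players' actual strategies. The *final-move
expected value* `fit_final_move_ev()` asks a stopping-problem question: what
is the value of changing direction now and running straight thereafter? It
is trained only on each trial's final change point, one GP per opponent
condition, pooled across participants. Trials with no change point are
excluded from fitting but kept in win-rate denominators.

`timing_analysis()` evaluates the final-move EV counterfactually at every
timepoint of a trial, defines $t_{\mathrm{opt}}$ as the curve's argmax
(earliest step on ties), and reports the normalised deviation
$|t_{\mathrm{move}} - t_{\mathrm{opt}}|$. `hypothesis_comparison()`
contrasts the top and bottom scorers with two statistics on the same
win-probability scale: the late-trial EV offset (positioning account, H1)
and the timing-gain offset, EV at the chosen final move minus the trial's
mean EV (timing account, H2); offsets under 0.05 are treated as sampling
noise ("neither").

## The synthetic cohort generator

`generate_dataset()` is first-class, tested code: it defines the study
conditions under which every recovery experiment runs.

The goalie (`goalie_policy()`) implements the task's track-then-guess
heuristic: it tracks the puck's lagged vertical position (a "variable
reaction time", drawn discrete-uniform on 3–12 steps), then at a random
onset near the end of the trial (uniform on 0.75–0.9 of its steps) commits
to a maximal-speed dash in one direction. The human-like condition ($\omega = 1$) uses a slightly faster
parameterisation that guesses toward the puck's side 70% of the time.

The shooter (`synthetic_shooter_policy()`) holds $|u| = 1$ and flips
direction with probability $\Phi(f_{\text{true}})$, where
$f_{\text{true}}$ is *linear* in the raw predictors — the simplest family
whose gradients are known exactly, which is what the sensitivity oracles
need. The default coefficients were fixed once, before any recovery
experiment was frozen, to two calibration anchors that the emulated task
itself supplies: direction changes at ≈4.6% of timepoints, and a policy
predictable enough to support the ~0.9 held-out AUC that real players
exhibit. That combination requires a steep refractory-then-burst hazard —
dominated by time-since-last-change-point (weight 60 on the normalised
clock, intercept −11), modulated by screen position and by opponent
identity (probit shift 1.5) — making switching near-periodic within a
trial, a reasonable cartoon of the stereotyped "down-up-guess" rhythms real
players show. Shooters also time one *final* move: with probability `skill`
it is placed reactively a few steps after the goalie commits to its dash
(aimed away from the dash), otherwise uniformly at random; `u_scale < 1`
models timid vertical positioning. These two dials generate the
timing-skill and positioning-skill cohorts for the hypothesis-comparison
controls.

What the generator does *not* emulate: human opponents with genuine
adaptive strategies (opponent experience never enters the default hazard,
making it a clean null input for ARD checks), within-segment input
modulation, and realistic loss rates — the dash goalie overshoots
mid-screen pucks, so synthetic win rates (~0.9) run above the 43–76% range
real participants experience. Passing recovery tests on this cohort
therefore shows the estimators work under known ground truth, not that real
behaviour is this regular.

## Numerical choices and degenerate inputs

* Gram matrices carry a jitter of $10^{-6}\sigma^2$; predictive variances
  are floored at $10^{-12}$; log length scales are clamped to $[-6, 8]$.
* A non-finite ELBO aborts with the iteration and hyperparameter state.
* Single-class labels, zero-variance decompositions, non-positive-definite
  gradient covariance blocks (reported with a condition number), and
  degenerate splits are errors, not silent results.
* Ties in the EV argmax resolve to the earliest step; a participant with a
  single trial contributes no trial-level variance (warned).
* Probabilities can be averaged on the probit scale
  (`average_probability()`), the right scale for summarising
  low-probability events; curves and averages in figures use it.

## Problem sizes

The bundled experiments are sized for a single CPU: cohorts of 2–6
synthetic participants with 20–40 trials per opponent (10–45k design rows),
25–50 inducing points, and 300–1200 optimiser iterations. At these sizes the
policy recovery experiment reaches held-out AUC ≈ 0.95 and an ARD
null/driving length-scale ratio well above 5, and all distributional
oracles (χ², coverage, permutation null) run at their stated replication
counts (2000 draws, 1000 shuffles).

## Known limitations

* The SVGP optimiser is plain R; it is comfortable to ~50k rows and 100
  inducing points but is not a GPU-scale implementation.
* Inducing locations are fixed at k-means centres; pathological input
  densities could warrant optimising them.
* The empirical-Q and final-move models inherit the policy model's
  independence assumption across timepoints.
* The hypothesis contrast compares the single top and bottom scorers, as in
  the analyses it mirrors; it is descriptive, not a formal test.
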