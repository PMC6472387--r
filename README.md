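# penaltygp

Tools for quantifying *instantaneous* strategy in a continuous, competitive
penalty-shot video game: a shooter steers a puck rightward past a goalie's
bar, both players controlling only vertical velocity. Shooter trajectories
reduce to straight segments separated by **change points** (joystick
direction reversals), which turns strategy estimation into a sparse binary
classification problem over game states. For researchers in computational
cognitive science and behavioural game theory, the package provides:

* a faithful simulator of the task's physics (constant-velocity puck,
  accelerating bar, normalised screen coordinates) plus a track-then-guess
  goalie and parametric synthetic shooters with known ground truth;
* **policy models** `pi(s, omega) = Phi(f(s, omega))`, with
  `f ~ GP(0, k)` under an ARD-RBF kernel
  `k(x, x') = sigma^2 exp(-sum_i (x_i - x_i')^2 / (2 lambda_i^2))`, fitted by
  sparse variational inference (inducing points, whitened variational
  posterior, empirical-Bayes hyperparameters, Adam);
* gradient-based **sensitivity indices**
  `nu_i(x) = (grad_i f / sigma_i)^2` (chi-squared(1) under the null) and the
  whitened opponent-action index `varsigma = ||L^{-1} grad_(y,v) f||^2`,
  with noncentral-chi-squared credible intervals;
* an exact ANOVA-style **variance decomposition** of any per-timepoint index
  into participant/trial/residual proportions summing to 1, with a
  label-shuffling permutation null;
* **value models**: the empirical action value `Q(a | s, omega)` and the
  final-move expected value (a stopping-problem value trained on each
  trial's last change point), with optimal-timing analysis
  `|t_move - t_opt|` and a positioning-versus-timing hypothesis contrast.

## Worked example

```r
library(penaltygp)

cfg <- game_config()          # 95 steps/trial; puck (-0.75, 0) -> goal x = 0.77
ds  <- generate_dataset(2, 30, cfg, seed = 21)   # 2 shooters x 60 trials
d   <- build_design(ds)       # 1 labelled row per timepoint
mean(d$a)                     # 0.0474: sparse change points

sp  <- split_train_test(d, 0.8, seed = 5)
fit <- fit_svgp(as.matrix(sp$train[, c(state_predictors(), "omega")]),
                sp$train$a, n_inducing = 50, n_iters = 1000,
                lr_hyper = 0.1, seed = 7)
evaluate_auc(fit, sp$test)    # 0.949 held-out AUC
round(setNames(fit$kernel$lambda, c(state_predictors(), "omega")), 2)
#>              puck_x              puck_y               bar_y             puck_vy
#>                1.08               12.00                5.45                1.61
#>              bar_vy  time_since_last_cp opponent_experience               omega
#>                2.98                1.20               15.06                2.94
```

The length scales are read like relevance weights: switching is driven by
the time since the last change point and by horizontal (= temporal)
position, while opponent experience — which never enters the generative
policy — is pruned to a long scale. Sensitivities and their multilevel
structure:

```r
rec <- sensitivity_records(fit, d)     # nu_* per input + varsigma per timepoint
decompose_indices(rec, n_perm = 1000)  # participant/trial/residual proportions
```

An end-to-end run (simulate -> extract -> fit -> sensitivities ->
decomposition -> value/timing -> report) with stage caching:

```r
run_pipeline(default_run_config(seed = 1, out_dir = "run1"))
```

A thin CLI over the same stages ships in `inst/cli/penaltygp`
(`penaltygp pipeline --seed 1 --out run1`).

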