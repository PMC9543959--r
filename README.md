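# taskmod

Task-relevant spatiotemporal module decomposition of trial-structured
kinematics.

## The problem

Whole-body movements engage far more joints and time points than a task
strictly requires. Two classical ways to compress this redundancy are
**modules** (fixed groups of joints driven by shared time courses, extracted
by PCA/SVD of the motion itself) and **task-relevant components** (the
directions of motion that actually change the outcome, e.g. jump height).
Conventional modules are chosen to reconstruct the *motion*; they say
nothing about which patterns matter for the *task*. `taskmod` implements a
framework that joins the two ideas: it estimates, from trials of joint-angle
time series plus one performance value per trial, which spatiotemporal
patterns of motion predict performance, and decomposes that predictive map
into task-relevant spatial and temporal modules.

The intended user analyses goal-directed, repeated motor tasks — e.g.
targeted vertical jumps with toe/ankle/knee/hip angles sampled at 120 Hz
over the 500 ms before take-off — and wants to compare task-relevant modules
against conventional motion-relevant modules, or track how modules are
re-weighted during motor adaptation to perturbed feedback.

## The model

Motion is an array `X[i, j, k]` (joint `i = 1..I`, frame `j = 1..J`, trial
`k = 1..K`) with scalar performance `d_k`. After standardization, a ridge
regression estimates the **relevance map** `W` in

```
y_k = <W, X[,,k]> + const = sum_ij W[i,j] X[i,j,k] + const,
```

by minimizing `1/2 sum_k (d_k - y_k)^2 + sigma2/2 ||W||^2` in closed form,
with `sigma2` selected by trial-level cross-validation. The thin SVD

```
W = sum_r lambda_r s_r t_r'
```

yields task-relevant spatial modules `s_r` (length I) and temporal modules
`t_r` (length J), and splits each trial's prediction into per-module
fragments `yhat[k, r] = lambda_r s_r' X[,,k] t_r`. The package also
provides:

* conventional motion-relevant modules from SVDs of the `I x JK` and
  `J x IK` unfoldings, with per-trial temporal coefficients;
* the exact spectral identity `vec(W) = sum_r f(omega_r) g_r v_r` linking
  the ridge map to the SVD of the trial-vectorized motion
  (`f(omega) = 1/(omega^2 + sigma2)`, `g_r = v_r' x'd`);
* adaptation statistics: perturbation–fragment correlations, group-level
  t-tests with multiplicity correction, phase-averaged module features, and
  one-way ANOVA + Tukey HSD across experiments;
* a synthetic generator with planted modules, a planted relevance map, a
  gradual gain-perturbation schedule and a single-state error-driven
  learner, so the whole pipeline is testable without any recordings.

Normalized prediction error is `sum (d - y)^2 / sum d^2` on standardized
performance: 1 means no predictive relationship, 0 a perfect one.

## Worked example

Simulate a gain-adaptation experiment (150 trials, feedback perturbation
ramped by 0.005/trial for 10 trials after a 10-trial baseline and then
held), fit the relevance map, and decompose it:

```r
library(taskmod)

cfg <- synthetic_config(K = 150, seed = 42, adaptation_gain = 2)
sim <- simulate_adaptation(cfg)
fit <- fit_relevance(sim$motion, sim$trials, seed = 42)
glance(fit)
#> # A tibble: 1 x 8
#>   sigma2 cv_error folds  seed n_joints n_frames n_trials const
#>    <dbl>    <dbl> <dbl> <dbl>    <int>    <int>    <int> <dbl>
#> 1   31.6   0.0133    10    42        4       60      150 -7.09
```

Cross-validation selected `sigma2 = 31.6`; the held-out normalized
prediction error 0.013 means motion predicts performance almost perfectly
in this low-noise simulation (compare: 1 would mean no relationship).

```r
tm <- task_modules(fit, rank = 2)
tm
#> <task_modules> 2 modules (I = 4 joints, J = 60 frames)
#> lambda: 0.4812, 0.2578

fr <- module_fragments(tm, sim$motion)
performance_variance_explained(fr)
#> # A tibble: 2 x 2
#>   modules fraction
#>     <int>    <dbl>
#> 1       1    0.911
#> 2       2    1

perturbation_correlation(fr, sim$trials$perturbation)
#> # A tibble: 2 x 2
#>   module     rho
#>    <int>   <dbl>
#> 1      1 -0.626
#> 2      2 -0.0691
```

The first task-relevant module carries 91% of the predicted-performance
variance, and only its fragment correlates negatively with the applied
perturbation (-0.63): the simulated learner compensates for the feedback
shift by re-scaling exactly the planted module, which the pipeline
recovers. Across several subjects, `group_correlation_test()` turns the
per-subject correlations into corrected group-level tests, and
`autoplot(tm)` / `plot_contribution_curves()` draw the standard module and
contribution figures.

The same pipeline is scriptable from a shell via the thin wrapper:

```sh
Rscript inst/cli/taskmod simulate --out run1 --seed 1
Rscript inst/cli/taskmod fit --motion run1/motion.csv --trials run1/trials.csv --out run1
```

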