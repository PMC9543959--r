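test_that("generators are bit-reproducible given the config", {
  cfg <- synthetic_config(I = 3, J = 20, K = 30, n_basis = 4, seed = 11)
  expect_identical(generate_motion(cfg)$angles, generate_motion(cfg)$angles)
  ds <- generate_motion(cfg)
  expect_identical(generate_performance(ds, cfg)$performance,
                   generate_performance(ds, cfg)$performance)
  s1 <- simulate_adaptation(cfg)
  s2 <- simulate_adaptation(cfg)
  expect_identical(s1$motion$angles, s2$motion$angles)
  expect_identical(s1$trials$performance, s2$trials$performance)
})

test_that("noiseless motion is exactly rank-limited per trial and overall", {
  cfg <- synthetic_config(I = 4, J = 30, K = 40, rank_motion = 1,
                          noise_sd_motion = 0, seed = 2)
  ds <- generate_motion(cfg)
  for (k in c(1, 20, 40)) {
    sv <- svd(ds$angles[, , k])$d
    expect_lt(sv[2] / sv[1], 1e-12)   # each trial is a rank-1 matrix
  }
  cfg2 <- synthetic_config(I = 4, J = 30, K = 40, rank_motion = 2, n_basis = 5,
                           noise_sd_motion = 0, seed = 3)
  x <- vecK(generate_motion(cfg2))
  sv <- svd(x)$d
  expect_lt(sv[11] / sv[1], 1e-10)    # vectorized rank <= rank * n_basis
})

test_that("the singular-value spectrum shows the planted modules above the noise floor", {
  cfg <- synthetic_config(K = 150, seed = 4)   # defaults: rank 2, SNR 10
  ds <- generate_motion(cfg)
  std <- standardize_for_ridge(ds)
  om2 <- vectorized_svd(std)$omega^2
  n_signal <- cfg$rank_motion * cfg$n_basis
  expect_gt(om2[n_signal] / om2[n_signal + 1], 20)
})

test_that("planted performance is the stored noiseless inner product plus noise", {
  cfg <- synthetic_config(I = 3, J = 16, K = 25, n_basis = 4, seed = 5)
  ds <- generate_motion(cfg)
  tr <- generate_performance(ds, cfg)
  W <- planted_relevance(cfg)
  X <- standardize_per_joint(ds)$X
  manual <- vapply(1:25, function(k) sum(W * X[, , k]), numeric(1))
  expect_equal(tr$performance_true, manual, tolerance = 1e-12)
  resid <- tr$performance - tr$performance_true
  expect_gt(sd(resid), 0)
  expect_lt(sd(resid), 0.3 * sd(tr$performance_true))
  # zero planted map: performance is pure noise, unpredictable from motion
  cfg0 <- synthetic_config(I = 3, J = 16, K = 60, n_basis = 4, seed = 6,
                           planted_W = matrix(0, 3, 16))
  ds0 <- generate_motion(cfg0)
  tr0 <- generate_performance(ds0, cfg0)
  cv <- cross_validate(ds0, tr0, folds = 5, seed = 6)
  expect_gt(cv$cv_error, 0.7)
})

test_that("the perturbation schedule follows its piecewise definition exactly", {
  cfg <- synthetic_config(K = 30, seed = 1)   # baseline 10, ramp 10, step 0.005
  p <- perturbation_schedule(cfg)
  expect_identical(p[20], 0.05)               # exact, not approximate
  expect_true(all(p[1:10] == 0))
  k <- 1:30
  manual <- ifelse(k <= 10, 0, ifelse(k <= 20, (k - 10) * 0.005, 0.05))
  expect_identical(p, manual)
  p0 <- perturbation_schedule(synthetic_config(K = 30, ramp_step = 0, hold_value = 0))
  expect_true(all(p0 == 0))
  expect_error(perturbation_schedule(synthetic_config(K = 15, seed = 1)),
               "exceeds")
})

test_that("adaptation couples module 1 negatively to the perturbation by construction", {
  # fast learner, strong gain, low noise: the coupling saturates
  cfg <- synthetic_config(K = 80, seed = 7, adaptation_gain = 5,
                          amplitude_jitter = 0.02, noise_sd_motion = 0.02,
                          noise_sd_perf = 0.02, learning_rate = 0.8,
                          retention = 0.6)
  sim <- simulate_adaptation(cfg)
  tm <- task_modules(planted_relevance(cfg), rank = 2)
  fr <- module_fragments(tm, sim$motion)
  rho <- perturbation_correlation(fr, sim$trials$perturbation)$rho
  expect_lt(rho[1], -0.9)                     # strong gain, low noise
  expect_lt(cor(sim$amplitudes[, 1], sim$trials$perturbation), -0.9)

  cfg0 <- synthetic_config(K = 80, seed = 8, adaptation_gain = 0)
  sim0 <- simulate_adaptation(cfg0)
  fr0 <- module_fragments(task_modules(planted_relevance(cfg0), rank = 2),
                          sim0$motion)
  rho0 <- perturbation_correlation(fr0, sim0$trials$perturbation)$rho
  expect_lt(max(abs(rho0)), 0.35)
})

test_that("ballistic height and release detection follow their definitions", {
  expect_equal(parabola_height(0, 0), 0)
  expect_equal(parabola_height(0.3, 0), 0.3)
  expect_equal(parabola_height(0.1, 1.4), 0.2)
  expect_equal(detect_release(c(0, 0, 0.05, 0.2, 1.0)), 3L)  # 0-based index
  ramp <- seq(0, 1, by = 0.1)
  expect_equal(detect_release(ramp), 2L)       # first frame above 0.1 * max
  set.seed(9)
  for (rep in 1:10) {
    s <- abs(diffinv(rnorm(30)))               # random nonnegative series
    idx <- detect_release(s)
    scan <- which(s > 0.1 * max(s))[1] - 1L    # linear-scan oracle
    expect_identical(idx, scan)
  }
  expect_error(detect_release(rep(0, 5)), "identically zero")
  # detected release feeds the window extraction directly
  toe <- c(rep(0.01, 70), seq(0.02, 1, length.out = 30))
  rf <- detect_release(toe)
  expect_gte(rf, 60)
  expect_length(extract_prerelease_window(toe, rf, 60), 60)
})

test_that("the full pipeline recovers planted modules from one generated dataset", {
  cfg <- synthetic_config(K = 200, seed = 42)
  ds <- generate_motion(cfg)
  tr <- generate_performance(ds, cfg)
  fit <- fit_relevance(ds, tr, sigma2 = 316)
  tm <- task_modules(fit, rank = 2)
  st <- taskmod:::synth_structure(cfg)
  expect_lt(principal_angle(tm$S, st$B), 10)
  expect_lt(principal_angle(tm$T, st$T0), 10)
  # motion-relevant spatial modules recover the planted frame as well
  sm <- spatial_modules(ds)
  expect_lt(principal_angle(sm$modules[, 1:2], st$B), 10)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(rank_motion = 10), "exceeds")
  expect_error(synthetic_config(noise_sd_motion = -1), ">= 0")
  expect_error(synthetic_config(seed = 2^31), "seed")
  expect_error(synthetic_config(I = 0), "dimensions")
})
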