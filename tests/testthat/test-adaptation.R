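test_that("fragment-perturbation correlations match the textbook formula", {
  set.seed(1)
  p <- c(rep(0, 10), seq(0.005, 0.05, by = 0.005), rep(0.05, 20))
  y1 <- -3 * p                            # perfectly compensating module
  y2 <- rnorm(40)
  got <- perturbation_correlation(cbind(y1, y2), p)
  expect_equal(got$rho[1], -1, tolerance = 1e-12)
  manual <- sum((y2 - mean(y2)) * (p - mean(p))) /
    sqrt(sum((y2 - mean(y2))^2) * sum((p - mean(p))^2))
  expect_equal(got$rho[2], manual, tolerance = 1e-12)

  sub <- 11:40
  got_sub <- perturbation_correlation(cbind(y1, y2), p, trial_subset = sub)
  expect_equal(got_sub$rho[2], cor(y2[sub], p[sub]))
  expect_error(perturbation_correlation(cbind(y1, y2), p, trial_subset = 1:5),
               "constant")
  expect_error(perturbation_correlation(cbind(y1, y2), rep(1, 40)), "constant")
})

test_that("the group test rejects consistent correlations and not symmetric ones", {
  rho_neg <- matrix(rep(c(-0.6, -0.5, -0.7), length.out = 26), 13, 2)
  rho_neg[, 2] <- rep(c(0.2, -0.2), length.out = 13) + seq(-0.06, 0.06, length.out = 13)
  gt <- group_correlation_test(rho_neg)
  expect_lt(gt$p_corrected[1], 0.001)
  expect_gt(gt$p_corrected[2], 0.2)
  expect_true(all(gt$p_corrected >= gt$p_raw))
  expect_error(group_correlation_test(matrix(0.4, 6, 2)), "identical")
  expect_error(group_correlation_test(matrix(c(0.1, 0.2), 1, 2)), "2 subjects")
})

test_that("the group test decision agrees with a sign-permutation oracle", {
  set.seed(2)
  for (rep in 1:6) {
    shift <- sample(c(0, -0.35), 1)
    rho <- rnorm(13, mean = shift, sd = 0.2)
    p_t <- group_correlation_test(matrix(rho, 13, 1))$p_raw
    # oracle: exact sign-flip permutation test of the mean
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 13)))
    null_means <- abs(flips %*% rho) / 13
    p_perm <- mean(null_means >= abs(mean(rho)) - 1e-12)
    expect_equal(p_t < 0.05, p_perm < 0.05)
  }
})

test_that("phase averaging splits frames into contiguous near-equal blocks", {
  set.seed(3)
  tmod <- rnorm(60)
  got <- phase_average(tmod)
  expect_equal(got$n_frames, c(20L, 20L, 20L))
  expect_equal(got$mean,
               c(mean(tmod[1:20]), mean(tmod[21:40]), mean(tmod[41:60])))
  # indivisible J: earliest blocks are larger
  got10 <- phase_average(rnorm(10), n_phases = 3)
  expect_equal(got10$n_frames, c(4L, 3L, 3L))
  expect_equal(phase_average(rep(2.5, 9))$mean, rep(2.5, 3))
  expect_error(phase_average(rnorm(2), n_phases = 3), "exceeds")
})

test_that("across-experiment ANOVA and Tukey flag exactly the separated group", {
  subj <- paste0("S", 1:8)
  base <- rep(c(-0.1, 0.1), 4)
  feats <- dplyr::bind_rows(
    tibble::tibble(subject = subj, experiment = "E1", feature = "knee", value = base),
    tibble::tibble(subject = subj, experiment = "E2", feature = "knee", value = base + 5),
    tibble::tibble(subject = subj, experiment = "E3", feature = "knee", value = base)
  )
  cmp <- compare_across_experiments(feats)
  expect_lt(cmp$anova$p, 1e-6)
  tk <- cmp$tukey
  expect_lt(tk$p_adj[tk$contrast == "E2-E1"], 0.001)
  expect_lt(tk$p_adj[tk$contrast == "E3-E2"], 0.001)
  expect_gt(tk$p_adj[tk$contrast == "E3-E1"], 0.9)

  # identical groups: no between-group variance at all
  same <- dplyr::bind_rows(
    tibble::tibble(subject = subj, experiment = "E1", feature = "f", value = base),
    tibble::tibble(subject = subj, experiment = "E2", feature = "f", value = base)
  )
  cmp0 <- compare_across_experiments(same)
  expect_equal(cmp0$anova$F, 0, tolerance = 1e-12)
  expect_equal(cmp0$anova$p, 1, tolerance = 1e-9)
})

test_that("the ANOVA F statistic matches from-scratch sums of squares", {
  set.seed(4)
  feats <- tidyr::expand_grid(subject = paste0("S", 1:6),
                              experiment = c("E1", "E2", "E3"))
  feats$feature <- "f1"
  feats$value <- rnorm(nrow(feats)) + ifelse(feats$experiment == "E2", 0.8, 0)
  cmp <- compare_across_experiments(feats)
  g_means <- tapply(feats$value, feats$experiment, mean)
  grand <- mean(feats$value)
  ss_b <- 6 * sum((g_means - grand)^2)
  ss_w <- sum((feats$value - g_means[feats$experiment])^2)
  F_manual <- (ss_b / 2) / (ss_w / (18 - 3))
  expect_equal(cmp$anova$F, F_manual, tolerance = 1e-10)
})

test_that("simulated adaptation drives only the perturbation-coupled module", {
  rhos <- t(sapply(1:8, function(s) {
    cfg <- synthetic_config(K = 120, seed = 300 + s, adaptation_gain = 2)
    sim <- simulate_adaptation(cfg)
    fit <- fit_relevance(sim$motion, sim$trials, sigma2 = 316)
    fr <- module_fragments(task_modules(fit, rank = 2), sim$motion)
    perturbation_correlation(fr, sim$trials$perturbation)$rho
  }))
  gt <- group_correlation_test(rhos)
  expect_lt(gt$mean_rho[1], -0.4)       # compensating module tracks -perturbation
  expect_lt(gt$p_corrected[1], 0.01)
  expect_gt(gt$p_corrected[2], 0.05)    # uncoupled module stays null
})
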