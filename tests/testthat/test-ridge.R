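test_that("orthonormal-column designs collapse to the closed form x'd / (1 + sigma2)", {
  set.seed(1)
  x <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5)))   # x'x = I
  d <- rnorm(50)
  for (s2 in c(0, 0.5, 2)) {
    expect_equal(fit_ridge(x, d, s2), as.numeric(crossprod(x, d)) / (1 + s2),
                 tolerance = 1e-12)
  }
})

test_that("primal and dual solves agree and match a gradient-descent oracle", {
  set.seed(2)
  x <- matrix(rnorm(50 * 5), 50, 5)
  d <- rnorm(50)
  s2 <- 0.7
  w <- fit_ridge(x, d, s2)

  # independent oracle: plain gradient descent on the ridge cost
  w_gd <- numeric(5)
  lr <- 1 / (max(svd(x)$d)^2 + s2)
  for (it in 1:20000) {
    grad <- -as.numeric(crossprod(x, d - x %*% w_gd)) + s2 * w_gd
    w_gd <- w_gd - lr * grad
  }
  expect_lt(max(abs(w - w_gd)), 1e-6)

  # dual route (more features than trials) equals the primal normal equations
  xw <- matrix(rnorm(20 * 35), 20, 35)
  dw <- rnorm(20)
  w_dual <- fit_ridge(xw, dw, s2)
  w_primal <- solve(crossprod(xw) + s2 * diag(35), crossprod(xw, dw))
  expect_lt(max(abs(w_dual - as.numeric(w_primal))), 1e-9)
})

test_that("regularization shrinks: coefficient norm is non-increasing in sigma2", {
  set.seed(3)
  x <- matrix(rnorm(40 * 10), 40, 10)
  d <- rnorm(40)
  norms <- vapply(10^seq(-3, 4, by = 0.5),
                  function(s2) sqrt(sum(fit_ridge(x, d, s2)^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 1e-2 * norms[1])  # sigma2 -> Inf kills W
})

test_that("sigma2 = 0 gives least squares on full-rank designs and errors otherwise", {
  set.seed(4)
  x <- matrix(rnorm(30 * 4), 30, 4)
  d <- rnorm(30)
  expect_equal(fit_ridge(x, d, 0),
               as.numeric(coef(lm(d ~ x - 1))), tolerance = 1e-9)
  x_sing <- cbind(x, x[, 1])
  expect_error(fit_ridge(x_sing, d, 0), "sigma2 > 0")
})

test_that("prediction error is 0 for perfect prediction and 1 for no prediction", {
  set.seed(5)
  d <- rnorm(25)
  expect_equal(prediction_error(d, d), 0)
  expect_equal(prediction_error(rep(0, 25), d), 1)
  y <- rnorm(25)
  expect_equal(prediction_error(y, d), sum((d - y)^2) / sum(d^2))
  expect_error(prediction_error(y, rep(0, 25)), "identically zero")
})

test_that("predicting from a fit matches the module-space expression with offset", {
  cfg <- synthetic_config(I = 3, J = 12, K = 40, n_basis = 4, seed = 6)
  ds <- generate_motion(cfg)
  tr <- generate_performance(ds, cfg)
  fit <- fit_relevance(ds, tr, sigma2 = 1, folds = 5)
  y <- predict(fit)$.pred
  X <- standardize_per_joint(ds)$X
  y_mod <- as.numeric(vecK(X) %*% as.numeric(fit$W)) + fit$const
  expect_lt(max(abs(y - y_mod)), 1e-9)
  # zero map predicts zero
  fit0 <- fit
  fit0$W_tilde[] <- 0
  expect_true(all(predict(fit0)$.pred == 0))
})

test_that("a one-value grid reduces cross-validation to a manual fold loop", {
  cfg <- synthetic_config(I = 2, J = 10, K = 30, n_basis = 4, seed = 7)
  ds <- generate_motion(cfg)
  tr <- generate_performance(ds, cfg)
  s2 <- 0.5
  folds <- 5
  seed <- 42
  got <- cross_validate(ds, tr, s2, folds = folds, seed = seed)

  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), 30))
  errs <- vapply(seq_len(folds), function(f) {
    trn <- which(fold_of != f); tst <- which(fold_of == f)
    m_tr <- motion_data(ds$angles[, , trn])
    std <- standardize_for_ridge(m_tr, tr[trn, ])
    w <- fit_ridge(vecK(std$x), std$d, s2)
    new <- apply_ridge_standardization(std, motion_data(ds$angles[, , tst]),
                                       tr$performance[tst])
    prediction_error(as.numeric(vecK(new$x) %*% w), new$d)
  }, numeric(1))
  expect_equal(got$cv_error, mean(errs), tolerance = 1e-10)
  expect_equal(got$best_sigma2, s2)
})

test_that("cross-validated error sits at its two scale anchors", {
  # no relationship: error near 1
  cfg <- synthetic_config(I = 4, J = 20, K = 100, rank_motion = 0, seed = 8)
  ds <- generate_motion(cfg)
  set.seed(991)
  tr <- trial_data(rnorm(100))
  cv <- cross_validate(ds, tr, folds = 10, seed = 8)
  expect_gt(cv$cv_error, 0.85)
  expect_lt(cv$cv_error, 1.2)
  # exact linear, noiseless: error near 0
  cfg2 <- synthetic_config(I = 4, J = 20, K = 100, noise_sd_motion = 0,
                           noise_sd_perf = 0, seed = 9)
  ds2 <- generate_motion(cfg2)
  tr2 <- generate_performance(ds2, cfg2)
  cv2 <- cross_validate(ds2, tr2, 1e-6, folds = 10, seed = 9)
  expect_lt(cv2$cv_error, 1e-6)
})

test_that("cross-validation guards its preconditions", {
  cfg <- synthetic_config(I = 2, J = 5, K = 8, n_basis = 3, seed = 10)
  ds <- generate_motion(cfg)
  tr <- generate_performance(ds, cfg)
  expect_error(cross_validate(ds, tr, folds = 9), "fewer than")
  expect_error(cross_validate(ds, tr, numeric(0), folds = 2), "empty")
  expect_error(cross_validate(ds, tr, folds = 1), ">= 2")
})
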