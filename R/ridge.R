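#' Closed-form ridge estimate of the relevance map
#'
#' Minimizes `0.5 * sum_k (d_k - x_k . w)^2 + 0.5 * sigma2 * |w|^2` for the
#' vectorized relevance map `w`. The solve uses the primal normal equations
#' when the number of features is at most the number of trials and the
#' exact dual form `x' (x x' + sigma2 I)^{-1} d` otherwise, which is cheaper
#' in the usual regime of many (joint, frame) features and fewer trials.
#'
#' @param x K x P matrix of standardized motion, one vectorized trial per
#'   row (column-major vec of the I x J trial matrix).
#' @param d Length-K standardized performance vector.
#' @param sigma2 Regularization parameter, `>= 0`. With `sigma2 = 0` the
#'   design must have full column rank.
#' @return Length-P coefficient vector.
#' @export
fit_ridge <- function(x, d, sigma2) {
  x <- as.matrix(x)
  K <- nrow(x); P <- ncol(x)
  if (length(d) != K) abort("`d` must have one value per row of `x`")
  if (sigma2 < 0) abort("`sigma2` must be >= 0")
  solve_spd <- function(A, b) {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      abort("system is singular at sigma2 = 0; use sigma2 > 0")
    }
    backsolve(ch, forwardsolve(t(ch), b))
  }
  if (P <= K) {
    A <- crossprod(x)
    diag(A) <- diag(A) + sigma2
    as.numeric(solve_spd(A, crossprod(x, d)))
  } else {
    G <- tcrossprod(x)
    diag(G) <- diag(G) + sigma2
    as.numeric(crossprod(x, solve_spd(G, d)))
  }
}

#' Normalized prediction error
#'
#' `sum((d - y)^2) / sum(d^2)`: on standardized performance this equals 1
#' when the prediction carries no information and 0 for a perfect
#' prediction.
#'
#' @param y Predicted standardized performance.
#' @param d Actual standardized performance.
#' @return Scalar error in `[0, Inf)`.
#' @export
prediction_error <- function(y, d) {
  if (length(y) != length(d)) abort("`y` and `d` must have equal length")
  denom <- sum(d^2)
  if (denom == 0) abort("`d` is identically zero; error scale undefined")
  sum((d - y)^2) / denom
}

vec_trials <- function(x_array) {
  d3 <- dim(x_array)
  t(matrix(x_array, nrow = d3[1L] * d3[2L]))  # K x (I*J), column-major vec
}

default_sigma2_grid <- function() 10^seq(-3, 3, length.out = 13)

#' Cross-validated selection of the ridge regularization
#'
#' Trial-level shuffled k-fold cross-validation. Standardization statistics
#' are refit on each training fold and applied to the held-out trials; the
#' held-out score is the [prediction_error()] averaged over folds. The grid
#' value minimizing the mean error is selected.
#'
#' Internally each fold eigendecomposes the training Gram matrix once and
#' scores the whole grid from it; this is algebraically identical to
#' refitting [fit_ridge()] at every grid value.
#'
#' @param motion A [motion_data] object.
#' @param trials Trial table (as from [trial_data()]).
#' @param sigma2_grid Candidate regularization values (default: 13 points,
#'   log-spaced from 1e-3 to 1e3).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return List with `best_sigma2`, `cv_error` (mean held-out error at the
#'   selected value), and `path`, a tibble of `(sigma2, cv_error)` over the
#'   grid.
#' @export
cross_validate <- function(motion, trials, sigma2_grid = default_sigma2_grid(),
                           folds = 10, seed = 1) {
  stopifnot(inherits(motion, "motion_data"))
  K <- n_trials(motion)
  if (folds < 2) abort("`folds` must be >= 2")
  if (K < folds) abort(sprintf("K = %d trials is fewer than %d folds", K, folds))
  if (length(sigma2_grid) == 0) abort("`sigma2_grid` is empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), K))
  errs <- matrix(NA_real_, folds, length(sigma2_grid))
  for (f in seq_len(folds)) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    m_tr <- subset_trials(motion, tr)
    std <- standardize_for_ridge(m_tr, trials[tr, ])
    x_tr <- vec_trials(std$x)
    new <- apply_ridge_standardization(std, subset_trials(motion, te),
                                       trials$performance[te])
    x_te <- vec_trials(new$x)
    # eigendecompose the training Gram matrix once, score all sigma2 values
    G <- tcrossprod(x_tr)
    eg <- eigen(G, symmetric = TRUE)
    q <- crossprod(eg$vectors, std$d)          # Q' d
    M <- x_te %*% t(x_tr) %*% eg$vectors       # x_te x_tr' Q
    for (g in seq_along(sigma2_grid)) {
      s2 <- sigma2_grid[g]
      ev <- eg$values + s2
      if (any(ev <= 0)) {
        abort("singular system at sigma2 = 0; use sigma2 > 0")
      }
      y_te <- as.numeric(M %*% (q / ev))
      errs[f, g] <- prediction_error(y_te, new$d)
    }
  }
  cv <- colMeans(errs)
  best <- which.min(cv)
  list(
    best_sigma2 = sigma2_grid[best],
    cv_error = cv[best],
    path = tibble::tibble(sigma2 = sigma2_grid, cv_error = cv)
  )
}

subset_trials <- function(motion, idx) {
  motion_data(motion$angles[, , idx, drop = FALSE], joints = motion$joints,
              sample_rate = motion$sample_rate, units = motion$units,
              subject_id = motion$subject_id,
              experiment_id = motion$experiment_id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit the motion-to-performance relevance map
#'
#' The main entry point of the package: standardizes the dataset, estimates
#' the regression-space relevance map by closed-form ridge regression,
#' selects the regularization by cross-validation when not supplied, and
#' maps the coefficients to the module-comparison (per-joint standardized)
#' space, where `y_k = <W, X_k> + const`.
#'
#' @inheritParams cross_validate
#' @param sigma2 Fixed regularization parameter; when `NULL` (default) it is
#'   selected from `sigma2_grid` by `folds`-fold cross-validation.
#' @return An object of class `relevance_fit` with elements `W_tilde`, `W`
#'   (I x J matrices), `const`, `sigma2`, `cv_error`, `cv_path`, `folds`,
#'   `seed`, and the stored standardizations. Use [tidy()] for a per-cell
#'   table, [glance()] for a one-row summary, [predict()] for new trials and
#'   [task_modules()] to decompose the map.
#' @examples
#' cfg <- synthetic_config(K = 60, seed = 1)
#' ds <- generate_motion(cfg)
#' tr <- generate_performance(ds, cfg)
#' fit <- fit_relevance(ds, tr, sigma2 = 1)
#' glance(fit)
#' @export
fit_relevance <- function(motion, trials, sigma2 = NULL,
                          sigma2_grid = default_sigma2_grid(),
                          folds = 10, seed = 1) {
  stopifnot(inherits(motion, "motion_data"))
  if (is.null(sigma2)) {
    cv <- cross_validate(motion, trials, sigma2_grid, folds = folds, seed = seed)
  } else {
    cv <- cross_validate(motion, trials, sigma2, folds = folds, seed = seed)
  }
  ridge_std <- standardize_for_ridge(motion, trials)
  joint_std <- standardize_per_joint(motion)
  d3 <- dim(motion$angles)
  w <- fit_ridge(vec_trials(ridge_std$x), ridge_std$d, cv$best_sigma2)
  W_tilde <- matrix(w, d3[1L], d3[2L], dimnames = list(motion$joints, NULL))
  mapped <- map_coefficients(W_tilde, ridge_std, joint_std)
  structure(
    list(
      W_tilde = W_tilde, W = mapped$W, const = mapped$const,
      sigma2 = cv$best_sigma2, cv_error = cv$cv_error, cv_path = cv$path,
      folds = folds, seed = seed,
      ridge_std = ridge_std, joint_std = joint_std,
      joints = motion$joints, dims = d3
    ),
    class = "relevance_fit"
  )
}

#' @export
print.relevance_fit <- function(x, ...) {
  cat(sprintf(
    "<relevance_fit> %d joints x %d frames, K = %d trials\n  sigma2 = %g, cv_error = %.4g (%d-fold)\n",
    x$dims[1L], x$dims[2L], x$dims[3L], x$sigma2, x$cv_error, x$folds
  ))
  invisible(x)
}

#' Predict standardized performance for trials
#'
#' `y_k = sum_ij x[i,j,k] * W_tilde[i,j]`, with new motion standardized by
#' the training statistics. Identically (by the coefficient mapping)
#' `y_k = sum_ij X[i,j,k] * W[i,j] + const` on per-joint standardized motion.
#'
#' @param object A `relevance_fit`.
#' @param newdata Optional [motion_data]; defaults to the fitting data.
#' @param ... Unused.
#' @return A tibble with columns `trial` and `.pred` (standardized
#'   performance units).
#' @export
predict.relevance_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$ridge_std$x
  } else {
    apply_ridge_standardization(object$ridge_std, newdata)$x
  }
  if (!all(dim(x)[1:2] == dim(object$W_tilde))) abort("shape mismatch")
  y <- as.numeric(vec_trials(x) %*% as.numeric(object$W_tilde))
  tibble::tibble(trial = seq_along(y), .pred = y)
}

#' @export
tidy.relevance_fit <- function(x, ...) {
  d <- dim(x$W_tilde)
  tibble::tibble(
    joint = rep(x$joints, times = d[2L]),
    frame = rep(seq_len(d[2L]) - 1L, each = d[1L]),
    w_tilde = as.numeric(x$W_tilde),
    w = as.numeric(x$W)
  )
}

#' @export
glance.relevance_fit <- function(x, ...) {
  tibble::tibble(
    sigma2 = x$sigma2, cv_error = x$cv_error, folds = x$folds,
    seed = x$seed, n_joints = x$dims[1L], n_frames = x$dims[2L],
    n_trials = x$dims[3L], const = x$const
  )
}
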