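unfold_spatial <- function(X) matrix(X, nrow = dim(X)[1L])      # I x (J*K)

unfold_temporal <- function(X) {
  # J x (I*K): stack trials of the transposed trial matrices
  d3 <- dim(X)
  out <- matrix(0, d3[2L], d3[1L] * d3[3L])
  for (k in seq_len(d3[3L])) {
    out[, ((k - 1L) * d3[1L] + 1L):(k * d3[1L])] <- t(X[, , k])
  }
  out
}

std_columnwise <- function(M) {
  # standardize every column of the unfolded matrix across its rows
  m <- colMeans(M)
  s <- sqrt(colMeans(sweep(M, 2, m)^2))
  if (any(s <= 0)) {
    abort(sprintf("column %d of the unfolded matrix has zero variance; columnwise standardization undefined",
                  which(s <= 0)[1L]))
  }
  sweep(sweep(M, 2, m), 2, s, "/")
}

prepare_unfolded <- function(motion, mode, std) {
  X <- if (inherits(motion, "motion_data")) {
    if (std == "joint") standardize_per_joint(motion)$X else motion$angles
  } else {
    motion  # raw array, used as given under "joint"; standardized if columnwise
  }
  M <- if (mode == "spatial") unfold_spatial(X) else unfold_temporal(X)
  if (std == "columnwise") M <- std_columnwise(M)
  M
}

#' Motion-relevant spatial or temporal modules
#'
#' Conventional module extraction: the motion array is unfolded to
#' `I x (J*K)` (spatial) or `J x (I*K)` (temporal) and decomposed by SVD.
#' The left singular vectors are the trial-invariant modules, identical to
#' the principal axes of the unfolded data; the singular values `a_r` rank
#' their contribution to reconstructing the motion.
#'
#' Two standardizations are available: `"joint"` (default) standardizes
#' each joint over all frames and trials before unfolding; `"columnwise"`
#' standardizes each column of the unfolded matrix across its rows.
#'
#' @param motion A [motion_data] object or an I x J x K array (an array is
#'   taken as already standardized under `std = "joint"`).
#' @param std `"joint"` or `"columnwise"`.
#' @return An object of class `motion_modules`: list with `modules`
#'   (columns are modules, sign convention as in [task_modules()]), `a`
#'   (singular values), `mode`, `std`, and the standardized array `X` the
#'   modules were extracted from.
#' @export
spatial_modules <- function(motion, std = c("joint", "columnwise")) {
  std <- match.arg(std)
  motion_modules_impl(motion, "spatial", std)
}

#' @rdname spatial_modules
#' @export
temporal_modules <- function(motion, std = c("joint", "columnwise")) {
  std <- match.arg(std)
  motion_modules_impl(motion, "temporal", std)
}

motion_modules_impl <- function(motion, mode, std) {
  M <- prepare_unfolded(motion, mode, std)
  if (all(M == 0)) abort("motion is identically zero")
  sv <- svd_signed(M, rank = min(dim(M)))
  keep <- sv$d > max(dim(M)) * .Machine$double.eps * max(sv$d, 1)
  X <- if (inherits(motion, "motion_data")) {
    if (std == "joint") standardize_per_joint(motion)$X else motion$angles
  } else {
    motion
  }
  structure(
    list(modules = sv$u[, keep, drop = FALSE], a = sv$d[keep],
         mode = mode, std = std, X = X),
    class = "motion_modules"
  )
}

#' @export
print.motion_modules <- function(x, ...) {
  cat(sprintf("<motion_modules> %s, %d modules (std = %s)\n",
              x$mode, length(x$a), x$std))
  cat("a:", paste(signif(head(x$a, 6), 4), collapse = ", "),
      if (length(x$a) > 6) "...\n" else "\n")
  invisible(x)
}

#' @export
tidy.motion_modules <- function(x, ...) {
  n <- nrow(x$modules); R <- ncol(x$modules)
  tibble::tibble(
    module = rep(seq_len(R), each = n),
    component = x$mode,
    index = rep(if (x$mode == "temporal") seq_len(n) - 1L else seq_len(n),
                times = R),
    value = as.numeric(x$modules),
    a = rep(x$a, each = n)
  )
}

#' Per-trial temporal coefficients of spatial modules
#'
#' Given trial-invariant spatial modules `b_r` with singular values `a_r`,
#' the trial-varying temporal coefficient of module `r` on trial `k` is the
#' projection `c[r, k] = X_k' b_r / a_r`. The reconstruction
#' `sum_r a_r b_r c[r, k]'` equals the projection of each trial onto the
#' span of the retained spatial modules. The per-trial coefficients of
#' different modules are orthogonal in the exactly low-rank (noiseless)
#' case but only approximately so on noisy data.
#'
#' @param sm A `motion_modules` object from [spatial_modules()].
#' @param rank Number of modules retained (default all with `a_r > 0`).
#' @return Array of dimension `c(J, rank, K)`: coefficient curves per
#'   module per trial.
#' @export
per_trial_temporal_coefficients <- function(sm, rank = NULL) {
  stopifnot(inherits(sm, "motion_modules"), sm$mode == "spatial")
  rank <- rank %||% length(sm$a)
  if (rank > length(sm$a)) abort("`rank` exceeds the number of modules")
  if (any(sm$a[seq_len(rank)] <= 0)) {
    abort("a retained module has zero singular value")
  }
  d3 <- dim(sm$X)
  C <- array(0, c(d3[2L], rank, d3[3L]))
  for (k in seq_len(d3[3L])) {
    C[, , k] <- crossprod(sm$X[, , k], sm$modules[, seq_len(rank), drop = FALSE]) %*%
      diag(1 / sm$a[seq_len(rank)], rank)
  }
  C
}

#' Cumulative motion variance explained by motion-relevant modules
#'
#' `sum_{r <= rhat} a_r^2 / sum_r a_r^2` for each leading module count.
#'
#' @param a Singular values, or a `motion_modules` object.
#' @return A tibble with columns `modules` and `fraction` (non-decreasing,
#'   in `[0, 1]`, ending at 1).
#' @export
motion_variance_explained <- function(a) {
  if (inherits(a, "motion_modules")) a <- a$a
  if (all(a == 0)) abort("all singular values are zero")
  tibble::tibble(modules = seq_along(a), fraction = cumsum(a^2) / sum(a^2))
}
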