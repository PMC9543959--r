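svd_signed <- function(M, rank = NULL) {
  # thin SVD with a deterministic sign convention: the largest-|.| element
  # of each left vector is made positive, the right vector flipped jointly
  sv <- svd(M)
  r <- if (is.null(rank)) length(sv$d) else min(rank, length(sv$d))
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  d <- sv$d[seq_len(r)]
  for (i in seq_len(r)) {
    piv <- which.max(abs(U[, i]))
    if (U[piv, i] < 0) {
      U[, i] <- -U[, i]
      V[, i] <- -V[, i]
    }
  }
  list(d = d, u = U, v = V)
}

#' Task-relevant spatiotemporal modules
#'
#' Decomposes the relevance map by thin SVD,
#' `W = sum_r lambda_r s_r t_r'`, into task-relevant spatial modules `s_r`
#' (one weight per joint) and temporal modules `t_r` (one weight per frame),
#' ordered by non-increasing singular value `lambda_r`. The sign convention
#' makes the largest-magnitude element of each spatial module positive
#' (flipping the paired temporal module jointly), so modules are comparable
#' across subjects and experiments.
#'
#' @param W An I x J relevance map, or a `relevance_fit` whose `W` is used.
#' @param rank Number of modules retained (default `min(I, J)`).
#' @return An object of class `task_modules`: list with `lambda`, `S`
#'   (I x R), `T` (J x R), `rank`, `joints`, and `const` (carried from a
#'   `relevance_fit`, else 0).
#' @export
task_modules <- function(W, rank = NULL) {
  const <- 0
  joints <- NULL
  if (inherits(W, "relevance_fit")) {
    const <- W$const
    joints <- W$joints
    W <- W$W
  }
  W <- as.matrix(W)
  if (!all(is.finite(W))) abort("`W` must be finite")
  if (is.null(joints)) joints <- rownames(W) %||% paste0("joint", seq_len(nrow(W)))
  sv <- svd_signed(W, rank = rank %||% min(dim(W)))
  structure(
    list(lambda = sv$d, S = sv$u, T = sv$v, rank = length(sv$d),
         joints = joints, const = const),
    class = "task_modules"
  )
}

#' @export
print.task_modules <- function(x, ...) {
  cat(sprintf("<task_modules> %d modules (I = %d joints, J = %d frames)\n",
              x$rank, nrow(x$S), nrow(x$T)))
  cat("lambda:", paste(signif(x$lambda, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.task_modules <- function(x, ...) {
  sp <- tibble::tibble(
    module = rep(seq_len(x$rank), each = nrow(x$S)),
    component = "spatial",
    index = rep(seq_len(nrow(x$S)), times = x$rank),
    label = rep(x$joints, times = x$rank),
    value = as.numeric(x$S)
  )
  te <- tibble::tibble(
    module = rep(seq_len(x$rank), each = nrow(x$T)),
    component = "temporal",
    index = rep(seq_len(nrow(x$T)) - 1L, times = x$rank),
    label = NA_character_,
    value = as.numeric(x$T)
  )
  dplyr::bind_rows(sp, te)
}

#' @export
glance.task_modules <- function(x, ...) {
  tibble::tibble(rank = x$rank, lambda_1 = x$lambda[1L],
                 frobenius = sqrt(sum(x$lambda^2)))
}

#' Reconstruct the relevance map from its modules
#' @param modules A `task_modules` object.
#' @return The I x J matrix `sum_r lambda_r s_r t_r'`.
#' @export
reconstruct_relevance <- function(modules) {
  modules$S %*% (modules$lambda * t(modules$T))
}

#' Per-module predicted-performance fragments
#'
#' Splits each trial's predicted performance into the contribution of each
#' task-relevant module: `yhat[k, r] = lambda_r * s_r' X_k t_r`, evaluated
#' on per-joint standardized motion. The fragments sum back to the full
#' prediction: `sum_r yhat[k, r] + const = <W, X_k> + const`.
#'
#' @param modules A `task_modules` object.
#' @param X Per-joint standardized motion: a `joint_standardization`, a
#'   [motion_data] (standardized internally), or a raw I x J x K array
#'   assumed already standardized.
#' @param const Offset added to the summed fragments (defaults to the one
#'   stored in `modules`).
#' @return An object of class `module_fragments`: list with `yhat` (K x R
#'   matrix) and `const`.
#' @export
module_fragments <- function(modules, X, const = modules$const) {
  stopifnot(inherits(modules, "task_modules"))
  if (inherits(X, "joint_standardization")) X <- X$X
  if (inherits(X, "motion_data")) X <- standardize_per_joint(X)$X
  d3 <- dim(X)
  if (d3[1L] != nrow(modules$S) || d3[2L] != nrow(modules$T)) {
    abort("motion dimensions do not match the modules")
  }
  x <- vec_trials(X)                                   # K x IJ
  w_r <- vapply(seq_len(modules$rank), function(r) {
    as.numeric(modules$lambda[r] * tcrossprod(modules$S[, r], modules$T[, r]))
  }, numeric(d3[1L] * d3[2L]))                         # IJ x R
  yhat <- x %*% w_r
  colnames(yhat) <- paste0("module", seq_len(modules$rank))
  structure(list(yhat = yhat, const = const), class = "module_fragments")
}

#' @export
tidy.module_fragments <- function(x, ...) {
  K <- nrow(x$yhat); R <- ncol(x$yhat)
  tibble::tibble(
    trial = rep(seq_len(K), times = R),
    module = rep(seq_len(R), each = K),
    yhat = as.numeric(x$yhat)
  )
}

#' Cumulative variance of predicted performance explained by modules
#'
#' For each leading set of modules `1..r`, the variance across trials of the
#' partial sum of fragments divided by the variance of the full prediction.
#' The final value is 1 by construction.
#'
#' @param fragments A `module_fragments` object.
#' @return A tibble with columns `modules` and `fraction`.
#' @export
performance_variance_explained <- function(fragments) {
  yhat <- fragments$yhat
  if (nrow(yhat) < 2) abort("need at least 2 trials")
  total <- var(rowSums(yhat))
  if (total == 0) abort("predicted performance has zero variance")
  frac <- vapply(seq_len(ncol(yhat)), function(r) {
    var(rowSums(yhat[, seq_len(r), drop = FALSE])) / total
  }, numeric(1))
  tibble::tibble(modules = seq_len(ncol(yhat)), fraction = frac)
}

#' Motion variance captured by task-relevant modules
#'
#' Scores each task-relevant module as a direction in the vectorized motion
#' space: `lambdahat_r = w_r' (X'X) w_r` with `w_r = vec(lambda_r s_r t_r')`
#' and `X` the K x IJ trial-vectorized motion, then reports the cumulative
#' normalized contributions. The module vectors are not eigenvectors of
#' `X'X`, so unlike a PCA curve this one measures how much motion variance
#' the task-relevant directions happen to capture.
#'
#' @param modules A `task_modules` object.
#' @param motion A [motion_data], or a pre-standardized I x J x K array /
#'   K x IJ matrix.
#' @param standardization `"joint"` (default) or `"ridge"`: which
#'   standardized space the motion is vectorized in when `motion` is a
#'   [motion_data].
#' @return A tibble with columns `modules`, `lambdahat`, `fraction`
#'   (cumulative, ending at 1).
#' @export
motion_variance_explained_by_task_modules <- function(modules, motion,
                                                      standardization = c("joint", "ridge")) {
  standardization <- match.arg(standardization)
  if (inherits(motion, "motion_data")) {
    motion <- if (standardization == "joint") {
      standardize_per_joint(motion)$X
    } else {
      standardize_for_ridge(motion)$x
    }
  }
  x <- if (is.matrix(motion)) motion else vec_trials(motion)
  if (all(x == 0)) abort("motion is identically zero")
  lam <- vapply(seq_len(modules$rank), function(r) {
    w_r <- as.numeric(modules$lambda[r] *
                        tcrossprod(modules$S[, r], modules$T[, r]))
    sum((x %*% w_r)^2)
  }, numeric(1))
  if (sum(lam) == 0) abort("all module contributions are zero")
  tibble::tibble(
    modules = seq_len(modules$rank),
    lambdahat = lam,
    fraction = cumsum(lam) / sum(lam)
  )
}
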