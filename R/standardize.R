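#' Standardize motion and performance for the ridge regression
#'
#' Standardizes each (joint, frame) cell series across trials to zero mean
#' and unit variance, and likewise the per-trial performance. Population
#' moments (divide by K) are used throughout, matching the convention of the
#' relevance-map estimator; the stored means and standard deviations are
#' those of the fitting set, so held-out trials can be transformed with
#' training statistics via [apply_ridge_standardization()].
#'
#' @param motion A [motion_data] object.
#' @param trials Optional trial table (as from [trial_data()]) whose
#'   `performance` column is standardized alongside.
#' @return An object of class `ridge_standardization`: list with `x`
#'   (standardized I x J x K array), `m`, `s` (I x J matrices), `d`,
#'   `d_mean`, `d_sd`, and a dataset fingerprint.
#' @export
standardize_for_ridge <- function(motion, trials = NULL) {
  stopifnot(inherits(motion, "motion_data"))
  a <- motion$angles
  d3 <- dim(a)
  m <- apply(a, c(1, 2), mean)
  s <- sqrt(apply(a, c(1, 2), function(v) mean((v - mean(v))^2)))
  if (any(s <= 0 | !is.finite(s))) {
    bad <- which(s <= 0 | !is.finite(s), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "zero trial-to-trial variance at joint %d ('%s'), frame %d; cell cannot be standardized",
      bad[1L], motion$joints[bad[1L]], bad[2L]
    ))
  }
  x <- (a - array(m, d3)) / array(s, d3)
  d <- d_mean <- d_sd <- NULL
  if (!is.null(trials)) {
    perf <- trials$performance
    if (length(perf) != d3[3L]) abort("trial table length does not match K")
    d_mean <- mean(perf)
    d_sd <- sqrt(mean((perf - d_mean)^2))
    if (d_sd <= 0) abort("performance has zero variance across trials")
    d <- (perf - d_mean) / d_sd
  }
  structure(
    list(x = x, m = m, s = s, d = d, d_mean = d_mean, d_sd = d_sd,
         joints = motion$joints, fingerprint = dataset_fingerprint(motion)),
    class = "ridge_standardization"
  )
}

#' Standardize motion per joint
#'
#' Standardizes each joint's angle series to zero mean and unit variance
#' over all frames and trials jointly (population moments). This is the
#' standardization under which the relevance map is compared with
#' motion-relevant modules.
#'
#' @param motion A [motion_data] object.
#' @return An object of class `joint_standardization`: list with `X`
#'   (standardized array), `m_i`, `s_i` (length-I vectors), and a dataset
#'   fingerprint.
#' @export
standardize_per_joint <- function(motion) {
  stopifnot(inherits(motion, "motion_data"))
  a <- motion$angles
  d3 <- dim(a)
  flat <- matrix(a, nrow = d3[1L])   # I x (J*K)
  m_i <- rowMeans(flat)
  s_i <- sqrt(rowMeans((flat - m_i)^2))
  if (any(s_i <= 0 | !is.finite(s_i))) {
    bad <- which(s_i <= 0 | !is.finite(s_i))[1L]
    abort(sprintf("zero variance for joint %d ('%s') over frames and trials",
                  bad, motion$joints[bad]))
  }
  X <- (a - array(rep(m_i, d3[2L] * d3[3L]), d3)) /
    array(rep(s_i, d3[2L] * d3[3L]), d3)
  structure(
    list(X = X, m_i = m_i, s_i = s_i, joints = motion$joints,
         fingerprint = dataset_fingerprint(motion)),
    class = "joint_standardization"
  )
}

dataset_fingerprint <- function(motion) {
  c(dim(motion$angles), sum(motion$angles), sum(motion$angles^2))
}

#' Apply stored ridge standardization to new trials
#'
#' Transforms held-out motion (and optionally performance) with the means
#' and standard deviations stored from the fitting set, as needed for
#' cross-validation.
#'
#' @param std A `ridge_standardization` (training statistics).
#' @param motion New [motion_data] with the same joints and frames.
#' @param performance Optional numeric performance vector.
#' @return List with `x` (standardized array) and `d` (or `NULL`).
#' @export
apply_ridge_standardization <- function(std, motion, performance = NULL) {
  a <- motion$angles
  d3 <- dim(a)
  if (!all(d3[1:2] == dim(std$m))) abort("new data has mismatched (I, J)")
  x <- (a - array(std$m, d3)) / array(std$s, d3)
  d <- NULL
  if (!is.null(performance)) d <- (performance - std$d_mean) / std$d_sd
  list(x = x, d = d)
}

#' Map regression-space coefficients to the module-comparison space
#'
#' The relevance map is estimated on per-cell standardized motion
#' (coefficients `W_tilde`) but compared with motion-relevant modules on
#' per-joint standardized motion. This maps between the two spaces:
#' `W[i,j] = (s_i / s[i,j]) * W_tilde[i,j]` with offset
#' `const = sum_ij W_tilde[i,j] * (m_i - m[i,j]) / s[i,j]`, so that for every
#' trial `sum_ij x*W_tilde == sum_ij X*W + const`.
#'
#' @param W_tilde I x J regression-space relevance map.
#' @param ridge_std A `ridge_standardization` of the fitting dataset.
#' @param joint_std A `joint_standardization` of the same dataset.
#' @return List with `W` (I x J map) and `const` (scalar).
#' @export
map_coefficients <- function(W_tilde, ridge_std, joint_std) {
  stopifnot(inherits(ridge_std, "ridge_standardization"),
            inherits(joint_std, "joint_standardization"))
  if (!isTRUE(all.equal(ridge_std$fingerprint, joint_std$fingerprint))) {
    abort("standardizations come from different datasets (fingerprint mismatch)")
  }
  W_tilde <- as.matrix(W_tilde)
  if (!all(dim(W_tilde) == dim(ridge_std$m))) {
    abort("W_tilde shape does not match the standardization (I, J)")
  }
  s_i <- joint_std$s_i
  m_i <- joint_std$m_i
  W <- (s_i / ridge_std$s) * W_tilde
  const <- sum(W_tilde * (m_i - ridge_std$m) / ridge_std$s)
  list(W = W, const = const)
}
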