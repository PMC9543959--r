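#' SVD basis of the trial-vectorized motion
#'
#' Thin SVD of the K x IJ matrix whose rows are vectorized trials:
#' `x = U H V'`. The rows of `V'` are the motion-relevant spatiotemporal
#' modules `v_r` (spatial and temporal information mixed), `omega_r` their
#' contribution to reconstructing the motion, and `U` the per-trial
#' loadings. The sign convention matches [task_modules()], applied to the
#' spatiotemporal modules.
#'
#' @param x K x IJ matrix of standardized vectorized trials, a
#'   `ridge_standardization`, or a [motion_data] (per-cell standardized
#'   internally).
#' @return An object of class `spectral_basis`: list with `omega`
#'   (non-increasing), `U` (K x R), `V` (IJ x R), `rank`.
#' @export
vectorized_svd <- function(x) {
  if (inherits(x, "motion_data")) x <- standardize_for_ridge(x)
  if (inherits(x, "ridge_standardization")) x <- vec_trials(x$x)
  x <- as.matrix(x)
  if (!all(is.finite(x))) abort("`x` must be finite")
  if (all(x == 0)) {
    return(structure(list(omega = numeric(0),
                          U = matrix(0, nrow(x), 0),
                          V = matrix(0, ncol(x), 0), rank = 0L),
                     class = "spectral_basis"))
  }
  sv <- svd_signed(t(x))   # so the sign pivot is on the module side
  keep <- sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1L]
  structure(
    list(omega = sv$d[keep], U = sv$v[, keep, drop = FALSE],
         V = sv$u[, keep, drop = FALSE], rank = sum(keep)),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> rank %d (K = %d trials, IJ = %d features)\n",
              x$rank, nrow(x$U), nrow(x$V)))
  invisible(x)
}

#' Relevance map via the spectral identity
#'
#' Builds the ridge solution from the SVD of the motion rather than by
#' solving the normal equations:
#' `w = sum_r v_r (v_r' x' d) / (omega_r^2 + sigma2)`. With `sigma2 > 0`
#' the ridge solution lies in the row space of the motion, so the thin SVD
#' restricted to that space is exact; the result equals [fit_ridge()] on
#' the same inputs.
#'
#' @param basis A `spectral_basis`.
#' @param d Standardized performance, length K.
#' @param sigma2 Regularization parameter (`> 0`, or 0 with full row rank).
#' @return Length-IJ relevance vector.
#' @export
relevance_via_spectrum <- function(basis, d, sigma2) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (length(d) != nrow(basis$U)) abort("`d` must have one value per trial")
  if (sigma2 < 0) abort("`sigma2` must be >= 0")
  if (sigma2 == 0 && basis$rank < nrow(basis$V)) {
    abort("sigma2 = 0 with rank-deficient motion; use sigma2 > 0")
  }
  beta_r <- basis$omega * as.numeric(crossprod(basis$U, d))  # v_r' x' d
  as.numeric(basis$V %*% (beta_r / (basis$omega^2 + sigma2)))
}

#' Spectral weights linking motion-relevant modules to the relevance map
#'
#' Expresses the relevance map as spatiotemporal modules weighted by two
#' factors: `f_r = 1 / (omega_r^2 + sigma2)`, a strictly decreasing
#' function of the module's contribution to reconstructing the motion, and
#' `g_r = v_r' beta` with `beta = x'd`, the motion-performance correlation
#' profile projected onto the module. Then
#' `w = sum_r f_r g_r v_r`, identical to [relevance_via_spectrum()].
#'
#' Under the (1/K)-moment standardization, `beta = x'd` equals K times the
#' per-feature Pearson correlation with performance; both scalings are
#' returned (`beta`, `beta_over_K`), and the identity holds with the
#' un-divided `beta`.
#'
#' @inheritParams relevance_via_spectrum
#' @return An object of class `spectral_weights`: list with `weights` (a
#'   tibble of `r`, `omega`, `f`, `g`), `beta`, `beta_over_K`, `w` (the
#'   reconstructed relevance vector), `sigma2`.
#' @export
spectral_weights <- function(basis, d, sigma2) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (length(d) != nrow(basis$U)) abort("`d` must have one value per trial")
  g <- basis$omega * as.numeric(crossprod(basis$U, d))
  f <- 1 / (basis$omega^2 + sigma2)
  beta <- as.numeric(basis$V %*% g)   # x'd reconstructed in the row space
  w <- as.numeric(basis$V %*% (f * g))
  structure(
    list(
      weights = tibble::tibble(r = seq_len(basis$rank), omega = basis$omega,
                               f = f, g = g),
      beta = beta, beta_over_K = beta / nrow(basis$U), w = w, sigma2 = sigma2
    ),
    class = "spectral_weights"
  )
}

#' @export
tidy.spectral_weights <- function(x, ...) x$weights
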