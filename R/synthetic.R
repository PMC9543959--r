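#' Configuration for the synthetic kinematics generator
#'
#' Collects the dimensions, planted structure, noise scales and
#' perturbation schedule for the synthetic generators. The defaults mirror
#' the jump paradigm the framework targets: 4 joints, 60 frames at 120 Hz
#' (a 500 ms pre-release window), about 150 analysed trials, 13 subjects in
#' a group, a gradual gain perturbation of 0.005 per trial over 10 trials
#' after a 10-trial baseline, then held at 0.05.
#'
#' @param I,J,K Joints, frames per trial, trials.
#' @param sample_rate Hz.
#' @param rank_motion Number of planted motion modules; 0 gives pure
#'   i.i.d. standard-normal motion (no smooth structure).
#' @param n_basis Number of low-order cosine basis functions generating the
#'   smooth temporal coefficients.
#' @param singular_decay Geometric decay of the planted module strengths
#'   `a_r = singular_decay^(r-1)`.
#' @param noise_sd_motion Additive motion noise sd, relative to the unit
#'   element-wise sd of the planted signal (0.1 = SNR 10).
#' @param noise_sd_perf Performance noise sd, relative to the sd of the
#'   noiseless planted performance (0.1 = SNR 10).
#' @param planted_lambda Singular values of the planted relevance map
#'   (recycled/truncated to `rank_motion`).
#' @param planted_W Optional explicit I x J planted relevance map; default
#'   is built from the planted module directions (see
#'   [planted_relevance()]).
#' @param baseline_trials,ramp_trials,ramp_step,hold_value Perturbation
#'   schedule: zeros, then a linear ramp of `ramp_step` per trial, then a
#'   constant hold (default `ramp_trials * ramp_step`).
#' @param adaptation_gain Coupling of the low-pass-filtered perturbation to
#'   the recruitment of planted module 1 in [simulate_adaptation()].
#' @param learning_rate,retention Single-state error-driven learner:
#'   `state <- retention * state + learning_rate * perturbation`.
#' @param amplitude_jitter Trial-to-trial sd of module recruitment
#'   amplitudes in [simulate_adaptation()].
#' @param seed Integer seed (< 2^31 - 10); all generators are
#'   bit-reproducible given the config.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(I = 4, J = 60, K = 150, sample_rate = 120,
                             rank_motion = 2, n_basis = 6,
                             singular_decay = 0.7,
                             noise_sd_motion = 0.1, noise_sd_perf = 0.1,
                             planted_lambda = c(1, 0.5),
                             planted_W = NULL,
                             baseline_trials = 10, ramp_trials = 10,
                             ramp_step = 0.005, hold_value = NULL,
                             adaptation_gain = 2,
                             learning_rate = 0.3, retention = 0.9,
                             amplitude_jitter = 0.1,
                             seed = 1) {
  if (I < 1 || J < 2 || K < 2) abort("dimensions must satisfy I >= 1, J >= 2, K >= 2")
  if (rank_motion > min(I, J)) abort("`rank_motion` exceeds min(I, J)")
  if (noise_sd_motion < 0 || noise_sd_perf < 0) abort("noise scales must be >= 0")
  if (seed >= 2^31 - 10 || seed != round(seed)) abort("`seed` must be an integer below 2^31")
  if (!is.null(planted_W) && !all(dim(as.matrix(planted_W)) == c(I, J))) {
    abort("`planted_W` must be I x J")
  }
  structure(
    list(I = I, J = J, K = K, sample_rate = sample_rate,
         rank_motion = rank_motion, n_basis = min(n_basis, J),
         singular_decay = singular_decay,
         noise_sd_motion = noise_sd_motion, noise_sd_perf = noise_sd_perf,
         planted_lambda = planted_lambda, planted_W = planted_W,
         baseline_trials = baseline_trials, ramp_trials = ramp_trials,
         ramp_step = ramp_step,
         hold_value = hold_value %||% (ramp_trials * ramp_step),
         adaptation_gain = adaptation_gain,
         learning_rate = learning_rate, retention = retention,
         amplitude_jitter = amplitude_jitter,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# band-limited smooth basis: cosine/sine pairs of the lowest frequencies.
# Paired harmonics give every frame the same variance under isotropic
# coefficients (cos^2 + sin^2 is constant), so trial-to-trial variability
# is stationary across the window, as in steady pre-release kinematics.
cosine_basis <- function(J, n_basis) {
  j <- seq_len(J) - 0.5
  Phi <- vapply(seq_len(n_basis), function(q) {
    m <- ceiling(q / 2)
    if (q %% 2 == 1) cos(2 * pi * m * j / J) else sin(2 * pi * m * j / J)
  }, numeric(J))
  qr.Q(qr(Phi))
}

# rotate the joint coordinates (Givens sweeps, Schur-Horn construction) so
# that diag(B diag(a^2) B') is constant: every joint then carries the same
# planted-signal variance, and per-joint standardization rescales all joints
# equally instead of tilting the planted spatial subspace
equalize_diag <- function(B, a) {
  M <- B %*% (a^2 * t(B))
  n <- nrow(M)
  target <- sum(a^2) / n
  Q <- diag(n)
  for (iter in seq_len(4L * n)) {
    dg <- diag(M)
    if (max(abs(dg - target)) < 1e-12) break
    i <- which.max(dg); j <- which.min(dg)
    m <- M[i, j]
    disc <- m^2 - (dg[j] - target) * (dg[i] - target)
    t1 <- (-m + sqrt(disc)) / (dg[j] - target)
    t2 <- (-m - sqrt(disc)) / (dg[j] - target)
    tt <- if (abs(t1) < abs(t2)) t1 else t2
    cth <- 1 / sqrt(1 + tt^2); sth <- tt * cth
    G <- diag(n); G[i, i] <- cth; G[j, j] <- cth; G[i, j] <- sth; G[j, i] <- -sth
    M <- G %*% M %*% t(G)
    Q <- G %*% Q
  }
  Q %*% B
}

# planted module directions: drawn at the head of the seed's RNG stream so
# every generator that needs them reproduces the same structure
synth_structure <- function(config) {
  set.seed(config$seed)
  R <- max(config$rank_motion, 1L)
  a <- config$singular_decay^(seq_len(R) - 1)
  B <- qr.Q(qr(matrix(rnorm(config$I * R), config$I, R)))
  B <- equalize_diag(B, a)
  Phi <- cosine_basis(config$J, config$n_basis)
  T0 <- qr.Q(qr(Phi %*% matrix(rnorm(config$n_basis * R), config$n_basis, R)))
  list(B = B, T0 = T0, Phi = Phi, a = a)
}

#' Planted relevance map of a synthetic configuration
#'
#' The ground-truth map used by [generate_performance()]:
#' `W = sum_r planted_lambda_r b_r t0_r'` built from the planted spatial
#' directions and smooth temporal directions (or `config$planted_W` when
#' given). Recovery tests compare fitted maps and modules against it.
#'
#' @param config A [synthetic_config()].
#' @return An I x J matrix.
#' @export
planted_relevance <- function(config) {
  if (!is.null(config$planted_W)) return(as.matrix(config$planted_W))
  if (config$rank_motion < 1) abort("no planted structure with rank_motion = 0; supply `planted_W`")
  st <- synth_structure(config)
  lam <- rep_len(config$planted_lambda, config$rank_motion)
  st$B %*% (lam * t(st$T0))
}

# K x (n_basis * R) matrix of temporal-coefficient loadings. When K allows,
# the loadings are made empirically white (exactly zero-mean and
# uncorrelated across trials), which is what the scores of an SVD of real
# trial data look like; for very small K plain Gaussian draws are used.
coeff_loadings <- function(K, M, R) {
  G <- matrix(rnorm(K * M * R), K, M * R)
  if (K > M * R + 1L) {
    G <- sweep(G, 2, colMeans(G))
    qr.Q(qr(G)) * sqrt(K)
  } else {
    G
  }
}

#' Generate a synthetic motion dataset
#'
#' Planted low-rank smooth structure: each trial is
#' `X_k = sum_r a_r b_r c[r,k]'` with orthonormal spatial directions `b_r`,
#' smooth per-trial temporal coefficient curves `c[r,k]` (random mixtures
#' of low-order cosine/sine harmonics) and geometric strengths `a_r`. The
#' spatial frame is rotated so every joint carries the same signal
#' variance, and the coefficient loadings are empirically white across
#' trials, so the per-joint and per-cell standardizations of the analysis
#' rescale the data without tilting the planted structure. The signal is
#' scaled to unit element-wise sd and i.i.d. Gaussian noise of sd
#' `noise_sd_motion` is added. With `rank_motion = 0` the dataset is pure
#' i.i.d. standard-normal noise.
#'
#' @param config A [synthetic_config()].
#' @return A [motion_data] object.
#' @export
generate_motion <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  I <- config$I; J <- config$J; K <- config$K
  if (config$rank_motion == 0) {
    set.seed(config$seed)
    return(motion_data(array(rnorm(I * J * K), c(I, J, K)),
                       sample_rate = config$sample_rate))
  }
  st <- synth_structure(config)  # sets the seed, stream continues below
  R <- config$rank_motion
  M <- config$n_basis
  Z <- coeff_loadings(K, M, R)
  signal <- array(0, c(I, J, K))
  for (r in seq_len(R)) {
    Cr <- st$Phi %*% t(Z[, ((r - 1L) * M + 1L):(r * M), drop = FALSE])  # J x K
    signal <- signal + outer(st$B[, r] * st$a[r], Cr)
  }
  dim(signal) <- c(I, J, K)
  signal <- signal / sd(as.numeric(signal))
  noise <- array(rnorm(I * J * K, sd = config$noise_sd_motion), c(I, J, K))
  motion_data(signal + noise, sample_rate = config$sample_rate)
}

#' Generate per-trial performance from a planted relevance map
#'
#' `d_k = <W_planted, X_k>` on per-joint standardized motion, plus Gaussian
#' noise of sd `noise_sd_perf` relative to the sd of the noiseless values.
#' The noiseless values are kept in the `performance_true` column for
#' recovery tests.
#'
#' @param motion A [motion_data], typically from [generate_motion()].
#' @param config A [synthetic_config()]; the planted map is
#'   [planted_relevance()] of this config.
#' @param perturbation Optional per-trial perturbation stored alongside.
#' @return A trial tibble as from [trial_data()], with the extra column
#'   `performance_true`.
#' @export
generate_performance <- function(motion, config, perturbation = 0) {
  stopifnot(inherits(motion, "motion_data"), inherits(config, "synthetic_config"))
  W <- planted_relevance(config)
  if (!all(dim(W) == dim(motion$angles)[1:2])) abort("planted map is not I x J")
  X <- standardize_per_joint(motion)$X
  signal <- as.numeric(vec_trials(X) %*% as.numeric(W))
  set.seed(config$seed + 1L)
  scale <- sd(signal)
  if (scale == 0) scale <- 1   # zero planted map: performance is pure noise
  noise_sd <- config$noise_sd_perf * scale
  d_raw <- signal + rnorm(length(signal), sd = noise_sd)
  out <- trial_data(d_raw, target = 50, perturbation = perturbation,
                    subject_id = motion$subject_id)
  out$performance_true <- signal
  out
}

#' Gain-perturbation schedule
#'
#' Zeros for `baseline_trials`, then a linear ramp of `ramp_step` per trial
#' for `ramp_trials`, then constant at `hold_value` for the remaining
#' trials. With the default baseline 10 / ramp 10 / step 0.005, the value
#' on trial 20 is exactly 0.05 and stays there.
#'
#' @param config A [synthetic_config()].
#' @param K Number of trials (default `config$K`).
#' @return Numeric vector of length `K`.
#' @export
perturbation_schedule <- function(config, K = config$K) {
  b <- config$baseline_trials; r <- config$ramp_trials
  if (b + r > K) abort("baseline + ramp exceeds the number of trials")
  k <- seq_len(K)
  ifelse(k <= b, 0,
         ifelse(k <= b + r, (k - b) * config$ramp_step, config$hold_value))
}

#' Simulate a gain-adaptation experiment
#'
#' Generates a dataset in which the recruitment of planted module 1 tracks
#' a single-state error-driven learner responding to the perturbation:
#' `state <- retention * state + learning_rate * p_k`, and the module-1
#' amplitude on trial k is shifted by `-adaptation_gain * state`. Module 2
#' (and higher) amplitudes vary only by independent jitter. Performance is
#' generated from the planted relevance map, so the module-1 fragment
#' correlates negatively with the perturbation while other modules do not.
#'
#' @param config A [synthetic_config()] with `rank_motion >= 1`.
#' @return List with `motion` (a [motion_data]), `trials` (a trial tibble
#'   with the perturbation column filled), and `amplitudes` (K x R matrix
#'   of planted recruitment amplitudes).
#' @export
simulate_adaptation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$rank_motion < 1) abort("adaptation simulation needs rank_motion >= 1")
  I <- config$I; J <- config$J; K <- config$K; R <- config$rank_motion
  p <- perturbation_schedule(config)
  state <- numeric(K)
  s <- 0
  for (k in seq_len(K)) {
    state[k] <- s
    s <- config$retention * s + config$learning_rate * p[k]
  }
  st <- synth_structure(config)  # seeds the stream
  a <- st$a
  amp <- matrix(1 + rnorm(K * R, sd = config$amplitude_jitter), K, R)
  amp[, 1] <- amp[, 1] - config$adaptation_gain * state
  signal <- array(0, c(I, J, K))
  for (k in seq_len(K)) {
    # smooth jitter around the planted temporal directions, unit-norm curves
    Craw <- st$T0 + 0.2 * (st$Phi %*% matrix(rnorm(config$n_basis * R),
                                             config$n_basis, R))
    C <- sweep(Craw, 2, sqrt(colSums(Craw^2)), "/")
    signal[, , k] <- st$B %*% ((a * amp[k, ]) * t(C))
  }
  ssd <- sd(as.numeric(signal))
  signal <- signal / ssd
  noise <- array(rnorm(I * J * K, sd = config$noise_sd_motion), c(I, J, K))
  motion <- motion_data(signal + noise, sample_rate = config$sample_rate)
  trials <- generate_performance(motion, config, perturbation = p)
  list(motion = motion, trials = trials, amplitudes = amp)
}

#' Ballistic jump height from release state
#'
#' `h = p + v^2 / (2 g)` with `g = 9.8 m/s^2`: the parabolic flight height
#' reached from release position `p` (m) and vertical release velocity `v`
#' (m/s).
#'
#' @param p Release height in metres.
#' @param v Vertical release velocity in m/s.
#' @return Jump height in metres.
#' @examples
#' parabola_height(0.1, 1.4)  # 0.2
#' @export
parabola_height <- function(p, v) p + v^2 / (2 * 9.8)

#' Detect the release frame from a toe-height series
#'
#' The release is the first frame at which the toe height exceeds 10% of
#' its within-trial maximum. The returned index is 0-based, so it can be
#' passed directly to [extract_prerelease_window()].
#'
#' @param toe_height Non-negative per-frame series with a positive maximum.
#' @return Integer 0-based frame index of the release.
#' @export
detect_release <- function(toe_height) {
  if (any(toe_height < 0)) abort("toe height must be non-negative")
  mx <- max(toe_height)
  if (mx <= 0) abort("toe height is identically zero; no release detectable")
  idx <- which(toe_height > 0.10 * mx)[1L]
  as.integer(idx - 1L)
}
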