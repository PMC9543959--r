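# shared helpers: small datasets built in code, subspace angles

tiny_motion <- function(I = 2, J = 3, K = 2, seed = 1) {
  set.seed(seed)
  motion_data(array(rnorm(I * J * K), c(I, J, K)))
}

random_motion <- function(I = 4, J = 60, K = 100, seed = 1) {
  set.seed(seed)
  motion_data(array(rnorm(I * J * K, sd = 2) + 10, c(I, J, K)))
}

random_trials <- function(K, seed = 1) {
  set.seed(seed + 500)
  trial_data(rnorm(K))
}

# largest principal angle (degrees) between the column spans of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  max(acos(pmin(1, svd(crossprod(qa, qb))$d)) * 180 / pi)
}

vecK <- function(motion_or_array) {
  a <- if (inherits(motion_or_array, "motion_data")) motion_or_array$angles else motion_or_array
  d <- dim(a)
  t(matrix(a, nrow = d[1] * d[2]))
}
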