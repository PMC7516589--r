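# Independent oracles used across test files.

# Monte Carlo rejection estimate of the volume of {A x <= b} inside the
# unit box [0,1]^3, with binomial standard error.
mc_volume_oracle <- function(poly, n = 2e5, seed = 1) {
  A <- do.call(rbind, lapply(poly$halfspaces, `[[`, "normal"))
  b <- vapply(poly$halfspaces, `[[`, 0, "offset")
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n), ncol = 3)
  inside <- rowSums(pts %*% t(A) <= rep(b, each = n) + 1e-12) == length(b)
  frac <- mean(inside)
  list(volume = frac, se = sqrt(frac * (1 - frac) / n))
}

# Random genuine joint distribution over three binary events.
random_joint <- function() {
  x <- stats::rexp(8)
  x / sum(x)
}

# Hand-built operator oracle for the causal-strength matrix route:
# explicit 2x2 matrices written out entry by entry (independent of the
# package's pauli/projector constructors).
oracle_matrix_strength <- function(k, p) {
  psi <- c(sqrt(p), sqrt(1 - p))
  PY_plus <- matrix(c(1 / 2, k - 1 / 2, k - 1 / 2, 1 / 2), 2, 2)
  PX_plus <- diag(c(k, 1 - k))
  PX_minus <- diag(c(1 - k, k))
  e <- function(M) as.numeric(psi %*% M %*% psi)
  e(PY_plus %*% PX_plus) - e(PY_plus %*% PX_minus)
}
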