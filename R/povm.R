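# Quantum formalism: Pauli algebra, Bloch-direction projectors, unsharp and
# bistable POV projections, state preparation, expectation values.
# All matrices are 2x2 complex (sigma_y needs i); default states are real.

.MATRIX_TOL <- 1e-10
.I2 <- diag(2) + 0i

#' Pauli matrices
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return The standard 2x2 complex Pauli matrix: traceless, Hermitian,
#'   unitary, squaring to the identity.
#' @export
pauli <- function(axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  switch(axis,
    x = matrix(c(0, 1, 1, 0) + 0i, 2, 2),
    y = matrix(c(0, 1i, -1i, 0), 2, 2),
    z = matrix(c(1, 0, 0, -1) + 0i, 2, 2))
}

#' Measurement direction on the Bloch sphere
#'
#' Two-level measurement directions are parameterised by the polar angle
#' `theta` in `[0, pi]` and azimuth `phi` in `[0, 2*pi)`, giving the unit
#' vector `n_hat = (sin(theta)cos(phi), sin(theta)sin(phi), cos(theta))`.
#' The convenience strings `"x"`, `"y"`, `"z"` name the coordinate axes.
#'
#' @param theta polar angle in radians, or one of `"x"`, `"y"`, `"z"`.
#' @param phi azimuth angle in radians.
#' @return An object of class `"bloch_direction"`: list with `theta`,
#'   `phi`, and the unit 3-vector `n_hat`.
#' @export
bloch_direction <- function(theta, phi = 0) {
  if (is.character(theta)) {
    theta <- match.arg(theta, c("x", "y", "z"))
    ang <- switch(theta, x = c(pi / 2, 0), y = c(pi / 2, pi / 2), z = c(0, 0))
    theta <- ang[1]; phi <- ang[2]
  }
  if (!is.numeric(theta) || !is.numeric(phi) || length(theta) != 1L ||
      length(phi) != 1L || is.na(theta) || is.na(phi)) {
    stop("`theta` and `phi` must be single finite angles in radians", call. = FALSE)
  }
  n_hat <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  n_hat <- n_hat / sqrt(sum(n_hat^2))
  structure(list(theta = theta, phi = phi, n_hat = n_hat),
            class = "bloch_direction")
}

as_bloch_direction <- function(direction) {
  if (inherits(direction, "bloch_direction")) return(direction)
  if (is.character(direction) && length(direction) == 1L) {
    return(bloch_direction(direction))
  }
  if (is.numeric(direction) && length(direction) %in% c(1L, 2L)) {
    return(bloch_direction(direction[1], if (length(direction) == 2L) direction[2] else 0))
  }
  stop("`direction` must be a bloch_direction, an axis name, or (theta, phi)",
       call. = FALSE)
}

#' @export
print.bloch_direction <- function(x, ...) {
  cat(sprintf("Bloch direction: theta = %.6g, phi = %.6g\n  n_hat = (%.6g, %.6g, %.6g)\n",
              x$theta, x$phi, x$n_hat[1], x$n_hat[2], x$n_hat[3]))
  invisible(x)
}

# sigma . n_hat for a direction
sigma_dot_n <- function(direction) {
  d <- as_bloch_direction(direction)
  d$n_hat[1] * pauli("x") + d$n_hat[2] * pauli("y") + d$n_hat[3] * pauli("z")
}

sign_pm <- function(sign) {
  if (is.numeric(sign) && length(sign) == 1L && sign %in% c(1, -1)) return(sign)
  if (is.character(sign) && length(sign) == 1L && sign %in% c("+", "-")) {
    return(if (sign == "+") 1 else -1)
  }
  stop('`sign` must be "+", "-", +1 or -1', call. = FALSE)
}

#' Sharp (projective) measurement operator along a Bloch direction
#'
#' The rank-one projector `pi_(+/-)n = (I +/- sigma.n_hat) / 2`.  The pair
#' `{pi_+, pi_-}` is orthogonal, idempotent, and complete.
#'
#' @param direction a [bloch_direction()], axis name, or `(theta, phi)` pair.
#' @param sign `"+"` or `"-"` (equivalently `+1` / `-1`).
#' @return 2x2 complex Hermitian projector matrix.
#' @export
sharp_projector <- function(direction, sign = "+") {
  s <- sign_pm(sign)
  (.I2 + s * sigma_dot_n(direction)) / 2
}

#' Unsharp (noisy) measurement operator
#'
#' The unsharp two-outcome POVM element
#' `E_(+/-)n = I/2 +/- (eta/2) sigma.n_hat` with noise parameter `eta` in
#' the extended interval `[-1, 1]`.  `eta = 1` recovers the sharp
#' projector, `eta = 0` the fully depolarised `I/2`, and `eta = 2k - 1`
#' reproduces the bistable projection with parameter `k`.
#'
#' @inheritParams sharp_projector
#' @param eta noise parameter in `[-1, 1]`.
#' @return 2x2 complex Hermitian POVM element.
#' @seealso [bistable_projection()], [eta_from_k()]
#' @export
unsharp_projection <- function(direction, eta, sign = "+") {
  eta <- check_eta(eta)
  s <- sign_pm(sign)
  .I2 / 2 + s * (eta / 2) * sigma_dot_n(direction)
}

#' Bistable POV projection
#'
#' The bistable measurement operators
#' \deqn{P_{\pm\hat n} = (1 - k) I + (2k - 1)\,\pi_{\pm\hat n}}
#' form a POVM: both elements are positive semidefinite with eigenvalues
#' `{k, 1 - k}` (independent of direction) and sum to the identity.  At
#' `k = 1` they reduce to the sharp projectors; at `k = 0.5` to `I/2`, so
#' every outcome probability is exactly one half for every state.  In the
#' `z` direction the pair is `diag(k, 1-k)` / `diag(1-k, k)`.
#'
#' @inheritParams sharp_projector
#' @inheritParams pk_plus
#' @return Object of class `"bistable_projection"`: the 2x2 complex
#'   Hermitian matrix with attributes `k`, `direction`, `sign`.
#' @export
bistable_projection <- function(k, direction = "z", sign = "+") {
  k <- check_k(k)
  stopifnot(length(k) == 1L)
  d <- as_bloch_direction(direction)
  s <- sign_pm(sign)
  m <- (1 - k) * .I2 + (2 * k - 1) * sharp_projector(d, s)
  structure(m, k = k, direction = d, sign = if (s > 0) "+" else "-",
            class = c("bistable_projection", class(m)))
}

#' Decision state encoding a rational probability
#'
#' Prepares the two-component unit state vector whose squared component
#' magnitudes are `(p, 1 - p)`, i.e. `psi = (sqrt(p), sqrt(1 - p))`, with
#' real nonnegative amplitudes (a real Hilbert space carries the original
#' probability of the system).  The expectation of the `+` bistable
#' projection in the `z` direction on this state equals [pk_plus()]`(k, p)`.
#'
#' Note on conventions: the components themselves are the square roots of
#' the encoded probabilities.  Writing the state's entries as the
#' probabilities `(p, 1 - p)` directly would give the bilinear form
#' `k p^2 + (1-k)(1-p)^2`, which does not reproduce the bistable map; the
#' amplitude (square-root) convention does, exactly.
#'
#' @inheritParams pk_plus
#' @return Object of class `"decision_state"`: numeric length-2 unit
#'   vector with attribute `p`.
#' @export
state_from_p <- function(p) {
  p <- check_p(p)
  stopifnot(length(p) == 1L)
  structure(c(sqrt(p), sqrt(1 - p)), p = p, class = "decision_state")
}

#' Expectation value of an operator in a decision state
#'
#' The real bilinear form `<psi| M |psi>`.  For a single bistable POVM
#' element the value lies in `[min(k, 1-k), max(k, 1-k)]`; for products of
#' two Hermitian operators (sequential-measurement correlators) the real
#' part is returned.
#'
#' @param state a [state_from_p()] state or numeric length-2 unit vector.
#' @param operator 2x2 matrix (complex allowed).
#' @return Real scalar expectation value.
#' @export
expectation <- function(state, operator) {
  psi <- as.complex(unclass(state))
  if (length(psi) != 2L || anyNA(psi)) {
    stop("`state` must be a two-component vector", call. = FALSE)
  }
  nrm <- sqrt(sum(Mod(psi)^2))
  if (abs(nrm - 1) > 1e-9) {
    stop("`state` must be unit norm", call. = FALSE)
  }
  m <- unclass(operator)
  if (!is.matrix(m) || !all(dim(m) == c(2L, 2L)) || any(!is.finite(Mod(m)))) {
    stop("`operator` must be a finite 2x2 matrix", call. = FALSE)
  }
  Re(Conj(psi) %*% m %*% psi)[1]
}

#' Diagnostic validation of a POVM element set
#'
#' Checks the defining properties of a positive-operator-valued measure:
#' completeness (the elements sum to the identity), positivity (minimum
#' eigenvalue over all elements), and Hermiticity.  Also reports, per
#' element, whether it is idempotent -- bistable projections with
#' `k` strictly inside `(0, 1)` are not (`E E != E`), which is what
#' distinguishes an unsharp measurement from a projective one.
#'
#' @param elements list of 2x2 matrices.
#' @param tol numerical tolerance for the flags (max-abs entry scale).
#' @return List with `completeness_deviation` (max-abs entry deviation of
#'   the element sum from the identity), `min_eigenvalue`, `hermitian`,
#'   `idempotent` (logical per element), and `is_povm`.
#' @export
povm_validate <- function(elements, tol = .MATRIX_TOL) {
  if (!is.list(elements) || length(elements) == 0L) {
    stop("`elements` must be a nonempty list of 2x2 matrices", call. = FALSE)
  }
  mats <- lapply(elements, function(m) {
    m <- unclass(m)
    stopifnot(is.matrix(m), all(dim(m) == c(2L, 2L)))
    m + 0i
  })
  total <- Reduce(`+`, mats)
  completeness <- max(Mod(total - .I2))
  hermitian <- all(vapply(mats, function(m) max(Mod(m - Conj(t(m)))) < tol, TRUE))
  min_eig <- min(vapply(mats, function(m) {
    min(Re(eigen((m + Conj(t(m))) / 2, only.values = TRUE)$values))
  }, 0))
  idem <- vapply(mats, function(m) max(Mod(m %*% m - m)) < tol, TRUE)
  list(
    completeness_deviation = completeness,
    min_eigenvalue = min_eig,
    hermitian = hermitian,
    idempotent = idem,
    is_povm = completeness < tol && hermitian && min_eig > -tol
  )
}
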