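# Causal inference under bistability: Reichenbach-style factorization,
# delta-P causal strength and causal power, classical and operator routes.

#' Perceived deviation from probabilistic independence under bistability
#'
#' By Reichenbach's common cause principle, causal independence implies
#' factorization `P(Y, Z) = P(Y) P(Z)`.  A bistable observer perceives
#' every probability through the map `f_k(x) = 1 - x - k + 2kx`, so the
#' factorization they can check is
#' `f_k(pYZ) - f_k(pY) f_k(pZ)`.  At `k = 1` this is the classical gap
#' `pYZ - pY pZ`; for `k < 1` it is generally nonzero even for truly
#' independent variables -- irrationality destroys the ability to
#' recognise independence.
#'
#' @param pY,pZ marginal probabilities of `Y = +` and `Z = +`.
#' @param pYZ joint probability of `(Y = +, Z = +)`; must respect the
#'   Frechet bounds `max(0, pY + pZ - 1) <= pYZ <= min(pY, pZ)`.
#' @inheritParams pk_plus
#' @return The perceived factorization gap (0 means the bistable observer
#'   perceives independence).
#' @export
factorization_gap <- function(pY, pZ, pYZ, k) {
  pY <- check_unit_interval(pY, "pY")
  pZ <- check_unit_interval(pZ, "pZ")
  pYZ <- check_unit_interval(pYZ, "pYZ")
  if (any(pYZ < pmax(0, pY + pZ - 1) - .BOUNDARY_TOL) ||
      any(pYZ > pmin(pY, pZ) + .BOUNDARY_TOL)) {
    stop("`pYZ` violates the Frechet bounds for the given marginals", call. = FALSE)
  }
  k <- check_k(k)
  pk_plus(k, pYZ) - pk_plus(k, pY) * pk_plus(k, pZ)
}

#' Classical delta-P causal strength
#'
#' `deltaP = P(Y | X) - P(Y | not X)`: the difference the putative cause
#' makes to the probability of the effect.
#'
#' @param pY_given_X,pY_given_notX conditional probabilities in `[0, 1]`.
#' @return `deltaP` in `[-1, 1]`.
#' @export
delta_p_classical <- function(pY_given_X, pY_given_notX) {
  check_unit_interval(pY_given_X, "pY_given_X") -
    check_unit_interval(pY_given_notX, "pY_given_notX")
}

#' Classical causal power
#'
#' `kappa = deltaP / P(not Y | not X)`: delta-P normalised by the base
#' rate of the effect's absence, so a cause gets more credit when the
#' effect is otherwise unlikely to be absent.
#'
#' @param delta_p causal strength in `[-1, 1]`.
#' @param p_notY_given_notX probability `P(not Y | not X)`, must be > 0.
#' @return `kappa` (possibly outside `[-1, 1]`).
#' @export
kappa_classical <- function(delta_p, p_notY_given_notX) {
  if (!is.numeric(delta_p) || anyNA(delta_p) || any(abs(delta_p) > 1 + .BOUNDARY_TOL)) {
    stop("`delta_p` must be numeric in [-1, 1]", call. = FALSE)
  }
  d <- check_unit_interval(p_notY_given_notX, "p_notY_given_notX")
  if (any(d == 0)) {
    stop("undefined-power: P(notY | notX) = 0 makes causal power undefined",
         call. = FALSE)
  }
  delta_p / d
}

#' Closed-form causal strength of the bistable final judgement
#'
#' For a final judgement with probability `P(Xout = +) = 1 - p - k + 2kp`,
#' the printed closed forms of the causal strength and its power are
#' \deqn{\Delta P_k = k + p - 1, \qquad
#'       \kappa = \frac{k + p - 1}{(1 - p)(1 - k)}.}
#' Increasing irrationality (lower `k`) decreases both.  `kappa` is
#' undefined at `k = 1` or `p = 1` (zero denominator); `delta_p` is still
#' returned there with `kappa = NA` and a `kappa_defined = FALSE` flag.
#'
#' These forms are taken verbatim; the conditioning events behind them are
#' not defined operationally, so no derivation is imputed.  The operator
#' route [strength_bistable_matrix()] is the canonical one for the
#' two-variable cause-effect setting.
#'
#' @inheritParams pk_plus
#' @return List with `delta_p`, `kappa`, `kappa_defined`.
#' @export
strength_bistable_closed <- function(k, p) {
  k <- check_k(k)
  p <- check_p(p)
  dp <- k + p - 1
  den <- (1 - p) * (1 - k)
  list(delta_p = dp,
       kappa = ifelse(den > 0, dp / den, NA_real_),
       kappa_defined = den > 0)
}

# expectation of PY(sy) PX(sx) product in the state for p, at bistability k.
# Y is measured along x, X along z (fixed axes of the two-variable setting).
.product_expectation <- function(k, p, sy, sx) {
  psi <- state_from_p(p)
  PY <- bistable_projection(k, "x", sy)
  PX <- bistable_projection(k, "z", sx)
  expectation(psi, unclass(PY) %*% unclass(PX))
}

#' Operator-route causal strength under bistability
#'
#' Models a cause-effect pair (X causes Y) with bistable measurements:
#' X is measured along the Bloch `z` axis, Y along `x`, both with the same
#' bistable parameter `k`, on the state encoding the rational probability
#' `p`.  The causal strength is the difference of sequential-measurement
#' correlators
#' \deqn{\Delta P_k = \langle P^Y_k(+) P^X_k(+)\rangle -
#'                    \langle P^Y_k(+) P^X_k(-)\rangle}
#' and the power divides by the complementary correlator
#' `<PY(-) PX(-)>`.  Evaluated literally, the operator products give
#' `deltaP = (2k - 1)(2p - 1) / 2`, which vanishes identically at
#' `k = 0.5`: maximal ambivalence makes it impossible to establish any
#' cause-effect relationship.  This matrix route is the canonical result.
#'
#' `as_printed = TRUE` instead returns the published closed forms
#' `deltaP = (1 - k - p + 2kp) / 2` and
#' `kappa = (1 - p - k + 2kp) / (p + k - 2kp + (1 - 2k) p (1 - p))`.
#' These do **not** vanish at `k = 0.5` (the deltaP form gives 1/4 there),
#' contradicting the vanishing-at-ambivalence property, and are exposed
#' only for comparison; a warning is issued.
#'
#' `conditional = TRUE` normalises each correlator by the probability of
#' the conditioning X outcome (`<PX(s)>`), turning joint expectations into
#' conditional ones; the default `FALSE` matches the joint-expectation
#' subtraction of the printed derivation.
#'
#' @inheritParams pk_plus
#' @param conditional normalise correlators by `<PX(s)>` (default FALSE).
#' @param as_printed return the published closed forms instead of the
#'   operator computation (documented discrepancy; default FALSE).
#' @return List with `delta_p`, `kappa`, `kappa_defined`, `route`.
#' @export
strength_bistable_matrix <- function(k, p, conditional = FALSE, as_printed = FALSE) {
  k <- check_k(k); stopifnot(length(k) == 1L)
  p <- check_p(p); stopifnot(length(p) == 1L)
  check_flag(conditional, "conditional")
  check_flag(as_printed, "as_printed")
  if (as_printed) {
    warning(paste0(
      "as_printed closed forms do not vanish at k = 0.5 ",
      "(documented discrepancy with the operator route)"), call. = FALSE)
    dp <- (1 - k - p + 2 * k * p) / 2
    den <- p + k - 2 * k * p + (1 - 2 * k) * p * (1 - p)
    return(list(delta_p = dp,
                kappa = if (abs(den) > 0) (1 - p - k + 2 * k * p) / den else NA_real_,
                kappa_defined = abs(den) > 0,
                route = "as-printed"))
  }
  epp <- .product_expectation(k, p, "+", "+")
  epm <- .product_expectation(k, p, "+", "-")
  emm <- .product_expectation(k, p, "-", "-")
  if (conditional) {
    psi <- state_from_p(p)
    px_plus <- expectation(psi, bistable_projection(k, "z", "+"))
    px_minus <- expectation(psi, bistable_projection(k, "z", "-"))
    if (px_plus == 0 || px_minus == 0) {
      stop("undefined-power: conditioning outcome has probability 0", call. = FALSE)
    }
    epp <- epp / px_plus
    epm <- epm / px_minus
    emm <- emm / px_minus
  }
  dp <- epp - epm
  list(delta_p = dp,
       kappa = if (abs(emm) > 0) dp / emm else NA_real_,
       kappa_defined = abs(emm) > 0,
       route = if (conditional) "matrix-conditional" else "matrix")
}

#' Verdict on a bistable observer's perception of (in)dependence
#'
#' Compares the perceived factorization gap at the observer's `k` against
#' the true (rational, `k = 1`) gap:
#' \describe{
#'   \item{independent}{truly independent and perceived as such.}
#'   \item{spuriously-causal}{truly independent, but the bistable gap is
#'     nonzero -- the observer discerns causality that is not there.}
#'   \item{causal}{truly dependent and the perceived gap matches the true
#'     one (faithful perception; always the case at `k = 1`).}
#'   \item{causality-masked}{truly dependent, but bistability distorts the
#'     perceived gap away from the true one, masking the real relation.}
#' }
#'
#' @inheritParams factorization_gap
#' @param tol independence tolerance on gap magnitudes (default 1e-9).
#' @return List with `verdict`, `gap_k`, `gap_rational`.
#' @export
independence_verdict <- function(pY, pZ, pYZ, k, tol = 1e-9) {
  stopifnot(is.numeric(tol), tol > 0)
  gap_k <- factorization_gap(pY, pZ, pYZ, k)
  gap_1 <- factorization_gap(pY, pZ, pYZ, 1)
  verdict <- if (abs(gap_1) <= tol) {
    if (abs(gap_k) <= tol) "independent" else "spuriously-causal"
  } else {
    if (abs(gap_k - gap_1) <= tol) "causal" else "causality-masked"
  }
  list(verdict = verdict, gap_k = gap_k, gap_rational = gap_1)
}
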