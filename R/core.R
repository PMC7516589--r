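#' Bistable probability of the System-1-preferred outcome
#'
#' The bistable probability map combines the intuitive System-1 propensity
#' `k` for outcome A with the deliberative System-2 agreement probability
#' `p` into the final decision probability
#' \deqn{P_k(+) = 1 - p - k + 2kp.}
#' System 1 opts for A with probability `k`; System 2 intervenes and flips
#' the choice with probability `1 - p`.  At `k = 1` the map reproduces the
#' rational probability `p`; at `k = 0` its converse `1 - p`; at `k = 0.5`
#' the decision is a fair coin regardless of `p`.
#'
#' The map is affine in `p` with slope `2k - 1` and is symmetric in its two
#' arguments, so `(k, p)` are not jointly identifiable from a single
#' outcome frequency.
#'
#' @param k bistable parameter in `[0, 1]`; `k = 1` is fully rational,
#'   `k = 0` fully inverting, `k = 0.5` maximally ambivalent.
#' @param p rational (System 2) probability in `[0, 1]`.
#' @return Probability of the final choice being outcome A (vectorised).
#' @examples
#' pk_plus(0.8, 0.9)  # 0.74 -- bank-teller option in the Linda problem
#' pk_plus(0.3, 0.2)  # 0.62
#' @seealso [pk_minus()], [invert_map()], [classify_regime()]
#' @export
pk_plus <- function(k, p) {
  k <- check_k(k)
  p <- check_p(p)
  n <- max(length(k), length(p))
  k <- rep_len(k, n); p <- rep_len(p, n)
  out <- 1 - p - k + 2 * k * p
  # boundary regimes are definitional identities: evaluate them exactly
  # rather than through the formula's floating-point rounding
  out[k == 1] <- p[k == 1]
  out[p == 1] <- k[p == 1]
  out[k == 0] <- 1 - p[k == 0]
  out[p == 0] <- 1 - k[p == 0]
  out[k == 0.5 | p == 0.5] <- 0.5
  out
}

#' Bistable probability of the alternative outcome
#'
#' Complement of [pk_plus()]:
#' \deqn{P_k(-) = p + k - 2kp = 1 - P_k(+).}
#'
#' @inheritParams pk_plus
#' @return Probability of the final choice being outcome B (vectorised).
#' @export
pk_minus <- function(k, p) {
  k <- check_k(k)
  p <- check_p(p)
  n <- max(length(k), length(p))
  k <- rep_len(k, n); p <- rep_len(p, n)
  out <- p + k - 2 * k * p
  out[k == 1] <- 1 - p[k == 1]
  out[p == 1] <- 1 - k[p == 1]
  out[k == 0] <- p[k == 0]
  out[p == 0] <- k[p == 0]
  out[k == 0.5 | p == 0.5] <- 0.5
  out
}

#' Classify the rationality regime of a bistable parameter
#'
#' Regimes are definitional, not estimated, so boundaries use exact
#' comparison on the supplied value: `k = 1` is `"rational"` (System 2
#' fully determines the judgement), `k = 0` `"irrational-inverting"`
#' (the converse of the rational judgement), `k = 0.5` `"ambivalent"`
#' (caught between two minds; the decision is random), and any interior
#' value `"partially-irrational"`.
#'
#' @inheritParams pk_plus
#' @return Character vector of regime labels.
#' @export
classify_regime <- function(k) {
  k <- check_k(k)
  ifelse(k == 1, "rational",
    ifelse(k == 0, "irrational-inverting",
      ifelse(k == 0.5, "ambivalent", "partially-irrational")))
}

#' Invert the bistable map for one unknown parameter
#'
#' Solves `observed = 1 - p - k + 2kp` for whichever of `k`, `p` is not
#' supplied.  The map is symmetric in `(k, p)`, so the algebra is the same
#' either way: `unknown = (observed - 1 + value) / (2 * value - 1)`.
#'
#' The inversion is singular when the known parameter equals 0.5 (the map
#' is then constant at 0.5 in the other argument).  An algebraic solution
#' outside `[0, 1]` is an infeasibility error, never silently clipped:
#' out-of-range solutions surface model misfit.
#'
#' @param observed observed final-choice probability in `[0, 1]`.
#' @param known which parameter is known: `"k"` or `"p"`.
#' @param value the known parameter's value, in `[0, 1]` and not 0.5.
#' @return The unique solving value of the other parameter.
#' @export
invert_map <- function(observed, known = c("p", "k"), value) {
  known <- match.arg(known)
  observed <- check_unit_interval(observed, "observed")
  value <- check_unit_interval(value, known)
  if (any(value == 0.5)) {
    stop(sprintf("inversion is singular at %s = 0.5: the bistable map is constant there",
                 known), call. = FALSE)
  }
  out <- (observed - 1 + value) / (2 * value - 1)
  bad <- out < -.BOUNDARY_TOL | out > 1 + .BOUNDARY_TOL
  if (any(bad)) {
    stop(sprintf("infeasible: solved %s = %s lies outside [0, 1]",
                 if (known == "p") "k" else "p",
                 paste(format(out[bad]), collapse = ", ")), call. = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

#' Noise parameter of the equivalent unsharp quantum measurement
#'
#' The bistable parameter maps linearly onto the noise parameter of an
#' unsharp (noisy) quantum measurement, `eta = 2k - 1`, with the interval
#' extended to `eta` in `[-1, 1]` so that inverting regimes (`k < 0.5`)
#' are representable.
#'
#' @inheritParams pk_plus
#' @return `eta = 2k - 1` in `[-1, 1]`.
#' @seealso [k_from_eta()] for the inverse, [unsharp_projection()]
#' @export
eta_from_k <- function(k) {
  2 * check_k(k) - 1
}

#' @rdname eta_from_k
#' @param eta noise parameter in `[-1, 1]`.
#' @return `k_from_eta`: `k = (eta + 1) / 2` in `[0, 1]`.
#' @export
k_from_eta <- function(eta) {
  (check_eta(eta) + 1) / 2
}
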