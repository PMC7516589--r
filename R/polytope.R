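# Boole's conditions, the bistable accessible-information polytope, exact
# volumes, and the pure irrational information volume (PIIV) functional.

#' Check Boole's conditions for two events and their conjunction
#'
#' For events with probabilities `P1`, `P2` and conjunction probability
#' `P12`, the conditions of possible experience are
#' `0 <= Pi <= 1`, `Pi >= P12`, `P12 >= 0`, and `P1 + P2 - P12 <= 1`
#' (equivalently `P(E1 v E2) <= 1`).  A point satisfying all of them is a
#' potential rational choice; each violated condition is listed by name.
#'
#' (Some renderings of the fourth condition carry the opposite inequality
#' sign; the `<= 1` direction used here is the standard union-bound form
#' and the one consistent with the three-event conditions.)
#'
#' @param p1,p2 event probabilities (finite reals; violations reported,
#'   not rejected).
#' @param p12 conjunction probability.
#' @param tol violation tolerance (default 1e-12).
#' @return List with `rational` (no violations) and `violated` (character
#'   vector of violated condition descriptions).
#' @export
boole_check <- function(p1, p2, p12, tol = 1e-12) {
  stopifnot(is.finite(p1), is.finite(p2), is.finite(p12))
  violated <- character(0)
  if (p1 < -tol || p1 > 1 + tol) violated <- c(violated, "0 <= P1 <= 1")
  if (p2 < -tol || p2 > 1 + tol) violated <- c(violated, "0 <= P2 <= 1")
  if (p12 < -tol) violated <- c(violated, "P12 >= 0")
  if (p1 < p12 - tol) violated <- c(violated, "P1 >= P12")
  if (p2 < p12 - tol) violated <- c(violated, "P2 >= P12")
  if (p1 + p2 - p12 > 1 + tol) violated <- c(violated, "P1 + P2 - P12 <= 1")
  list(rational = length(violated) == 0L, violated = violated)
}

#' Accessible-information polytope of bistable outputs
#'
#' The convex region in `(P1, P2, P12)` coordinates accessible to a
#' bistable decision maker with parameter `k`, bounded by
#' \deqn{(2k-1) P_i - P_{12} \ge k - 1 \quad (i = 1, 2),}
#' \deqn{(2k-1)(P_1 + P_2) - P_{12} \le 2k - 1,}
#' together with the base constraints `0 <= P1, P2 <= 1` and `P12 >= 0`
#' (the base constraints are required for a bounded region and follow
#' from Boole's `0 <= Pi <= 1`, `P12 >= 0`).  At `k = 1` the region is the
#' classical Boole polytope: the tetrahedron with vertices
#' `(0,0,0), (0,1,0), (1,0,0), (1,1,1)`.  At `k = 0.5` the `Pi` decouple
#' and the region is the box `[0,1]^2 x [0, 1/2]`.  Decreasing `k`
#' enlarges the region: irrationality gives access to more information.
#'
#' Vertices are computed by exact half-space intersection (plane-triple
#' enumeration); both representations describe the same region.
#'
#' @inheritParams pk_plus
#' @return Object of class `"prob_polytope"`: list with `k`, `halfspaces`
#'   (list of `normal`, `offset` meaning `normal . x <= offset`),
#'   `vertices` (matrix, one row per vertex), `volume`.
#' @export
bistable_polytope <- function(k) {
  k <- check_k(k)
  stopifnot(length(k) == 1L)
  e <- 2 * k - 1
  A <- rbind(
    c(-e, 0, 1),   # (2k-1) P1 - P12 >= k-1
    c(0, -e, 1),   # (2k-1) P2 - P12 >= k-1
    c(e, e, -1),   # (2k-1)(P1+P2) - P12 <= 2k-1
    c(-1, 0, 0), c(1, 0, 0),
    c(0, -1, 0), c(0, 1, 0),
    c(0, 0, -1))
  b <- c(1 - k, 1 - k, e, 0, 1, 0, 1, 0)
  hs <- dedupe_halfspaces(A, b)
  V <- halfspace_vertices(hs$A, hs$b)
  if (nrow(V) == 0L) stop("degenerate: empty polytope region", call. = FALSE)
  vol <- halfspace_volume(hs$A, hs$b, V)
  structure(list(
    k = k,
    halfspaces = lapply(seq_len(nrow(hs$A)), function(i) {
      list(normal = hs$A[i, ], offset = hs$b[i])
    }),
    vertices = V,
    volume = vol
  ), class = "prob_polytope")
}

#' @export
print.prob_polytope <- function(x, ...) {
  cat(sprintf("Bistable probability polytope (k = %.4g)\n", x$k))
  cat(sprintf("  %d half-spaces, %d vertices, volume %.6f\n",
              length(x$halfspaces), nrow(x$vertices), x$volume))
  invisible(x)
}

#' Volume of a probability polytope
#'
#' Exact 3-D Lebesgue volume by fan triangulation of the hull faces
#' (deterministic; no sampling).
#'
#' @param poly a [bistable_polytope()] object.
#' @return Nonnegative volume.
#' @export
polytope_volume <- function(poly) {
  stopifnot(inherits(poly, "prob_polytope"))
  poly$volume
}

#' Pure irrational information volume (PIIV)
#'
#' The excess accessible-information volume of an irrational decision
#' maker over a rational one:
#' \deqn{\Delta(k) = V(k) - V(k = 1),}
#' where `V(k)` is the volume of [bistable_polytope()]`(k)`.  `Delta`
#' is zero at `k = 1` and grows as `k` decreases on `[0.5, 1]` (to
#' `1/2 - 1/6 = 1/3` at maximal ambivalence): irrationality widens the
#' space of probability assignments the agent can entertain.
#'
#' Both volumes are computed numerically from the half-space geometry;
#' no closed algebraic form is used.
#'
#' @inheritParams pk_plus
#' @return List with `k`, `volume_k`, `volume_rational`, `delta`.
#' @export
piiv <- function(k) {
  k <- check_k(k)
  stopifnot(length(k) == 1L)
  vk <- bistable_polytope(k)$volume
  v1 <- bistable_polytope(1)$volume
  list(k = k, volume_k = vk, volume_rational = v1, delta = vk - v1)
}

#' PIIV curve over a grid of bistable parameters
#'
#' @param k_grid numeric vector of bistable parameters (order preserved;
#'   no hidden sorting).
#' @return `data.frame` with columns `k`, `n_vertices`, `volume`, `piiv`.
#' @export
piiv_curve <- function(k_grid) {
  k_grid <- check_k(k_grid)
  v1 <- bistable_polytope(1)$volume
  rows <- lapply(k_grid, function(k) {
    poly <- bistable_polytope(k)
    data.frame(k = k, n_vertices = nrow(poly$vertices),
               volume = poly$volume, piiv = poly$volume - v1)
  })
  do.call(rbind, rows)
}

#' Convex weights of a point over the rational polytope's vertices
#'
#' Any point of the rational (`k = 1`) Boole tetrahedron is a convex
#' combination `sum(lambda_i * v_i)` of its four vertices with
#' `lambda_i >= 0`, `sum(lambda) = 1`.  Solves for the (unique) weights
#' and reports feasibility.
#'
#' @param point numeric length-3 `(P1, P2, P12)` point.
#' @param tol feasibility tolerance (default 1e-9).
#' @return List with `lambda` (length 4, ordered over vertices
#'   `(0,0,0), (0,1,0), (1,0,0), (1,1,1)`) and `feasible`.
#' @export
convex_weights <- function(point, tol = 1e-9) {
  stopifnot(is.numeric(point), length(point) == 3L, all(is.finite(point)))
  verts <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 1))
  M <- rbind(t(verts), rep(1, 4))
  lambda <- as.numeric(solve(M, c(point, 1)))
  list(lambda = lambda, feasible = all(lambda >= -tol))
}
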