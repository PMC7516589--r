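# Boole's conditions of possible experience for three events, bistable
# attenuation of a probability assignment, and violation sweeps.

#' Three-event probability assignment
#'
#' Bundles the marginal probabilities `p1, p2, p3` of events `E1, E2, E3`
#' and their pairwise conjunction probabilities `p12, p13, p23`.  A point
#' inside the Bell-Wigner polytope (all of [bw_inequalities()] satisfied)
#' admits a classical joint distribution; a point outside cannot arise
#' from any classical joint and is "quantum-like".
#'
#' @param p1,p2,p3 marginal probabilities in `[0, 1]`.
#' @param p12,p13,p23 pairwise joint probabilities in `[0, 1]`.
#' @return Object of class `"bw_assignment"` (named list of the six
#'   probabilities).
#' @export
bw_assignment <- function(p1, p2, p3, p12, p13, p23) {
  vals <- c(p1 = p1, p2 = p2, p3 = p3, p12 = p12, p13 = p13, p23 = p23)
  for (nm in names(vals)) vals[[nm]] <- check_unit_interval(vals[[nm]], nm)
  structure(as.list(vals), class = "bw_assignment")
}

#' @export
print.bw_assignment <- function(x, ...) {
  cat(sprintf(
    "Bell-Wigner assignment: p1=%.4g p2=%.4g p3=%.4g | p12=%.4g p13=%.4g p23=%.4g\n",
    x$p1, x$p2, x$p3, x$p12, x$p13, x$p23))
  invisible(x)
}

#' Assignment from a full joint distribution over three binary events
#'
#' Marginalises an 8-cell joint over `(E1, E2, E3)` outcomes into the
#' marginals and pairwise joints.  Assignments built this way are
#' classically realizable by construction, hence satisfy every
#' Bell-Wigner inequality.
#'
#' @param joint numeric length 8, nonnegative, summing to 1 (within
#'   1e-12).  Cell order: `(+++, ++-, +-+, +--, -++, -+-, --+, ---)`
#'   where the signs are the truth of `(E1, E2, E3)`.
#' @return A [bw_assignment()].
#' @export
assignment_from_joint <- function(joint) {
  if (!is.numeric(joint) || length(joint) != 8L || anyNA(joint) || any(joint < 0)) {
    stop("`joint` must be 8 nonnegative probabilities", call. = FALSE)
  }
  if (abs(sum(joint) - 1) > 1e-12) {
    stop("`joint` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  # cell order has E3's sign varying fastest; index 1 = event true
  j <- array(0, c(2L, 2L, 2L))
  idx <- 0L
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    idx <- idx + 1L
    j[a, b, cc] <- joint[idx]
  }
  bw_assignment(
    p1 = sum(j[1, , ]), p2 = sum(j[, 1, ]), p3 = sum(j[, , 1]),
    p12 = sum(j[1, 1, ]), p13 = sum(j[1, , 1]), p23 = sum(j[, 1, 1]))
}

#' Bell-Wigner inequality values for an assignment
#'
#' Evaluates Boole's conditions of possible experience for three events:
#' the range conditions `0 <= pi <= 1` and `0 <= pij <= min(pi, pj)`, the
#' pairwise union bounds `pi + pj - pij <= 1`, the triple union bound
#' `p1 + p2 + p3 - p12 - p13 - p23 <= 1`, and the three triangle
#' conditions of the form `p1 - p12 - p13 + p23 >= 0`.  A record is
#' produced per inequality with its value and a violation flag (breach
#' beyond `tol`).
#'
#' @param a a [bw_assignment()].
#' @param tol violation tolerance (default 1e-12).
#' @return `data.frame` with columns `id`, `value`, `bound`, `direction`
#'   (`"ge"`/`"le"`), `violated`.
#' @export
bw_inequalities <- function(a, tol = 1e-12) {
  stopifnot(inherits(a, "bw_assignment"))
  p <- c(a$p1, a$p2, a$p3)
  pj <- list(`12` = a$p12, `13` = a$p13, `23` = a$p23)
  rows <- list()
  add <- function(id, value, bound, direction) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, value = value, bound = bound, direction = direction,
      violated = if (direction == "ge") value < bound - tol else value > bound + tol,
      stringsAsFactors = FALSE)
  }
  for (i in 1:3) {
    add(sprintf("27.%d.lo", i), p[i], 0, "ge")
    add(sprintf("27.%d.hi", i), p[i], 1, "le")
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs) {
    nm <- paste0(pr[1], pr[2])
    add(sprintf("28.%s.lo", nm), pj[[nm]], 0, "ge")
    add(sprintf("28.%s.hi", nm), pj[[nm]], min(p[pr[1]], p[pr[2]]), "le")
    add(sprintf("29.%s", nm), p[pr[1]] + p[pr[2]] - pj[[nm]], 1, "le")
  }
  add("30", sum(p) - pj$`12` - pj$`13` - pj$`23`, 1, "le")
  add("31", p[1] - pj$`12` - pj$`13` + pj$`23`, 0, "ge")
  add("32", p[2] - pj$`12` - pj$`23` + pj$`13`, 0, "ge")
  add("33", p[3] - pj$`13` - pj$`23` + pj$`12`, 0, "ge")
  do.call(rbind, rows)
}

#' Bistable attenuation of a three-event assignment
#'
#' Applies the bistable map `f_k(x) = 1 - x - k + 2kx` with per-event
#' parameters `k1, k2, k3` to an assignment.  Marginals are always mapped
#' `pi -> f_ki(pi)`.  Two schemes are offered for the pairwise joints:
#' \describe{
#'   \item{sequential composition (default)}{`pij -> f_ki(f_kj(pij))`,
#'     each event's bistability acting once on the conjunction (the
#'     composition is commutative, so the order of `i`, `j` is
#'     immaterial).}
#'   \item{marginals only (`marginals_only = TRUE`)}{joints untouched --
#'     the literal reading of attenuating only `p1, p2, p3`.}
#' }
#' Neither scheme is claimed to be uniquely correct; both keep every
#' entry in `[0, 1]`, and `k1 = k2 = k3 = 1` is the identity under both.
#' Notably, for `k` restricted to `[0.5, 1]` the sequential-composition
#' scheme can never produce an inequality violation from a classically
#' realizable base (the attenuated value is multilinear in the
#' `2k_i - 1`, with all box-vertex values classically realizable), so
#' violation sweeps over that range use the marginals-only scheme.
#'
#' @param a a [bw_assignment()].
#' @param k1,k2,k3 bistable parameters in `[0, 1]`.
#' @param marginals_only attenuate only the marginals (default FALSE).
#' @return The attenuated [bw_assignment()].
#' @export
bw_attenuate <- function(a, k1, k2, k3, marginals_only = FALSE) {
  stopifnot(inherits(a, "bw_assignment"))
  k1 <- check_unit_interval(k1, "k1")
  k2 <- check_unit_interval(k2, "k2")
  k3 <- check_unit_interval(k3, "k3")
  check_flag(marginals_only, "marginals_only")
  f <- function(k, x) 1 - x - k + 2 * k * x
  if (marginals_only) {
    bw_assignment(f(k1, a$p1), f(k2, a$p2), f(k3, a$p3), a$p12, a$p13, a$p23)
  } else {
    bw_assignment(f(k1, a$p1), f(k2, a$p2), f(k3, a$p3),
                  f(k1, f(k2, a$p12)), f(k1, f(k3, a$p13)), f(k2, f(k3, a$p23)))
  }
}

#' Default base assignment for violation sweeps
#'
#' Three independent events, each with probability `p` (so every pairwise
#' joint is `p^2`).  With the default `p = 0.9` this is the documented
#' fixture for the attenuation sweep.
#'
#' @param p common marginal probability (default 0.9).
#' @return A [bw_assignment()].
#' @export
bw_independent_fixture <- function(p = 0.9) {
  p <- check_p(p)
  bw_assignment(p, p, p, p^2, p^2, p^2)
}

#' Sweep bistable attenuation over a grid of (k1, k2, k3)
#'
#' Attenuates the base assignment at every point of the full factorial
#' grid and records the value of the selected inequality.  Rows are
#' ordered with `k3` slowest (one block per `k3` value), then `k2`,
#' then `k1` -- one block per panel of a violation-surface plot.
#'
#' @param a base [bw_assignment()].
#' @param k1_grid,k2_grid,k3_grid numeric grids in `[0, 1]`.
#' @param inequality inequality id as in [bw_inequalities()] (default
#'   `"31"`, the first triangle condition).
#' @inheritParams bw_attenuate
#' @param tol violation tolerance (default 1e-12).
#' @return `data.frame` with columns `k1, k2, k3, ineq_id, value,
#'   violated`.
#' @export
bw_sweep <- function(a, k1_grid, k2_grid, k3_grid = 1, inequality = "31",
                     marginals_only = FALSE, tol = 1e-12) {
  stopifnot(inherits(a, "bw_assignment"))
  k1_grid <- check_unit_interval(k1_grid, "k1_grid")
  k2_grid <- check_unit_interval(k2_grid, "k2_grid")
  k3_grid <- check_unit_interval(k3_grid, "k3_grid")
  grid <- expand.grid(k1 = k1_grid, k2 = k2_grid, k3 = k3_grid,
                      KEEP.OUT.ATTRS = FALSE)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    att <- bw_attenuate(a, grid$k1[i], grid$k2[i], grid$k3[i],
                        marginals_only = marginals_only)
    ineqs <- bw_inequalities(att, tol = tol)
    row <- ineqs[ineqs$id == inequality, ]
    if (nrow(row) != 1L) stop(sprintf("unknown inequality id '%s'", inequality),
                              call. = FALSE)
    c(row$value, as.numeric(row$violated))
  }, numeric(2))
  data.frame(k1 = grid$k1, k2 = grid$k2, k3 = grid$k3,
             ineq_id = inequality, value = vals[1, ],
             violated = vals[2, ] > 0, stringsAsFactors = FALSE)
}

#' Maximum violation in a sweep table
#'
#' @param sweep a [bw_sweep()] result.
#' @return The single row whose value breaches its inequality the most
#'   (for `"ge"`-type triangle/positivity inequalities: the most negative
#'   value); `NULL` if the sweep contains no violation.
#' @export
bw_max_violation <- function(sweep) {
  stopifnot(is.data.frame(sweep), "violated" %in% names(sweep))
  hits <- sweep[sweep$violated, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[which.min(hits$value), , drop = FALSE]
}
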