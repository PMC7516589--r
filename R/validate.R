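# Internal argument validation.
#
# All probabilities and bistable parameters are validated on entry.  Values
# that stray outside [0, 1] by no more than `tol` (floating-point boundary
# excursions, e.g. 1 + 2e-16 from upstream arithmetic) are snapped back to
# the boundary; anything further out is an error.

.BOUNDARY_TOL <- 1e-12

check_unit_interval <- function(x, name, tol = .BOUNDARY_TOL) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric value in [0, 1]", name), call. = FALSE)
  }
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop(sprintf("`%s` must lie in [0, 1] (got %s)", name,
                 paste(format(x[x < -tol | x > 1 + tol]), collapse = ", ")),
         call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

check_k <- function(k) check_unit_interval(k, "k")
check_p <- function(p) check_unit_interval(p, "p")

check_eta <- function(eta, tol = .BOUNDARY_TOL) {
  if (!is.numeric(eta) || anyNA(eta)) {
    stop("`eta` must be numeric in [-1, 1]", call. = FALSE)
  }
  if (any(eta < -1 - tol) || any(eta > 1 + tol)) {
    stop("`eta` must lie in [-1, 1]", call. = FALSE)
  }
  pmin(pmax(eta, -1), 1)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  x
}

check_count <- function(n, name) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  as.integer(n)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed)) {
    stop("an explicit integer `seed` is required (no silent nondeterminism)",
         call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}
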