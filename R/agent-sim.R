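# Monte Carlo simulation of the two-system decision agent, frequency
# estimation, and parameter recovery.

#' Simulate the two-system bistable decision agent
#'
#' Draws `n_trials` independent decisions from the two-coin process:
#' System 1 chooses outcome `A` with probability `k`; System 2 then
#' intervenes and flips the choice with probability `1 - p` (or agrees,
#' leaving it, with probability `p`).  The final-choice frequency of `A`
#' converges to [pk_plus()]`(k, p) = 1 - p - k + 2kp`.  No temporal
#' ordering of the two systems is modelled; the process is a static pair
#' of Bernoulli draws.
#'
#' Reproducibility contract: a single generator is seeded with `seed`
#' (R's Mersenne-Twister); trial `i` consumes exactly uniform draws
#' `2i - 1` (System 1's choice) and `2i` (System 2's intervention) from
#' one `runif(2 * n_trials)` stream, so identical configurations give
#' byte-identical trial records.
#'
#' @inheritParams pk_plus
#' @param n_trials number of trials (positive integer).
#' @param seed integer seed (required; no silent nondeterminism).
#' @return List of class `"agent_sim"` with `trials` (`data.frame`:
#'   `trial`, `s1_choice` `"A"`/`"B"`, `intervened`, `final`), `freq_A`
#'   (final-choice frequency of `A`), `expected` (the exact
#'   `pk_plus(k, p)`), and the configuration.
#' @export
simulate_agent <- function(k, p, n_trials, seed) {
  k <- check_k(k); stopifnot(length(k) == 1L)
  p <- check_p(p); stopifnot(length(p) == 1L)
  n <- check_count(n_trials, "n_trials")
  seed <- check_seed(seed)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  u <- stats::runif(2L * n)
  u1 <- u[seq(1L, 2L * n, by = 2L)]
  u2 <- u[seq(2L, 2L * n, by = 2L)]

  s1_A <- u1 < k
  intervened <- u2 < 1 - p
  final_A <- xor(s1_A, intervened)   # intervention flips the binary choice
  trials <- data.frame(
    trial = seq_len(n),
    s1_choice = ifelse(s1_A, "A", "B"),
    intervened = intervened,
    final = ifelse(final_A, "A", "B"),
    stringsAsFactors = FALSE)
  structure(list(
    trials = trials,
    freq_A = mean(final_A),
    expected = pk_plus(k, p),
    k = k, p = p, n_trials = n, seed = seed
  ), class = "agent_sim")
}

#' @export
print.agent_sim <- function(x, ...) {
  cat(sprintf(
    "Bistable agent simulation: k=%.4g p=%.4g n=%d seed=%d\n  freq(A) = %.6f (expected %.6f)\n",
    x$k, x$p, x$n_trials, x$seed, x$freq_A, x$expected))
  invisible(x)
}

#' Estimate the bistable parameter from an observed frequency
#'
#' Inverts the bistable map at a known System-2 probability:
#' `k_hat = (freq_A - 1 + p) / (2p - 1)`, with a delta-method standard
#' error `sqrt(freq_A (1 - freq_A) / n) / |2p - 1|` when the number of
#' trials is supplied.  Estimates outside `[0, 1]` are flagged
#' (`in_range = FALSE`), never clipped.  The map is constant in `k` at
#' `p = 0.5`, so `k` is not identifiable there and the call errors.
#'
#' @param freq_A observed final-choice frequency of outcome A.
#' @param p_known the known System-2 probability (not 0.5).
#' @param n_trials optional trial count behind `freq_A`, for the
#'   standard error.
#' @return List with `k_hat`, `se` (`NA` without `n_trials`), `in_range`.
#' @export
estimate_k <- function(freq_A, p_known, n_trials = NULL) {
  freq_A <- check_unit_interval(freq_A, "freq_A")
  p_known <- check_p(p_known)
  if (any(p_known == 0.5)) {
    stop("singular: k is not identifiable at p = 0.5 (the map is constant in k)",
         call. = FALSE)
  }
  k_hat <- (freq_A - 1 + p_known) / (2 * p_known - 1)
  se <- if (is.null(n_trials)) NA_real_ else {
    n <- check_count(n_trials, "n_trials")
    sqrt(freq_A * (1 - freq_A) / n) / abs(2 * p_known - 1)
  }
  list(k_hat = k_hat, se = se,
       in_range = k_hat >= -.BOUNDARY_TOL & k_hat <= 1 + .BOUNDARY_TOL)
}

#' Parameter-recovery experiment for the bistable agent
#'
#' Repeatedly simulates the agent at known `(true_k, true_p)` and
#' re-estimates `k` from each run's final-choice frequency ([estimate_k()]
#' with `p` known).  Reports the mean estimate, bias, RMSE, and the Monte
#' Carlo standard error of the bias.  The estimator is affine in a
#' binomial frequency, hence unbiased, with bias shrinking as
#' `1/sqrt(n_trials * n_reps)`.
#'
#' Replicate `r` uses seed `seed + r`, keeping the whole experiment a
#' deterministic function of `seed`.
#'
#' @param true_k,true_p generating parameters (`true_p != 0.5`).
#' @param n_trials trials per replicate.
#' @param n_reps number of replicates.
#' @param seed integer base seed.
#' @return List with `estimates` (numeric, length `n_reps`), `mean_k_hat`,
#'   `bias`, `rmse`, `mc_se`, and the configuration.
#' @export
recovery_experiment <- function(true_k, true_p, n_trials, n_reps, seed) {
  true_k <- check_k(true_k)
  true_p <- check_p(true_p)
  if (true_p == 0.5) {
    stop("singular: k is not identifiable at p = 0.5", call. = FALSE)
  }
  n_reps <- check_count(n_reps, "n_reps")
  seed <- check_seed(seed)
  estimates <- vapply(seq_len(n_reps), function(r) {
    sim <- simulate_agent(true_k, true_p, n_trials, seed = seed + r)
    estimate_k(sim$freq_A, true_p)$k_hat
  }, 0)
  list(estimates = estimates,
       mean_k_hat = mean(estimates),
       bias = mean(estimates) - true_k,
       rmse = sqrt(mean((estimates - true_k)^2)),
       mc_se = stats::sd(estimates) / sqrt(n_reps),
       true_k = true_k, true_p = true_p,
       n_trials = n_trials, n_reps = n_reps, seed = seed)
}
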