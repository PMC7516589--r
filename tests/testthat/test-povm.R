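test_that("Pauli matrices are the standard ones and square to identity", {
  expect_equal(pauli("x"), matrix(c(0, 1, 1, 0) + 0i, 2, 2))
  expect_equal(pauli("z"), matrix(c(1, 0, 0, -1) + 0i, 2, 2))
  expect_equal(pauli("y"), matrix(c(0, 1i, -1i, 0), 2, 2))
  for (ax in c("x", "y", "z")) {
    s <- pauli(ax)
    expect_equal(s %*% s, diag(2) + 0i)
    expect_equal(sum(diag(s)), 0 + 0i)
    expect_equal(Conj(t(s)), s)
  }
  expect_error(pauli("w"))
})

test_that("sharp projectors are orthogonal idempotent and direction-correct", {
  expect_equal(sharp_projector("z", "+"), diag(c(1, 0)) + 0i)
  # theta = pi/2, phi = 0 is the x-axis projector 1/2 [[1,1],[1,1]]
  expect_equal(sharp_projector(bloch_direction(pi / 2, 0), "+"),
               matrix(0.5 + 0i, 2, 2))
  set.seed(11)
  for (i in 1:20) {
    d <- bloch_direction(runif(1, 0, pi), runif(1, 0, 2 * pi))
    pp <- sharp_projector(d, "+"); pm <- sharp_projector(d, "-")
    expect_lt(max(Mod(pp %*% pp - pp)), 1e-12)          # idempotent
    expect_lt(max(Mod(pp %*% pm)), 1e-12)               # orthogonal
    expect_lt(max(Mod(pp + pm - diag(2))), 1e-12)       # complete
    expect_equal(Re(sum(diag(pp))), 1)                  # rank one
  }
})

test_that("unsharp projection with eta = 2k - 1 equals the bistable projection", {
  set.seed(12)
  for (i in 1:25) {
    k <- runif(1)
    d <- bloch_direction(runif(1, 0, pi), runif(1, 0, 2 * pi))
    for (s in c("+", "-")) {
      expect_lt(max(Mod(unsharp_projection(d, eta_from_k(k), s) -
                          bistable_projection(k, d, s))), 1e-10)
    }
  }
  expect_equal(unsharp_projection("z", 1, "+"), sharp_projector("z", "+"))
  expect_equal(unsharp_projection("x", 0, "+"), diag(2) / 2 + 0i)
  expect_error(unsharp_projection("z", 1.5), "eta")
})

test_that("bistable projections take the published z- and x-direction forms", {
  k <- 0.8
  expect_equal(unclass(bistable_projection(k, "z", "+")), diag(c(k, 1 - k)) + 0i,
               ignore_attr = TRUE)
  expect_equal(unclass(bistable_projection(k, "z", "-")), diag(c(1 - k, k)) + 0i,
               ignore_attr = TRUE)
  expect_equal(unclass(bistable_projection(k, "x", "+")),
               matrix(c(0.5, k - 0.5, k - 0.5, 0.5) + 0i, 2, 2),
               ignore_attr = TRUE)
  # k = 1 recovers the projective measurement in any direction
  d <- bloch_direction(1.1, 2.3)
  expect_equal(unclass(bistable_projection(1, d, "+")), sharp_projector(d, "+"),
               ignore_attr = TRUE)
  expect_equal(unclass(bistable_projection(1, d, "-")), sharp_projector(d, "-"),
               ignore_attr = TRUE)
})

test_that("POVM completeness and {k, 1-k} spectrum hold for random draws", {
  set.seed(99)
  for (i in 1:200) {
    k <- runif(1)
    d <- bloch_direction(runif(1, 0, pi), runif(1, 0, 2 * pi))
    pp <- bistable_projection(k, d, "+")
    pm <- bistable_projection(k, d, "-")
    expect_lt(max(Mod(unclass(pp) + unclass(pm) - diag(2))), 1e-12)
    ev <- sort(Re(eigen(unclass(pp), only.values = TRUE)$values))
    expect_equal(ev, sort(c(k, 1 - k)), tolerance = 1e-10)
    expect_gte(min(ev), -1e-10)  # positive semidefinite
  }
})

test_that("decision state encodes p in squared amplitudes", {
  expect_identical(as.numeric(state_from_p(1)), c(1, 0))
  expect_identical(as.numeric(state_from_p(0)), c(0, 1))
  s <- state_from_p(0.5)
  expect_equal(as.numeric(s)^2, c(0.5, 0.5))
  s <- state_from_p(0.37)
  expect_equal(sum(as.numeric(s)^2), 1)
  expect_equal(as.numeric(s)[1]^2, 0.37)
})

test_that("operator expectations reproduce the scalar bistable map", {
  # the worked example through the quantum route
  expect_equal(expectation(state_from_p(0.9), bistable_projection(0.8, "z", "+")),
               0.74, tolerance = 1e-14)
  expect_equal(expectation(state_from_p(0.9), bistable_projection(0.8, "z", "-")),
               0.26, tolerance = 1e-14)
  # k = 0.5 gives 1/2 for every state and direction (operator is I/2)
  for (p in c(0, 0.2, 0.9)) {
    expect_equal(expectation(state_from_p(p),
                             bistable_projection(0.5, bloch_direction(0.7, 1.2), "+")),
                 0.5, tolerance = 1e-14)
  }
  # dense-grid agreement with pk_plus / pk_minus
  g <- seq(0, 1, length.out = 21)
  for (k in g) {
    Pp <- bistable_projection(k, "z", "+")
    Pm <- bistable_projection(k, "z", "-")
    for (p in g) {
      psi <- state_from_p(p)
      expect_equal(expectation(psi, Pp), pk_plus(k, p), tolerance = 1e-12)
      expect_equal(expectation(psi, Pm), pk_minus(k, p), tolerance = 1e-12)
    }
  }
})

test_that("povm_validate reports completeness, spectrum and unsharpness", {
  k <- 0.3
  d <- bloch_direction(0.4, 5.1)
  rep_b <- povm_validate(list(bistable_projection(k, d, "+"),
                              bistable_projection(k, d, "-")))
  expect_lt(rep_b$completeness_deviation, 1e-12)
  expect_equal(rep_b$min_eigenvalue, min(k, 1 - k), tolerance = 1e-10)
  expect_true(rep_b$is_povm)
  expect_false(any(rep_b$idempotent))   # unsharp: E E != E

  rep_s <- povm_validate(list(sharp_projector(d, "+"), sharp_projector(d, "-")))
  expect_true(rep_s$is_povm)
  expect_true(all(rep_s$idempotent))

  rep_half <- povm_validate(list(sharp_projector(d, "+")))
  expect_false(rep_half$is_povm)
  expect_gt(rep_half$completeness_deviation, 0.5)
})
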