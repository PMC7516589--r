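test_that("Boole's conditions for two events are checked condition by condition", {
  expect_true(boole_check(0.5, 0.5, 0.25)$rational)
  v <- boole_check(0.3, 0.3, 0.5)
  expect_false(v$rational)
  expect_true(any(grepl("P1 >= P12", v$violated)))
  v <- boole_check(0.9, 0.9, 0.2)
  expect_false(v$rational)
  expect_identical(v$violated, "P1 + P2 - P12 <= 1")
  expect_true(boole_check(1, 1, 1)$rational)
})

test_that("rational polytope is the Boole tetrahedron with volume 1/6", {
  poly <- bistable_polytope(1)
  expect_equal(nrow(poly$vertices), 4L)
  want <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 1))
  got <- poly$vertices[order(poly$vertices[, 1], poly$vertices[, 2],
                             poly$vertices[, 3]), ]
  expect_equal(unname(got), want[order(want[, 1], want[, 2], want[, 3]), ],
               tolerance = 1e-10)
  # independent volume route: determinant of the spanning vectors / 6
  expect_equal(poly$volume, abs(det(want[2:4, ] - rep(want[1, ], each = 3))) / 6,
               tolerance = 1e-12)
  expect_equal(poly$volume, 1 / 6, tolerance = 1e-12)
})

test_that("maximal ambivalence decouples the joint: the box [0,1]^2 x [0,1/2]", {
  poly <- bistable_polytope(0.5)
  expect_equal(nrow(poly$vertices), 8L)
  expect_equal(range(poly$vertices[, 1]), c(0, 1))
  expect_equal(range(poly$vertices[, 2]), c(0, 1))
  expect_equal(range(poly$vertices[, 3]), c(0, 0.5))
  expect_equal(poly$volume, 0.5, tolerance = 1e-12)
})

test_that("double-description consistency and active half-spaces at k = 0.9", {
  for (k in c(1, 0.9, 0.75, 0.5)) {
    poly <- bistable_polytope(k)
    A <- do.call(rbind, lapply(poly$halfspaces, `[[`, "normal"))
    b <- vapply(poly$halfspaces, `[[`, 0, "offset")
    # every vertex satisfies every half-space
    expect_true(all(poly$vertices %*% t(A) <= rep(b, each = nrow(poly$vertices)) + 1e-9))
  }
  poly <- bistable_polytope(0.9)
  A <- do.call(rbind, lapply(poly$halfspaces, `[[`, "normal"))
  b <- vapply(poly$halfspaces, `[[`, 0, "offset")
  # each half-space supports at least one vertex (all constraints active)
  slack <- abs(poly$vertices %*% t(A) - rep(b, each = nrow(poly$vertices)))
  expect_true(all(apply(slack, 2, min) < 1e-9))
})

test_that("exact volumes agree with the Monte Carlo rejection oracle", {
  for (k in c(1, 0.8, 0.5)) {
    poly <- bistable_polytope(k)
    mc <- mc_volume_oracle(poly, n = 2e5, seed = 20 + round(10 * k))
    expect_lt(abs(poly$volume - mc$volume), 3 * mc$se)
  }
})

test_that("unit-box fixture exercises the geometry machinery exactly", {
  A <- rbind(diag(3), -diag(3))
  b <- c(1, 1, 1, 0, 0, 0)
  hs <- bistable:::dedupe_halfspaces(A, b)
  V <- bistable:::halfspace_vertices(hs$A, hs$b)
  expect_equal(nrow(V), 8L)
  expect_equal(bistable:::halfspace_volume(hs$A, hs$b, V), 1, tolerance = 1e-12)
})

test_that("PIIV is zero when rational and grows with irrationality", {
  expect_equal(piiv(1)$delta, 0, tolerance = 1e-12)
  expect_equal(piiv(0.5)$delta, 1 / 3, tolerance = 1e-12)
  expect_gt(piiv(0.9)$delta, 0)
  expect_lt(piiv(0.9)$delta, piiv(0.8)$delta)
  tab <- piiv_curve(seq(0.5, 1, 0.1))
  expect_equal(nrow(tab), 6L)
  expect_true(all(diff(tab$piiv) < 0))   # strictly decreasing toward k = 1
  expect_equal(tab$piiv[6], 0, tolerance = 1e-12)
  # order preserved as given, no hidden sorting
  rev_tab <- piiv_curve(rev(seq(0.5, 1, 0.1)))
  expect_equal(rev_tab$k, rev(tab$k))
  expect_equal(rev_tab$piiv, rev(tab$piiv))
  one <- piiv_curve(1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$piiv, 0, tolerance = 1e-12)
})

test_that("bistable regions grow in volume but clip the conjunction apex", {
  # the accessible region is NOT a superset of the rational tetrahedron:
  # at P1 = P2 = 1 the bistable constraints cap the joint at P12 <= k, so
  # the apex (1,1,1) lies outside every k < 1 region even though the
  # total volume grows as k falls
  v1 <- bistable_polytope(1)$vertices
  ord <- order(v1[, 1] + v1[, 2] + v1[, 3])
  base_verts <- v1[ord[1:3], , drop = FALSE]   # (0,0,0), (0,1,0), (1,0,0)
  apex <- v1[ord[4], ]                         # (1,1,1)
  for (k in c(0.5, 0.6, 0.75, 0.9, 0.99)) {
    poly <- bistable_polytope(k)
    A <- do.call(rbind, lapply(poly$halfspaces, `[[`, "normal"))
    b <- vapply(poly$halfspaces, `[[`, 0, "offset")
    expect_true(all(base_verts %*% t(A) <= rep(b, each = 3) + 1e-9))
    expect_false(all(A %*% apex <= b + 1e-9))
    # the clipped apex sits at P12 = k instead
    expect_true(all(A %*% c(1, 1, k) <= b + 1e-9))
    expect_gt(poly$volume, 1 / 6)
  }
})

test_that("points of the rational polytope admit convex vertex weights", {
  w <- convex_weights(c(0, 0, 0))
  expect_true(w$feasible)
  expect_equal(w$lambda, c(1, 0, 0, 0))
  set.seed(33)
  verts <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 1))
  for (i in 1:50) {
    lam <- rexp(4); lam <- lam / sum(lam)     # uniform-ish interior point
    pt <- as.numeric(lam %*% verts)
    w <- convex_weights(pt)
    expect_true(w$feasible)
    expect_equal(sum(w$lambda), 1, tolerance = 1e-12)
    expect_equal(w$lambda, lam, tolerance = 1e-9)
  }
  expect_false(convex_weights(c(0.9, 0.9, 0))$feasible)  # outside the tetrahedron
})
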