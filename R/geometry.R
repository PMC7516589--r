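# Minimal exact 3-D half-space geometry: vertex enumeration by plane-triple
# intersection, double-description consistency, and hull volume by face
# fan-triangulation.  Deterministic; no Monte Carlo.  (No qhull binding is
# available in the target environment, and the regions here are tiny --
# at most a dozen half-spaces -- so brute-force enumeration is exact and fast.)

# Normalize rows to unit normals and drop duplicates (same plane, same side).
dedupe_halfspaces <- function(A, b, tol = 1e-9) {
  nrm <- sqrt(rowSums(A^2))
  if (any(nrm < tol)) {
    keep0 <- nrm >= tol
    # a zero normal with b >= 0 is vacuous; with b < 0 infeasible
    if (any(b[!keep0] < -tol)) stop("infeasible half-space system", call. = FALSE)
    A <- A[keep0, , drop = FALSE]; b <- b[keep0]; nrm <- nrm[keep0]
  }
  A <- A / nrm
  b <- b / nrm
  keep <- rep(TRUE, nrow(A))
  for (i in seq_len(nrow(A))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(A))) {
      if (j <= i || !keep[j]) next
      if (max(abs(A[i, ] - A[j, ])) < tol) {
        # parallel same-direction: keep the tighter offset
        if (b[j] >= b[i]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  list(A = A[keep, , drop = FALSE], b = b[keep])
}

# All vertices of {x : A x <= b} in R^3 by intersecting plane triples.
halfspace_vertices <- function(A, b, tol = 1e-9) {
  m <- nrow(A)
  if (m < 3L) stop("need at least 3 half-spaces for a bounded 3-D region", call. = FALSE)
  verts <- list()
  combs <- utils::combn(m, 3L)
  for (jj in seq_len(ncol(combs))) {
    idx <- combs[, jj]
    M <- A[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- as.numeric(solve(M, b[idx]))
    if (all(A %*% x <= b + tol)) verts[[length(verts) + 1L]] <- x
  }
  if (length(verts) == 0L) return(matrix(numeric(0), 0L, 3L))
  V <- do.call(rbind, verts)
  # tolerance dedupe
  keep <- rep(TRUE, nrow(V))
  for (i in seq_len(nrow(V))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(V))) {
      if (j > i && keep[j] && max(abs(V[i, ] - V[j, ])) < 1e-8) keep[j] <- FALSE
    }
  }
  V[keep, , drop = FALSE]
}

# Order the vertices of a planar convex face counterclockwise around its
# centroid (in-plane angle sort).
order_face <- function(F, normal) {
  ctr <- colMeans(F)
  # orthonormal in-plane basis
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  rel <- sweep(F, 2, ctr)
  ang <- atan2(rel %*% v, rel %*% u)
  F[order(ang), , drop = FALSE]
}

# Exact volume of the bounded region {A x <= b} with vertex set V:
# fan-triangulate each face about its centroid, tetrahedra to the body
# centroid, sum |det|/6.
halfspace_volume <- function(A, b, V, tol = 1e-7) {
  if (nrow(V) < 4L) return(0)
  c0 <- colMeans(V)
  vol <- 0
  for (i in seq_len(nrow(A))) {
    on_face <- which(abs(V %*% A[i, ] - b[i]) < tol)
    if (length(on_face) < 3L) next
    F <- order_face(V[on_face, , drop = FALSE], A[i, ])
    fc <- colMeans(F)
    nf <- nrow(F)
    for (t in seq_len(nf)) {
      p1 <- F[t, ]
      p2 <- F[if (t == nf) 1L else t + 1L, ]
      vol <- vol + abs(det(rbind(p1 - c0, p2 - c0, fc - c0))) / 6
    }
  }
  vol
}
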