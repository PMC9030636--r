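# Triangle-mesh primitives used by the membrane templates: face normals,
# orientation bookkeeping, boundary-edge detection and exact closest-point
# queries. Meshes are plain lists (vertices: n x 3 mm, faces: m x 3 1-based
# integer indices); no external mesh library is required.

face_normals <- function(vertices, faces, normalize = TRUE) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  n <- cross3(b - a, c_ - a)
  if (normalize) {
    len <- row_norms(n)
    if (any(len <= 0)) stop("mesh contains degenerate (zero-area) faces")
    n <- n / len
  }
  n
}

# Flip face winding so every face normal has a positive z component in the
# template frame. The scala-vestibuli side is defined as the +z-leaning side
# of the ribbon, so a globally consistent orientation is required for signed
# distances.
orient_faces_up <- function(vertices, faces) {
  n <- face_normals(vertices, faces)
  flip <- n[, 3] < 0
  if (any(flip)) {
    tmp <- faces[flip, 2]
    faces[flip, 2] <- faces[flip, 3]
    faces[flip, 3] <- tmp
  }
  faces
}

# Edges belonging to exactly one face (the open boundary of the ribbon).
boundary_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  keep <- key %in% names(tab)[tab == 1L]
  unique(cbind(pmin(e[keep, 1], e[keep, 2]), pmax(e[keep, 1], e[keep, 2])))
}

# Closest point on a segment set for one query point; segments given by
# endpoint matrices a, b (k x 3). Returns list(dist2, point, u).
closest_on_segments <- function(p, a, b) {
  ab <- b - a
  denom <- rowSums(ab * ab)
  denom[denom == 0] <- 1
  u <- clamp(rowSums(sweep(-a, 2, p, "+") * ab) / denom, 0, 1)
  q <- a + ab * u
  d2 <- rowSums(sweep(q, 2, p, "-")^2)
  list(d2 = d2, q = q, u = u)
}

# Exact closest point on a triangulated surface for each query point.
# For every face the candidate is the interior plane projection when its
# barycentric coordinates are non-negative, otherwise the nearest point on
# one of the three edges; the per-face minimum is then minimized over faces.
# Returns, per query point: distance, closest point, face index and the
# barycentric coordinates (w, s, t) of the closest point in that face.
closest_point_mesh <- function(points, vertices, faces) {
  points <- as_point_matrix(points)
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e0 <- b - a
  e1 <- c_ - a
  aa <- rowSums(e0 * e0)
  bb <- rowSums(e0 * e1)
  cc <- rowSums(e1 * e1)
  det <- aa * cc - bb * bb
  det[det <= 0] <- NA_real_  # degenerate faces guarded elsewhere

  np <- nrow(points)
  out_dist <- numeric(np)
  out_q <- matrix(0, np, 3L)
  out_face <- integer(np)
  out_bary <- matrix(0, np, 3L)

  for (i in seq_len(np)) {
    p <- points[i, ]
    d <- sweep(a, 2, p, "-")
    dd <- rowSums(e0 * d)
    ee <- rowSums(e1 * d)
    s <- (bb * ee - cc * dd) / det
    t <- (bb * dd - aa * ee) / det
    inside <- !is.na(s) & s >= 0 & t >= 0 & (s + t) <= 1
    q_int <- a + e0 * s + e1 * t
    d2_int <- rowSums(sweep(q_int, 2, p, "-")^2)
    d2_int[!inside] <- Inf

    s_ab <- closest_on_segments(p, a, b)
    s_bc <- closest_on_segments(p, b, c_)
    s_ca <- closest_on_segments(p, c_, a)

    d2 <- pmin(d2_int, s_ab$d2, s_bc$d2, s_ca$d2)
    f <- which.min(d2)
    pick <- which.min(c(d2_int[f], s_ab$d2[f], s_bc$d2[f], s_ca$d2[f]))
    q <- switch(pick,
                q_int[f, ],
                s_ab$q[f, ],
                s_bc$q[f, ],
                s_ca$q[f, ])
    bar <- switch(pick,
                  c(1 - s[f] - t[f], s[f], t[f]),
                  c(1 - s_ab$u[f], s_ab$u[f], 0),
                  c(0, 1 - s_bc$u[f], s_bc$u[f]),
                  c(s_ca$u[f], 0, 1 - s_ca$u[f]))
    out_dist[i] <- sqrt(max(d2[f], 0))
    out_q[i, ] <- q
    out_face[i] <- f
    out_bary[i, ] <- bar
  }
  list(dist = out_dist, point = out_q, face = out_face, bary = out_bary)
}

# TRUE when the closest point returned by closest_point_mesh() lies on an
# open-boundary edge (or boundary vertex) of the mesh: queries overhanging
# the ribbon edge, where the tangent-plane sign is an extrapolation.
on_boundary_edge <- function(cp, vertices, bedges, tol = 1e-7) {
  if (nrow(bedges) == 0L) return(rep(FALSE, length(cp$face)))
  a <- vertices[bedges[, 1], , drop = FALSE]
  b <- vertices[bedges[, 2], , drop = FALSE]
  vapply(seq_along(cp$face), function(i) {
    min(closest_on_segments(cp$point[i, ], a, b)$d2) < tol^2
  }, logical(1))
}
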