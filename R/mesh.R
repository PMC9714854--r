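#' Triangle mesh
#'
#' A specimen's 3D surface: an n x 3 matrix of vertex coordinates (mm) and an
#' m x 3 integer matrix of 1-based vertex indices, one row per triangle.
#' Vertex order is meaningful (subsampling and landmark anchoring are defined
#' in vertex order) and is preserved by all I/O.
#'
#' @param vertices numeric matrix, n x 3, finite coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param name specimen identifier.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, name = name),
                    class = "triangle_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh, file = NULL) {
  where <- if (is.null(file)) mesh$name else file
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3 || nrow(v) < 4)
    stopf("invalid mesh '%s': need >= 4 vertices with 3 coordinates each", where)
  if (!all(is.finite(v)))
    stopf("invalid mesh '%s': non-finite vertex coordinates", where)
  if (!is.matrix(f) || ncol(f) != 3 || nrow(f) < 1)
    stopf("invalid mesh '%s': need >= 1 triangular face", where)
  if (any(f < 1L) || any(f > nrow(v)))
    stopf("invalid mesh '%s': face index out of range (vertices: %d)", where, nrow(v))
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# per-vertex normals: area-weighted average of incident face normals,
# oriented away from the mesh centroid
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    for (d in 1:3) n[, d] <- n[, d] + tapply_add(idx, fn[, d], nrow(v))
  }
  len <- row_norms(n)
  len[len < 1e-30] <- 1
  n <- n / len
  ctr <- colMeans(v)
  out <- rowSums(n * sweep(v, 2, ctr))
  flip <- out < 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  n
}

tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# closest point on the triangle surface of `mesh` for each row of `pts`
# (Ericson's closest-point-on-triangle, vectorised over faces per query point)
project_points_to_mesh <- function(pts, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  out <- matrix(NA_real_, nrow(pts), 3)
  for (i in seq_len(nrow(pts))) {
    cp <- closest_on_triangles(pts[i, ], a, b, c_)
    d2 <- rowSums((cp - matrix(pts[i, ], nrow(cp), 3, byrow = TRUE))^2)
    out[i, ] <- cp[which.min(d2), ]
  }
  out
}

closest_on_triangles <- function(p, a, b, c_) {
  m <- nrow(a)
  pm <- matrix(p, m, 3, byrow = TRUE)
  ab <- b - a
  ac <- c_ - a
  ap <- pm - a
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- pm - c_
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  res <- matrix(NA_real_, m, 3)
  done <- rep(FALSE, m)
  set <- function(mask, val) {
    mask <- mask & !done
    res[mask, ] <<- val[mask, , drop = FALSE]
    done[mask] <<- TRUE
  }
  set(d1 <= 0 & d2 <= 0, a)                                   # vertex a
  set(d3 >= 0 & d4 <= d3, b)                                  # vertex b
  set(d6 >= 0 & d5 <= d6, c_)                                 # vertex c
  vv <- d1 / pmax(d1 - d3, 1e-300)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * vv)               # edge ab
  ww <- d2 / pmax(d2 - d6, 1e-300)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * ww)               # edge ac
  w2 <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c_ - b) * w2)  # edge bc
  denom <- va + vb + vc
  denom[abs(denom) < 1e-300] <- 1e-300
  vbar <- vb / denom
  wbar <- vc / denom
  set(rep(TRUE, m), a + ab * vbar + ac * wbar)                # face interior
  res
}
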