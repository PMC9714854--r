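#' Sparse point cloud
#'
#' A set of 3D points subsampled from a mesh (or given directly), with the
#' spacing threshold used to create it recorded when known.
#'
#' @param points numeric matrix, P x 3 (mm).
#' @param source specimen identifier the cloud derives from.
#' @param spacing minimum pairwise spacing (mm) used at creation, or NULL.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, source = "cloud", spacing = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || nrow(points) < 1)
    stopf("point cloud must be a P x 3 matrix with P >= 1")
  if (!all(is.finite(points)))
    stopf("point cloud '%s': non-finite coordinates", source)
  dimnames(points) <- NULL
  structure(list(points = points, source = source, spacing = spacing),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud '%s': %d points%s>\n", x$source, nrow(x$points),
              if (is.null(x$spacing)) "" else
                sprintf(", spacing %.4g mm", x$spacing)))
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

as_points <- function(x) {
  if (inherits(x, "triangle_mesh")) x$vertices
  else if (inherits(x, "point_cloud")) x$points
  else as.matrix(x)
}

source_id <- function(x) {
  if (inherits(x, "triangle_mesh")) x$name
  else if (inherits(x, "point_cloud")) x$source
  else "cloud"
}

#' Subsample points by a minimum-spacing rule
#'
#' Greedy keep-first scan in vertex order: a point is retained iff it lies at
#' least `spacing` from every previously retained point. Deterministic; the
#' retained points are a subset of the input and no two retained points are
#' closer than `spacing`.
#'
#' @param x a [triangle_mesh()], [point_cloud()] or P x 3 matrix.
#' @param spacing minimum pairwise distance (mm); `0` keeps every point.
#' @return a [point_cloud()] with the spacing recorded.
#' @export
subsample_by_spacing <- function(x, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing < 0)
    stopf("spacing must be a single non-negative number")
  pts <- as_points(x)
  n <- nrow(pts)
  if (n < 1) stopf("cannot subsample an empty input")
  if (spacing == 0)
    return(point_cloud(pts, source = source_id(x), spacing = 0))
  s2 <- (spacing * (1 - 1e-9))^2
  kx <- numeric(n); ky <- numeric(n); kz <- numeric(n)
  keep_idx <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (k == 0L) {
      ok <- TRUE
    } else {
      d2 <- (kx[1:k] - pts[i, 1])^2 + (ky[1:k] - pts[i, 2])^2 +
        (kz[1:k] - pts[i, 3])^2
      ok <- all(d2 >= s2)
    }
    if (ok) {
      k <- k + 1L
      kx[k] <- pts[i, 1]; ky[k] <- pts[i, 2]; kz[k] <- pts[i, 3]
      keep_idx[k] <- i
    }
  }
  if (n >= 3 && k < 3)
    stopf("fewer than 3 points survive subsampling at spacing %.4g", spacing)
  point_cloud(pts[keep_idx[1:k], , drop = FALSE], source = source_id(x),
              spacing = spacing)
}

#' Closest-point correspondence against a target mesh
#'
#' For each point of `reference`, extracts the nearest vertex of `target`
#' (ties broken by lowest vertex index). The output cloud is row-correspondent
#' with `reference`. Caller is responsible for prior rigid alignment.
#'
#' @param reference a [point_cloud()].
#' @param target a [triangle_mesh()] (or point cloud of candidate points).
#' @return a [point_cloud()] with exactly as many points as `reference`.
#' @export
closest_point_correspondence <- function(reference, target) {
  ref <- as_points(reference)
  tgt <- as_points(target)
  if (nrow(tgt) < 1) stopf("empty target in closest-point correspondence")
  idx <- nn_index(ref, tgt)
  point_cloud(tgt[idx, , drop = FALSE], source = source_id(target),
              spacing = NULL)
}

#' Tune the subsampling spacing to reach a target point count
#'
#' Bisects the spacing until the subsample size is within
#' `target_count +/- tol_count`, or 50 iterations.
#'
#' @param x mesh, cloud or matrix of points.
#' @param target_count desired cloud size (>= 3).
#' @param tol_count acceptable deviation from `target_count`.
#' @return a list with elements `spacing` (mm) and `count` (achieved size).
#' @export
tune_spacing <- function(x, target_count, tol_count = max(1L, round(target_count / 20))) {
  if (target_count < 3) stopf("target_count must be >= 3")
  pts <- as_points(x)
  n <- nrow(pts)
  if (n < target_count - tol_count)
    stopf("unreachable count: input has %d points, target %d +/- %d",
          n, target_count, tol_count)
  if (n <= target_count + tol_count)
    return(list(spacing = 0, count = n))
  lo <- 0                      # count(n) at lo
  hi <- bbox_diagonal(pts)     # few points at hi
  count_at <- function(s) {
    cl <- tryCatch(subsample_by_spacing(pts, s), error = function(e) NULL)
    if (is.null(cl)) 0L else nrow(cl$points)
  }
  best <- NULL
  for (it in seq_len(50)) {
    mid <- (lo + hi) / 2
    cnt <- count_at(mid)
    if (is.null(best) || abs(cnt - target_count) < abs(best$count - target_count))
      best <- list(spacing = mid, count = cnt)
    if (cnt >= target_count - tol_count && cnt <= target_count + tol_count)
      return(list(spacing = mid, count = cnt))
    if (cnt > target_count) lo <- mid else hi <- mid
  }
  stopf("spacing tuning did not reach %d +/- %d points (best achieved: %d)",
        target_count, tol_count, best$count)
}
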