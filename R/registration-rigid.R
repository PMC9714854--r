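#' Similarity (rigid + uniform scale) transform
#'
#' Maps a point x to `scale * R x + t`, points as rows: `s * X R^T + t`.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector (mm).
#' @param scale positive scalar; 1 for a pure rigid motion.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stopf("rotation must be a 3 x 3 orthonormal matrix")
  if (det(rotation) <= 0) stopf("rotation must have det +1 (no reflection)")
  if (scale <= 0) stopf("scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: scale %.6g, translation (%.4g, %.4g, %.4g)>\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform a [rigid_transform()].
#' @param pts P x 3 matrix, [point_cloud()] or [triangle_mesh()] vertices.
#' @return transformed P x 3 matrix.
#' @export
transform_points <- function(transform, pts) {
  p <- as_points(pts)
  sweep(transform$scale * (p %*% t(transform$rotation)), 2,
        transform$translation, "+")
}

#' Serialize / deserialize a transform as JSON
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  doc <- list(rotation = as.vector(t(transform$rotation)),  # row-major
              translation = transform$translation,
              scale = transform$scale)
  writeLines(jsonlite::toJSON(doc, digits = 12), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- jsonlite::fromJSON(path)
  rigid_transform(matrix(doc$rotation, 3, 3, byrow = TRUE), doc$translation,
                  doc$scale)
}

# least-squares similarity transform X -> Y (paired rows), Umeyama-style,
# rotation-only orthogonal Procrustes with determinant correction
fit_similarity <- function(X, Y, allow_scale = TRUE, scale_limits = c(0.2, 5)) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stopf("degenerate geometry: correspondence set is (near-)collinear")
  dsign <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, dsign))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * c(1, 1, dsign)) / sum(Xc^2) else 1
  s <- min(max(s, scale_limits[1]), scale_limits[2])
  t <- my - s * as.vector(R %*% mx)
  rigid_transform(R, t, s)
}

#' Parameters for feature-based global rigid alignment
#'
#' Descriptor radii are expressed as multiples of the cloud spacing
#' (estimated from the median nearest-neighbor distance when not recorded).
#'
#' @param normal_radius_factor neighborhood radius for normal estimation.
#' @param feature_radius_factor neighborhood radius for FPFH features.
#' @param n_bins histogram bins per FPFH angle.
#' @param ransac_n correspondences per RANSAC sample.
#' @param inlier_factor inlier threshold as a multiple of spacing.
#' @param max_trials RANSAC trial budget.
#' @param confidence early-stop confidence for adaptive RANSAC.
#' @param allow_scale estimate a uniform scale (clamped to `scale_limits`).
#' @param scale_limits admissible scale range.
#' @param seed RNG seed driving RANSAC sampling.
#' @return a list of class `rigid_params`.
#' @export
rigid_params <- function(normal_radius_factor = 2, feature_radius_factor = 5,
                         n_bins = 11, ransac_n = 4, inlier_factor = 1.5,
                         max_trials = 2000, confidence = 0.999,
                         allow_scale = TRUE, scale_limits = c(0.2, 5),
                         restarts = 3, seed = 42) {
  structure(list(normal_radius_factor = normal_radius_factor,
                 feature_radius_factor = feature_radius_factor,
                 n_bins = n_bins, ransac_n = ransac_n,
                 inlier_factor = inlier_factor, max_trials = max_trials,
                 confidence = confidence, allow_scale = allow_scale,
                 scale_limits = scale_limits, restarts = restarts,
                 seed = seed),
            class = "rigid_params")
}

estimate_spacing <- function(pts) {
  d2 <- pdist2(pts, pts)
  diag(d2) <- Inf
  stats::median(sqrt(apply(d2, 1, min)))
}

# normals by local plane fit (PCA of radius neighborhoods), oriented away
# from the cloud centroid
cloud_normals <- function(pts, radius) {
  d2 <- pdist2(pts, pts)
  r2 <- radius^2
  n <- nrow(pts)
  normals <- matrix(0, n, 3)
  ctr <- colMeans(pts)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= r2)
    if (length(nb) < 5) nb <- order(d2[i, ])[1:min(6, n)]
    nbp <- pts[nb, , drop = FALSE]
    cov <- crossprod(sweep(nbp, 2, colMeans(nbp)))
    ev <- eigen(cov, symmetric = TRUE)
    nv <- ev$vectors[, 3]
    if (sum(nv * (pts[i, ] - ctr)) < 0) nv <- -nv
    normals[i, ] <- nv
  }
  normals
}

# Fast point feature histograms (simplified): per point, histogram the
# Darboux-frame angles (alpha, phi, theta) over radius neighbors, then blend
# neighbors' histograms weighted by inverse distance.
fpfh_features <- function(pts, normals, radius, n_bins = 11) {
  n <- nrow(pts)
  d2 <- pdist2(pts, pts)
  r2 <- radius^2
  spfh <- matrix(0, n, 3 * n_bins)
  nb_list <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- setdiff(which(d2[i, ] <= r2), i)
    nb_list[[i]] <- nb
    if (!length(nb)) next
    diff <- pts[nb, , drop = FALSE] -
      matrix(pts[i, ], length(nb), 3, byrow = TRUE)
    dist <- sqrt(rowSums(diff^2))
    dist[dist < 1e-12] <- 1e-12
    d <- diff / dist
    u <- normals[i, ]
    v <- cbind(u[2] * d[, 3] - u[3] * d[, 2],
               u[3] * d[, 1] - u[1] * d[, 3],
               u[1] * d[, 2] - u[2] * d[, 1])
    vlen <- row_norms(v)
    vlen[vlen < 1e-12] <- 1e-12
    v <- v / vlen
    w <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
               u[3] * v[, 1] - u[1] * v[, 3],
               u[1] * v[, 2] - u[2] * v[, 1])
    n2 <- normals[nb, , drop = FALSE]
    alpha <- rowSums(v * n2)                        # in [-1, 1]
    phi <- d %*% u                                  # in [-1, 1]
    theta <- atan2(rowSums(w * n2), n2 %*% u)       # in [-pi, pi]
    b1 <- bin_clamp(alpha, -1, 1, n_bins)
    b2 <- bin_clamp(phi, -1, 1, n_bins)
    b3 <- bin_clamp(theta, -pi, pi, n_bins)
    h <- numeric(3 * n_bins)
    for (j in seq_along(nb)) {
      h[b1[j]] <- h[b1[j]] + 1
      h[n_bins + b2[j]] <- h[n_bins + b2[j]] + 1
      h[2 * n_bins + b3[j]] <- h[2 * n_bins + b3[j]] + 1
    }
    spfh[i, ] <- h / length(nb)
  }
  fpfh <- spfh
  for (i in seq_len(n)) {
    nb <- nb_list[[i]]
    if (!length(nb)) next
    wts <- 1 / pmax(sqrt(d2[i, nb]), 1e-12)
    fpfh[i, ] <- spfh[i, ] +
      colSums(spfh[nb, , drop = FALSE] * wts) / length(nb)
  }
  sums <- rowSums(fpfh)
  sums[sums < 1e-12] <- 1
  fpfh / sums
}

bin_clamp <- function(x, lo, hi, n_bins) {
  b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Global rigid alignment by feature matching and RANSAC
#'
#' Estimates a similarity transform from `source` to `target` by matching
#' FPFH-style local descriptors and robustly fitting over candidate
#' correspondences with RANSAC (within a restart, best transform by inlier
#' count with ties broken by inlier RMS). Because near-symmetric shapes can
#' make descriptor matches pose-ambiguous, the RANSAC stage is restarted
#' `params$restarts` times and the candidates are disambiguated by the
#' nearest-neighbor RMS after a short ICP polish — the flipped pose of a
#' near-symmetric shape matches features but fits the surface worse. Both
#' clouds must have at least 10 points.
#'
#' @param source,target [point_cloud()] objects.
#' @param params a [rigid_params()] list.
#' @return a [rigid_transform()] mapping source onto target.
#' @export
global_rigid_align <- function(source, target, params = rigid_params()) {
  prep <- prepare_feature_matches(source, target, params)
  cands <- list()
  errs <- character(0)
  for (r in seq_len(max(1L, params$restarts))) {
    p <- params
    p$seed <- params$seed + (r - 1L) * 7919L
    cand <- tryCatch(ransac_from_matches(prep, p),
                     error = function(e) e)
    if (inherits(cand, "error")) errs <- c(errs, conditionMessage(cand))
    else cands[[length(cands) + 1L]] <- cand
  }
  if (!length(cands)) stop(errs[1], call. = FALSE)
  cands <- c(cands, principal_axes_candidates(source, target))
  if (length(cands) == 1L) return(cands[[1]])
  S <- as_points(source)
  T_ <- as_points(target)
  score <- vapply(cands, function(tf) {
    polished <- icp_refine(source, target, tf, max_iter = 10, tol = 1e-6,
                           allow_scale = params$allow_scale)
    moved <- transform_points(polished, S)
    sqrt(mean(pdist2(moved, T_)[cbind(seq_len(nrow(S)),
                                      nn_index(moved, T_))]))
  }, 1)
  cands[[which.min(score)]]
}

# coarse principal-axes alignment hypotheses: rotate source axes onto target
# axes under the four proper axis-sign combinations; the subsequent ICP-RMS
# scoring picks the physically correct one
principal_axes_candidates <- function(source, target) {
  S <- as_points(source)
  T_ <- as_points(target)
  cs <- colMeans(S)
  ct <- colMeans(T_)
  es <- eigen(stats::cov(S), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(T_), symmetric = TRUE)$vectors
  if (det(es) < 0) es[, 3] <- -es[, 3]
  if (det(et) < 0) et[, 3] <- -et[, 3]
  s <- sqrt(sum(sweep(T_, 2, ct)^2) / sum(sweep(S, 2, cs)^2))
  out <- list()
  for (fl in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    cand <- tryCatch({
      R <- et %*% diag(fl) %*% t(es)
      rigid_transform(R, ct - s * as.vector(R %*% cs), s)
    }, error = function(e) NULL)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

# descriptor computation and matching, shared by all RANSAC restarts
prepare_feature_matches <- function(source, target, params) {
  S <- as_points(source)
  T_ <- as_points(target)
  if (nrow(S) < 10 || nrow(T_) < 10)
    stopf("global alignment needs >= 10 points per cloud (got %d and %d)",
          nrow(S), nrow(T_))
  sp_s <- if (inherits(source, "point_cloud")) source$spacing else NULL
  sp_t <- if (inherits(target, "point_cloud")) target$spacing else NULL
  if (is.null(sp_s) || sp_s <= 0) sp_s <- estimate_spacing(S)
  if (is.null(sp_t) || sp_t <= 0) sp_t <- estimate_spacing(T_)

  ns <- cloud_normals(S, params$normal_radius_factor * sp_s)
  nt <- cloud_normals(T_, params$normal_radius_factor * sp_t)
  fs <- fpfh_features(S, ns, params$feature_radius_factor * sp_s, params$n_bins)
  ft <- fpfh_features(T_, nt, params$feature_radius_factor * sp_t, params$n_bins)
  match_idx <- nn_index(fs, ft)       # candidate target for each source point
  list(S = S, T_ = T_, sp_s = sp_s, sp_t = sp_t, match_idx = match_idx,
       corr_t = T_[match_idx, , drop = FALSE])
}

ransac_from_matches <- function(prep, params) {
  S <- prep$S
  T_ <- prep$T_
  sp_s <- prep$sp_s
  sp_t <- prep$sp_t
  match_idx <- prep$match_idx
  corr_t <- prep$corr_t

  thr2 <- (params$inlier_factor * sp_t)^2
  n <- nrow(S)
  m <- params$ransac_n
  best <- list(count = -1L, rms = Inf, inliers = NULL)
  withr::with_seed(params$seed, {
    trials_needed <- params$max_trials
    trial <- 0L
    while (trial < min(params$max_trials, trials_needed)) {
      trial <- trial + 1L
      idx <- sample.int(n, m)
      if (anyDuplicated(match_idx[idx])) next
      Xs <- S[idx, , drop = FALSE]
      Ys <- corr_t[idx, , drop = FALSE]
      # edge-length compatibility pruning (ratios consistent up to 30%)
      ds <- sqrt(pdist2(Xs, Xs))[upper.tri(diag(m))]
      dt <- sqrt(pdist2(Ys, Ys))[upper.tri(diag(m))]
      if (any(ds < 0.5 * sp_s)) next
      ratio <- dt / ds
      if (max(ratio) > 1.3 * min(ratio)) next
      tf <- tryCatch(fit_similarity(Xs, Ys, params$allow_scale,
                                    params$scale_limits),
                     error = function(e) NULL)
      if (is.null(tf)) next
      moved <- transform_points(tf, S)
      res2 <- rowSums((moved - corr_t)^2)
      inl <- res2 < thr2
      cnt <- sum(inl)
      if (cnt >= 3) {
        rms <- sqrt(mean(res2[inl]))
        if (cnt > best$count || (cnt == best$count && rms < best$rms)) {
          best <- list(count = cnt, rms = rms, inliers = which(inl))
          frac <- cnt / n
          trials_needed <- if (frac >= 1) 1 else
            ceiling(log(1 - params$confidence) /
                    log(max(1 - frac^m, 1e-12)))
        }
      }
    }
  })
  if (best$count < 3)
    stopf("global alignment failed to converge: no correspondence set with >= 3 inliers")
  fit_similarity(S[best$inliers, , drop = FALSE],
                 corr_t[best$inliers, , drop = FALSE],
                 params$allow_scale, params$scale_limits)
}

#' Refine an alignment with iterative closest point
#'
#' Point-to-point ICP with similarity (scale-allowing) refits against nearest
#' neighbors in the target cloud. The inlier RMS is monotone non-increasing
#' across iterations; the per-iteration values are attached as attribute
#' `rms_history`.
#'
#' @param source,target [point_cloud()] objects.
#' @param init initial [rigid_transform()].
#' @param max_iter iteration budget; `0` returns `init` unchanged.
#' @param tol stop when the RMS improves by less than this (mm).
#' @param allow_scale refit uniform scale as well.
#' @return a [rigid_transform()] with attribute `rms_history`.
#' @export
icp_refine <- function(source, target, init = rigid_transform(),
                       max_iter = 50, tol = 1e-8, allow_scale = TRUE) {
  stopifnot(inherits(init, "rigid_transform"))
  S <- as_points(source)
  T_ <- as_points(target)
  tf <- init
  history <- numeric(0)
  prev <- Inf
  if (max_iter >= 1) {
    for (it in seq_len(max_iter)) {
      cur <- transform_points(tf, S)
      j <- nn_index(cur, T_)
      corr <- T_[j, , drop = FALSE]
      rms <- sqrt(mean(rowSums((cur - corr)^2)))
      history <- c(history, rms)
      if (prev - rms < tol) break
      prev <- rms
      tf <- fit_similarity(S, corr, allow_scale)
    }
  }
  attr(tf, "rms_history") <- history
  tf
}
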