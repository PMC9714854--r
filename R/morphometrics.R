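#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the standard geometric-morphometrics size measure. Invariant to
#' translation and rotation, homogeneous of degree 1 in scale.
#'
#' @param x a [landmark_set()], [point_cloud()] or L x 3 matrix with L >= 2.
#' @return centroid size (mm).
#' @export
centroid_size <- function(x) {
  m <- if (inherits(x, "landmark_set")) x$coords else as_points(x)
  if (nrow(m) < 2) stopf("centroid size needs at least 2 landmarks")
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

# rotation-only orthogonal Procrustes: rotation R (det +1) minimizing
# || A R - B ||_F
procrustes_rotation <- function(A, B) {
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of K correspondent configurations: each is
#' centered, optionally scaled to unit centroid size, and rotated (rotation
#' only, no reflection) to the current mean shape until the mean stabilizes.
#' The final orientation is canonicalized to the mean shape's principal axes
#' (signs fixed by third moments) so the output does not depend on the
#' specimens' original poses.
#'
#' @param configs list of L x 3 matrices / [landmark_set()]s, or a
#'   K x L x 3 array. K >= 2, equal L.
#' @param scale scale each configuration to unit centroid size (classical
#'   GM convention). Centroid sizes are recorded before scaling either way.
#' @param max_iter,tol iteration controls on the mean-shape change.
#' @return an object of class `gpa_result` with fields `aligned`
#'   (K x L x 3), `mean_shape`, `centroid_sizes`, `scaled`, `iterations`,
#'   `ids`.
#' @export
gpa <- function(configs, scale = TRUE, max_iter = 100, tol = 1e-10) {
  arr <- configs_to_array(configs)
  K <- dim(arr)[1]
  L <- dim(arr)[2]
  if (K < 2) stopf("GPA needs at least 2 configurations")
  if (L < 3) stopf("GPA needs at least 3 landmarks")
  ids <- dimnames(arr)[[1]] %||% paste0("config", seq_len(K))

  sizes <- numeric(K)
  X <- vector("list", K)
  for (i in seq_len(K)) {
    m <- arr[i, , ]
    m <- sweep(m, 2, colMeans(m))
    sizes[i] <- sqrt(sum(m^2))
    if (sizes[i] < 1e-12)
      stopf("degenerate configuration '%s': all landmarks coincident", ids[i])
    X[[i]] <- if (scale) m / sizes[i] else m
  }

  mean_shape <- X[[1]]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(K)) X[[i]] <- X[[i]] %*% procrustes_rotation(X[[i]], mean_shape)
    new_mean <- Reduce(`+`, X) / K
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }

  # canonical orientation: principal axes of the mean shape, signs fixed by
  # third moments of the projections (rotation-invariant), right-handed
  ev <- eigen(crossprod(mean_shape), symmetric = TRUE)$vectors
  for (j in 1:2) {
    s3 <- sum((mean_shape %*% ev[, j])^3)
    if (abs(s3) < 1e-12) {
      if (ev[which.max(abs(ev[, j])), j] < 0) ev[, j] <- -ev[, j]
    } else if (s3 < 0) ev[, j] <- -ev[, j]
  }
  ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
               ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
               ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  mean_shape <- mean_shape %*% ev
  aligned <- array(NA_real_, c(K, L, 3), dimnames = list(ids, NULL, NULL))
  for (i in seq_len(K)) aligned[i, , ] <- X[[i]] %*% ev

  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = stats::setNames(sizes, ids),
                 scaled = scale, iterations = iterations, ids = ids),
            class = "gpa_result")
}

configs_to_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3) return(configs)
  if (!is.list(configs)) stopf("configs must be a list or a K x L x 3 array")
  mats <- lapply(configs, function(x)
    if (inherits(x, "landmark_set")) x$coords else as_points(x))
  L <- unique(vapply(mats, nrow, 1L))
  if (length(L) != 1)
    stopf("configurations differ in landmark count: %s",
          paste(sort(L), collapse = ", "))
  ids <- names(configs) %||% vapply(seq_along(configs), function(i) {
    x <- configs[[i]]
    if (inherits(x, "landmark_set")) x$specimen
    else if (inherits(x, "point_cloud")) x$source
    else paste0("config", i)
  }, "")
  arr <- array(NA_real_, c(length(mats), L, 3), dimnames = list(ids, NULL, NULL))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("<gpa_result: %d configurations, %d landmarks, %s, %d iterations>\n",
              dim(x$aligned)[1], dim(x$aligned)[2],
              if (x$scaled) "scaled to unit centroid size" else "unscaled",
              x$iterations))
  invisible(x)
}

#' @export
tidy.gpa_result <- function(x, ...) {
  tibble::tibble(specimen = x$ids,
                 centroid_size = unname(x$centroid_sizes))
}

#' Pairwise Procrustes distance matrix
#'
#' Entry (i, j) is the Euclidean norm of the difference between aligned
#' configurations i and j; symmetric with a zero diagonal.
#'
#' @param g a `gpa_result`.
#' @return K x K symmetric matrix.
#' @export
procrustes_distance_matrix <- function(g) {
  stopifnot(inherits(g, "gpa_result"))
  K <- dim(g$aligned)[1]
  flat <- matrix(g$aligned, nrow = K)
  d <- as.matrix(stats::dist(flat))
  dimnames(d) <- list(g$ids, g$ids)
  d
}

#' PCA of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the flattened aligned
#' coordinates. The number of components is `min(K - 1, 3L)`; eigenvalues are
#' non-negative and non-increasing and sum to the total variance of the
#' centered coordinates.
#'
#' @param g a `gpa_result` with K >= 3 configurations.
#' @return an object of class `pca_result` with `scores` (K x C),
#'   `components` (C x 3L), `eigenvalues` (length C), `center`, `ids`.
#' @export
pca_shape <- function(g) {
  stopifnot(inherits(g, "gpa_result"))
  K <- dim(g$aligned)[1]
  if (K < 3) stopf("shape PCA needs at least 3 configurations")
  flat <- matrix(g$aligned, nrow = K)
  C <- min(K - 1, ncol(flat))
  pr <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  C <- min(C, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(C), drop = FALSE],
                 components = t(pr$rotation[, seq_len(C), drop = FALSE]),
                 eigenvalues = pr$sdev[seq_len(C)]^2,
                 center = pr$center,
                 ids = g$ids),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<pca_result: %d specimens, %d components; PC1 %.1f%% of variance>\n",
              nrow(x$scores), length(ev), 100 * ev[1] / sum(ev)))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$scores))
  tibble::add_column(out, specimen = x$ids, .before = 1)
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores),
                 n_components = length(x$eigenvalues),
                 total_variance = sum(x$eigenvalues),
                 pc1_prop = x$eigenvalues[1] / sum(x$eigenvalues))
}

#' @export
autoplot.pca_result <- function(object, ...) {
  df <- data.frame(PC1 = object$scores[, 1],
                   PC2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0,
                   specimen = object$ids)
  pv <- 100 * object$eigenvalues / sum(object$eigenvalues)
  ggplot(df, aes(x = PC1, y = PC2)) +
    geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
         y = if (length(pv) >= 2) sprintf("PC2 (%.1f%%)", pv[2]) else "PC2",
         title = "Shape PCA of Procrustes-aligned coordinates") +
    theme_minimal()
}
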