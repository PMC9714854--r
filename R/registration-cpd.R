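#' Parameters for coherent point drift
#'
#' Clouds are internally rescaled so the target bounding-box diagonal spans
#' 25 units (the convention of the point-cloud landmarking tools this package
#' follows); `beta` and `lambda` are expressed on that scale.
#'
#' @param beta Gaussian kernel width of the coherent displacement field.
#' @param lambda motion-coherence regularization weight.
#' @param w_outlier expected outlier fraction in `[0, 1)`.
#' @param max_iter EM iteration budget.
#' @param tol relative change in the noise variance at which EM stops.
#' @return a list of class `cpd_params`.
#' @export
cpd_params <- function(beta = 2, lambda = 2, w_outlier = 0.1,
                       max_iter = 150, tol = 1e-5) {
  if (beta <= 0 || lambda <= 0) stopf("beta and lambda must be positive")
  if (w_outlier < 0 || w_outlier >= 1) stopf("w_outlier must be in [0, 1)")
  structure(list(beta = beta, lambda = lambda, w_outlier = w_outlier,
                 max_iter = max_iter, tol = tol),
            class = "cpd_params")
}

#' Deformable registration by coherent point drift
#'
#' Fits a smooth Gaussian-kernel displacement field moving `source` toward
#' `target` by EM (Myronenko-Song coherent point drift). Clouds should be
#' rigidly pre-aligned. If EM does not reach `tol` within `max_iter`
#' iterations the best-so-far fit is returned with a warning and
#' `converged = FALSE`.
#'
#' @param source,target [point_cloud()] objects (or P x 3 matrices).
#' @param params a [cpd_params()] list.
#' @return an object of class `deformable_map` with the control points,
#'   kernel weights, normalization, fitted target positions, and the
#'   negative log-likelihood trace.
#' @export
cpd_deformable <- function(source, target, params = cpd_params()) {
  Y0 <- as_points(source)
  X0 <- as_points(target)
  M <- nrow(Y0)
  N <- nrow(X0)
  if (M < 3 || N < 3) stopf("CPD needs >= 3 points per cloud")
  ctr <- colMeans(X0)
  sc <- bbox_diagonal(X0) / 25
  if (sc <= 0) stopf("degenerate target cloud (zero extent)")
  Y <- sweep(Y0, 2, ctr) / sc
  X <- sweep(X0, 2, ctr) / sc

  beta <- params$beta
  lambda <- params$lambda
  w <- params$w_outlier
  G <- exp(-pdist2(Y, Y) / (2 * beta^2))
  W <- matrix(0, M, 3)
  Tm <- Y
  sigma2 <- sum(pdist2(X, Y)) / (3 * M * N)
  nll_hist <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(params$max_iter)) {
    d2 <- pdist2(X, Tm)                         # N x M
    Pnum <- exp(-d2 / (2 * sigma2))
    cconst <- (2 * pi * sigma2)^(3 / 2) * (w / (1 - w)) * (M / N)
    den <- rowSums(Pnum) + cconst
    den[den < 1e-300] <- 1e-300
    P <- Pnum / den                             # N x M responsibilities
    nll <- -sum(log(den)) +
      N * ((3 / 2) * log(2 * pi * sigma2) - log((1 - w) / M))
    nll_hist <- c(nll_hist, nll)

    P1 <- colSums(P)                            # length M
    Pt1 <- rowSums(P)                           # length N
    Np <- sum(P1)
    PX <- crossprod(P, X)                       # M x 3
    lhs <- P1 * G                               # row-scaled G
    # ridge keeps the system well-posed when sigma2 collapses or points
    # carry no responsibility
    diag(lhs) <- diag(lhs) + lambda * sigma2 + 1e-9
    W <- solve(lhs, PX - P1 * Y)
    Tm <- Y + G %*% W
    xPx <- sum(Pt1 * rowSums(X^2))
    trPXT <- sum(PX * Tm)
    tTt <- sum(P1 * rowSums(Tm^2))
    sigma2_new <- (xPx - 2 * trPXT + tTt) / (3 * Np)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-10) {
      # variance floor reached: the fit is as tight as numerics allow
      sigma2 <- 1e-10
      converged <- TRUE
      break
    }
    if (abs(sigma2 - sigma2_new) < params$tol * sigma2) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  if (!converged)
    warning(sprintf(
      "CPD did not converge within %d iterations; returning best-so-far fit",
      params$max_iter), call. = FALSE)

  structure(list(
    source_points = Y0,
    control = Y,
    weights = W,
    kernel_width = beta,
    regularization = lambda,
    center = ctr,
    scale_factor = sc,
    fitted = sweep(Tm * sc, 2, ctr, "+"),
    sigma2 = sigma2,
    nll_history = nll_hist,
    converged = converged,
    n_iter = length(nll_hist)
  ), class = "deformable_map")
}

#' @export
print.deformable_map <- function(x, ...) {
  cat(sprintf(
    "<deformable_map: %d control points, beta %.3g, lambda %.3g, %d EM iters%s>\n",
    nrow(x$control), x$kernel_width, x$regularization, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Warp arbitrary points through a fitted deformable map
#'
#' Evaluates the Gaussian-kernel displacement field at `pts`. Evaluating at
#' the map's own source points reproduces the fitted target positions
#' exactly.
#'
#' @param map a `deformable_map` from [cpd_deformable()].
#' @param pts L x 3 matrix (or landmark/cloud object).
#' @return warped L x 3 matrix.
#' @export
warp_points <- function(map, pts) {
  p <- if (inherits(pts, "landmark_set")) pts$coords else as_points(pts)
  U <- sweep(p, 2, map$center) / map$scale_factor
  K <- exp(-pdist2(U, map$control) / (2 * map$kernel_width^2))
  out <- U + K %*% map$weights
  sweep(out * map$scale_factor, 2, map$center, "+")
}
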