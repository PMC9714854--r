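#' Root-mean-square error between two landmark sets
#'
#' `sqrt( sum_i [ (x̂_i − x_i)² + (ŷ_i − y_i)² + (ẑ_i − ẑ_i)² ] / N )` over
#' the N landmarks of a specimen: a single value summarizing the overall
#' deviation between an estimated and a reference landmark set, in mm.
#' Both sets must have the same length and label order.
#'
#' @param a,b [landmark_set()] objects (or L x 3 matrices, compared
#'   positionally).
#' @return RMSE in mm.
#' @export
rmse <- function(a, b) {
  if (inherits(a, "landmark_set") && inherits(b, "landmark_set")) {
    check_comparable(a, b)
    a <- a$coords
    b <- b$coords
  } else {
    a <- as_points(a)
    b <- as_points(b)
    if (nrow(a) != nrow(b))
      stopf("landmark sets not comparable: %d vs %d landmarks", nrow(a), nrow(b))
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Per-landmark Euclidean errors
#'
#' Elementwise Euclidean distances between corresponding landmarks, label
#' order preserved. `rmse(a, b)^2` equals the mean of these squared errors.
#'
#' @inheritParams rmse
#' @return named numeric vector of length L (mm).
#' @export
per_landmark_errors <- function(a, b) {
  if (inherits(a, "landmark_set") && inherits(b, "landmark_set")) {
    check_comparable(a, b)
    out <- row_norms(a$coords - b$coords)
    names(out) <- a$labels
    out
  } else {
    a <- as_points(a)
    b <- as_points(b)
    if (nrow(a) != nrow(b))
      stopf("landmark sets not comparable: %d vs %d landmarks", nrow(a), nrow(b))
    row_norms(a - b)
  }
}

#' Per-specimen RMSE report
#'
#' RMSEs between matched estimated and reference landmark sets, in mm and as
#' a percentage of each specimen's reference centroid size.
#'
#' @param est_sets,ref_sets named lists of [landmark_set()]s; matched by
#'   name when both are named, positionally otherwise.
#' @return a tibble with columns specimen, rmse_mm, rmse_pct_cs, n_landmarks.
#' @export
rmse_report <- function(est_sets, ref_sets) {
  pairs <- match_sets(est_sets, ref_sets)
  rows <- lapply(names(pairs$est), function(id) {
    e <- pairs$est[[id]]
    r <- pairs$ref[[id]]
    rm <- rmse(e, r)
    tibble::tibble(specimen = id, rmse_mm = rm,
                   rmse_pct_cs = 100 * rm / centroid_size(r),
                   n_landmarks = nrow(r$coords))
  })
  do.call(rbind, rows)
}

match_sets <- function(est_sets, ref_sets) {
  en <- names(est_sets)
  rn <- names(ref_sets)
  if (!is.null(en) && !is.null(rn) && all(nzchar(en)) && all(nzchar(rn))) {
    common <- intersect(en, rn)
    if (!length(common)) stopf("no specimens shared between the two families")
    list(est = est_sets[common], ref = ref_sets[common])
  } else {
    if (length(est_sets) != length(ref_sets))
      stopf("unnamed families must have equal length")
    ids <- vapply(ref_sets, function(x) x$specimen, "")
    names(est_sets) <- ids
    names(ref_sets) <- ids
    list(est = est_sets, ref = ref_sets)
  }
}

#' One-sided Welch t-test
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a one-sided p-value, used to compare error distributions
#' (e.g. whether multi-template errors are smaller than single-template
#' errors).
#'
#' @param x,y numeric samples, each n >= 2; at least one with nonzero
#'   variance.
#' @param alternative `"less"` (mean of x smaller) or `"greater"`.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_one_sided <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stopf("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stopf("zero variance in both samples; Welch test undefined")
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Correlation report between estimated and reference morphometrics
#'
#' Performs separate generalized Procrustes analyses of the estimated and
#' reference landmark families, then reports Pearson correlations of
#' (i) centroid sizes, (ii) upper-triangle pairwise Procrustes distances and
#' (iii) the first `n_pc` PC scores of each family against each other
#' (C x C matrix). Because principal component signs are arbitrary, the
#' absolute correlations are reported alongside the signed values.
#'
#' @param est_sets,ref_sets named lists of [landmark_set()]s covering the
#'   same K >= 3 specimens.
#' @param n_pc number of principal components to correlate (default 6).
#' @param scale scale configurations to unit centroid size in the GPAs.
#' @return an object of class `correlation_report`.
#' @export
correlation_report <- function(est_sets, ref_sets, n_pc = 6, scale = TRUE) {
  pairs <- match_sets(est_sets, ref_sets)
  K <- length(pairs$est)
  if (K < 3) stopf("correlation report needs at least 3 matched specimens")
  for (id in names(pairs$est)) check_comparable(pairs$est[[id]], pairs$ref[[id]])

  g_est <- gpa(pairs$est, scale = scale)
  g_ref <- gpa(pairs$ref, scale = scale)
  cs_est <- vapply(pairs$est, centroid_size, 1)
  cs_ref <- vapply(pairs$ref, centroid_size, 1)
  r_cs <- stats::cor(cs_est, cs_ref)

  pd_est <- procrustes_distance_matrix(g_est)
  pd_ref <- procrustes_distance_matrix(g_ref)
  ut <- upper.tri(pd_est)
  r_pd <- stats::cor(pd_est[ut], pd_ref[ut])

  p_est <- pca_shape(g_est)
  p_ref <- pca_shape(g_ref)
  C <- min(n_pc, ncol(p_est$scores), ncol(p_ref$scores))
  pc_r <- matrix(NA_real_, C, C,
                 dimnames = list(paste0("est_PC", seq_len(C)),
                                 paste0("ref_PC", seq_len(C))))
  for (i in seq_len(C)) for (j in seq_len(C))
    pc_r[i, j] <- stats::cor(p_est$scores[, i], p_ref$scores[, j])

  structure(list(centroid_size_r = r_cs, procrustes_r = r_pd,
                 pc_r = pc_r, pc_abs_r = abs(pc_r), n = K, n_pc = C),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report over %d specimens>\n", x$n))
  cat(sprintf("  centroid size r        = %.4f\n", x$centroid_size_r))
  cat(sprintf("  Procrustes distance r  = %.4f\n", x$procrustes_r))
  cat(sprintf("  PC diagonal |r|        = %s\n",
              paste(sprintf("%.3f", diag(x$pc_abs_r)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  C <- x$n_pc
  pc <- tibble::tibble(
    quantity = paste0("pc", rep(seq_len(C), each = C), "_vs_pc",
                      rep(seq_len(C), times = C)),
    r = as.vector(t(x$pc_r)),
    abs_r = as.vector(t(x$pc_abs_r)))
  rbind(tibble::tibble(quantity = c("centroid_size", "procrustes_distance"),
                       r = c(x$centroid_size_r, x$procrustes_r),
                       abs_r = abs(c(x$centroid_size_r, x$procrustes_r))),
        pc)
}

#' @export
autoplot.correlation_report <- function(object, ...) {
  C <- object$n_pc
  df <- data.frame(est = factor(rep(seq_len(C), times = C)),
                   ref = factor(rep(seq_len(C), each = C)),
                   r = as.vector(object$pc_r))
  ggplot(df, aes(x = ref, y = est, fill = r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", r)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "reference PC", y = "estimated PC",
         title = "PC score correlations (estimated vs reference)") +
    theme_minimal()
}

#' Permutation test of template-set quality
#'
#' Draws `n_perm` random k-subsets of the specimen list, runs a full
#' multi-template transfer with each subset as templates (templates use
#' their reference landmark sets), scores every remaining specimen by RMSE
#' against its reference landmarks, and compares the focal template set's
#' mean RMSE against the permutation distribution. The focal combination is
#' not excluded from the sample space. Because transfers are deterministic
#' for a given (template, target) pair, pairs recurring across permutations
#' are computed once and reused.
#'
#' @param meshes named list of [triangle_mesh()] objects.
#' @param ref_landmarks named list of [landmark_set()]s for all specimens.
#' @param k templates per combination (k < number of specimens).
#' @param n_perm number of random combinations (>= 1).
#' @param focal_template_ids the template set under evaluation (e.g. the
#'   K-means selection).
#' @param params an [alpaca_params()] list.
#' @param seed seed for the permutation draws.
#' @return an object of class `permutation_result` with the per-permutation
#'   mean RMSEs, the per-specimen RMSE matrix, the focal mean RMSE and its
#'   rank fraction (proportion of permutation means strictly below it).
#' @export
permutation_template_test <- function(meshes, ref_landmarks, k, n_perm,
                                      focal_template_ids,
                                      params = alpaca_params(), seed = 1) {
  ids <- names(meshes) %||% vapply(meshes, function(m) m$name, "")
  names(meshes) <- ids
  K <- length(ids)
  if (k >= K) stopf("k must be smaller than the number of specimens")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  missing_ref <- setdiff(ids, names(ref_landmarks))
  if (length(missing_ref))
    stopf("reference landmarks missing for: %s",
          paste(missing_ref, collapse = ", "))
  bad_focal <- setdiff(focal_template_ids, ids)
  if (length(bad_focal))
    stopf("unknown focal template ids: %s", paste(bad_focal, collapse = ", "))

  if (is.null(params$spacing))
    params$spacing <- tune_spacing(meshes[[focal_template_ids[1]]],
                                   params$target_points,
                                   params$tol_points)$spacing

  cache <- new.env(parent = emptyenv())
  # a failing (template, target) pair behaves as in batch runs: its slice is
  # excluded from the median rather than aborting the whole permutation
  pair_estimate <- function(tpl, tgt) {
    key <- paste(tpl, tgt, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(
      alpaca_single(meshes[[tpl]], ref_landmarks[[tpl]], meshes[[tgt]],
                    params),
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NA
      })
    cache[[key]] <- val
    val
  }
  eval_set <- function(tpl_ids) {
    tgts <- setdiff(ids, tpl_ids)
    vapply(tgts, function(tgt) {
      L <- length(ref_landmarks[[tpl_ids[1]]]$labels)
      est <- array(NA_real_, c(length(tpl_ids), L, 3))
      for (ti in seq_along(tpl_ids)) {
        pe <- pair_estimate(tpl_ids[ti], tgt)
        if (inherits(pe, "landmark_set")) est[ti, , ] <- pe$coords
      }
      stack <- estimate_stack(est, tpl_ids,
                              ref_landmarks[[tpl_ids[1]]]$labels, tgt)
      if (all(stack$missing)) return(NA_real_)
      rmse(median_aggregate(stack), ref_landmarks[[tgt]])
    }, 1)
  }

  combos <- withr::with_seed(seed,
    lapply(seq_len(n_perm), function(i) sort(sample(ids, k))))
  per_spec <- matrix(NA_real_, n_perm, K, dimnames = list(NULL, ids))
  perm_means <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    r <- eval_set(combos[[i]])
    per_spec[i, names(r)] <- r
    perm_means[i] <- mean(r, na.rm = TRUE)
  }
  focal_r <- eval_set(focal_template_ids)
  focal_mean <- mean(focal_r, na.rm = TRUE)
  structure(list(per_permutation_mean_rmse = perm_means,
                 per_specimen_rmse = per_spec,
                 combos = combos,
                 focal_template_ids = focal_template_ids,
                 focal_per_specimen_rmse = focal_r,
                 focal_mean_rmse = focal_mean,
                 focal_rank_fraction = mean(perm_means < focal_mean),
                 k = k, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: %d permutations of k = %d templates>\n",
              x$n_perm, x$k))
  cat(sprintf("  focal mean RMSE %.4g mm; rank fraction %.3f (share of random sets doing better)\n",
              x$focal_mean_rmse, x$focal_rank_fraction))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm),
                 mean_rmse = x$per_permutation_mean_rmse,
                 templates = vapply(x$combos, paste, "", collapse = ";"))
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, k = x$k,
                 focal_mean_rmse = x$focal_mean_rmse,
                 focal_rank_fraction = x$focal_rank_fraction,
                 perm_mean_rmse = mean(x$per_permutation_mean_rmse))
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- data.frame(mean_rmse = object$per_permutation_mean_rmse)
  ggplot(df, aes(x = mean_rmse)) +
    geom_histogram(bins = max(10, object$n_perm %/% 5), fill = "grey70",
                   colour = "grey30") +
    geom_vline(xintercept = object$focal_mean_rmse, colour = "red") +
    labs(x = "mean RMSE of random template sets (mm)", y = "count",
         title = "Random template sets vs the focal selection (red)") +
    theme_minimal()
}
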