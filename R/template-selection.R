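#' Correspondent point clouds across a mesh population
#'
#' Builds row-correspondent sparse point clouds for every specimen: the
#' reference mesh is subsampled once, rigidly registered (feature-based
#' global alignment + ICP) to each other specimen, moved by the fitted
#' transform, and each moved reference point is replaced by its closest
#' vertex on that specimen's mesh. Row i of every cloud corresponds to row i
#' of the reference cloud.
#'
#' Specimens whose mean correspondence distance exceeds 5x the population
#' median are flagged as outliers in the result (never silently dropped).
#'
#' @param meshes named list of [triangle_mesh()] objects (>= 2).
#' @param reference_index which specimen seeds the correspondence (first by
#'   default, the usual convention when no better prior exists).
#' @param spacing subsampling spacing (mm); when NULL, tuned on the reference
#'   to `target_points`.
#' @param target_points,tol_points spacing-tuning controls.
#' @param rigid a [rigid_params()] list.
#' @return an object of class `correspondent_cloud_set` with fields `clouds`
#'   (K x P x 3), `reference_index`, `specimen_ids`, `spacing`,
#'   `mean_correspondence`, `outlier`.
#' @export
build_correspondent_clouds <- function(meshes, reference_index = 1,
                                       spacing = NULL, target_points = 250,
                                       tol_points = 25,
                                       rigid = rigid_params()) {
  K <- length(meshes)
  if (K < 2) stopf("need at least 2 meshes")
  ids <- names(meshes) %||% vapply(meshes, function(m) m$name, "")
  if (any(!nzchar(ids))) ids <- vapply(meshes, function(m) m$name, "")
  if (anyDuplicated(ids)) stopf("duplicate specimen ids in mesh list")
  if (reference_index < 1 || reference_index > K)
    stopf("reference_index out of range")
  for (m in meshes) validate_mesh(m)

  ref_mesh <- meshes[[reference_index]]
  spacing <- spacing %||% tune_spacing(ref_mesh, target_points, tol_points)$spacing
  ref_cloud <- subsample_by_spacing(ref_mesh, spacing)
  P <- nrow(ref_cloud$points)

  clouds <- array(NA_real_, c(K, P, 3), dimnames = list(ids, NULL, NULL))
  mean_d <- numeric(K)
  for (i in seq_len(K)) {
    if (i == reference_index) {
      clouds[i, , ] <- ref_cloud$points   # reference vertices are their own
      mean_d[i] <- 0                      # closest points by construction
      next
    }
    tgt_cloud <- subsample_by_spacing(meshes[[i]], spacing)
    tf <- tryCatch({
      tf0 <- global_rigid_align(ref_cloud, tgt_cloud, rigid)
      icp_refine(ref_cloud, tgt_cloud, tf0,
                 allow_scale = rigid$allow_scale)
    }, error = function(e) {
      stopf("registration failed for specimen '%s': %s", ids[i],
            conditionMessage(e))
    })
    moved <- transform_points(tf, ref_cloud)
    corr <- closest_point_correspondence(point_cloud(moved), meshes[[i]])
    clouds[i, , ] <- corr$points
    mean_d[i] <- mean(row_norms(corr$points - moved))
  }
  med <- stats::median(mean_d[-reference_index])
  outlier <- mean_d > 5 * med & seq_len(K) != reference_index
  structure(list(clouds = clouds, reference_index = reference_index,
                 specimen_ids = ids, spacing = spacing,
                 mean_correspondence = stats::setNames(mean_d, ids),
                 outlier = stats::setNames(outlier, ids)),
            class = "correspondent_cloud_set")
}

#' @export
print.correspondent_cloud_set <- function(x, ...) {
  cat(sprintf("<correspondent_cloud_set: %d specimens x %d points (reference '%s')%s>\n",
              dim(x$clouds)[1], dim(x$clouds)[2],
              x$specimen_ids[x$reference_index],
              if (any(x$outlier)) sprintf(", %d flagged outliers", sum(x$outlier))
              else ""))
  invisible(x)
}

#' K-means selection of template specimens from PC scores
#'
#' Partitions specimens into k clusters by K-means (Lloyd iterations, 10
#' random restarts under a fixed seed) on the full, unstandardized PC score
#' matrix, then picks within each cluster the specimen closest to the
#' cluster centroid (full-dimensional Euclidean distance, ties broken by
#' lowest specimen index).
#'
#' @param pc_scores K x C numeric matrix (rows named by specimen).
#' @param k number of templates (1 <= k <= K).
#' @param seed RNG seed.
#' @param n_init number of random restarts (and retry budget for empty
#'   clusters).
#' @param standardize scale each PC to unit variance before clustering
#'   (off by default: PCs enter raw, so they are implicitly
#'   variance-weighted).
#' @return an object of class `template_selection_result`.
#' @export
kmeans_select <- function(pc_scores, k, seed = 42, n_init = 10,
                          standardize = FALSE) {
  pc_scores <- as.matrix(pc_scores)
  K <- nrow(pc_scores)
  ids <- rownames(pc_scores) %||% paste0("spec", seq_len(K))
  if (k < 1 || k > K) stopf("k must be between 1 and %d (got %g)", K, k)
  Xk <- if (standardize) scale(pc_scores) else pc_scores
  if (sum(scale(Xk, scale = FALSE)^2) < 1e-18)
    stopf("degenerate input: all specimens identical in score space; template selection is meaningless")

  if (k == K) {
    assignment <- stats::setNames(seq_len(K), ids)
    return(new_selection_result(ids, assignment, Xk, k, seed, pc_scores, ids))
  }

  km <- NULL
  for (attempt in seq_len(n_init)) {
    km <- tryCatch(
      withr::with_seed(seed + attempt - 1L,
        suppressWarnings(stats::kmeans(Xk, centers = k, algorithm = "Lloyd",
                                       nstart = n_init, iter.max = 200))),
      error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km))
    stopf("K-means failed to produce %d non-empty clusters after %d restarts",
          k, n_init)

  template_ids <- character(k)
  for (cl in seq_len(k)) {
    members <- which(km$cluster == cl)
    d2 <- rowSums((Xk[members, , drop = FALSE] -
                   matrix(km$centers[cl, ], length(members), ncol(Xk),
                          byrow = TRUE))^2)
    template_ids[cl] <- ids[members[which.min(d2)]]
  }
  assignment <- stats::setNames(km$cluster, ids)
  new_selection_result(template_ids, assignment, km$centers, k, seed,
                       pc_scores, ids)
}

new_selection_result <- function(template_ids, assignment, centroids, k,
                                 seed, pc_scores, ids) {
  structure(list(template_ids = template_ids,
                 cluster_assignment = assignment,
                 centroids = centroids, k = k, seed = seed,
                 pc_scores = pc_scores, specimen_ids = ids),
            class = "template_selection_result")
}

#' @export
print.template_selection_result <- function(x, ...) {
  cat(sprintf("<template_selection_result: k = %d of %d specimens>\n",
              x$k, length(x$specimen_ids)))
  cat("  templates:", paste(x$template_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.template_selection_result <- function(x, ...) {
  base <- data.frame(specimen = x$specimen_ids,
                     cluster = unname(x$cluster_assignment[x$specimen_ids]),
                     is_template = x$specimen_ids %in% x$template_ids,
                     stringsAsFactors = FALSE)
  if (!is.null(x$groups)) base$group <- unname(x$groups[x$specimen_ids])
  if (is.null(x$pc_scores)) return(tibble::as_tibble(base))
  sc <- as.data.frame(x$pc_scores)
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  tibble::as_tibble(cbind(base, sc))
}

#' @export
autoplot.template_selection_result <- function(object, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster)
  ggplot(df, aes(x = PC1, y = PC2, colour = cluster, shape = is_template)) +
    geom_point(size = 2) +
    scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                       labels = c("specimen", "template"), name = NULL) +
    labs(title = "K-means template selection in the shape morphospace") +
    theme_minimal()
}

#' Select template specimens from a mesh population
#'
#' Full selection workflow: correspondent point clouds, generalized
#' Procrustes analysis, PCA of the shape coordinates, and K-means selection
#' of the k specimens nearest the cluster centroids.
#'
#' @inheritParams build_correspondent_clouds
#' @param k number of templates.
#' @param seed RNG seed for K-means restarts.
#' @param scale scale configurations to unit centroid size in the GPA.
#' @param standardize standardize PC scores before K-means.
#' @return a `template_selection_result` additionally carrying `gpa`, `pca`
#'   and `clouds`.
#' @export
select_templates <- function(meshes, k, spacing = NULL, seed = 42,
                             reference_index = 1, target_points = 250,
                             tol_points = 25, rigid = rigid_params(),
                             scale = TRUE, standardize = FALSE) {
  ccs <- build_correspondent_clouds(meshes, reference_index = reference_index,
                                    spacing = spacing,
                                    target_points = target_points,
                                    tol_points = tol_points, rigid = rigid)
  g <- gpa(ccs$clouds, scale = scale)
  p <- pca_shape(g)
  scores <- p$scores
  rownames(scores) <- ccs$specimen_ids
  sel <- kmeans_select(scores, k, seed = seed, standardize = standardize)
  sel$gpa <- g
  sel$pca <- p
  sel$clouds <- ccs
  sel
}

#' Per-group template selection
#'
#' Runs [select_templates()] independently within each group (separate
#' correspondence, GPA, PCA and K-means per group; reference is the first
#' specimen of the group) and unions the per-group templates, as one would
#' for a multi-species sample.
#'
#' @inheritParams select_templates
#' @param group_labels vector of group labels, one per mesh.
#' @param k_per_group templates to pick within each group.
#' @return a `template_selection_result`; `cluster_assignment` numbers
#'   clusters uniquely across groups and `groups` records the per-specimen
#'   labels.
#' @export
select_templates_grouped <- function(meshes, group_labels, k_per_group,
                                     spacing = NULL, seed = 42,
                                     target_points = 250, tol_points = 25,
                                     rigid = rigid_params(), scale = TRUE,
                                     standardize = FALSE) {
  K <- length(meshes)
  if (length(group_labels) != K)
    stopf("group_labels must have one label per mesh (%d vs %d)",
          length(group_labels), K)
  ids <- names(meshes) %||% vapply(meshes, function(m) m$name, "")
  group_labels <- as.character(group_labels)
  groups <- unique(group_labels)
  template_ids <- character(0)
  assignment <- stats::setNames(integer(K), ids)
  scores_list <- list()
  offset <- 0L
  for (gname in groups) {
    sel_idx <- which(group_labels == gname)
    if (length(sel_idx) < k_per_group)
      stopf("group '%s' has %d specimens, fewer than k_per_group = %d",
            gname, length(sel_idx), k_per_group)
    sub <- meshes[sel_idx]
    names(sub) <- ids[sel_idx]
    sel <- select_templates(sub, k = k_per_group, spacing = spacing,
                            seed = seed, reference_index = 1,
                            target_points = target_points,
                            tol_points = tol_points, rigid = rigid,
                            scale = scale, standardize = standardize)
    template_ids <- c(template_ids, sel$template_ids)
    assignment[ids[sel_idx]] <- sel$cluster_assignment[ids[sel_idx]] + offset
    offset <- offset + sel$k
    scores_list[[gname]] <- sel$pc_scores
  }
  out <- new_selection_result(template_ids, assignment, NULL,
                              length(template_ids), seed, NULL, ids)
  out$groups <- stats::setNames(group_labels, ids)
  out$per_group_scores <- scores_list
  out
}
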