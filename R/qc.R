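#' Detect outlier estimates in a per-template stack
#'
#' For one target specimen, computes the Euclidean distance between every
#' template's estimate of every landmark and the corresponding fused
#' (median) landmark, pools the T x L distances, and flags as outliers the
#' estimates whose distance strictly exceeds `mean + n_sd * sd` of the pool.
#' The threshold is per-specimen: another specimen's stack never influences
#' this one's mask. The sd is the sample standard deviation (divisor
#' T*L - 1); this choice is recorded in the result.
#'
#' @param stack an [estimate_stack()] with T >= 2 non-missing slices.
#' @param median_lms the fused landmarks to measure against; defaults to
#'   [median_aggregate()] of the stack.
#' @param n_sd heuristic multiplier (default 2); raise it to pinpoint only
#'   exceptionally poor estimates.
#' @return an object of class `outlier_mask` with `flags` (T x L logical),
#'   `distances` (T x L, mm), `threshold_mm`, `n_sd`, `sd_type`.
#' @export
detect_outliers <- function(stack, median_lms = NULL, n_sd = 2) {
  stopifnot(inherits(stack, "estimate_stack"))
  Tn <- dim(stack$estimates)[1]
  if (sum(!stack$missing) < 2)
    stopf("outlier detection needs >= 2 non-missing template slices")
  median_lms <- median_lms %||% median_aggregate(stack)
  stopifnot(inherits(median_lms, "landmark_set"))
  if (!identical(median_lms$labels, stack$labels))
    stopf("median landmarks do not match the stack's labels")
  L <- dim(stack$estimates)[2]
  distances <- matrix(NA_real_, Tn, L,
                      dimnames = list(stack$template_ids, stack$labels))
  for (t in seq_len(Tn)) {
    if (stack$missing[t]) next
    distances[t, ] <- row_norms(stack$estimates[t, , ] - median_lms$coords)
  }
  pooled <- distances[!is.na(distances)]
  threshold <- mean(pooled) + n_sd * stats::sd(pooled)
  if (is.na(threshold)) threshold <- mean(pooled)  # single pooled value
  flags <- !is.na(distances) & distances > threshold
  structure(list(target_id = stack$target_id, flags = flags,
                 distances = distances, threshold_mm = threshold,
                 n_sd = n_sd, sd_type = "sample"),
            class = "outlier_mask")
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat(sprintf("<outlier_mask '%s': %d / %d estimates flagged (threshold %.4g mm)>\n",
              x$target_id, sum(x$flags), sum(!is.na(x$distances)),
              x$threshold_mm))
  invisible(x)
}

#' @export
tidy.outlier_mask <- function(x, ...) {
  Tn <- nrow(x$flags)
  L <- ncol(x$flags)
  tibble::tibble(target = x$target_id,
                 template = rep(rownames(x$flags), times = L),
                 label = rep(colnames(x$flags), each = Tn),
                 distance_mm = as.vector(x$distances),
                 outlier = as.vector(x$flags),
                 threshold_mm = x$threshold_mm)
}

#' @export
autoplot.outlier_mask <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = label, y = template, fill = distance_mm)) +
    geom_tile() +
    geom_point(data = df[df$outlier & !is.na(df$outlier), ],
               shape = 4, size = 2) +
    labs(x = NULL, y = NULL,
         title = sprintf("Estimate-to-median distances, '%s' (x = outlier)",
                         object$target_id)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Recompute the fused landmarks excluding flagged outliers
#'
#' Per-coordinate median over the unflagged template estimates only. Every
#' landmark must retain at least one unflagged template.
#'
#' @param stack an [estimate_stack()].
#' @param mask an `outlier_mask` from [detect_outliers()].
#' @return a [landmark_set()].
#' @export
recompute_median_excluding <- function(stack, mask) {
  stopifnot(inherits(stack, "estimate_stack"), inherits(mask, "outlier_mask"))
  if (!identical(dim(mask$flags), dim(stack$estimates)[1:2]))
    stopf("mask does not match the stack's dimensions")
  est <- stack$estimates
  for (t in seq_len(dim(est)[1])) est[t, mask$flags[t, ], ] <- NA_real_
  alive <- apply(!is.na(est[, , 1, drop = FALSE]), 2, sum)
  dead <- which(alive == 0)
  if (length(dead))
    stopf("every template flagged for landmark '%s'; cannot recompute median",
          stack$labels[dead[1]])
  med <- apply(est, c(2, 3), stats::median, na.rm = TRUE)
  landmark_set(med, labels = stack$labels, specimen = stack$target_id)
}

#' Fuse a subset of templates only
#'
#' Median aggregation restricted to the named template slices, e.g. a
#' group-specific fusion using only the templates of the target's own
#' species.
#'
#' @param stack an [estimate_stack()].
#' @param template_subset non-empty character vector of template ids in the
#'   stack.
#' @return a [landmark_set()].
#' @export
subset_fusion <- function(stack, template_subset) {
  stopifnot(inherits(stack, "estimate_stack"))
  if (!length(template_subset)) stopf("template subset must be non-empty")
  idx <- match(template_subset, stack$template_ids)
  if (anyNA(idx))
    stopf("unknown template id '%s'", template_subset[which(is.na(idx))[1]])
  sub <- estimate_stack(stack$estimates[idx, , , drop = FALSE],
                        stack$template_ids[idx], stack$labels,
                        stack$target_id)
  median_aggregate(sub)
}

#' Drop a whole template slice from a stack
#'
#' Convenience for excluding every estimate of one template for a target.
#'
#' @param stack an [estimate_stack()].
#' @param template_id template to remove.
#' @return an [estimate_stack()] without that slice.
#' @export
exclude_template <- function(stack, template_id) {
  stopifnot(inherits(stack, "estimate_stack"))
  idx <- match(template_id, stack$template_ids)
  if (is.na(idx)) stopf("unknown template id '%s'", template_id)
  keep <- setdiff(seq_along(stack$template_ids), idx)
  if (!length(keep)) stopf("cannot remove the only template slice")
  estimate_stack(stack$estimates[keep, , , drop = FALSE],
                 stack$template_ids[keep], stack$labels, stack$target_id)
}
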