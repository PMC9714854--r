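#' Per-template landmark estimate stack
#'
#' The T x L x 3 array of landmark estimates for one target specimen, one
#' slice per template, all in the target's own coordinate frame. Slices of a
#' template whose registration failed may be all-NA (recorded, never
#' zero-filled); all non-missing values must be finite.
#'
#' @param estimates numeric array T x L x 3 (mm).
#' @param template_ids character vector, length T.
#' @param labels landmark labels, length L.
#' @param target_id target specimen identifier.
#' @return an object of class `estimate_stack`.
#' @export
estimate_stack <- function(estimates, template_ids, labels, target_id) {
  estimates <- as.array(estimates)
  if (length(dim(estimates)) != 3 || dim(estimates)[3] != 3)
    stopf("estimates must be a T x L x 3 array")
  Tn <- dim(estimates)[1]
  L <- dim(estimates)[2]
  if (Tn < 1) stopf("estimate stack needs at least one template slice")
  if (length(template_ids) != Tn)
    stopf("%d template ids for %d slices", length(template_ids), Tn)
  if (anyDuplicated(template_ids)) stopf("duplicate template ids in stack")
  labels <- as.character(labels)
  if (length(labels) != L) stopf("%d labels for %d landmarks", length(labels), L)
  if (anyDuplicated(labels)) stopf("duplicate landmark labels in stack")
  missing_slice <- apply(estimates, 1, function(s) all(is.na(s)))
  for (t in which(!missing_slice)) {
    if (!all(is.finite(estimates[t, , ])))
      stopf("non-finite estimates in slice '%s'", template_ids[t])
  }
  dimnames(estimates) <- list(template_ids, labels, c("x", "y", "z"))
  structure(list(estimates = estimates,
                 template_ids = as.character(template_ids),
                 labels = labels, target_id = target_id,
                 missing = stats::setNames(missing_slice, template_ids)),
            class = "estimate_stack")
}

#' @export
print.estimate_stack <- function(x, ...) {
  cat(sprintf("<estimate_stack '%s': %d templates x %d landmarks%s>\n",
              x$target_id, dim(x$estimates)[1], dim(x$estimates)[2],
              if (any(x$missing)) sprintf(" (%d missing slices)", sum(x$missing))
              else ""))
  invisible(x)
}

#' @export
tidy.estimate_stack <- function(x, ...) {
  e <- x$estimates
  Tn <- dim(e)[1]
  L <- dim(e)[2]
  tibble::tibble(
    target = x$target_id,
    template = rep(x$template_ids, times = L),
    label = rep(x$labels, each = Tn),
    x = as.vector(e[, , 1]),
    y = as.vector(e[, , 2]),
    z = as.vector(e[, , 3]))
}

#' Fuse an estimate stack by the coordinate-wise median
#'
#' Each of the x, y and z coordinates of every landmark is, independently,
#' the median of the corresponding estimates over all (non-missing)
#' templates; for an even count the midpoint of the two central values. The
#' median is robust to outlier estimates from templates that registered
#' poorly, which is why it is preferred over the mean.
#'
#' @param stack an [estimate_stack()].
#' @return a [landmark_set()] with the stack's labels, in the target frame.
#' @export
median_aggregate <- function(stack) {
  stopifnot(inherits(stack, "estimate_stack"))
  if (all(stack$missing)) stopf("all template slices are missing")
  med <- apply(stack$estimates, c(2, 3), stats::median, na.rm = TRUE)
  landmark_set(med, labels = stack$labels, specimen = stack$target_id)
}

#' Experimental mean fusion (off the default path)
#' @inheritParams median_aggregate
#' @export
mean_aggregate <- function(stack) {
  stopifnot(inherits(stack, "estimate_stack"))
  if (all(stack$missing)) stopf("all template slices are missing")
  m <- apply(stack$estimates, c(2, 3), mean, na.rm = TRUE)
  landmark_set(m, labels = stack$labels, specimen = stack$target_id)
}

#' Multi-template landmark transfer (MALPACA)
#'
#' Runs one independent single-template transfer per template per target and
#' fuses each target's per-template estimates by the coordinate-wise median.
#' Per-template results are identical whether a pair is run alone or within
#' the batch (all runs use `params$seed`). A failing (template, target) pair
#' is recorded in the manifest and its slice marked missing — excluded from
#' the median, never zero-filled.
#'
#' @param templates list of `list(mesh = , landmarks = )` pairs; all landmark
#'   sets must share labels and order.
#' @param targets named list of [triangle_mesh()] targets; must not overlap
#'   the templates.
#' @param params an [alpaca_params()] list. A NULL spacing is tuned once on
#'   the first template and shared by every run.
#' @param out_dir when non-NULL, writes per-template and median FCSV files
#'   (`<target>_<template>.fcsv`, `<target>_median.fcsv`), a long-format
#'   `estimate_stack.csv` and a `manifest.csv` into this directory.
#' @return an object of class `malpaca_result`: per-target list of
#'   `stack` and `median`, plus the run `manifest` tibble.
#' @export
run_malpaca <- function(templates, targets, params = alpaca_params(),
                        out_dir = NULL) {
  if (!length(templates)) stopf("need at least one template")
  if (!length(targets)) stopf("need at least one target")
  tpl_ids <- vapply(templates, function(t) t$landmarks$specimen, "")
  nm <- names(templates)
  if (!is.null(nm) && all(nzchar(nm))) tpl_ids <- nm
  if (anyDuplicated(tpl_ids)) stopf("duplicate template ids")
  tgt_ids <- names(targets) %||% vapply(targets, function(m) m$name, "")
  if (any(!nzchar(tgt_ids))) tgt_ids <- vapply(targets, function(m) m$name, "")
  if (anyDuplicated(tgt_ids)) stopf("duplicate target ids")
  both <- intersect(tpl_ids, tgt_ids)
  if (length(both))
    stopf("targets must exclude templates (overlap: %s)",
          paste(both, collapse = ", "))

  labels <- templates[[1]]$landmarks$labels
  for (t in templates) check_comparable(templates[[1]]$landmarks, t$landmarks)
  L <- length(labels)

  if (is.null(params$spacing))
    params$spacing <- tune_spacing(templates[[1]]$mesh, params$target_points,
                                   params$tol_points)$spacing

  results <- vector("list", length(targets))
  names(results) <- tgt_ids
  manifest <- list()
  for (si in seq_along(targets)) {
    est <- array(NA_real_, c(length(templates), L, 3))
    for (ti in seq_along(templates)) {
      res <- tryCatch(
        alpaca_single(templates[[ti]]$mesh, templates[[ti]]$landmarks,
                      targets[[si]], params),
        error = function(e) e)
      if (inherits(res, "error")) {
        manifest[[length(manifest) + 1L]] <- list(
          target = tgt_ids[si], template = tpl_ids[ti], status = "failed",
          message = conditionMessage(res))
      } else {
        est[ti, , ] <- res$coords
        manifest[[length(manifest) + 1L]] <- list(
          target = tgt_ids[si], template = tpl_ids[ti], status = "ok",
          message = "")
      }
    }
    stack <- estimate_stack(est, tpl_ids, labels, tgt_ids[si])
    if (any(stack$missing))
      warning(sprintf("target '%s': %d template slice(s) failed and were excluded from the median",
                      tgt_ids[si], sum(stack$missing)), call. = FALSE)
    results[[si]] <- list(stack = stack, median = median_aggregate(stack))
  }
  manifest <- tibble::as_tibble(do.call(rbind, lapply(manifest, function(r)
    data.frame(r, stringsAsFactors = FALSE))))
  out <- structure(list(targets = results, manifest = manifest,
                        template_ids = tpl_ids, labels = labels,
                        spacing = params$spacing, seed = params$seed),
                   class = "malpaca_result")
  if (!is.null(out_dir)) write_malpaca_result(out, out_dir)
  out
}

#' @export
print.malpaca_result <- function(x, ...) {
  cat(sprintf("<malpaca_result: %d targets x %d templates (spacing %.4g mm)>\n",
              length(x$targets), length(x$template_ids), x$spacing))
  nf <- sum(x$manifest$status == "failed")
  if (nf) cat(sprintf("  %d failed (template, target) pairs; see $manifest\n", nf))
  invisible(x)
}

write_malpaca_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  long <- list()
  for (tgt in names(result$targets)) {
    entry <- result$targets[[tgt]]
    stack <- entry$stack
    for (t in seq_along(stack$template_ids)) {
      if (stack$missing[t]) next
      est <- landmark_set(stack$estimates[t, , ], labels = stack$labels,
                          specimen = tgt)
      write_landmarks(est, file.path(out_dir,
        sprintf("%s_%s.fcsv", tgt, stack$template_ids[t])))
    }
    write_landmarks(entry$median,
                    file.path(out_dir, sprintf("%s_median.fcsv", tgt)))
    long[[tgt]] <- tidy(stack)
  }
  long_tab <- do.call(rbind, long)
  write_table_deterministic(long_tab, file.path(out_dir, "estimate_stack.csv"))
  write_table_deterministic(result$manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

# deterministic CSV writer (fixed significant digits, LF endings)
write_table_deterministic <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  }
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(as.list(df)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format estimate-stack CSV back into stacks
#'
#' Inverse of the `estimate_stack.csv` written by [run_malpaca()].
#'
#' @param path CSV with columns target, template, label, x, y, z.
#' @return named list of [estimate_stack()] objects, one per target.
#' @export
read_estimate_stacks <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "template", "label", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stopf("estimate-stack CSV must have columns %s", paste(need, collapse = ","))
  out <- list()
  for (tgt in unique(tab$target)) {
    sub <- tab[tab$target == tgt, ]
    tpls <- unique(sub$template)
    labs <- unique(sub$label)
    est <- array(NA_real_, c(length(tpls), length(labs), 3))
    for (ti in seq_along(tpls)) {
      s2 <- sub[sub$template == tpls[ti], ]
      idx <- match(labs, s2$label)
      est[ti, , ] <- cbind(s2$x[idx], s2$y[idx], s2$z[idx])
    }
    out[[tgt]] <- estimate_stack(est, tpls, labs, tgt)
  }
  out
}
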