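#' Parameters for single-template landmark transfer
#'
#' @param spacing point-cloud subsampling spacing (mm). When NULL, tuned on
#'   the template mesh to reach `target_points`.
#' @param target_points desired cloud size when tuning spacing.
#' @param tol_points tolerance on `target_points` during tuning.
#' @param rigid a [rigid_params()] list for the global alignment.
#' @param cpd a [cpd_params()] list for the deformable step.
#' @param icp_max_iter,icp_tol ICP refinement controls.
#' @param project_to_surface snap warped landmarks to the nearest point on
#'   the target triangle surface. Off by default: raw warped positions are
#'   reported.
#' @param seed RNG seed for every stochastic step (RANSAC).
#' @return a list of class `alpaca_params`.
#' @export
alpaca_params <- function(spacing = NULL, target_points = 250,
                          tol_points = 25, rigid = rigid_params(),
                          cpd = cpd_params(), icp_max_iter = 50,
                          icp_tol = 1e-8, project_to_surface = FALSE,
                          seed = 42) {
  if (!is.null(spacing) && spacing <= 0) stopf("spacing must be positive")
  structure(list(spacing = spacing, target_points = target_points,
                 tol_points = tol_points, rigid = rigid, cpd = cpd,
                 icp_max_iter = icp_max_iter, icp_tol = icp_tol,
                 project_to_surface = project_to_surface, seed = seed),
            class = "alpaca_params")
}

#' Single-template landmark transfer (ALPACA)
#'
#' Subsamples template and target meshes with a common spacing, rigidly
#' aligns the template to the target (feature-based global alignment + ICP),
#' deformably registers the aligned template cloud to the target cloud by
#' coherent point drift, and warps the template landmarks through the fitted
#' displacement field. Estimates are returned in the target specimen's own
#' (untransformed) coordinate frame, with the template's labels and order.
#'
#' @param template_mesh,target_mesh [triangle_mesh()] objects.
#' @param template_landmarks a [landmark_set()] on the template surface.
#' @param params an [alpaca_params()] list.
#' @return a [landmark_set()] of estimated landmarks on the target.
#' @export
alpaca_single <- function(template_mesh, template_landmarks, target_mesh,
                          params = alpaca_params()) {
  validate_mesh(template_mesh)
  validate_mesh(target_mesh)
  stopifnot(inherits(template_landmarks, "landmark_set"))
  spacing <- params$spacing %||%
    tune_spacing(template_mesh, params$target_points, params$tol_points)$spacing

  # landmarks should sit on/near the template surface
  dlm <- sqrt(apply(pdist2(template_landmarks$coords, template_mesh$vertices),
                    1, min))
  if (max(dlm) > 5 * spacing)
    warning(sprintf(
      "template landmarks of '%s' lie up to %.3g mm from the template surface (> 5 x spacing)",
      template_landmarks$specimen, max(dlm)), call. = FALSE)

  tcloud <- subsample_by_spacing(template_mesh, spacing)
  scloud <- subsample_by_spacing(target_mesh, spacing)

  rigid <- params$rigid
  rigid$seed <- params$seed
  tf <- tryCatch({
    tf0 <- global_rigid_align(tcloud, scloud, rigid)
    icp_refine(tcloud, scloud, tf0, max_iter = params$icp_max_iter,
               tol = params$icp_tol, allow_scale = rigid$allow_scale)
  }, error = function(e) {
    stopf("registration failed (template '%s' -> target '%s'): %s",
          template_mesh$name, target_mesh$name, conditionMessage(e))
  })

  moved_cloud <- point_cloud(transform_points(tf, tcloud),
                             source = tcloud$source, spacing = NULL)
  moved_lms <- transform_points(tf, template_landmarks$coords)
  map <- tryCatch(
    cpd_deformable(moved_cloud, scloud, params$cpd),
    error = function(e) {
      stopf("deformable registration failed (template '%s' -> target '%s'): %s",
            template_mesh$name, target_mesh$name, conditionMessage(e))
    })
  est <- warp_points(map, moved_lms)
  if (params$project_to_surface)
    est <- project_points_to_mesh(est, target_mesh)
  landmark_set(est, labels = template_landmarks$labels,
               specimen = target_mesh$name)
}
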