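base_cloud <- function() {
  b <- fixture_base()
  cached("basecloud", subsample_by_spacing(b$mesh, tune_spacing(b$mesh, 250, 25)$spacing))
}

test_that("global alignment recovers identity and planted similarity transforms", {
  cl <- base_cloud()
  tf_id <- global_rigid_align(cl, cl, rigid_params(seed = 1))
  expect_lt(max(abs(tf_id$rotation - diag(3))), 1e-5)
  expect_lt(max(abs(tf_id$translation)), 1e-5)
  expect_equal(tf_id$scale, 1, tolerance = 1e-6)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  planted <- rigid_transform(R, c(5, -2, 1), 1)
  tgt <- point_cloud(transform_points(planted, cl), spacing = cl$spacing)
  tf <- global_rigid_align(cl, tgt, rigid_params(seed = 2))
  resid <- mean(sqrt(rowSums((transform_points(tf, cl) - tgt$points)^2)))
  diag_len <- malpaca:::bbox_diagonal(cl$points)
  expect_lt(resid, 0.01 * diag_len)
})

test_that("degenerate or tiny clouds are rejected", {
  line <- point_cloud(cbind(1:5, 0, 0))
  expect_error(global_rigid_align(line, line, rigid_params(seed = 1)),
               ">= 10 points")
  collinear <- cbind(1:12, 0, 0)
  expect_error(malpaca:::fit_similarity(collinear, collinear), "degenerate")
})

test_that("ICP refines the global alignment with monotone RMS and honors max_iter = 0", {
  cl <- base_cloud()
  R <- random_rotation_seeded(21)
  planted <- rigid_transform(R, c(3, 1, -4), 1.05)
  tgt <- point_cloud(transform_points(planted, cl), spacing = cl$spacing)
  g <- global_rigid_align(cl, tgt, rigid_params(seed = 3))
  err_g <- mean(sqrt(rowSums((transform_points(g, cl) - tgt$points)^2)))
  refined <- icp_refine(cl, tgt, g)
  err_i <- mean(sqrt(rowSums((transform_points(refined, cl) - tgt$points)^2)))
  expect_lte(err_i, err_g + 1e-12)
  hist <- attr(refined, "rms_history")
  expect_true(all(diff(hist) <= 1e-9))

  # planted transform recovered to high relative accuracy by global + ICP
  expect_lt(max(abs(refined$rotation - R)), 1e-3)
  expect_lt(abs(refined$scale - 1.05) / 1.05, 1e-3)

  same <- icp_refine(cl, cl, rigid_transform(), max_iter = 0)
  expect_equal(same$rotation, diag(3))
  expect_equal(same$scale, 1)

  near <- icp_refine(cl, cl, rigid_transform())
  expect_lt(max(abs(transform_points(near, cl) - cl$points)), 1e-8)
})

test_that("CPD returns near-zero displacement on identical clouds", {
  cl <- base_cloud()
  map <- cpd_deformable(cl, cl)
  diam <- malpaca:::bbox_diagonal(cl$points)
  disp <- sqrt(rowSums((warp_points(map, cl$points) - cl$points)^2))
  expect_lt(max(disp), 1e-3 * diam)
  expect_true(map$converged)
  # negative log-likelihood is non-increasing along EM
  nll <- map$nll_history
  expect_true(all(diff(nll) <= 1e-6 * pmax(abs(nll[-length(nll)]), 1)))
})

test_that("CPD recovers a planted smooth warp on and off the control points", {
  b <- fixture_base()
  warp <- random_warp(b, n_centers = 1, amplitude = 0.3, width = 1.5, seed = 4)
  b2 <- apply_smooth_warp(b, warp)
  sp <- tune_spacing(b$mesh, 250, 25)$spacing
  cl <- subsample_by_spacing(b$mesh, sp)
  cl2 <- subsample_by_spacing(b2$mesh, sp)
  map <- cpd_deformable(cl, cl2)
  diam <- malpaca:::bbox_diagonal(cl2$points)

  # warped source points land within 1% of the diameter of their true images
  truth_cl <- cl$points + warp_displacement(warp, cl$points)
  err_nodes <- sqrt(rowSums((warp_points(map, cl$points) - truth_cl)^2))
  expect_lt(mean(err_nodes), 0.01 * diam)

  # off-node evaluation against the analytic warp
  withr::with_seed(6, off <- b$mesh$vertices[sample(nrow(b$mesh$vertices), 40), ])
  truth_off <- off + warp_displacement(warp, off)
  err_off <- sqrt(rowSums((warp_points(map, off) - truth_off)^2))
  expect_lt(max(err_off), 0.02 * diam)

  # evaluating at the source points reproduces the fitted targets
  expect_equal(warp_points(map, map$source_points), map$fitted, tolerance = 1e-10)
})

test_that("very strong regularization collapses CPD toward a spatially uniform field", {
  cl <- base_cloud()
  shifted <- point_cloud(sweep(cl$points, 2, c(0.5, -0.2, 0.1), "+"))
  map <- cpd_deformable(cl, shifted,
                        cpd_params(lambda = 1e8, max_iter = 60))
  disp <- warp_points(map, cl$points) - cl$points
  diam <- malpaca:::bbox_diagonal(cl$points)
  expect_lt(mean(apply(disp, 2, var)), 1e-3 * diam^2)
})

test_that("transforms serialize to JSON and back", {
  tf <- rigid_transform(random_rotation_seeded(2), c(1, 2, 3), 1.3)
  p <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, p)
  tf2 <- read_transform(p)
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-9)
  expect_equal(tf2$translation, tf$translation)
  expect_equal(tf2$scale, tf$scale)
})
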