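test_that("base shape has the analytic vertex count and on-surface landmarks", {
  b <- make_base_shape(3, 10, seed = 1)
  expect_equal(nrow(b$mesh$vertices), 642)  # 10 * 4^3 + 2
  expect_equal(nrow(b$true_landmarks$coords), 16)
  # landmarks are exact mesh vertices
  idx <- b$generating_params$landmark_vertex_idx
  expect_equal(b$true_landmarks$coords, b$mesh$vertices[idx, ],
               ignore_attr = TRUE)
  expect_equal(length(unique(idx)), 16)
  # same seed regenerates identical vertices
  b2 <- make_base_shape(3, 10, seed = 1)
  expect_identical(b2$mesh$vertices, b$mesh$vertices)
  b3 <- make_base_shape(3, 10, seed = 2)
  expect_false(identical(b3$mesh$vertices, b$mesh$vertices))
  expect_equal(nrow(make_base_shape(2, 4, seed = 1)$mesh$vertices), 162)
  expect_error(make_base_shape(1), ">= 2")
})

test_that("smooth warps displace landmarks exactly per the analytic formula", {
  b <- fixture_base()
  w <- random_warp(b, n_centers = 3, amplitude = 0.2, width = 1.3, seed = 2)
  wb <- apply_smooth_warp(b, w)
  # independent evaluation of the Gaussian RBF field at the landmarks
  lm0 <- b$true_landmarks$coords
  disp <- matrix(0, nrow(lm0), 3)
  for (j in seq_len(nrow(w$centers))) {
    k <- exp(-rowSums(sweep(lm0, 2, w$centers[j, ])^2) / (2 * w$width^2))
    disp <- disp + outer(k, w$amplitudes[j, ])
  }
  expect_equal(wb$true_landmarks$coords, lm0 + disp, tolerance = 1e-12)

  # zero amplitude is the identity
  w0 <- rbf_warp(w$centers, w$amplitudes * 0, w$width)
  expect_equal(apply_smooth_warp(b, w0)$mesh$vertices, b$mesh$vertices)

  # two successive warps compose and are recorded in order
  w2 <- random_warp(b, n_centers = 2, amplitude = 0.1, width = 1.5, seed = 3)
  both <- apply_smooth_warp(wb, w2)
  expect_equal(length(both$generating_params$warps), 2)
  expect_equal(both$mesh$vertices,
               wb$mesh$vertices + warp_displacement(w2, wb$mesh$vertices))

  # over-aggressive warps are refused
  expect_error(apply_smooth_warp(b, rbf_warp(matrix(0, 1, 3),
                                             matrix(c(0.9, 0, 0), 1, 3),
                                             width = 0.3)),
               "self-intersection|15%")
})

test_that("populations carry group labels, poses and exact ground truth", {
  pop <- make_population(n = 12, n_groups = 3, seed = 4, subdivisions = 2)
  expect_length(pop, 12)
  expect_equal(sort(unique(unname(population_groups(pop)))),
               c("g1", "g2", "g3"))
  # same seed -> identical population
  pop2 <- make_population(n = 12, n_groups = 3, seed = 4, subdivisions = 2)
  expect_identical(population_meshes(pop)$spec07$vertices,
                   population_meshes(pop2)$spec07$vertices)
  # landmarks remain exact mesh vertices after warp + pose + scale
  for (id in c("spec01", "spec08")) {
    idx <- pop[[id]]$generating_params$landmark_vertex_idx
    expect_equal(pop[[id]]$true_landmarks$coords,
                 pop[[id]]$mesh$vertices[idx, ], ignore_attr = TRUE)
  }
  # every specimen passes mesh validity and a PLY round trip
  p <- withr::local_tempfile(fileext = ".ply")
  write_mesh(pop$spec03$mesh, p)
  expect_equal(read_mesh(p)$vertices, pop$spec03$mesh$vertices)
})

test_that("degenerate population settings behave as documented", {
  # no individual variation, no pose/scale: meshes differ only by group warp
  pop <- make_population(n = 4, n_groups = 2, within_amp = 0, pose = FALSE,
                         scale_range = c(1, 1), seed = 5, subdivisions = 2)
  same_group <- population_groups(pop) == "g1"
  ids <- names(pop)[same_group]
  expect_identical(pop[[ids[1]]]$mesh$vertices, pop[[ids[2]]]$mesh$vertices)

  # single group, no individual variation: identical up to pose and scale,
  # so GPA distances vanish
  pop1 <- make_population(n = 5, n_groups = 1, between_group_amp = 0,
                          within_amp = 0, seed = 6, subdivisions = 2)
  g <- gpa(lapply(pop1, function(s) s$true_landmarks$coords))
  expect_lt(max(procrustes_distance_matrix(g)), 1e-6)
})

test_that("corrupting a template slice is seeded and magnitude-scaled", {
  st <- random_stack(4, 10, seed = 11)
  expect_identical(corrupt_template_slice(st, "tpl1", 0, seed = 1), st)
  b1 <- corrupt_template_slice(st, "tpl1", 5, seed = 1)
  b2 <- corrupt_template_slice(st, "tpl1", 5, seed = 1)
  expect_identical(b1$estimates, b2$estimates)
  # offsets have exactly the requested magnitude, only on the target slice
  d <- sqrt(rowSums((b1$estimates[1, , ] - st$estimates[1, , ])^2))
  expect_equal(d, rep(5, 10), ignore_attr = TRUE)
  expect_identical(b1$estimates[-1, , ], st$estimates[-1, , ])
})
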