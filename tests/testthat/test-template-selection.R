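test_that("kmeans_select honors trivial k, picks brute-force representatives, and is seeded", {
  withr::with_seed(1, scores <- matrix(rnorm(24), nrow = 12,
                                       dimnames = list(sprintf("s%02d", 1:12),
                                                       NULL)))
  # k = K: every specimen its own template
  all_sel <- kmeans_select(scores, k = 12, seed = 1)
  expect_setequal(all_sel$template_ids, rownames(scores))

  # k = 1: template is the specimen nearest the grand centroid (exhaustive)
  one <- kmeans_select(scores, k = 1, seed = 1)
  d2 <- rowSums(sweep(scores, 2, colMeans(scores))^2)
  expect_equal(one$template_ids, names(which.min(d2)))

  # two well-separated point masses: assignment equals nearest-mass labeling
  withr::with_seed(2, {
    a <- matrix(rnorm(10 * 2, sd = 0.05), ncol = 2)
    b <- matrix(rnorm(8 * 2, sd = 0.05), ncol = 2) + 50
  })
  X <- rbind(a, b)
  rownames(X) <- sprintf("m%02d", 1:18)
  sel2 <- kmeans_select(X, k = 2, seed = 3)
  truth <- rep(1:2, c(10, 8))
  got <- sel2$cluster_assignment
  agree <- max(mean(got == truth), mean(got == 3 - truth))
  expect_equal(agree, 1)
  # representatives equal brute-force arg-min to each cluster centroid
  for (cl in 1:2) {
    members <- which(got == cl)
    cen <- colMeans(X[members, , drop = FALSE])
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2, cen)^2)
    expect_equal(sel2$template_ids[cl], rownames(X)[members[which.min(d2)]])
  }

  # determinism under a fixed seed
  expect_identical(kmeans_select(X, k = 2, seed = 3)$template_ids,
                   sel2$template_ids)
  expect_error(kmeans_select(X, k = 19, seed = 1), "between 1 and")
  expect_error(kmeans_select(matrix(1, 5, 2), k = 2, seed = 1), "degenerate")
})

test_that("K-means objective beats random partitions of the same data", {
  withr::with_seed(4, X <- matrix(rnorm(40 * 3), ncol = 3))
  rownames(X) <- sprintf("r%02d", 1:40)
  sel <- kmeans_select(X, k = 4, seed = 5)
  wss <- function(assign) {
    sum(vapply(unique(assign), function(cl) {
      m <- X[assign == cl, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, 1))
  }
  ours <- wss(sel$cluster_assignment)
  rand <- withr::with_seed(6, vapply(1:100, function(i)
    wss(sample(rep(1:4, length.out = 40))), 1))
  expect_true(all(ours <= rand))
})

test_that("correspondent clouds are row-correspondent and near the planted truth", {
  pop <- fixture_population()
  meshes <- population_meshes(pop)
  ccs <- build_correspondent_clouds(meshes)
  expect_equal(dim(ccs$clouds)[1], 12)
  expect_equal(ccs$reference_index, 1)
  # P equals the reference subsample count
  ref_cloud <- subsample_by_spacing(meshes[[1]], ccs$spacing)
  expect_equal(dim(ccs$clouds)[2], nrow(ref_cloud$points))
  expect_equal(ccs$clouds[1, , ], ref_cloud$points)

  # planted-correspondence check: each reference point is a base-mesh
  # vertex, and the corresponding row of every specimen's cloud should be
  # near that vertex's image in the specimen (within 2 x spacing for the
  # bulk of points)
  base_pop <- make_population(n = 12, n_groups = 3, seed = 2, pose = FALSE,
                              scale_range = c(1, 1))
  ccs0 <- build_correspondent_clouds(population_meshes(base_pop))
  ref0 <- subsample_by_spacing(base_pop$spec01$mesh, ccs0$spacing)
  vidx <- vapply(seq_len(nrow(ref0$points)), function(i)
    bf_nearest(ref0$points[i, ], base_pop$spec01$mesh$vertices), 1L)
  ok <- vapply(2:12, function(si) {
    truth <- base_pop[[si]]$mesh$vertices[vidx, ]
    mean(sqrt(rowSums((ccs0$clouds[si, , ] - truth)^2)) < 2 * ccs0$spacing)
  }, 1)
  expect_gte(min(ok), 0.95)
})

test_that("identical meshes in different poses give coincident correspondent clouds", {
  pop <- make_population(n = 5, n_groups = 1, between_group_amp = 0,
                         within_amp = 0, seed = 7, subdivisions = 2,
                         scale_range = c(1, 1))
  ccs <- build_correspondent_clouds(population_meshes(pop),
                                    target_points = 120)
  g <- gpa(ccs$clouds)
  expect_lt(max(procrustes_distance_matrix(g)), 1e-6)
})

test_that("select_templates recovers planted groups and is deterministic", {
  pop <- fixture_population()
  meshes <- population_meshes(pop)
  groups <- population_groups(pop)
  sel <- select_templates(meshes, k = 3, seed = 2)
  expect_length(sel$template_ids, 3)
  expect_setequal(unname(groups[sel$template_ids]), c("g1", "g2", "g3"))
  # cluster assignment recovers the planted partition (independent oracle)
  expect_equal(mclust::adjustedRandIndex(
    sel$cluster_assignment[names(groups)], groups), 1)
  # templates are members of the population
  expect_true(all(sel$template_ids %in% names(meshes)))
  sel2 <- select_templates(meshes, k = 3, seed = 2)
  expect_identical(sel2$template_ids, sel$template_ids)
  # diagnostic scatter table is exposed
  tt <- tidy(sel)
  expect_true(all(c("specimen", "cluster", "is_template", "PC1") %in%
                    names(tt)))
})

test_that("grouped selection returns k templates per group from their own groups", {
  pop <- fixture_population()
  meshes <- population_meshes(pop)
  groups <- population_groups(pop)
  sel <- select_templates_grouped(meshes, groups, k_per_group = 2, seed = 2,
                                  target_points = 150)
  expect_length(sel$template_ids, 6)
  expect_equal(unname(table(groups[sel$template_ids])), rep(2L, 3),
               ignore_attr = TRUE)
  expect_error(select_templates_grouped(meshes, groups, k_per_group = 5,
                                        seed = 2), "fewer than")

  # single group: identical template set to ungrouped selection
  sub <- meshes[groups == "g1"]
  s1 <- select_templates_grouped(sub, rep("g1", length(sub)),
                                 k_per_group = 2, seed = 3,
                                 target_points = 150)
  s2 <- select_templates(sub, k = 2, seed = 3, target_points = 150)
  expect_setequal(s1$template_ids, s2$template_ids)
})
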