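test_that("RMSE matches its definition exactly", {
  a <- random_landmarks(51, seed = 1)
  expect_equal(rmse(a, a), 0)

  # uniform (3,4,0) displacement gives exactly 5 for any landmark count
  # (integer base coordinates keep the float arithmetic exact)
  for (L in c(3, 17, 51)) {
    x <- withr::with_seed(L,
      landmark_set(matrix(sample(-50:50, L * 3, replace = TRUE), ncol = 3)))
    y <- landmark_set(sweep(x$coords, 2, c(3, 4, 0), "+"), x$labels)
    expect_identical(rmse(x, y), 5)
  }

  # brute-force agreement on random pairs
  b <- random_landmarks(51, seed = 2)
  b2 <- landmark_set(b$coords + matrix(rnorm(51 * 3), ncol = 3), a$labels)
  a2 <- landmark_set(a$coords, a$labels)
  expect_lt(abs(rmse(a2, b2) - bf_rmse(a2$coords, b2$coords)), 1e-12)

  # label mismatch errors name the first offending position
  c1 <- landmark_set(a$coords, paste0("p", 1:51))
  expect_error(rmse(a2, c1), "position 1")
})

test_that("rmse is invariant under a common rigid motion of both sets", {
  a <- random_landmarks(20, seed = 3)
  b <- landmark_set(a$coords + matrix(rnorm(60, sd = 0.5), ncol = 3), a$labels)
  R <- random_rotation_seeded(4)
  t <- c(4, -7, 2)
  am <- landmark_set(rigid_move_lms(a$coords, R, t), a$labels)
  bm <- landmark_set(rigid_move_lms(b$coords, R, t), b$labels)
  expect_lt(abs(rmse(am, bm) - rmse(a, b)), 1e-9)
})

test_that("per-landmark errors are consistent with RMSE", {
  a <- random_landmarks(10, seed = 5)
  expect_equal(unname(per_landmark_errors(a, a)), rep(0, 10))
  shifted <- a$coords
  shifted[4, ] <- shifted[4, ] + c(0, 0, 2)
  b <- landmark_set(shifted, a$labels)
  e <- per_landmark_errors(a, b)
  expect_equal(unname(e[4]), 2)
  expect_equal(sum(e > 0), 1)
  # rmse^2 == mean squared per-landmark error, exactly
  b2 <- landmark_set(a$coords + matrix(rnorm(30), ncol = 3), a$labels)
  expect_equal(rmse(a, b2)^2, mean(per_landmark_errors(a, b2)^2))
})

test_that("one-sided Welch test behaves at the null, under shift, and under swap", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- welch_t_one_sided(x, x, "less")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)

  withr::with_seed(6, {
    lo <- rnorm(30, 0, 1)
    hi <- rnorm(30, 10, 1)
  })
  expect_lt(welch_t_one_sided(lo, hi, "less")$p, 1e-6)
  # agreement with the reference implementation in stats
  ref <- stats::t.test(lo, hi, alternative = "less")
  got <- welch_t_one_sided(lo, hi, "less")
  expect_equal(got$p, ref$p.value)
  expect_equal(got$df, unname(ref$parameter))
  # swapping samples and flipping the alternative leaves p unchanged
  expect_equal(welch_t_one_sided(hi, lo, "greater")$p, got$p)

  expect_error(welch_t_one_sided(c(1, 1), c(1, 1), "less"), "variance")
  expect_error(welch_t_one_sided(1, c(1, 2), "less"), "n >= 2")
})

test_that("rmse_report scales by the reference centroid size", {
  refs <- lapply(1:3, function(i) random_landmarks(10, seed = 20 + i))
  names(refs) <- paste0("s", 1:3)
  ests <- lapply(refs, function(r)
    landmark_set(sweep(r$coords, 2, c(3, 4, 0), "+"), r$labels))
  tab <- rmse_report(ests, refs)
  expect_equal(tab$rmse_mm, rep(5, 3))
  expect_equal(tab$rmse_pct_cs,
               100 * 5 / vapply(refs, centroid_size, 1),
               ignore_attr = TRUE)
  expect_equal(tab$n_landmarks, rep(10L, 3), ignore_attr = TRUE)
})

test_that("correlation report is exact for identical and rigidly moved families", {
  refs <- lapply(1:8, function(i) random_landmarks(12, seed = 30 + i))
  names(refs) <- paste0("s", 1:8)
  cr <- correlation_report(refs, refs)
  expect_equal(cr$centroid_size_r, 1, tolerance = 1e-12)
  expect_equal(cr$procrustes_r, 1, tolerance = 1e-12)
  expect_equal(unname(diag(cr$pc_abs_r)), rep(1, cr$n_pc), tolerance = 1e-8)

  # per-specimen rigid motions leave Procrustes-distance correlation at 1
  moved <- lapply(seq_along(refs), function(i)
    landmark_set(rigid_move_lms(refs[[i]]$coords,
                                random_rotation_seeded(500 + i),
                                withr::with_seed(600 + i, runif(3, -9, 9))),
                 refs[[i]]$labels))
  names(moved) <- names(refs)
  cr2 <- correlation_report(moved, refs)
  expect_equal(cr2$procrustes_r, 1, tolerance = 1e-8)

  # small iid noise keeps centroid-size correlation high
  noisy <- lapply(refs, function(r)
    landmark_set(r$coords + matrix(rnorm(36, sd = 0.01), ncol = 3), r$labels))
  cr3 <- correlation_report(noisy, refs)
  expect_gt(cr3$centroid_size_r, 0.99)

  expect_error(correlation_report(refs[1:2], refs[1:2]), "at least 3")
})

test_that("permutation machinery is seeded, bounded and reproducible on a tiny population", {
  pop <- cached("pop_perm", make_population(n = 6, n_groups = 2, seed = 3,
                                            subdivisions = 2))
  meshes <- population_meshes(pop)
  refs <- population_landmarks(pop)
  pr1 <- permutation_template_test(meshes, refs, k = 2, n_perm = 3,
                                   focal_template_ids = c("spec01", "spec02"),
                                   params = alpaca_params(seed = 7,
                                                          target_points = 120),
                                   seed = 9)
  pr2 <- permutation_template_test(meshes, refs, k = 2, n_perm = 3,
                                   focal_template_ids = c("spec01", "spec02"),
                                   params = alpaca_params(seed = 7,
                                                          target_points = 120),
                                   seed = 9)
  expect_identical(pr1$per_permutation_mean_rmse,
                   pr2$per_permutation_mean_rmse)
  expect_gte(pr1$focal_rank_fraction, 0)
  expect_lte(pr1$focal_rank_fraction, 1)
  expect_equal(pr1$focal_rank_fraction,
               mean(pr1$per_permutation_mean_rmse < pr1$focal_mean_rmse))
  expect_equal(dim(pr1$per_specimen_rmse), c(3, 6))
  # templates of a permutation carry NA rows; targets carry values
  for (i in 1:3) {
    expect_true(all(is.na(pr1$per_specimen_rmse[i, pr1$combos[[i]]])))
    expect_true(all(!is.na(
      pr1$per_specimen_rmse[i, setdiff(names(meshes), pr1$combos[[i]])])))
  }
  expect_error(permutation_template_test(meshes, refs, k = 6, n_perm = 2,
                                         focal_template_ids = "spec01"),
               "smaller")
  expect_error(permutation_template_test(meshes, refs, k = 2, n_perm = 0,
                                         focal_template_ids = c("spec01", "spec02")),
               "n_perm")
})
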