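test_that("exact agreement across templates yields a zero threshold and zero flags", {
  one <- random_stack(1, 8, seed = 1)
  est <- array(rep(one$estimates[1, , ], each = 4), c(4, 8, 3))
  st <- estimate_stack(est, paste0("t", 1:4), one$labels, "tgt")
  mask <- detect_outliers(st)
  expect_equal(max(mask$distances), 0)
  expect_equal(mask$threshold_mm, 0)
  expect_false(any(mask$flags))   # strict inequality: 0 > 0 is FALSE
})

test_that("threshold arithmetic (mean + 2 sd, strict exceed) matches a brute-force oracle", {
  for (seed in 1:4) {
    st <- random_stack(5, 9, seed = 100 + seed)
    med <- median_aggregate(st)
    mask <- detect_outliers(st, med)
    # independent recomputation with explicit loops
    d <- matrix(NA_real_, 5, 9)
    for (t in 1:5) for (l in 1:9)
      d[t, l] <- sqrt(sum((st$estimates[t, l, ] - med$coords[l, ])^2))
    pooled <- as.vector(d)
    thr <- mean(pooled) + 2 * sqrt(sum((pooled - mean(pooled))^2) /
                                     (length(pooled) - 1))
    expect_equal(mask$threshold_mm, thr)
    expect_identical(unname(mask$flags), d > thr)
  }
  expect_error(detect_outliers(random_stack(1, 4, seed = 1)), ">= 2")
})

test_that("a single grossly displaced estimate is flagged and only it", {
  st <- random_stack(3, 16, seed = 5)
  cs <- centroid_size(median_aggregate(st))
  est <- st$estimates
  est[2, 7, ] <- est[2, 7, ] + c(100 * cs, 0, 0)
  bad <- estimate_stack(est, st$template_ids, st$labels, st$target_id)
  mask <- detect_outliers(bad)
  expect_true(mask$flags[2, 7])
  expect_equal(sum(mask$flags), 1)
})

test_that("whole corrupted slices are flagged at T = 6 and medians recompute from clean slices", {
  st <- random_stack(6, 16, seed = 6)
  cs <- centroid_size(median_aggregate(st))
  bad <- corrupt_template_slice(st, "tpl3", magnitude = 100 * cs, seed = 2)
  mask <- detect_outliers(bad)
  expect_gte(mean(mask$flags[3, ]), 0.95)
  expect_false(any(mask$flags[-3, ]))

  refined <- recompute_median_excluding(bad, mask)
  clean <- subset_fusion(bad, paste0("tpl", c(1, 2, 4, 5, 6)))
  expect_equal(refined$coords, clean$coords)
})

test_that("recompute_median_excluding handles empty and near-total masks", {
  st <- random_stack(4, 5, seed = 7)
  mask <- detect_outliers(st)
  mask$flags[] <- FALSE
  expect_equal(recompute_median_excluding(st, mask)$coords,
               median_aggregate(st)$coords)

  # all but one template flagged for one landmark -> survivor's estimate
  mask$flags[1:3, 2] <- TRUE
  out <- recompute_median_excluding(st, mask)
  expect_equal(out$coords[2, ], st$estimates[4, 2, ], ignore_attr = TRUE)

  mask$flags[4, 2] <- TRUE
  expect_error(recompute_median_excluding(st, mask), "lm2")
})

test_that("subset fusion restricts the median to named slices", {
  st <- random_stack(5, 6, seed = 8)
  expect_equal(subset_fusion(st, st$template_ids)$coords,
               median_aggregate(st)$coords)
  expect_equal(subset_fusion(st, "tpl2")$coords, st$estimates[2, , ],
               ignore_attr = TRUE)
  # size-2 subset: per-coordinate midpoint
  two <- subset_fusion(st, c("tpl1", "tpl4"))
  expect_equal(two$coords, (st$estimates[1, , ] + st$estimates[4, , ]) / 2,
               ignore_attr = TRUE)
  expect_error(subset_fusion(st, "nope"), "unknown template")
  expect_error(subset_fusion(st, character(0)), "non-empty")
})

test_that("per-specimen thresholds are independent across stacks and outlier removal is stable", {
  st1 <- random_stack(6, 8, seed = 9, target_id = "a")
  st2 <- random_stack(6, 8, seed = 10, target_id = "b")
  m1 <- detect_outliers(st1)
  # corrupting another specimen's stack cannot change this specimen's mask
  cs2 <- centroid_size(median_aggregate(st2))
  st2b <- corrupt_template_slice(st2, "tpl1", 50 * cs2, seed = 3)
  m1b <- detect_outliers(st1)
  expect_identical(m1$flags, m1b$flags)
  expect_identical(m1$threshold_mm, m1b$threshold_mm)

  # removal never pushes the fused output away from the clean consensus
  cs1 <- centroid_size(median_aggregate(st1))
  bad <- corrupt_template_slice(st1, "tpl2", 80 * cs1, seed = 4)
  mask <- detect_outliers(bad)
  clean_consensus <- subset_fusion(st1, setdiff(st1$template_ids, "tpl2"))
  d_before <- rmse(median_aggregate(bad), clean_consensus)
  d_after <- rmse(recompute_median_excluding(bad, mask), clean_consensus)
  expect_lte(d_after, d_before + 1e-12)

  # excluding a whole template drops its slice
  dropped <- exclude_template(st1, "tpl2")
  expect_equal(dropped$template_ids, paste0("tpl", c(1, 3:6)))
})
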