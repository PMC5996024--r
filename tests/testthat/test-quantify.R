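# Intensity ratios, normalisations, ROUT outlier removal, group tests.

test_that("band projection sums the documented six planes", {
  d <- c(8, 8, 12)
  a <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)  # plane z has value z
  g <- voxel_grid(a, c(0.1, 0.1, 0.23))
  anchor <- 6.5 * 0.23                     # voxel-centre of plane 7
  proj <- band_projection(g, anchor)
  # anchor plane + 3 above + 2 below: planes 5..10
  expect_equal(attr(proj, "planes"), 5:10)
  expect_true(all(proj == sum(5:10)))
  # identical planes: projection mean = 6 * plane mean
  g2 <- voxel_grid(array(3, d), c(0.1, 0.1, 0.23))
  expect_true(all(band_projection(g2, anchor) == 18))
  # single nonzero plane inside the band
  a3 <- array(0, d); a3[, , 7] <- 5
  expect_true(all(band_projection(voxel_grid(a3, c(0.1, 0.1, 0.23)),
                                  anchor) == 5))
  # truncated band proceeds with a warning
  expect_warning(band_projection(g, 0.1), "truncated")
  expect_error(band_projection(g, 99), "outside")
})

test_that("patch ratio behaves on uniform and two-level images", {
  img <- matrix(1, 10, 10)
  patch <- matrix(FALSE, 10, 10); patch[4:6, 4:6] <- TRUE
  cell <- matrix(TRUE, 10, 10)
  expect_equal(patch_ratio(img, patch, cell), 1.0)
  img2 <- img; img2[patch] <- 2
  expect_equal(patch_ratio(img2, patch, cell), 2.0)
  # scale invariance
  expect_equal(patch_ratio(img2 * 17, patch, cell), 2.0)
  expect_error(patch_ratio(img, patch, !patch), "subset")
  expect_warning(patch_ratio(img, cell, cell), "empty rest")
})

test_that("neighbour normalisation picks the three closest cells", {
  res <- neighbour_normalised_intensity(5, c(10, 10, 10, 99),
                                        c(1, 2, 3, 0.5))
  # the closest three are ids 4, 1, 2 -> mean (99 + 10 + 10) / 3
  expect_equal(res$fold_change, 5 / mean(c(99, 10, 10)))
  expect_false(res$flag)
  same <- neighbour_normalised_intensity(7, c(7, 7, 7), c(1, 2, 3))
  expect_equal(same$fold_change, 1.0)
  half <- neighbour_normalised_intensity(5, c(10, 10, 10), c(1, 2, 3))
  expect_equal(half$fold_change, 0.5)
  few <- neighbour_normalised_intensity(5, c(10, 10), c(1, 2))
  expect_true(few$flag)
})

test_that("fold changes are scale-free and exact on known inputs", {
  expect_equal(fold_change_counts(15, rep(30, 10))$mean_fold_change, 0.5)
  x <- c(20, 30, 40); ref <- c(25, 35, 30)
  f1 <- fold_change_counts(x, ref)$fold_changes
  f2 <- fold_change_counts(2 * x, 2 * ref)$fold_changes
  expect_equal(f1, f2)
  same <- fold_change_counts(ref, ref)$mean_fold_change
  expect_equal(same, 1.0)
  expect_error(fold_change_counts(1, numeric(0)), "non-empty")
  expect_error(fold_change_counts(1, c(0, 0)), "zero reference")
})

test_that("ROUT removes gross contaminants but spares clean samples", {
  set.seed(10)
  removals <- vapply(1:20, function(i) {
    x <- rnorm(100)
    length(remove_outliers_rout(x, Q = 1)$removed)
  }, integer(1))
  expect_true(all(removals <= 5))
  set.seed(11)
  x <- c(rnorm(50), 10)
  res <- remove_outliers_rout(x, Q = 1)
  expect_true(10 %in% res$removed)
  # constant sample: nothing removed
  res2 <- remove_outliers_rout(rep(3, 20), Q = 1)
  expect_equal(length(res2$removed), 0)
  expect_warning(remove_outliers_rout(rnorm(5)), "fewer than 10")
})

test_that("ROUT removals vanish as Q -> 0 and grow with Q", {
  set.seed(12)
  x <- c(rnorm(60), 6, 8, -7)
  n_rm <- vapply(c(0.0001, 0.1, 1, 5, 10), function(q)
    length(remove_outliers_rout(x, Q = q)$removed), integer(1))
  expect_equal(n_rm[1], 3)  # the 3 gross contaminants always fail
  expect_true(all(diff(n_rm) >= 0))
  tiny <- remove_outliers_rout(rnorm(30), Q = 1e-9)
  expect_equal(length(tiny$removed), 0)
})

test_that("two-group comparison is a Mann-Whitney with sane nulls", {
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  res <- compare_groups(c(x, y), rep(c("a", "b"), each = 30))
  expect_equal(res$method, "mann-whitney")
  expect_gt(res$p_value, 0.001)
  res2 <- compare_groups(c(x, x + 3), rep(c("a", "b"), each = 30))
  expect_lt(res2$p_value, 1e-6)
})

test_that("multi-group comparison runs Kruskal-Wallis then Dunn", {
  set.seed(14)
  v <- c(rnorm(20), rnorm(20) + 2, rnorm(20))
  g <- rep(c("ctrl", "drug", "sham"), each = 20)
  res <- compare_groups(v, g)
  expect_equal(res$method, "kruskal-dunn")
  expect_lt(res$p_value, 0.001)
  pw <- res$pairwise
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p - 1e-15))
  sig <- pw[pw$group1 == "ctrl" & pw$group2 == "drug", ]
  expect_lt(sig$p_adj, 0.01)
  ns <- pw[pw$group1 == "ctrl" & pw$group2 == "sham", ]
  expect_gt(ns$p_adj, 0.05)
})

test_that("rank tests are well-calibrated under the null", {
  set.seed(15)
  rej <- vapply(1:300, function(i) {
    v <- rnorm(60)
    compare_groups(v, rep(c("a", "b"), each = 30))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("the trend test detects a drifting binned distribution", {
  a <- c(40, 30, 20, 10)
  b <- c(10, 20, 30, 40)
  # suppressWarnings: chi-square machinery warns on a deterministic gradient
  res <- suppressWarnings(trend_test_counts(a, b))
  expect_lt(res$p_value, 1e-6)
  flat <- suppressWarnings(trend_test_counts(c(25, 25, 25, 25),
                                             c(25, 25, 25, 25)))
  expect_gt(flat$p_value, 0.99)
})
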