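# Gaussian/LoG filtering and 3D local-maximum extraction.

make_blob_grid <- function(centres_um, d = c(40, 40, 12),
                           vs = c(0.1, 0.1, 0.23),
                           sigma = c(0.1, 0.1, 0.25), amp = 100) {
  a <- array(0, d)
  g <- voxel_grid(a, vs)
  for (k in seq_len(nrow(centres_um))) {
    cv <- centres_um[k, ] / vs + 0.5
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) {
      x <- seq_len(d[1])
      a[, y, z] <- a[, y, z] + amp *
        exp(-((x - cv[1])^2 * vs[1]^2 / (2 * sigma[1]^2) +
              (y - cv[2])^2 * vs[2]^2 / (2 * sigma[2]^2) +
              (z - cv[3])^2 * vs[3]^2 / (2 * sigma[3]^2)))
    }
  }
  voxel_grid(a, vs)
}

test_that("a constant stack has zero LoG response", {
  g <- voxel_grid(array(7.5, c(16, 16, 8)))
  resp <- filter_stack(g)
  expect_lt(max(abs(resp$data)), 1e-10)
  expect_equal(nrow(extract_maxima(resp)), 0)
})

test_that("the response peaks at the centre of a rendered blob", {
  centre <- matrix(c(2.05, 1.95, 1.25), 1)
  g <- make_blob_grid(centre)
  resp <- filter_stack(g)
  # brute-force argmax over the filtered array
  k <- arrayInd(which.max(resp$data), dim(resp$data))
  pos <- (k - 0.5) * g$voxel_size
  expect_lt(sqrt(sum((pos - centre)^2)), sqrt(sum((g$voxel_size / 2)^2)) + 1e-9)
})

test_that("two blobs 2 um apart give two maxima at the blob centres", {
  centres <- rbind(c(1.0, 2.0, 1.25), c(3.0, 2.0, 1.25))
  g <- make_blob_grid(centres)
  det <- extract_maxima(filter_stack(g),
                        detection_params(threshold_quantile = 0.999))
  expect_equal(nrow(det), 2)
  for (k in 1:2) {
    dd <- sqrt((det$x_um - centres[k, 1])^2 + (det$y_um - centres[k, 2])^2 +
               (det$z_um - centres[k, 3])^2)
    expect_lt(min(dd), 0.2)
  }
})

test_that("all ground-truth spots are recovered on a noiseless render", {
  sc <- render_stack(quiet_scene(seed = 5))
  det <- extract_maxima(filter_stack(sc$channels$centrin),
                        detection_params(threshold_quantile = 0.999))
  truth <- sc$truth$points[sc$truth$points$type == "centrin", ]
  expect_equal(nrow(det), 30)
  m <- match_detections(as.matrix(det[, c("x_um", "y_um", "z_um")]),
                        as.matrix(truth[, c("x_um", "y_um", "z_um")]),
                        radius_um = 0.3)
  expect_equal(m$tp, 30)
  # centroid error bounded by the voxel half-diagonal
  half_diag <- sqrt(sum((c(0.1, 0.1, 0.23) / 2)^2))
  dm <- sqrt(outer(det$x_um, truth$x_um, `-`)^2 +
             outer(det$y_um, truth$y_um, `-`)^2 +
             outer(det$z_um, truth$z_um, `-`)^2)
  expect_lt(max(apply(dm, 1, min)), half_diag + 1e-9)
})

test_that("detections shift with the stack (translation equivariance)", {
  sc <- render_stack(quiet_scene(seed = 6, centrioles_per_cell = 10))
  g <- sc$channels$centrin
  p <- detection_params(threshold_quantile = 0.999)
  det0 <- extract_maxima(filter_stack(g, p), p)
  shift <- c(3L, 2L, 1L)
  a <- g$data
  d <- dim(a)
  b <- array(0, d)
  b[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
    a[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
  det1 <- extract_maxima(filter_stack(voxel_grid(b, g$voxel_size), p), p)
  # compare the common spots (ones not too close to the moved border)
  off <- shift * g$voxel_size
  o0 <- det0[order(det0$x_um, det0$y_um, det0$z_um), ]
  o1 <- det1[order(det1$x_um, det1$y_um, det1$z_um), ]
  expect_equal(nrow(o0), nrow(o1))
  expect_equal(o1$x_um, o0$x_um + off[1], tolerance = 1e-9)
  expect_equal(o1$y_um, o0$y_um + off[2], tolerance = 1e-9)
  expect_equal(o1$z_um, o0$z_um + off[3], tolerance = 1e-9)
})

test_that("positions are invariant to intensity scaling with quantile thresholds", {
  sc <- render_stack(quiet_scene(seed = 7, centrioles_per_cell = 15))
  g <- sc$channels$centrin
  p <- detection_params(threshold_quantile = 0.999)
  d1 <- extract_maxima(filter_stack(g, p), p)
  g2 <- voxel_grid(g$data * 3.7, g$voxel_size)
  d2 <- extract_maxima(filter_stack(g2, p), p)
  expect_equal(d1[, c("x_um", "y_um", "z_um")],
               d2[, c("x_um", "y_um", "z_um")])
})

test_that("counts are monotone non-increasing in threshold and min-distance", {
  sc <- render_stack(quiet_scene(seed = 8))
  resp <- filter_stack(sc$channels$centrin)
  qs <- c(0.99, 0.995, 0.999, 0.9999)
  ns <- vapply(qs, function(q)
    nrow(extract_maxima(resp, detection_params(threshold_quantile = q))),
    integer(1))
  expect_true(all(diff(ns) <= 0))
  ds <- c(0.2, 0.3, 0.5, 1.0)
  nd <- vapply(ds, function(md)
    nrow(extract_maxima(resp, detection_params(min_distance_um = md,
                                               threshold_quantile = 0.999))),
    integer(1))
  expect_true(all(diff(nd) <= 0))
})

test_that("few false positives arise from pure noise at a high threshold", {
  fp <- vapply(1:20, function(seed) {
    set.seed(seed)
    g <- voxel_grid(array(rnorm(32 * 32 * 10), c(32, 32, 10)))
    nrow(extract_maxima(filter_stack(g),
                        detection_params(threshold_quantile = 0.999)))
  }, integer(1))
  n_vox <- 32 * 32 * 10
  nbhd <- (2 * 3 + 1)^2 * (2 * 1 + 1)   # box neighbourhood at defaults
  expected <- 0.001 * n_vox / nbhd
  expect_lte(mean(fp), 3 * max(expected, 1))
})

test_that("spots are assigned to cells with a documented edge tie-break", {
  polys <- list(cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)),
                cbind(x = c(2, 4, 4, 2), y = c(0, 0, 2, 2)))
  spots <- spot_set(rbind(c(1, 1, 0.5),     # cell 1
                          c(3, 0.5, 0.5),   # cell 2
                          c(2, 1, 0.5),     # shared edge
                          c(5, 5, 0.5)))    # outside
  res <- count_centrioles(spots, polys)
  expect_equal(unname(res$counts), c(2L, 1L))
  expect_true(res$spots$on_edge[3])
  expect_equal(res$spots$cell_id[3], 1L)    # lowest cell id wins
  expect_equal(nrow(res$unassigned), 1)
  # overlapping polygons are a hard error
  overlap <- list(cbind(x = c(0, 3, 3, 0), y = c(0, 0, 2, 2)),
                  cbind(x = c(2, 4, 4, 2), y = c(0, 0, 2, 2)))
  expect_error(count_centrioles(spot_set(matrix(c(2.5, 1, 0.5), 1)), overlap),
               "overlapping")
})

test_that("under-resolved filter sigmas trigger a warning", {
  g <- voxel_grid(array(runif(8 * 8 * 4), c(8, 8, 4)), c(0.1, 0.1, 0.23))
  expect_warning(gaussian_smooth(g, c(0.1, 0.1, 0.05)), "under-resolved")
})
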