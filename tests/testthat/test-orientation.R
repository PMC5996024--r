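# Hungarian pairing, orientation fields, circular histograms and tests.

test_that("identical point sets map by identity at zero cost", {
  pts <- cbind(runif(6), runif(6))
  pg <- assign_pairs(pts, pts)
  expect_equal(pg$pairs$centrin_idx, pg$pairs$cep164_idx)
  expect_equal(pg$total_cost, 0)
})

test_that("a collinear 3x3 instance matches in order at the known cost", {
  cen <- rbind(c(0, 0), c(1, 0), c(2, 0))
  cep <- rbind(c(0.1, 0), c(1.1, 0), c(2.1, 0))
  pg <- assign_pairs(cen, cep)
  expect_equal(pg$pairs$cep164_idx, 1:3)
  expect_equal(pg$total_cost, 0.3, tolerance = 1e-12)
  cost <- sqrt(outer(cen[, 1], cep[, 1], `-`)^2 +
               outer(cen[, 2], cep[, 2], `-`)^2)
  expect_equal(pg$total_cost, brute_force_assignment_cost(cost),
               tolerance = 1e-12)
})

test_that("assignment cost equals the factorial oracle on random instances", {
  set.seed(2024)
  for (rep in 1:120) {
    n <- sample(1:7, 1)
    m <- if (n == 7) 7L else sample(n:7, 1)
    cen <- cbind(runif(n), runif(n))
    cep <- cbind(runif(m), runif(m))
    pg <- assign_pairs(cen, cep)
    cost <- sqrt(outer(cen[, 1], cep[, 1], `-`)^2 +
                 outer(cen[, 2], cep[, 2], `-`)^2)
    expect_equal(pg$total_cost, brute_force_assignment_cost(cost),
                 tolerance = 1e-9)
    expect_equal(nrow(pg$pairs), n)
  }
})

test_that("assignment handles unequal sizes and empty sets", {
  cen <- cbind(runif(5), runif(5))
  cep <- cbind(runif(3), runif(3))
  pg <- assign_pairs(cen, cep)
  expect_equal(nrow(pg$pairs), 3)
  expect_equal(length(pg$unmatched_centrin), 2)
  pg0 <- assign_pairs(matrix(numeric(0), ncol = 2), cep)
  expect_equal(nrow(pg0$pairs), 0)
})

test_that("total cost is invariant under common rotation/translation", {
  set.seed(77)
  cen <- cbind(runif(10), runif(10))
  cep <- cen + 0.25 * cbind(cos(runif(10, 0, 2 * pi)),
                            sin(runif(10, 0, 2 * pi)))
  c0 <- assign_pairs(cen, cep)$total_cost
  th <- 1.2
  Rm <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  c1 <- assign_pairs(cen %*% Rm + 5, cep %*% Rm + 5)$total_cost
  expect_equal(c0, c1, tolerance = 1e-9)
})

test_that("orientation stats recover aligned and degenerate fields", {
  cen <- cbind(1:4, rep(0, 4))
  cep <- cen + matrix(rep(c(0, 0.25), each = 4), ncol = 2)  # all at 90 deg
  of <- orientation_stats(assign_pairs(cen, cep))
  expect_equal(of$mean_direction_rad, pi / 2, tolerance = 1e-12)
  expect_equal(of$R, 1, tolerance = 1e-12)
  expect_true(all(abs(of$deviations_rad) < 1e-12))
  # antipodal pair: R = 0, mean undefined
  anti <- list(pairs = data.frame(centrin_x = c(0, 0), centrin_y = c(0, 0),
                                  cep164_x = c(1, -1), cep164_y = c(0, 0)))
  of2 <- orientation_stats(anti)
  expect_lt(of2$R, 1e-10)
  expect_false(of2$mean_defined)
  # zero-length displacement excluded with a warning
  z <- list(pairs = data.frame(centrin_x = c(0, 0), centrin_y = c(0, 1),
                               cep164_x = c(0, 1), cep164_y = c(0, 1)))
  expect_warning(of3 <- orientation_stats(z), "zero-length")
  expect_equal(of3$n, 1)
})

test_that("rotating inputs rotates the mean and preserves R and deviations", {
  set.seed(3)
  cen <- cbind(runif(20), runif(20))
  ang <- rvonmises(20, 0.7, 4)
  cep <- cen + 0.25 * cbind(cos(ang), sin(ang))
  of0 <- orientation_stats(assign_pairs(cen, cep))
  phi <- 0.9
  Rm <- rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  of1 <- orientation_stats(assign_pairs(cen %*% Rm, cep %*% Rm))
  expect_equal(of1$R, of0$R, tolerance = 1e-9)
  expect_equal(wrap_angle(of1$mean_direction_rad -
                            (of0$mean_direction_rad + phi)), 0,
               tolerance = 1e-6)
  expect_equal(sort(of1$deviations_rad), sort(of0$deviations_rad),
               tolerance = 1e-6)
})

test_that("uniform angles give a small resultant length", {
  set.seed(55)
  small <- vapply(1:20, function(i) {
    a <- runif(1000, 0, 2 * pi)
    sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  }, numeric(1))
  expect_gte(mean(small <= 0.09), 0.95)
})

test_that("circular histogram uses 18 half-open 20-degree bins", {
  mids <- (seq_len(18) - 0.5) * 20
  h <- circular_histogram(mids * pi / 180)
  expect_equal(h$counts, rep(1L, 18))
  # exactly 20 degrees falls in the second bin
  h2 <- circular_histogram(20 * pi / 180)
  expect_equal(h2$counts[2], 1L)
  expect_equal(sum(h2$counts), 1L)
  # uniform grid of 360 angles: every bin holds 20
  h3 <- circular_histogram((0:359) * pi / 180)
  expect_equal(h3$counts, rep(20L, 18))
  expect_error(circular_histogram(0, bin_width_deg = 25), "divide")
})

test_that("Watson U2 is zero for a sample against itself", {
  set.seed(1)
  a <- runif(40, 0, 2 * pi)
  w <- watson_u2_test(a, a)
  expect_equal(w$statistic, 0, tolerance = 1e-12)
  expect_equal(w$p_value, 1, tolerance = 1e-6)
})

test_that("Watson U2 is invariant to a common rotation", {
  set.seed(2)
  a <- rvonmises(30, 0, 2)
  b <- rvonmises(35, 1, 2)
  w0 <- watson_u2_test(a, b)$statistic
  w1 <- watson_u2_test(a + 2.1, b + 2.1)$statistic
  expect_equal(w0, w1, tolerance = 1e-10)
  expect_true(watson_u2_test(a[1:5], b)$unreliable)
})

test_that("Watson U2 separates concentrated from uniform angles", {
  set.seed(6)
  rej <- vapply(1:100, function(i) {
    a <- rvonmises(50, 0, 4)
    b <- runif(50, -pi, pi)
    watson_u2_test(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("compare_angle_distributions returns both tests", {
  set.seed(4)
  a <- rvonmises(30, 0, 3)
  b <- rvonmises(30, 0.3, 3)
  res <- compare_angle_distributions(a, b)
  expect_true(is.finite(res$watson$statistic))
  expect_true(res$ks$p_value >= 0 && res$ks$p_value <= 1)
})
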