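# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (factorial / O(n^2) / O(n^4)) and share no
# code with the package internals.

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

# exhaustive minimum assignment cost of an n x m matrix, n <= m <= 8
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 8)
  best <- Inf
  for (p in all_perms(m)) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) best <- tot
  }
  best
}

# convex hull area by brute force: a point is a hull vertex iff it is not
# strictly inside the triangle of any three other points; vertices are then
# ordered by angle around their centroid and the shoelace formula applied
brute_force_hull_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= 0 && s2 >= 0 && s3 >= 0) || (s1 <= 0 && s2 <= 0 && s3 <= 0)
  }
  is_vertex <- rep(TRUE, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    combos <- utils::combn(others, 3)
    for (k in seq_len(ncol(combos))) {
      tri <- combos[, k]
      if (in_triangle(xy[i, ], xy[tri[1], ], xy[tri[2], ], xy[tri[3], ])) {
        # strictly inside or on the triangle: drop only if strictly inside
        a <- xy[tri[1], ]; b <- xy[tri[2], ]; cc <- xy[tri[3], ]
        p <- xy[i, ]
        s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
        s2 <- (cc[1] - b[1]) * (p[2] - b[2]) - (cc[2] - b[2]) * (p[1] - b[1])
        s3 <- (a[1] - cc[1]) * (p[2] - cc[2]) - (a[2] - cc[2]) * (p[1] - cc[1])
        if ((s1 > 0 && s2 > 0 && s3 > 0) || (s1 < 0 && s2 < 0 && s3 < 0)) {
          is_vertex[i] <- FALSE
          break
        }
      }
    }
  }
  v <- xy[is_vertex, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  ord <- order(atan2(v[, 2] - cy, v[, 1] - cx))
  v <- v[ord, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# O(n^2) nearest-neighbour oracle
brute_force_nn <- function(xy) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# greedy bipartite matching of detections to ground truth at a radius,
# used to score recall/precision independently of the detector
match_detections <- function(det, truth, radius_um) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(list(tp = 0, fp = nrow(det), fn = nrow(truth)))
  dm <- sqrt(outer(det[, 1], truth[, 1], `-`)^2 +
             outer(det[, 2], truth[, 2], `-`)^2 +
             outer(det[, 3], truth[, 3], `-`)^2)
  tp <- 0L
  while (TRUE) {
    k <- which.min(dm)
    if (dm[k] > radius_um) break
    ij <- arrayInd(k, dim(dm))
    tp <- tp + 1L
    dm[ij[1], ] <- Inf
    dm[, ij[2]] <- Inf
    if (all(!is.finite(dm))) break
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

# tiny default scene used across tests: one cell, zero noise
quiet_scene <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_cells = 1, centrioles_per_cell = 30, noise_sd = 0,
                   poisson_scale = 0, seed = seed)
  do.call(scene_spec, utils::modifyList(defaults, args))
}
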