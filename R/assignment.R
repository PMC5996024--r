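#' Minimum-cost assignment of a cost matrix (Hungarian method)
#'
#' Solves the rectangular linear assignment problem by the Jonker–Volgenant
#' shortest-augmenting-path formulation of the Hungarian algorithm in
#' O(n^2 m).  Every row of the (n <= m) cost matrix is matched to a distinct
#' column so that the total cost is minimal; rectangular inputs with more
#' rows than columns are solved on the transpose.
#'
#' @param cost numeric cost matrix, no NAs.
#' @return list with `rows`, `cols` (matched index pairs, one per
#'   `min(nrow, ncol)`) and `cost` (the minimal total).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L)
    return(list(rows = integer(0), cols = integer(0), cost = 0))
  INF <- .Machine$double.xmax / 4
  # potentials u (rows), v (cols); p[j] = row matched to column j.
  # index 1 of the column arrays stands for the virtual column 0.
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  rows <- integer(n); cols <- integer(n)
  k <- 0L
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) {
      k <- k + 1L
      rows[k] <- p[j + 1L]
      cols[k] <- j
    }
  }
  ord <- order(rows)
  rows <- rows[ord]; cols <- cols[ord]
  total <- sum(cost[cbind(rows, cols)])
  if (transposed) list(rows = cols, cols = rows, cost = total)
  else list(rows = rows, cols = cols, cost = total)
}

#' Pair centrin puncta with Cep164 puncta by minimum total distance
#'
#' Builds the xy Euclidean distance matrix between the two point sets of one
#' cell and solves the assignment that minimises the summed distance over
#' all pairs (Hungarian algorithm).  With unequal set sizes — detection of
#' the two markers is imperfect — `min(n, m)` pairs are produced and the
#' unmatched points of the larger set are reported, never silently dropped.
#'
#' @param centrins n x 2 matrix (or data.frame with `x_um`, `y_um`) of
#'   centrin xy positions (um).
#' @param cep164s m x 2 matrix of Cep164 xy positions (um).
#' @return a `pairing`: list with `pairs` (data.frame: centrin_idx,
#'   cep164_idx, centrin_x, centrin_y, cep164_x, cep164_y, distance_um),
#'   `total_cost`, `unmatched_centrin`, `unmatched_cep164`.
#' @export
assign_pairs <- function(centrins, cep164s) {
  cen <- as_xy(centrins)
  cep <- as_xy(cep164s)
  if (nrow(cen) == 0L || nrow(cep) == 0L) {
    return(list(pairs = data.frame(centrin_idx = integer(0),
                                   cep164_idx = integer(0),
                                   centrin_x = numeric(0),
                                   centrin_y = numeric(0),
                                   cep164_x = numeric(0),
                                   cep164_y = numeric(0),
                                   distance_um = numeric(0)),
                total_cost = 0,
                unmatched_centrin = seq_len(nrow(cen)),
                unmatched_cep164 = seq_len(nrow(cep))))
  }
  cost <- sqrt(outer(cen[, 1], cep[, 1], `-`)^2 +
               outer(cen[, 2], cep[, 2], `-`)^2)
  sol <- solve_assignment(cost)
  pairs <- data.frame(
    centrin_idx = sol$rows, cep164_idx = sol$cols,
    centrin_x = cen[sol$rows, 1], centrin_y = cen[sol$rows, 2],
    cep164_x = cep[sol$cols, 1], cep164_y = cep[sol$cols, 2],
    distance_um = cost[cbind(sol$rows, sol$cols)])
  pairs <- pairs[order(pairs$centrin_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, total_cost = sol$cost,
       unmatched_centrin = setdiff(seq_len(nrow(cen)), sol$rows),
       unmatched_cep164 = setdiff(seq_len(nrow(cep)), sol$cols))
}

#' @noRd
as_xy <- function(p) {
  if (is.data.frame(p)) {
    if (all(c("x_um", "y_um") %in% names(p)))
      return(cbind(p$x_um, p$y_um))
    p <- as.matrix(p)
  }
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}
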