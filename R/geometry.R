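#' Convex-hull area of a point set in the xy plane
#'
#' The centriolar patch size is defined as the area of the minimum convex
#' region in xy that contains every centriole of the cell.  Computed as the
#' shoelace area over the convex-hull vertices; degenerate sets (fewer than 3
#' points, or collinear) have area 0.  The z coordinate is deliberately
#' ignored throughout the patch geometry.
#'
#' @param xy n x 2 matrix (or spot-set columns) of positions in um.
#' @return area in um^2.
#' @export
hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) return(0)
  x <- xy[h, 1]; y <- xy[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Nearest-neighbour distance of every point in a set (xy)
#'
#' For each point, the Euclidean xy distance to its closest other point,
#' returned in input order.  Coincident points yield a distance of 0 and a
#' warning.
#'
#' @param xy n x 2 matrix of positions (um), n >= 2.
#' @return numeric vector of length n.
#' @export
nearest_neighbour_distances <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points for nearest-neighbour distances")
  dm <- as.matrix(stats::dist(xy[, 1:2, drop = FALSE]))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  if (any(nn == 0)) warning("duplicate positions: zero nearest-neighbour ",
                            "distance")
  unname(nn)
}

#' Density-based centriolar patch membership
#'
#' Formalises "patch boundaries estimated from the spatial density of the
#' centrins" as density connectivity: core spots have at least `min_density`
#' other spots within `density_radius_um` (xy); a cluster is a connected
#' component of core spots plus the non-core spots within reach of one.  The
#' patch is the cluster with the most members, ties broken by higher summed
#' score, then by lower lexicographic (x, y) centroid.  If no spot is core,
#' the patch degenerates to the single highest-scoring spot and is flagged
#' low-confidence.
#'
#' @param spots a `spot_set` from one cell (needs `x_um`, `y_um`, optionally
#'   `score`).
#' @param density_radius_um neighbourhood radius (um); a sensible default is
#'   about twice the typical inter-centriole spacing.
#' @param min_density minimum number of neighbours (excluding the spot
#'   itself) for a core spot.
#' @return list with `members` (integer indices into `spots`, sorted),
#'   `clusters` (list of all cluster index vectors), and `low_confidence`
#'   (logical).
#' @export
patch_boundary <- function(spots, density_radius_um = 0.8, min_density = 3) {
  n <- nrow(spots)
  if (n == 0) return(list(members = integer(0), clusters = list(),
                          low_confidence = TRUE))
  score <- if ("score" %in% names(spots)) spots$score else rep(1, n)
  if (n == 1) return(list(members = 1L, clusters = list(1L),
                          low_confidence = TRUE))
  dm <- as.matrix(stats::dist(cbind(spots$x_um, spots$y_um)))
  adj <- dm <= density_radius_um
  diag(adj) <- FALSE
  core <- rowSums(adj) >= min_density
  if (!any(core)) {
    best <- order(-score, spots$x_um, spots$y_um)[1]
    return(list(members = best, clusters = list(best),
                low_confidence = TRUE))
  }
  # flood-fill over core spots; border spots join a neighbouring core cluster
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (s in which(core)) {
    if (!is.na(cluster[s])) next
    next_id <- next_id + 1L
    queue <- s
    cluster[s] <- next_id
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(cluster) & core)
      cluster[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  for (s in which(!core)) {
    nb <- which(adj[s, ] & core)
    if (length(nb)) cluster[s] <- min(cluster[nb])
  }
  ids <- sort(unique(cluster[!is.na(cluster)]))
  clusters <- lapply(ids, function(id) which(cluster == id))
  size <- vapply(clusters, length, integer(1))
  tot <- vapply(clusters, function(ix) sum(score[ix]), numeric(1))
  cx <- vapply(clusters, function(ix) mean(spots$x_um[ix]), numeric(1))
  cy <- vapply(clusters, function(ix) mean(spots$y_um[ix]), numeric(1))
  best <- order(-size, -tot, cx, cy)[1]
  list(members = sort(clusters[[best]]), clusters = clusters,
       low_confidence = FALSE)
}

#' Per-cell patch model: members, hull, area, spacing, count
#'
#' Convenience wrapper running [patch_boundary()], [hull_area()] and
#' [nearest_neighbour_distances()] for the spots of one cell.
#'
#' @param spots `spot_set` of one cell.
#' @param cell_id identifier carried through to the output.
#' @inheritParams patch_boundary
#' @return a `patch_model` list: `cell_id`, `members`, `hull` (vertex matrix
#'   or NULL), `area_um2`, `nn_um` (vector), `count`, `low_confidence`.
#' @export
build_patch_model <- function(spots, cell_id = NA,
                              density_radius_um = 0.8, min_density = 3) {
  pb <- patch_boundary(spots, density_radius_um, min_density)
  mem <- spots[pb$members, , drop = FALSE]
  xy <- cbind(mem$x_um, mem$y_um)
  hull <- NULL
  if (nrow(xy) >= 3L) {
    h <- grDevices::chull(xy[, 1], xy[, 2])
    hull <- xy[h, , drop = FALSE]
  }
  structure(list(
    cell_id = cell_id,
    members = pb$members,
    hull = hull,
    area_um2 = hull_area(xy),
    nn_um = if (nrow(xy) >= 2L) nearest_neighbour_distances(xy)
            else numeric(0),
    count = nrow(mem),
    low_confidence = pb$low_confidence
  ), class = "patch_model")
}
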