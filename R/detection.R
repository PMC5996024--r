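#' Parameters of the centriole detector
#'
#' The detector reproduces a two-stage blob pipeline: Gaussian smoothing to
#' suppress noise, a (sign-flipped) Laplacian-of-Gaussian to enhance puncta
#' of centriole scale, and extraction of local 3D maxima.  Filter scales are
#' set from the average 3D size of a centriole and are meant to be held
#' constant across conditions; all of them are exposed here.
#'
#' @param gauss_sigma_um Gaussian pre-smoothing sigma (x, y, z) in um;
#'   defaults to the diffraction-limited centriole scale (0.1, 0.1, 0.25).
#' @param log_sigma_um LoG blob scale (x, y, z) in um; defaults to the
#'   rendered punctum width.
#' @param min_distance_um minimum separation between reported maxima (um);
#'   also the radius of the local-maximum neighbourhood.
#' @param threshold absolute response threshold; overrides
#'   `threshold_quantile` when given.
#' @param threshold_quantile quantile of the response used as the threshold
#'   when no absolute threshold is given (default 0.995).
#' @param border_margin_vox maxima closer than this many voxels to any stack
#'   face are discarded (default 1).
#' @param refine if `TRUE`, positions are refined to sub-voxel precision by a
#'   per-axis quadratic fit around each maximum.  Off by default: the
#'   reference counting procedure reports voxel maxima.
#'
#' @return object of class `detection_params`.
#' @export
detection_params <- function(gauss_sigma_um = c(0.1, 0.1, 0.25),
                             log_sigma_um = c(0.1, 0.1, 0.25),
                             min_distance_um = 0.3,
                             threshold = NULL,
                             threshold_quantile = 0.995,
                             border_margin_vox = 1L,
                             refine = FALSE) {
  if (any(gauss_sigma_um <= 0) || any(log_sigma_um <= 0))
    stop("filter sigmas must be strictly positive")
  if (min_distance_um <= 0) stop("min distance must be strictly positive")
  structure(list(gauss_sigma_um = gauss_sigma_um,
                 log_sigma_um = log_sigma_um,
                 min_distance_um = min_distance_um,
                 threshold = threshold,
                 threshold_quantile = threshold_quantile,
                 border_margin_vox = as.integer(border_margin_vox),
                 refine = isTRUE(refine)),
            class = "detection_params")
}

#' Gaussian + Laplacian-of-Gaussian blob enhancement
#'
#' Smooths the stack with an anisotropic 3D Gaussian, then applies a
#' sign-flipped Laplacian-of-Gaussian so that bright puncta become positive
#' peaks.  Sigmas are interpreted in physical um and converted per axis, so
#' anisotropic voxels are handled correctly.  A constant stack maps to a
#' response of exactly zero.
#'
#' @param grid a [voxel_grid()].
#' @param params a [detection_params()].
#' @return the response as a [voxel_grid()].
#' @export
filter_stack <- function(grid, params = detection_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  smoothed <- gaussian_smooth(grid, params$gauss_sigma_um)
  log_response(smoothed, params$log_sigma_um)
}

# separable box dilation with per-axis radius in voxels
#' @noRd
box_dilate <- function(a, radii_vox) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  for (ax in 1:3) {
    r <- radii_vox[ax]
    if (r < 1L) next
    n <- d[ax]
    out <- a
    for (off in c(seq_len(r), -seq_len(r))) {
      src <- idx
      src[[ax]] <- pmin.int(pmax.int(seq_len(n) + off, 1L), n)
      out <- pmax(out, do.call(`[`, c(list(a), src, list(drop = FALSE))))
    }
    a <- out
  }
  a
}

#' Extract local 3D maxima from a filter response
#'
#' A voxel is a candidate if it attains the maximum of its axis-aligned
#' neighbourhood (radius `min_distance_um`, converted per axis) and exceeds
#' the threshold.  Candidates are then greedily pruned, in descending score
#' and lexicographic (x, y, z) order, so that the returned spots are pairwise
#' at least `min_distance_um` apart in physical (Euclidean) distance.
#' An empty result is valid and simply means a count of zero.
#'
#' @param filtered response grid from [filter_stack()].
#' @param params a [detection_params()].
#' @return a `spot_set`: data.frame with columns `x_um`, `y_um`, `z_um`,
#'   `score`, ordered by descending score then position.
#' @export
extract_maxima <- function(filtered, params = detection_params()) {
  stopifnot(inherits(filtered, "voxel_grid"))
  a <- filtered$data
  d <- dim(a)
  vs <- filtered$voxel_size
  radii <- pmax(1L, floor(params$min_distance_um / vs))
  dil <- box_dilate(a, radii)
  th <- if (!is.null(params$threshold)) params$threshold
        else stats::quantile(a, params$threshold_quantile, names = FALSE)
  cand <- which(a >= dil & a > th, arr.ind = TRUE)
  m <- params$border_margin_vox
  if (m > 0L && nrow(cand) > 0) {
    keep <- cand[, 1] > m & cand[, 1] <= d[1] - m &
            cand[, 2] > m & cand[, 2] <= d[2] - m &
            cand[, 3] > m & cand[, 3] <= d[3] - m
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    return(empty_spot_set())
  score <- a[cand]
  ord <- order(-score, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  score <- score[ord]
  pos <- sweep(cand - 0.5, 2L, vs, `*`)
  # greedy minimum-distance suppression in physical coordinates
  kept <- integer(0)
  for (i in seq_len(nrow(pos))) {
    if (length(kept) == 0) { kept <- i; next }
    dd <- sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2))
    if (min(dd) >= params$min_distance_um) kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]
  score <- score[kept]
  pos <- pos[kept, , drop = FALSE]
  if (params$refine && nrow(cand) > 0) {
    for (ax in 1:3) {
      i0 <- cand[, ax]
      ok <- i0 > 1L & i0 < d[ax]
      delta <- numeric(nrow(cand))
      for (k in which(ok)) {
        idx <- as.list(cand[k, ])
        idx[[ax]] <- idx[[ax]] - 1L
        fm <- do.call(`[`, c(list(a), idx))
        idx[[ax]] <- idx[[ax]] + 2L
        fp <- do.call(`[`, c(list(a), idx))
        f0 <- score[k]
        den <- fm - 2 * f0 + fp
        if (den < 0) delta[k] <- max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
      }
      pos[, ax] <- pos[, ax] + delta * vs[ax]
    }
  }
  spot_set(pos, score)
}

#' Construct a spot set
#'
#' @param positions n x 3 matrix of (x, y, z) um positions.
#' @param score per-spot filter response (defaults to 1).
#' @param cell_id optional per-spot cell assignment.
#' @return a `spot_set` data.frame.
#' @export
spot_set <- function(positions, score = NULL, cell_id = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  df <- data.frame(x_um = positions[, 1], y_um = positions[, 2],
                   z_um = positions[, 3],
                   score = if (is.null(score)) rep(1, nrow(positions))
                           else as.numeric(score))
  if (!is.null(cell_id)) df$cell_id <- cell_id
  class(df) <- c("spot_set", "data.frame")
  df
}

#' @noRd
empty_spot_set <- function() {
  spot_set(matrix(numeric(0), ncol = 3), numeric(0))
}

# ray-casting point-in-polygon; 2L = on an edge/vertex, 1L = inside, 0L = out
#' @noRd
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cr <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cr) <= eps &&
        px >= min(xi, xj) - eps && px <= max(xi, xj) + eps &&
        py >= min(yi, yj) - eps && py <= max(yi, yj) + eps)
      return(2L)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) 1L else 0L
}

#' Assign detected spots to cells and count centrioles per cell
#'
#' Each spot is assigned to the unique cell polygon containing its xy
#' position.  A spot lying exactly on a shared edge is assigned to the
#' lowest cell id among the touching polygons and flagged `on_edge`.  Spots
#' outside every polygon are reported in the `unassigned` component, never
#' silently dropped.  Genuinely overlapping polygons (a spot strictly inside
#' more than one) raise an error, because the assignment would be ambiguous.
#'
#' @param spots a `spot_set`.
#' @param polygons list of polygon matrices (columns x, y, um), in cell-id
#'   order; they must tile the field without overlap.
#' @return list with `counts` (named integer vector per cell), `spots` (the
#'   input with `cell_id` and `on_edge` columns), and `unassigned` (spot-set
#'   subset outside all polygons).
#' @export
count_centrioles <- function(spots, polygons) {
  n <- nrow(spots)
  cell_id <- rep(NA_integer_, n)
  on_edge <- rep(FALSE, n)
  for (k in seq_len(n)) {
    status <- vapply(polygons, function(p)
      point_in_polygon(spots$x_um[k], spots$y_um[k], p), integer(1))
    ins <- which(status == 1L)
    edg <- which(status == 2L)
    if (length(ins) > 1L)
      stop("overlapping cell polygons: spot strictly inside more than one")
    if (length(ins) == 1L) {
      cell_id[k] <- ins
    } else if (length(edg) >= 1L) {
      cell_id[k] <- min(edg)
      on_edge[k] <- TRUE
    }
  }
  spots$cell_id <- cell_id
  spots$on_edge <- on_edge
  counts <- vapply(seq_along(polygons), function(i)
    sum(cell_id == i, na.rm = TRUE), integer(1))
  names(counts) <- if (!is.null(names(polygons))) names(polygons)
                   else paste0("cell", seq_along(polygons))
  list(counts = counts, spots = spots,
       unassigned = spots[is.na(cell_id), , drop = FALSE])
}
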