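#' Planes of a z-band centred on an anchor depth
#'
#' Picks the `n_slices` planes encompassing a marker plane: the anchor plane
#' itself plus, for an even count, one more plane above than below (anchor,
#' 3 above, 2 below for the default 6).  Bands truncated by the stack edge
#' keep the available planes and are flagged.
#' @noRd
band_planes <- function(anchor_z_um, dz_um, n_z, n_slices = 6L) {
  anchor <- max(1L, min(n_z, round(anchor_z_um / dz_um + 0.5)))
  above <- ceiling((n_slices - 1L) / 2)
  below <- n_slices - 1L - above
  planes <- (anchor - below):(anchor + above)
  truncated <- any(planes < 1L | planes > n_z)
  planes <- planes[planes >= 1L & planes <= n_z]
  list(planes = planes, anchor = anchor, truncated = truncated)
}

#' Sum projection of a z-band around an anchor plane
#'
#' Sums the `n_slices` z-planes encompassing the anchor depth — e.g. the six
#' planes covering the Cep164 staining for apical actin, or the Akap450
#' planes for subapical actin.  For an even slice count the band takes the
#' anchor plane, the 3 planes above and the 2 below.  Total intensity of the
#' included planes is conserved.  A band truncated by the stack edge
#' proceeds with the available planes and sets the `truncated` attribute.
#'
#' @param grid a [voxel_grid()].
#' @param anchor_z_um depth of the reference marker plane (um).
#' @param n_slices number of planes to sum (default 6).
#' @return 2D matrix (x by y) with attributes `planes` and `truncated`.
#' @export
band_projection <- function(grid, anchor_z_um, n_slices = 6L) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  if (anchor_z_um < 0 || anchor_z_um > d[3] * grid$voxel_size[3])
    stop("anchor plane lies outside the stack")
  bp <- band_planes(anchor_z_um, grid$voxel_size[3], d[3], n_slices)
  if (bp$truncated) warning("z-band truncated by the stack edge")
  proj <- matrix(0, d[1], d[2])
  for (z in bp$planes) proj <- proj + grid$data[, , z]
  attr(proj, "planes") <- bp$planes
  attr(proj, "truncated") <- bp$truncated
  proj
}

#' Patch-over-rest mean intensity ratio
#'
#' Mean intensity over the centriolar-patch mask divided by the mean over
#' the remaining cell surface (cell mask minus patch).  Border pixels are
#' excluded from both regions by masking them out of `cell_mask` before the
#' call (the generator's masks already exclude them).  The ratio is
#' invariant to any positive rescaling of the projection.
#'
#' @param projection 2D intensity matrix (e.g. from [band_projection()]).
#' @param patch_mask,cell_mask logical matrices of the projection's shape;
#'   `patch_mask` must be a subset of `cell_mask`.
#' @return the dimensionless ratio, or `NA` (with a warning) when the rest
#'   region is empty.
#' @export
patch_ratio <- function(projection, patch_mask, cell_mask) {
  if (any(patch_mask & !cell_mask))
    stop("patch mask must be a subset of the cell mask")
  rest <- cell_mask & !patch_mask
  if (!any(rest)) {
    warning("empty rest-of-cell region; ratio undefined")
    return(NA_real_)
  }
  if (!any(patch_mask)) {
    warning("empty patch mask; ratio undefined")
    return(NA_real_)
  }
  mean(projection[patch_mask]) / mean(projection[rest])
}

#' Intensity normalised to the three closest non-transfected neighbours
#'
#' Fold change of a transfected cell's mean intensity over the mean of the
#' mean intensities of its three closest non-transfected neighbour cells
#' (centroid-to-centroid distance, ties broken by lower cell id).  Fewer
#' than three eligible neighbours are used as available, with a flag.
#'
#' @param value the cell's mean intensity.
#' @param neighbour_values mean intensities of candidate neighbour cells.
#' @param neighbour_distances centroid distances to those cells (same
#'   order); used to pick the three closest.
#' @param neighbour_ids optional ids used for the deterministic tie-break.
#' @return list with `fold_change`, `used_ids` and `flag` (TRUE when < 3
#'   neighbours were available).
#' @export
neighbour_normalised_intensity <- function(value, neighbour_values,
                                           neighbour_distances,
                                           neighbour_ids =
                                             seq_along(neighbour_values)) {
  stopifnot(length(neighbour_values) == length(neighbour_distances))
  if (length(neighbour_values) == 0L)
    stop("no eligible neighbour cells")
  ord <- order(neighbour_distances, neighbour_ids)
  take <- ord[seq_len(min(3L, length(ord)))]
  ref <- mean(neighbour_values[take])
  if (ref == 0) stop("zero mean neighbour intensity")
  list(fold_change = value / ref,
       used_ids = neighbour_ids[take],
       flag = length(take) < 3L)
}

#' Fold change of centriole counts against a reference population
#'
#' Normalises per-cell counts by the mean count of a reference population:
#' the contralateral ventricular wall for drug-treated explants, the
#' surrounding non-transfected cells for shRNA experiments, or littermate
#' controls for mutants.  The normalisation mode is recorded with the
#' result; the arithmetic is the same for all three.
#'
#' @param treated integer vector of per-cell counts.
#' @param reference counts of the reference population (non-empty, nonzero
#'   mean).
#' @param mode one of `"contralateral"`, `"surrounding"`, `"littermate"`.
#' @return list with `fold_changes` (per treated cell), `mean_fold_change`,
#'   `reference_mean`, `mode`.
#' @export
fold_change_counts <- function(treated, reference,
                               mode = c("contralateral", "surrounding",
                                        "littermate")) {
  mode <- match.arg(mode)
  if (length(reference) == 0L) stop("reference counts must be non-empty")
  ref <- mean(reference)
  if (ref == 0) stop("zero reference mean")
  fc <- treated / ref
  list(fold_changes = fc, mean_fold_change = mean(fc),
       reference_mean = ref, mode = mode)
}

#' Robust outlier removal (ROUT-style, location model, FDR at rate Q)
#'
#' Identifies outliers in a univariate sample the way automatic-count
#' cleanups need it: fit a robust location/scale (median and the
#' normal-consistent MAD), convert residuals to two-sided t p-values, and
#' mark as outliers the points failing a Benjamini–Hochberg FDR test at
#' rate `Q`.  Removed points are returned explicitly, never silently
#' dropped.  With fewer than 10 observations nothing is removed and a
#' warning is emitted.  Removals are monotone non-decreasing in Q and Q -> 0
#' removes nothing.
#'
#' @param values numeric sample.
#' @param Q FDR rate in percent (default 1, i.e. 1%).
#' @return list with `kept`, `removed`, `removed_idx`, `center`, `scale`.
#' @export
remove_outliers_rout <- function(values, Q = 1) {
  n <- length(values)
  if (n < 10L) {
    warning("fewer than 10 values: no outlier removal performed")
    return(list(kept = values, removed = numeric(0),
                removed_idx = integer(0),
                center = stats::median(values), scale = NA_real_))
  }
  center <- stats::median(values)
  scale <- stats::mad(values, center = center)
  if (scale == 0) {
    # constant (or majority-constant) sample: fall back to a scale that
    # removes nothing when all residuals are zero
    resid <- values - center
    if (all(resid == 0))
      return(list(kept = values, removed = numeric(0),
                  removed_idx = integer(0), center = center, scale = 0))
    scale <- stats::mad(values[resid != 0], center = center)
    if (scale == 0) scale <- stats::sd(values)
  }
  t_stat <- abs(values - center) / scale
  p <- 2 * stats::pt(-t_stat, df = n - 1)
  ord <- order(p)
  q <- Q / 100
  thresh <- q * seq_len(n) / n
  passing <- which(p[ord] <= thresh)
  removed_idx <- if (length(passing)) sort(ord[seq_len(max(passing))])
                 else integer(0)
  list(kept = if (length(removed_idx)) values[-removed_idx] else values,
       removed = values[removed_idx],
       removed_idx = removed_idx,
       center = center, scale = scale)
}

#' Group comparisons for per-cell quantities
#'
#' Two groups are compared with the two-sided Mann–Whitney (Wilcoxon
#' rank-sum) test; more than two with the Kruskal–Wallis omnibus followed by
#' Dunn's pairwise rank comparisons with multiplicity adjustment.  Groups
#' with fewer than 3 observations are flagged as degenerate.
#'
#' @param values numeric response, one element per cell.
#' @param groups factor (or coercible) of condition labels.
#' @param p_adjust adjustment for Dunn's pairwise p-values (default
#'   `"bonferroni"`, the classic correction used with Dunn's test).
#' @return list with `method`, `statistic`, `p_value`, and for > 2 groups a
#'   `pairwise` data.frame (group1, group2, z, p, p_adj); `degenerate`
#'   names any group with n < 3.
#' @export
compare_groups <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ns <- table(groups)
  degenerate <- names(ns)[ns < 3]
  if (nlevels(groups) == 2L) {
    lv <- levels(groups)
    ht <- stats::wilcox.test(values[groups == lv[1]],
                             values[groups == lv[2]], exact = FALSE)
    return(list(method = "mann-whitney",
                statistic = unname(ht$statistic),
                p_value = ht$p.value, degenerate = degenerate))
  }
  kw <- stats::kruskal.test(values, groups)
  list(method = "kruskal-dunn",
       statistic = unname(kw$statistic),
       p_value = kw$p.value,
       pairwise = dunn_test(values, groups, p_adjust),
       degenerate = degenerate)
}

#' Dunn's pairwise rank comparisons after a Kruskal–Wallis test
#'
#' For each pair of groups, the standardised difference of mean ranks
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with the usual tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values,
#' and a multiplicity adjustment over all pairs.
#'
#' @inheritParams compare_groups
#' @return data.frame: group1, group2, z, p, p_adj.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcor <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- table(groups)
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  z <- apply(combs, 2L, function(g) {
    (mean_ranks[g[1]] - mean_ranks[g[2]]) /
      sqrt((N * (N + 1) / 12 - Tcor) * (1 / ns[g[1]] + 1 / ns[g[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ],
             z = as.numeric(z), p = as.numeric(p),
             p_adj = stats::p.adjust(p, method = p_adjust))
}

#' Chi-squared test for trend over binned distances
#'
#' Compares two binned nearest-neighbour distance distributions with the
#' Cochran–Armitage chi-squared test for trend: bins are ordered distance
#' classes, and the test asks whether the proportion belonging to one
#' condition drifts across them.
#'
#' @param counts_a,counts_b integer counts per ordered bin, equal lengths.
#' @param scores optional bin scores (default 1..k).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
trend_test_counts <- function(counts_a, counts_b,
                              scores = seq_along(counts_a)) {
  stopifnot(length(counts_a) == length(counts_b))
  tot <- counts_a + counts_b
  keep <- tot > 0
  ht <- stats::prop.trend.test(counts_a[keep], tot[keep], scores[keep])
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
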