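#' Specification of a synthetic multiciliated-cell scene
#'
#' Describes a field of ependymal cells, each carrying one centriolar patch,
#' rendered into a four-channel 3D stack (centrin, Cep164, actin, membrane)
#' together with exact ground truth.  Defaults emulate a mature (P15)
#' lateral-wall field: a handful of cells, ~30 centrioles per cell packed at
#' >= 0.4 um spacing into a patch placed towards one side of the cell, Cep164
#' puncta displaced from their centrin partner along a per-cell von Mises
#' orientation field, and an actin channel enriched over the patch at two
#' z-levels (apical at the Cep164 plane, subapical ~0.7 um deeper).
#'
#' @param n_cells number of cells; laid out on a near-square grid of
#'   rectangular (convex) borders tiling the field.
#' @param cell_size_um xy side length of each cell (um).
#' @param centrioles_per_cell integer count per cell (>= 0); a single value is
#'   recycled.
#' @param patch_radius_um radius of the disc inside which centrioles are
#'   placed (um).
#' @param patch_offset_um displacement of the patch centre from the cell
#'   centre (um); emulates the anterior asymmetry of the patch.
#' @param min_spacing_um minimum pairwise centriole distance (um).
#' @param cep164_offset_um displacement of each Cep164 punctum from its
#'   centrin partner (um), in the xy plane.
#' @param orientation_mean_rad per-cell mean beat direction (rad); a single
#'   value is recycled, `NA` draws each cell's mean uniformly.
#' @param orientation_kappa von Mises concentration of per-centriole
#'   directions around the cell mean (0 = uniform).
#' @param actin_ratio_apical,actin_ratio_subapical target patch/rest mean
#'   intensity ratios of the actin channel at the two z-bands.
#' @param psf_sigma_um Gaussian PSF sigma (x, y, z) in um.
#' @param peak_intensity peak amplitude of a rendered punctum above
#'   background.
#' @param noise_sd Gaussian read-noise standard deviation (0 = off).
#' @param poisson_scale if > 0, intensities are replaced by
#'   `rpois(lambda = x * scale) / scale` before Gaussian noise, mimicking
#'   shot noise; 0 disables.
#' @param voxel_size_um voxel spacing (x, y, z) um; z defaults to 0.23 um.
#' @param n_z number of z planes.
#' @param apical_z_um z position of the apical (Cep164) plane; defaults to
#'   60% of stack depth.
#' @param subapical_drop_um depth of the subapical (rootlet-level) band below
#'   the apical one.
#' @param seed integer seed making the scene reproducible.
#'
#' @return an object of class `scene_spec` (a validated list).
#' @export
scene_spec <- function(n_cells = 4,
                       cell_size_um = 6.4,
                       centrioles_per_cell = 30,
                       patch_radius_um = 1.8,
                       patch_offset_um = 1.1,
                       min_spacing_um = 0.4,
                       cep164_offset_um = 0.25,
                       orientation_mean_rad = NA_real_,
                       orientation_kappa = 4,
                       actin_ratio_apical = 2.0,
                       actin_ratio_subapical = 1.5,
                       psf_sigma_um = c(0.1, 0.1, 0.25),
                       peak_intensity = 100,
                       noise_sd = 0,
                       poisson_scale = 0,
                       voxel_size_um = c(0.1, 0.1, 0.23),
                       n_z = 14,
                       apical_z_um = NULL,
                       subapical_drop_um = 0.92,
                       seed = 1L) {
  counts <- rep_len(as.integer(centrioles_per_cell), n_cells)
  if (any(counts < 0)) stop("centriole counts must be >= 0")
  pos <- c(cell_size_um, patch_radius_um, min_spacing_um, cep164_offset_um,
           psf_sigma_um, voxel_size_um, subapical_drop_um)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all physical dimensions must be strictly positive")
  if (actin_ratio_apical < 0 || actin_ratio_subapical < 0)
    stop("actin ratios must be >= 0")
  if (patch_offset_um < 0) stop("patch offset must be >= 0")
  if (patch_offset_um + patch_radius_um > cell_size_um / 2)
    stop("patch (radius + offset) does not fit inside the cell")
  # hexagonal-packing feasibility guard: fail loudly before dart throwing
  max_count <- max(counts)
  packable <- floor(0.7 * pi * patch_radius_um^2 /
                      (pi * (min_spacing_um / 2)^2))
  if (max_count > 1 && max_count > packable)
    stop(sprintf(
      "cannot place %d centrioles with %.2f um spacing in a %.2f um patch",
      max_count, min_spacing_um, patch_radius_um))
  if (is.null(apical_z_um)) apical_z_um <- 0.6 * n_z * voxel_size_um[3]
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  structure(list(
    n_cells = as.integer(n_cells), cell_size_um = cell_size_um,
    grid_dims = c(ncol_grid, nrow_grid),
    centrioles_per_cell = counts,
    patch_radius_um = patch_radius_um, patch_offset_um = patch_offset_um,
    min_spacing_um = min_spacing_um, cep164_offset_um = cep164_offset_um,
    orientation_mean_rad = rep_len(orientation_mean_rad, n_cells),
    orientation_kappa = orientation_kappa,
    actin_ratio_apical = actin_ratio_apical,
    actin_ratio_subapical = actin_ratio_subapical,
    psf_sigma_um = psf_sigma_um, peak_intensity = peak_intensity,
    noise_sd = noise_sd, poisson_scale = poisson_scale,
    voxel_size_um = voxel_size_um, n_z = as.integer(n_z),
    apical_z_um = apical_z_um, subapical_drop_um = subapical_drop_um,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Draw from a von Mises distribution (Best & Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0); 0 gives the circular uniform.
#' @return angles in radians.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return((runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

#' Cell border polygons for a scene
#'
#' @param spec a [scene_spec()].
#' @return named list of closed-free polygon matrices (columns x, y, um),
#'   one per cell, in cell-id order.
#' @export
cell_polygons <- function(spec) {
  s <- spec$cell_size_um
  polys <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    cx <- (i - 1L) %% spec$grid_dims[1]
    cy <- (i - 1L) %/% spec$grid_dims[1]
    x0 <- cx * s; y0 <- cy * s
    polys[[i]] <- cbind(x = c(x0, x0 + s, x0 + s, x0),
                        y = c(y0, y0, y0 + s, y0 + s))
  }
  names(polys) <- paste0("cell", seq_len(spec$n_cells))
  polys
}

# dart-throwing placement of n points with min spacing inside a disc
#' @noRd
place_in_disc <- function(n, centre, radius, min_spacing, max_tries = 20000L) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("failed to place centrioles at the requested spacing; ",
           "reduce the count or the minimum distance")
    rr <- radius * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- centre + rr * c(cos(th), sin(th))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_spacing)
      pts <- rbind(pts, p)
  }
  pts
}

#' Sample the ground-truth point sets of a scene (no rendering)
#'
#' Draws, reproducibly from `spec$seed`, the centrin positions, the paired
#' Cep164 positions and the per-centriole orientation angles for every cell,
#' plus the cell borders.  [render_stack()] calls this internally; it is
#' exported so that point-level analyses (orientation recovery, fold-change
#' simulations) do not pay for voxel rendering.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `points` (data.frame: cell_id, id, type one of
#'   "centrin"/"cep164", x_um, y_um, z_um, partner_id, angle_rad),
#'   `cells` (per-cell data.frame: cell_id, mean_direction_rad, n_centrioles),
#'   and `polygons` (from [cell_polygons()]).
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  polys <- cell_polygons(spec)
  zc <- spec$apical_z_um
  rows <- list()
  cells <- data.frame(cell_id = seq_len(spec$n_cells),
                      mean_direction_rad = NA_real_,
                      n_centrioles = spec$centrioles_per_cell)
  for (i in seq_len(spec$n_cells)) {
    n <- spec$centrioles_per_cell[i]
    mu <- spec$orientation_mean_rad[i]
    if (is.na(mu)) mu <- runif(1, -pi, pi)
    cells$mean_direction_rad[i] <- mu
    if (n == 0) next
    poly <- polys[[i]]
    centre <- c(mean(range(poly[, 1])), mean(range(poly[, 2])))
    # patch displaced towards the cell's beat direction (anterior asymmetry)
    patch_centre <- centre + spec$patch_offset_um * c(cos(mu), sin(mu))
    cen <- place_in_disc(n, patch_centre, spec$patch_radius_um,
                         spec$min_spacing_um)
    ang <- rvonmises(n, mu, spec$orientation_kappa)
    cep <- cen + spec$cep164_offset_um * cbind(cos(ang), sin(ang))
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = i, id = seq_len(n), type = "centrin",
      x_um = cen[, 1], y_um = cen[, 2], z_um = zc,
      partner_id = seq_len(n), angle_rad = ang)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = i, id = seq_len(n), type = "cep164",
      x_um = cep[, 1], y_um = cep[, 2], z_um = zc,
      partner_id = seq_len(n), angle_rad = ang)
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), id = integer(), type = character(),
               x_um = numeric(), y_um = numeric(), z_um = numeric(),
               partner_id = integer(), angle_rad = numeric())
  list(points = points, cells = cells, polygons = polys)
}

# add a 3D Gaussian punctum at position p (um) into array a, in place-ish
#' @noRd
add_punctum <- function(a, p, sigma_um, voxel_size, amplitude) {
  d <- dim(a)
  win <- integer(0)
  idx <- vector("list", 3)
  prof <- vector("list", 3)
  for (ax in 1:3) {
    sv <- sigma_um[ax] / voxel_size[ax]
    cvox <- p[ax] / voxel_size[ax] + 0.5   # fractional voxel index of centre
    r <- ceiling(4 * sv)
    lo <- max(1L, floor(cvox - r)); hi <- min(d[ax], ceiling(cvox + r))
    if (lo > hi) return(a)
    idx[[ax]] <- lo:hi
    prof[[ax]] <- exp(-((lo:hi) - cvox)^2 / (2 * sv^2))
  }
  blob <- amplitude * (prof[[1]] %o% prof[[2]] %o% prof[[3]])
  a[idx[[1]], idx[[2]], idx[[3]]] <-
    a[idx[[1]], idx[[2]], idx[[3]]] + blob
  a
}

#' Render a synthetic multichannel stack with ground truth
#'
#' Produces a four-channel 3D stack (`centrin`, `cep164`, `actin`,
#' `membrane`) at the scene's voxel size:
#' diffraction-blurred puncta (3D Gaussians of PSF width) at the ground-truth
#' centrin/Cep164 positions; an actin channel whose patch-mask mean over
#' rest-mask mean equals the requested ratio, exactly, at each of the two
#' z-bands before noise; and a membrane channel tracing cell borders.
#' Noise is applied Poisson-then-Gaussian when enabled, both stages under the
#' scene seed, so identical spec + seed gives bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return a list: `channels` (named list of [voxel_grid()]), `truth`
#'   (from [sample_ground_truth()] augmented with per-cell patch hull area and
#'   the target actin ratios), `masks` (per-cell logical xy matrices: `cell`,
#'   `patch`, `border`), and `spec`.
#' @export
render_stack <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  truth <- sample_ground_truth(spec)      # seeds RNG from spec$seed
  vs <- spec$voxel_size_um
  nx <- ceiling(spec$grid_dims[1] * spec$cell_size_um / vs[1])
  ny <- ceiling(spec$grid_dims[2] * spec$cell_size_um / vs[2])
  d <- c(nx, ny, spec$n_z)
  centrin <- array(0, d); cep <- array(0, d)

  pts <- truth$points
  for (k in seq_len(nrow(pts))) {
    p <- c(pts$x_um[k], pts$y_um[k], pts$z_um[k])
    if (pts$type[k] == "centrin")
      centrin <- add_punctum(centrin, p, spec$psf_sigma_um, vs,
                             spec$peak_intensity)
    else
      cep <- add_punctum(cep, p, spec$psf_sigma_um, vs, spec$peak_intensity)
  }

  # xy masks at voxel centres
  xs <- (seq_len(nx) - 0.5) * vs[1]
  ys <- (seq_len(ny) - 0.5) * vs[2]
  masks <- scene_masks(spec, truth, xs, ys)

  # actin: two thin sheets (one plane each) at the apical and subapical
  # anchor depths; within a sheet, rest-of-cell intensity is 1 and the patch
  # carries the target ratio, borders excluded, so the patch/rest mean of any
  # band projection containing exactly one sheet equals the target exactly
  actin <- array(0, d)
  k_ap <- band_planes(spec$apical_z_um, vs[3], spec$n_z, 6L)$anchor
  sub_z <- spec$apical_z_um - spec$subapical_drop_um
  k_sub <- band_planes(sub_z, vs[3], spec$n_z, 6L)$anchor
  if (k_ap == k_sub)
    stop("apical and subapical actin planes coincide; increase the z ",
         "resolution or the subapical drop")
  plane_ap <- matrix(0, nx, ny); plane_sub <- matrix(0, nx, ny)
  for (i in seq_len(spec$n_cells)) {
    m <- masks[[i]]
    rest <- m$cell & !m$patch & !m$border
    plane_ap[rest] <- 1; plane_sub[rest] <- 1
    plane_ap[m$patch] <- spec$actin_ratio_apical
    plane_sub[m$patch] <- spec$actin_ratio_subapical
  }
  actin[, , k_ap] <- actin[, , k_ap] + plane_ap
  actin[, , k_sub] <- actin[, , k_sub] + plane_sub

  membrane <- array(0, d)
  border_all <- Reduce(`|`, lapply(masks, `[[`, "border"))
  for (z in seq_len(spec$n_z)) membrane[, , z] <- border_all * 1

  channels <- list(centrin = centrin, cep164 = cep, actin = actin,
                   membrane = membrane)
  if (spec$poisson_scale > 0)
    channels <- lapply(channels, function(a) {
      array(rpois(length(a), pmax(a, 0) * spec$poisson_scale) /
              spec$poisson_scale, dim(a))
    })
  if (spec$noise_sd > 0)
    channels <- lapply(channels, function(a)
      a + array(rnorm(length(a), 0, spec$noise_sd), dim(a)))
  channels <- lapply(names(channels), function(nm)
    voxel_grid(channels[[nm]], vs, nm))
  names(channels) <- c("centrin", "cep164", "actin", "membrane")

  truth$cells$patch_area_um2 <- vapply(seq_len(spec$n_cells), function(i) {
    cen <- pts[pts$cell_id == i & pts$type == "centrin", , drop = FALSE]
    if (nrow(cen) == 0) 0 else hull_area(cbind(cen$x_um, cen$y_um))
  }, numeric(1))
  truth$cells$actin_ratio_apical <- spec$actin_ratio_apical
  truth$cells$actin_ratio_subapical <- spec$actin_ratio_subapical

  list(channels = channels, truth = truth, masks = masks, spec = spec)
}

# per-cell logical masks over the xy voxel lattice
#' @noRd
scene_masks <- function(spec, truth, xs, ys) {
  border_w <- 2 * spec$voxel_size_um[1]   # ~2 px of excluded cell border
  lapply(seq_len(spec$n_cells), function(i) {
    poly <- truth$polygons[[i]]
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    inx <- xs > xr[1] & xs < xr[2]
    iny <- ys > yr[1] & ys < yr[2]
    cellm <- outer(inx, iny, `&`)
    corex <- xs > xr[1] + border_w & xs < xr[2] - border_w
    corey <- ys > yr[1] + border_w & ys < yr[2] - border_w
    borderm <- cellm & !outer(corex, corey, `&`)
    cen <- truth$points[truth$points$cell_id == i &
                          truth$points$type == "centrin", , drop = FALSE]
    if (nrow(cen) > 0) {
      mu <- truth$cells$mean_direction_rad[i]
      centre <- c(mean(range(poly[, 1])), mean(range(poly[, 2]))) +
        spec$patch_offset_um * c(cos(mu), sin(mu))
      r2 <- (spec$patch_radius_um + 2 * spec$psf_sigma_um[1])^2
      patchm <- outer((xs - centre[1])^2, (ys - centre[2])^2, `+`) <= r2
      patchm <- patchm & cellm & !borderm
    } else {
      patchm <- cellm & FALSE
    }
    list(cell = cellm, patch = patchm, border = borderm)
  })
}
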