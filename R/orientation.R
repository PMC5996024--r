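#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Per-cell orientation field from a centrin–Cep164 pairing
#'
#' Each matched centrin -> Cep164 displacement defines a unit vector — the
#' beat direction of that basal body.  The cell's mean direction is the
#' argument of the vector sum, the resultant length R = |mean unit vector|
#' measures alignment (1 = parallel, 0 = balanced), and per-centriole
#' deviations are angle differences to the mean wrapped to (-pi, pi].
#' Zero-length displacements carry no direction and are excluded with a
#' warning; when R is numerically zero the mean direction is undefined and
#' flagged.
#'
#' @param pairing result of [assign_pairs()] (or any list with a `pairs`
#'   data.frame in the same layout).
#' @return an `orientation_field`: list with `angles_rad`, `unit_vectors`,
#'   `mean_direction_rad`, `R`, `deviations_rad`, `n`,
#'   `mean_defined` (FALSE when R ~ 0), `excluded` (indices of zero-length
#'   pairs).
#' @export
orientation_stats <- function(pairing) {
  pr <- pairing$pairs
  dx <- pr$cep164_x - pr$centrin_x
  dy <- pr$cep164_y - pr$centrin_y
  len <- sqrt(dx^2 + dy^2)
  bad <- which(len == 0)
  if (length(bad)) {
    warning(length(bad), " zero-length displacement pair(s) excluded")
    dx <- dx[-bad]; dy <- dy[-bad]; len <- len[-bad]
  }
  if (length(dx) == 0L) stop("no pairs with nonzero displacement")
  ux <- dx / len; uy <- dy / len
  angles <- atan2(uy, ux)
  mx <- mean(ux); my <- mean(uy)
  R <- sqrt(mx^2 + my^2)
  mean_defined <- R > 1e-8
  mu <- if (mean_defined) atan2(my, mx) else NA_real_
  structure(list(
    angles_rad = angles,
    unit_vectors = cbind(cos = ux, sin = uy),
    mean_direction_rad = mu,
    R = R,
    deviations_rad = if (mean_defined) wrap_angle(angles - mu)
                     else rep(NA_real_, length(angles)),
    n = length(angles),
    mean_defined = mean_defined,
    excluded = bad
  ), class = "orientation_field")
}

#' Circular histogram with 20-degree bins
#'
#' Bins angles into half-open sectors `[k*w, (k+1)*w)` degrees covering
#' [0, 360); with the default 20-degree width there are 18 bins, the binning
#' used for the rose plots.  An angle of exactly 20 degrees falls in the
#' second bin (half-open convention).
#'
#' @param angles_rad angles in radians (any range; wrapped into [0, 360)
#'   degrees).
#' @param bin_width_deg sector width in degrees; must divide 360.
#' @return an `angle_histogram`: list with `counts`, `bin_start_deg`,
#'   `bin_end_deg`, `bin_mid_deg`.
#' @export
circular_histogram <- function(angles_rad, bin_width_deg = 20) {
  if (360 %% bin_width_deg != 0) stop("bin width must divide 360")
  nb <- as.integer(360 / bin_width_deg)
  deg <- (angles_rad * 180 / pi) %% 360
  # absorb degree-conversion round-off at bin boundaries (~1e-9 deg)
  bin <- (floor(deg / bin_width_deg + 1e-9) %% nb) + 1L
  counts <- tabulate(bin, nbins = nb)
  structure(list(counts = counts,
                 bin_start_deg = (seq_len(nb) - 1L) * bin_width_deg,
                 bin_end_deg = seq_len(nb) * bin_width_deg,
                 bin_mid_deg = (seq_len(nb) - 0.5) * bin_width_deg),
            class = "angle_histogram")
}

#' Circular standard error of a mean direction
#'
#' Large-sample standard error `1 / sqrt(n * R * kappa_hat)` with the
#' maximum-likelihood von Mises concentration recovered from R by the usual
#' rational approximation.
#'
#' @param field an `orientation_field`, or pass `R` and `n` directly.
#' @param R resultant length; @param n sample size.
#' @return standard error (rad).
#' @export
circular_se <- function(field = NULL, R = field$R, n = field$n) {
  k <- kappa_from_R(R)
  1 / sqrt(n * R * k)
}

#' @noRd
kappa_from_R <- function(R) {
  if (R < 1e-12) return(1e-12)
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}
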