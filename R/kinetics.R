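#' Construct a beat trace from raw samples
#'
#' @param samples numeric series (ROI mean intensity or tip position, um).
#' @param sampling_rate sampling frequency (Hz), default 250.
#' @param roi optional ROI descriptor carried through to outputs.
#' @return a `beat_trace`.
#' @export
beat_trace <- function(samples, sampling_rate = 250, roi = NULL) {
  if (sampling_rate <= 0) stop("sampling rate must be positive")
  n <- length(samples)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 time = (seq_len(n) - 1) / sampling_rate,
                 roi = roi),
            class = "beat_trace")
}

# peak prominences: height above the higher of the two bases, where a base
# is the minimum between the peak and the nearest higher point on that side
#' @noRd
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1) {
      seg <- x[1:(p - 1)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[(max(higher)):(p - 1)]) else min(seg)
    } else h
    right <- if (p < length(x)) {
      seg <- x[(p + 1):length(x)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:(min(higher))]) else min(seg)
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' @noRd
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Beat frequency of a cilium trace
#'
#' The primary estimator counts beat cycles as prominent peaks of the
#' linearly detrended trace and divides by the duration, mirroring manual
#' cycle counting on a z-axis profile; one peak = one full beat cycle.  The
#' prominence threshold is `3 *` a robust noise SD estimated from second
#' differences (`mad(diff(x, differences = 2)) / sqrt(6)`).  A spectral
#' cross-check — the dominant periodogram frequency — is reported alongside;
#' when the two disagree by more than one frequency bin (`1/duration`, the
#' resolution floor) the result is flagged.  The estimate is invariant to
#' intensity offset and positive scaling.
#'
#' @param trace a `beat_trace` (or numeric vector with `sampling_rate`).
#' @param sampling_rate used when `trace` is a bare numeric vector.
#' @return list with `frequency_hz` (peak-count estimate),
#'   `spectral_frequency_hz`, `n_peaks`, `resolution_hz`, `flagged`.
#' @export
beat_frequency <- function(trace, sampling_rate = 250) {
  if (!inherits(trace, "beat_trace"))
    trace <- beat_trace(trace, sampling_rate)
  x <- trace$samples
  n <- length(x)
  if (n < 4L) stop("trace too short")
  duration <- n / trace$sampling_rate
  t <- trace$time
  x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  noise_sd <- stats::mad(diff(x, differences = 2)) / sqrt(6)
  # floor guards against counting numerical ripple on (near-)constant traces
  prom_floor <- 1e-8 * max(1, max(abs(trace$samples)))
  prom_th <- max(3 * noise_sd, prom_floor)
  pk <- local_maxima(x)
  if (length(pk)) {
    prom <- peak_prominences(x, pk)
    pk <- pk[prom >= prom_th & prom > 0]
  }
  f_peaks <- length(pk) / duration
  # periodogram cross-check (exclude DC)
  spec <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1)
  f_axis <- (half - 1) / duration
  f_spec <- f_axis[which.max(spec[half])]
  if (length(pk) == 0L) f_spec_use <- 0 else f_spec_use <- f_spec
  resolution <- 1 / duration
  flagged <- length(pk) == 0L ||
    abs(f_peaks - f_spec) > resolution + 1e-9
  list(frequency_hz = f_peaks,
       spectral_frequency_hz = if (length(pk) == 0L) 0 else f_spec,
       n_peaks = length(pk),
       resolution_hz = resolution,
       flagged = flagged)
}

#' Beat amplitude from a tip-position series
#'
#' The distance between the maximal and minimal tip position over the
#' recording — the peak-to-peak excursion, i.e. twice the half-amplitude of
#' a sinusoidal beat.
#'
#' @param tip_positions_um tip positions (um), or a `beat_trace`.
#' @param expected_frequency_hz optional; when given, the result is flagged
#'   if the series covers less than one full expected period.
#' @param sampling_rate used with `expected_frequency_hz` on bare vectors.
#' @return list with `amplitude_um` (max - min) and `flagged`.
#' @export
beat_amplitude <- function(tip_positions_um, expected_frequency_hz = NULL,
                           sampling_rate = 250) {
  if (inherits(tip_positions_um, "beat_trace")) {
    sampling_rate <- tip_positions_um$sampling_rate
    tip_positions_um <- tip_positions_um$samples
  }
  if (length(tip_positions_um) < 2L) stop("need at least 2 samples")
  flagged <- FALSE
  if (!is.null(expected_frequency_hz) && expected_frequency_hz > 0) {
    duration <- length(tip_positions_um) / sampling_rate
    flagged <- duration * expected_frequency_hz < 1
  }
  list(amplitude_um = max(tip_positions_um) - min(tip_positions_um),
       flagged = flagged)
}

#' Kymograph: intensity along a line, over time
#'
#' Samples each frame of a movie along a polyline at unit (pixel) spacing
#' with bilinear interpolation, producing the position x time image used to
#' read beat periodicity.  The default window is 200 ms.
#'
#' @param movie 3D array `[x, y, t]` of frames.
#' @param line k x 2 matrix of polyline vertices in pixel coordinates
#'   (1-based, voxel-centre convention).
#' @param sampling_rate frame rate (Hz), default 250.
#' @param window_ms time window (ms) taken from the start of the movie.
#' @return a `kymograph`: list with `image` (position x time matrix),
#'   `positions_px`, `time_s`, `line`, `duration_ms`.
#' @export
make_kymograph <- function(movie, line, sampling_rate = 250,
                           window_ms = 200) {
  stopifnot(length(dim(movie)) == 3L)
  line <- as.matrix(line)
  seg_len <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  total <- sum(seg_len)
  if (total < 2) stop("line must be at least 2 pixels long")
  nt_avail <- dim(movie)[3]
  nt <- min(nt_avail, max(1L, round(window_ms / 1000 * sampling_rate)))
  if (round(window_ms / 1000 * sampling_rate) > nt_avail)
    stop("window exceeds the movie duration")
  # arc-length positions at unit spacing
  s <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  pts <- t(vapply(s, function(si) {
    seg <- max(1L, min(length(seg_len), findInterval(si, cum,
                                                     rightmost.closed = TRUE)))
    f <- (si - cum[seg]) / seg_len[seg]
    line[seg, ] + f * (line[seg + 1, ] - line[seg, ])
  }, numeric(2)))
  img <- matrix(0, nrow(pts), nt)
  for (ti in seq_len(nt))
    img[, ti] <- bilinear_sample(movie[, , ti], pts[, 1], pts[, 2])
  structure(list(image = img, positions_px = s,
                 time_s = (seq_len(nt) - 1) / sampling_rate,
                 line = line, duration_ms = nt / sampling_rate * 1000),
            class = "kymograph")
}

# bilinear interpolation of a matrix at fractional (x, y), clamped to edges
#' @noRd
bilinear_sample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}
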