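#' Specification of a synthetic cilium beating trace
#'
#' Emulates the tip-position (or ROI-intensity) time series extracted from a
#' high-speed phase-contrast recording of a single beating cilium.  The
#' default sampling rate is 250 Hz, the frame rate of the recordings the
#' analysis is designed for.  The beat amplitude has no published reference
#' value; the 5 um default is an assumption stated in the package vignette.
#'
#' @param frequency beat frequency (Hz); must be below the Nyquist rate.
#' @param amplitude half peak-to-peak excursion (um); the tip travels
#'   `2 * amplitude` over a cycle.
#' @param sampling_rate frames per second (default 250).
#' @param duration recording length (s); must cover >= 2 beat periods for a
#'   nonzero frequency.
#' @param noise_sd additive Gaussian noise SD (trace units).
#' @param waveform `"sinusoid"` or `"asymmetric"` (fast power stroke, slow
#'   recovery, modelled by a two-harmonic skewed wave of the same period and
#'   the same min/max excursion).
#' @param phase initial phase (rad).
#' @param seed integer seed for the noise draw.
#'
#' @return object of class `beat_spec`.
#' @export
beat_spec <- function(frequency = 28, amplitude = 5, sampling_rate = 250,
                      duration = 1, noise_sd = 0,
                      waveform = c("sinusoid", "asymmetric"),
                      phase = 0, seed = 1L) {
  waveform <- match.arg(waveform)
  if (sampling_rate <= 0 || duration <= 0)
    stop("sampling rate and duration must be strictly positive")
  if (frequency < 0) stop("frequency must be >= 0")
  if (frequency >= sampling_rate / 2)
    stop("frequency violates the Nyquist limit (rate/2)")
  if (frequency > 0 && duration * frequency < 2)
    stop("duration must cover at least 2 beat periods")
  structure(list(frequency = frequency, amplitude = amplitude,
                 sampling_rate = sampling_rate, duration = duration,
                 noise_sd = noise_sd, waveform = waveform, phase = phase,
                 seed = as.integer(seed)),
            class = "beat_spec")
}

#' Render a beating trace from its specification
#'
#' For the sinusoid waveform the noiseless tip-position range is exactly
#' `2 * amplitude`.  Identical spec + seed reproduces the trace bit for bit.
#'
#' @param spec a [beat_spec()].
#' @return a `beat_trace`: list with `samples` (um), `sampling_rate` (Hz),
#'   `time` (s) and the generating `spec`.
#' @export
render_trace <- function(spec) {
  stopifnot(inherits(spec, "beat_spec"))
  n <- round(spec$duration * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  ph <- 2 * pi * spec$frequency * t + spec$phase
  x <- switch(spec$waveform,
    sinusoid = sin(ph),
    asymmetric = sin(ph) + 0.35 * sin(2 * ph + pi / 2))
  # rescale the sampled waveform to span exactly [-1, 1]: the tip-position
  # range is then 2 * amplitude by construction, independent of whether the
  # sample grid is commensurate with the beat period
  if (max(x) > min(x))
    x <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  else
    x <- x * 0
  x <- spec$amplitude * x
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    x <- x + rnorm(n, 0, spec$noise_sd)
  }
  structure(list(samples = x, sampling_rate = spec$sampling_rate,
                 time = t, spec = spec),
            class = "beat_trace")
}
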