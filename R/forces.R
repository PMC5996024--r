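#' Geometry and fluid parameters of a beating cilium
#'
#' The force model treats a motile cilium as a rigid slender cylinder of
#' radius `r` and length `L`, anchored by a centriole of length `L_c`
#' embedded in the apical actin network, immersed in cerebrospinal fluid of
#' viscosity `mu`.  Defaults are the measured ependymal values: r = 99 nm,
#' L = 11.1 um, L_c = 510 nm, mu = 1e-3 N s m^-2.  Beat frequency `f` and
#' amplitude `A` have no standard values and must be supplied explicitly for
#' force evaluation.
#'
#' @param r_m cilium radius (m).
#' @param L_m cilium length (m).
#' @param Lc_m centriole length (m).
#' @param mu viscosity (N s m^-2).
#' @param f_hz beat frequency (Hz), optional until forces are computed.
#' @param A_m beat amplitude (m), optional until forces are computed.
#' @return object of class `cilia_geometry`.
#' @export
cilia_geometry <- function(r_m = 99e-9, L_m = 11.1e-6, Lc_m = 510e-9,
                           mu = 1e-3, f_hz = NULL, A_m = NULL) {
  vals <- c(r_m, L_m, Lc_m, mu)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("r, L, L_c and mu must be strictly positive")
  if (L_m <= r_m) stop("cilium length must exceed its radius")
  if (L_m <= Lc_m) stop("cilium length must exceed the centriole length")
  structure(list(r_m = r_m, L_m = L_m, Lc_m = Lc_m, mu = mu,
                 f_hz = f_hz, A_m = A_m),
            class = "cilia_geometry")
}

#' Normal drag coefficient of a slender cylinder
#'
#' `C = 4 pi mu / log10(L / r)`.  The base-10 logarithm is a deliberate
#' model choice: with the default ependymal geometry it gives
#' 6.13e-3 N s m^-2, i.e. the 6e-3 figure at one significant digit, whereas
#' a natural log gives 2.7e-3.  The base is configurable for sensitivity
#' analysis.  `C` depends on the geometry only through the ratio `L/r` and
#' is exactly linear in `mu`.
#'
#' @param geom a [cilia_geometry()].
#' @param log_base logarithm base (default 10).
#' @return drag coefficient (N s m^-2).
#' @export
drag_coefficient <- function(geom, log_base = 10) {
  if (geom$L_m / geom$r_m <= 1)
    stop("L/r must exceed 1 for the drag coefficient to be defined")
  4 * pi * geom$mu / log(geom$L_m / geom$r_m, base = log_base)
}

#' Force at the cilium base counteracting the fluid flow
#'
#' `F_flow = C f A L`: drag coefficient times beat frequency, beat
#' amplitude and cilium length.  Jointly linear in `f` and `A`.
#'
#' @inheritParams drag_coefficient
#' @return force (N).
#' @export
flow_force <- function(geom, log_base = 10) {
  if (is.null(geom$f_hz) || is.null(geom$A_m))
    stop("beat frequency and amplitude must be set to compute F_flow")
  drag_coefficient(geom, log_base) * geom$f_hz * geom$A_m * geom$L_m
}

#' Torque-induced force on the centriole
#'
#' The beating cilium applies a torque at its base; over the lever arm of
#' the centriole this amplifies into `F_torque = F_flow * L / L_c`, a local,
#' temporary force on the actin anchorage.  The amplification `L / L_c`
#' (21.76 with the default geometry) is independent of viscosity, beat
#' parameters and radius.
#'
#' @param geom a [cilia_geometry()].
#' @param f_flow_n the flow-counteracting force (N), e.g. from
#'   [flow_force()].
#' @return force (N).
#' @export
torque_force <- function(geom, f_flow_n) {
  if (f_flow_n < 0) stop("F_flow must be >= 0")
  f_flow_n * geom$L_m / geom$Lc_m
}

#' Force sensitivity over parameter ranges
#'
#' Evaluates the drag coefficient and both forces on the full grid of the
#' supplied parameter ranges (e.g. the measured mean +/- sem bounds of r, L
#' and L_c), holding unspecified parameters at the geometry's values.
#'
#' @param geom a [cilia_geometry()] with `f_hz` and `A_m` set.
#' @param ranges named list of numeric vectors over any of `r_m`, `L_m`,
#'   `Lc_m`, `mu`, `f_hz`, `A_m`.
#' @param log_base logarithm base for the drag coefficient.
#' @return data.frame with one row per grid point: the parameter values,
#'   `C`, `F_flow_N`, `F_torque_N`.
#' @export
sensitivity_table <- function(geom, ranges, log_base = 10) {
  base <- list(r_m = geom$r_m, L_m = geom$L_m, Lc_m = geom$Lc_m,
               mu = geom$mu, f_hz = geom$f_hz, A_m = geom$A_m)
  unknown <- setdiff(names(ranges), names(base))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  grid <- do.call(expand.grid, ranges)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    for (nm in names(ranges)) p[[nm]] <- grid[i, nm]
    g <- cilia_geometry(p$r_m, p$L_m, p$Lc_m, p$mu, p$f_hz, p$A_m)
    ff <- flow_force(g, log_base)
    data.frame(as.data.frame(p),
               C = drag_coefficient(g, log_base),
               F_flow_N = ff,
               F_torque_N = torque_force(g, ff))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse a unit-suffixed length ("99nm", "11.1um", "0.5mm") to metres
#'
#' @param x character scalar or plain number (taken as metres).
#' @return length in metres.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*(nm|um|mm|m)?$", trimws(x)))[[1]]
  if (length(m) == 0 || m[2] == "") stop("cannot parse length: ", x)
  v <- as.numeric(m[2])
  unit <- if (m[3] == "") "m" else m[3]
  v * switch(unit, nm = 1e-9, um = 1e-6, mm = 1e-3, m = 1)
}
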