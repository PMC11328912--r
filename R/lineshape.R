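#' @title Kubo lineshape synthesis
#'
#' @description
#' Forward synthesis of the linear IR absorption band from FFCF parameters.
#' For Gaussian frequency fluctuations with exponential memory the lineshape
#' function is
#'
#' `g(t) = sum_i Dw_i^2 tau_i^2 (exp(-t/tau_i) + t/tau_i - 1)`
#'
#' with `Dw_i = 2 pi c Delta_i` the amplitude converted from cm^-1 to rad/ps
#' (`c = 0.0299792458 cm/ps`; the conversion lives in [cm1_to_radps()] and
#' nowhere else). The band is
#'
#' `A(omega) ~ Re int_0^inf exp(i (omega - omega0) t) exp(-g(t)) exp(-t/2T1) dt`,
#'
#' evaluated as a half-sided discrete transform with trapezoidal end
#' correction and 4x zero padding. The two classic limits bracket the
#' behaviour: slow baths (`Dw tau >> 1`) give a Gaussian band of FWHM
#' `2 sqrt(2 ln 2) Delta`; fast baths (`Dw tau << 1`) give a motionally
#' narrowed Lorentzian of FWHM `2 Dw^2 tau / (2 pi c)` (pure dephasing rate
#' `1/T2* = Dw^2 tau`).
#'
#' @name lineshape
NULL

# decay time of |exp(-g(t) - t/2T1)|: time at which the exponent reaches
# `target` (log units), found by bisection
response_decay_time <- function(components, T1 = NULL, target = 18) {
  expo <- function(t) {
    g <- g_kubo(t, components)
    if (!is.null(T1)) g <- g + t / (2 * T1)
    g
  }
  hi <- 1
  while (expo(hi) < target && hi < 1e7) hi <- hi * 2
  lo <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (expo(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Lineshape parameters with grid validation
#'
#' When `dt_ps`/`t_max_ps` are omitted they are chosen automatically: the
#' time step resolves both the fastest component (`dt <= tau_min/20`) and the
#' response decay (`dt <= T_decay/100`), and the grid extends to ten times the
#' decay time of `exp(-g(t) - t/2T1)`. Explicit grids are validated against
#' the coarser requirements `dt <= tau_min/10` and `t_max >= 5 T_decay`;
#' violations are errors, never silent aliasing.
#'
#' @param components data frame with columns `delta_cm1` and `tau_ps` (as in a
#'   `vib_kubo_fit`), or a `vib_kubo_fit`.
#' @param omega0 band center in cm^-1.
#' @param T1 optional vibrational lifetime in ps; adds an `exp(-t/2T1)`
#'   population decay to the response.
#' @param dt_ps time grid step in ps (optional).
#' @param t_max_ps time grid extent in ps (optional).
#' @param span_cm1 frequency span of the returned spectrum, centered on
#'   `omega0` (optional; default covers the band generously).
#' @return a list of class `"vib_lineshape_params"`.
#' @export
lineshape_params <- function(components, omega0 = 1700, T1 = NULL,
                             dt_ps = NULL, t_max_ps = NULL,
                             span_cm1 = NULL) {
  if (inherits(components, "vib_kubo_fit")) components <- components$components
  if (!all(c("delta_cm1", "tau_ps") %in% names(components)))
    vib_stop("components must have columns delta_cm1 and tau_ps",
             "vib_invalid_params")
  if (any(components$delta_cm1 < 0) || any(components$tau_ps <= 0))
    vib_stop("component amplitudes must be >= 0 and times > 0",
             "vib_invalid_params")
  if (all(components$delta_cm1 == 0) && is.null(T1))
    vib_stop("all-zero amplitudes with no lifetime give no decay",
             "vib_invalid_params")
  tdec <- response_decay_time(components, T1)
  tau_min <- min(components$tau_ps[components$delta_cm1 > 0],
                 if (!is.null(T1)) T1 else Inf)
  if (is.null(dt_ps)) dt_ps <- min(tau_min / 12, tdec / 100)
  if (is.null(t_max_ps)) t_max_ps <- 6 * tdec
  if (dt_ps > tau_min / 10 + 1e-12)
    vib_stop(sprintf(
      "time step %g ps too coarse: must be <= tau_min/10 = %g ps",
      dt_ps, tau_min / 10), "vib_grid_too_coarse")
  if (t_max_ps < 5 * tdec)
    vib_stop(sprintf(
      "time grid extent %g ps too short: response decays over ~%g ps (need >= %g)",
      t_max_ps, tdec, 5 * tdec), "vib_grid_too_coarse")
  if (is.null(span_cm1)) {
    dtot <- sqrt(sum(components$delta_cm1^2))
    span_cm1 <- max(40 * dtot, 40 / (2 * pi * vib_constants$c_cm_per_ps * tdec),
                    50)
  }
  structure(list(components = components, omega0 = omega0, T1 = T1,
                 dt_ps = dt_ps, t_max_ps = t_max_ps, span_cm1 = span_cm1),
            class = "vib_lineshape_params")
}

#' Kubo lineshape function g(t)
#'
#' @param t_ps time(s) in ps, >= 0.
#' @param components data frame with `delta_cm1` (cm^-1) and `tau_ps` (ps), or
#'   a `vib_kubo_fit`.
#' @return g(t), dimensionless, same length as `t_ps`.
#' @export
g_kubo <- function(t_ps, components) {
  if (inherits(components, "vib_kubo_fit")) components <- components$components
  if (any(t_ps < 0))
    vib_stop("g(t) is defined for t >= 0", "vib_invalid_time")
  g <- numeric(length(t_ps))
  for (i in seq_len(nrow(components))) {
    dw <- cm1_to_radps(components$delta_cm1[i])
    tau <- components$tau_ps[i]
    # expm1 keeps the small-t limit (1/2 dw^2 t^2) accurate
    g <- g + dw^2 * tau^2 * (expm1(-t_ps / tau) + t_ps / tau)
  }
  g
}

#' Synthesize the linear absorption spectrum from FFCF parameters
#'
#' Half-sided discrete transform of `exp(-g(t) - t/2T1)` with trapezoidal end
#' correction and 4x zero padding (via FFT); the result is symmetric about
#' `omega0`, peak-normalized, and trimmed to the requested span.
#'
#' @param params a `vib_lineshape_params`.
#' @return an object of class `"vib_spectrum"`: a data frame with columns
#'   `wavenumber_cm1` and `absorbance` (peak-normalized), parameters in
#'   `attr(, "params")`.
#' @export
linear_spectrum <- function(params) {
  dt <- params$dt_ps
  nt <- as.integer(ceiling(params$t_max_ps / dt)) + 1L
  t <- dt * (0:(nt - 1L))
  expo <- g_kubo(t, params$components)
  if (!is.null(params$T1)) expo <- expo + t / (2 * params$T1)
  Fz <- exp(-expo)
  # trapezoidal end correction for the half-sided transform
  w <- rep(1, nt); w[1] <- 0.5; w[nt] <- 0.5
  Fw <- Fz * w
  npad <- 4L * 2^ceiling(log2(nt))
  Fpad <- c(Fw, rep(0, npad - nt))
  spec <- Re(stats::fft(Fpad)) * dt
  # FFT bin k corresponds to frequency offset k/(npad*dt) cycles/ps;
  # convert to cm^-1 offsets, assembling the symmetric two-sided axis
  f_cyc <- (0:(npad - 1L)) / (npad * dt)
  half <- seq_len(npad %/% 2L)
  off_cm1 <- f_cyc[half] / vib_constants$c_cm_per_ps
  ax <- c(-rev(off_cm1[-1]), off_cm1)
  ab <- c(rev(spec[half][-1]), spec[half])
  keep <- abs(ax) <= params$span_cm1 / 2
  ax <- ax[keep]; ab <- ab[keep]
  ab <- pmax(ab, 0)          # clip tiny negative truncation ripples
  mx <- max(ab)
  if (mx <= 0)
    vib_stop("spectrum is identically zero on the requested span",
             "vib_invalid_spectrum")
  out <- data.frame(wavenumber_cm1 = params$omega0 + ax,
                    absorbance = ab / mx)
  attr(out, "params") <- params
  class(out) <- c("vib_spectrum", "data.frame")
  out
}

#' Full width at half maximum of a single-peaked spectrum
#'
#' Locates the two half-maximum crossings by linear interpolation between
#' grid points. More than one crossing on a flank (a structured or multi-peak
#' band) is an error.
#'
#' @param spectrum a `vib_spectrum` or any data frame with `wavenumber_cm1`
#'   and `absorbance` columns.
#' @return FWHM in cm^-1.
#' @export
fwhm <- function(spectrum) {
  x <- spectrum$wavenumber_cm1
  y <- spectrum$absorbance
  ymax <- max(y)
  if (!is.finite(ymax) || ymax <= 0 || diff(range(y)) == 0)
    vib_stop("spectrum is flat: no peak to measure", "vib_not_single_peaked")
  y <- y / ymax
  half <- 0.5
  above <- y >= half
  runs <- rle(above)
  if (sum(runs$values) != 1)
    vib_stop("not single-peaked: multiple disjoint half-maximum regions",
             "vib_not_single_peaked")
  idx <- which(above)
  lo <- idx[1]; hi <- idx[length(idx)]
  if (lo == 1 || hi == length(y))
    vib_stop("half-maximum crossing lies outside the spectral span",
             "vib_not_single_peaked")
  # interpolate on each flank
  xl <- x[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) *
    (x[lo] - x[lo - 1])
  xr <- x[hi] + (half - y[hi]) / (y[hi + 1] - y[hi]) * (x[hi + 1] - x[hi])
  xr - xl
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum a `vib_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavenumber_cm1 = spectrum$wavenumber_cm1,
               absorbance = spectrum$absorbance),
    path, row.names = FALSE)
  invisible(path)
}
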