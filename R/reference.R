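#' Reference scan specification
#'
#' Parameters of the metallic-sphere reference measurement and of the
#' analytic reference pulse. The pulse is a first-derivative-of-Gaussian
#' wavelet (zero DC, band-limited), whose spectral magnitude peaks at
#' `1/(2*pi*sigma)` — about 0.64 THz at the default width, with energy
#' concentrated in 0.1–2 THz.
#'
#' @param radius_mm sphere radius (mm, > 0)
#' @param dt_ps sampling interval (ps, > 0)
#' @param n trace length in samples (power of two)
#' @param t0_ps pulse arrival time (ps)
#' @param sigma_ps Gaussian width of the wavelet (ps)
#' @return an object of class `reference_spec`
#' @export
reference_spec <- function(radius_mm = 8.02, dt_ps = 0.0333, n = 2048,
                           t0_ps = 10, sigma_ps = 0.25) {
  stopifnot(radius_mm > 0, dt_ps > 0, n >= 8, sigma_ps > 0)
  if (bitwAnd(n, n - 1L) != 0)
    stop("trace length must be a power of two")
  structure(list(radius_mm = radius_mm, dt_ps = dt_ps, n = as.integer(n),
                 t0_ps = t0_ps, sigma_ps = sigma_ps),
            class = "reference_spec")
}

#' Time axis of a reference specification
#' @param ref a [reference_spec()]
#' @return time axis (ps)
#' @export
ref_time_axis <- function(ref) (seq_len(ref$n) - 1) * ref$dt_ps

#' One-sided frequency axis of a reference specification
#' @param ref a [reference_spec()]
#' @return frequencies 0..Nyquist (THz), length `n/2 + 1`
#' @export
ref_freq_axis <- function(ref) (0:(ref$n / 2)) / (ref$n * ref$dt_ps)

#' Analytic reference pulse
#'
#' First derivative of a Gaussian, peak amplitude normalized to 1.
#'
#' @param ref a [reference_spec()]
#' @return a `thz_trace` (see [thz_trace()])
#' @export
reference_pulse <- function(ref) {
  stopifnot(inherits(ref, "reference_spec"))
  t <- ref_time_axis(ref)
  u <- (t - ref$t0_ps) / ref$sigma_ps
  p <- -u * exp(-u^2 / 2)
  p <- p / max(abs(p))
  thz_trace(t, p)
}

#' THz time-domain trace
#'
#' A uniformly sampled real-valued pulse with optional angular pixel
#' coordinates (degrees).
#'
#' @param t_ps uniform time axis (ps)
#' @param amplitude real amplitudes (arbitrary detector units)
#' @param elev_deg,azim_deg pixel angular coordinates (degrees), optional
#' @return an object of class `thz_trace`
#' @export
thz_trace <- function(t_ps, amplitude, elev_deg = NA_real_, azim_deg = NA_real_) {
  if (length(t_ps) != length(amplitude))
    stop("time axis and amplitude differ in length")
  if (!all(is.finite(amplitude))) stop("trace amplitudes must be finite")
  dt <- diff(t_ps)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time axis must be uniform")
  structure(list(t_ps = t_ps, amplitude = amplitude,
                 elev_deg = elev_deg, azim_deg = azim_deg),
            class = "thz_trace")
}

#' @export
print.thz_trace <- function(x, ...) {
  cat(sprintf("<thz_trace> %d samples, dt = %.4g ps, span %.1f ps\n",
              length(x$t_ps), x$t_ps[2] - x$t_ps[1], max(x$t_ps)))
  invisible(x)
}
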