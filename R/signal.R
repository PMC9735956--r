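# Signal processing: raw traces -> deconvolved transfer spectra -> band slopes.

# Gaussian high-pass gain, calibrated to 0.5 at the cutoff.
hp_gain <- function(freq_thz, cutoff_thz) {
  sigma_f <- cutoff_thz / sqrt(2 * log(2))
  1 - exp(-freq_thz^2 / (2 * sigma_f^2))
}

#' Gaussian high-pass filter
#'
#' Frequency-domain multiplication by `1 - exp(-f^2/(2*sigma_f^2))`, with
#' `sigma_f` set so the gain at the cutoff is exactly 0.5. Removes DC and
#' attenuates low-frequency drift while leaving the analysis band
#' (0.4–0.8 THz by default) essentially untouched.
#'
#' @param trace a [thz_trace()] or a numeric matrix of traces (columns)
#' @param cutoff_thz half-gain frequency (THz), below Nyquist
#' @param dt_ps sampling interval, required when `trace` is a bare matrix
#' @return filtered trace(s), same class and shape as the input
#' @export
highpass_filter <- function(trace, cutoff_thz = 0.1, dt_ps = NULL) {
  if (inherits(trace, "thz_trace")) {
    dt <- trace$t_ps[2] - trace$t_ps[1]
    x <- matrix(trace$amplitude, ncol = 1)
  } else {
    if (is.null(dt_ps)) stop("dt_ps required for matrix input")
    dt <- dt_ps
    x <- as.matrix(trace)
  }
  n <- nrow(x)
  nyq <- 1 / (2 * dt)
  if (cutoff_thz >= nyq) stop("cutoff must be below the Nyquist frequency")
  # full (two-sided) frequency axis; gain depends on |f| only
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * dt)
  g <- hp_gain(abs(f), cutoff_thz)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
  if (inherits(trace, "thz_trace")) {
    thz_trace(trace$t_ps, as.vector(y), trace$elev_deg, trace$azim_deg)
  } else y
}

#' One-sided spectrum of a trace
#'
#' Discrete Fourier transform, retaining the nonnegative-frequency half
#' (`n/2 + 1` bins for even `n`). Frequency resolution is `1/(n*dt)`.
#' No window is applied by default.
#'
#' @param trace a [thz_trace()] or numeric matrix of traces (columns)
#' @param dt_ps sampling interval, required for matrix input
#' @param window optional window function (e.g. [signal_hann()]) applied
#'   in the time domain before the transform
#' @return an object of class `thz_spectrum`: list with `freq_thz`,
#'   complex `values` (matrix, one column per trace), `n`, `dt_ps`
#' @export
compute_spectrum <- function(trace, dt_ps = NULL, window = NULL) {
  if (inherits(trace, "thz_trace")) {
    dt <- trace$t_ps[2] - trace$t_ps[1]
    steps <- diff(trace$t_ps)
    if (max(abs(steps - dt)) > 1e-9 * dt) stop("time axis must be uniform")
    x <- matrix(trace$amplitude, ncol = 1)
  } else {
    if (is.null(dt_ps)) stop("dt_ps required for matrix input")
    dt <- dt_ps
    x <- as.matrix(trace)
  }
  n <- nrow(x)
  if (!is.null(window)) x <- x * window(n)
  nh <- floor(n / 2) + 1
  vals <- stats::mvfft(x)[seq_len(nh), , drop = FALSE]
  structure(list(freq_thz = (seq_len(nh) - 1) / (n * dt),
                 values = vals, n = n, dt_ps = dt),
            class = "thz_spectrum")
}

#' Hann window generator
#' @return a function of the trace length returning window weights
#' @export
signal_hann <- function() function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Wiener-regularized deconvolution
#'
#' Transfer spectrum `H(f) = S(f) * Conj(R(f)) / (|R(f)|^2 + lambda^2)`
#' with `lambda = regularization * max|R|`. With zero regularization and
#' `S = R` this gives `|H| = 1` wherever `|R| > 0`; the small default
#' regularization suppresses out-of-band noise amplification where the
#' reference spectrum carries no energy.
#'
#' @param sample_spec `thz_spectrum` of the sample trace(s)
#' @param reference_spec_ `thz_spectrum` of the reference trace (1 column)
#' @param regularization noise-floor fraction of the reference peak (>= 0)
#' @return an object of class `transfer_spectrum`: list with `freq_thz`,
#'   complex `values` matrix (dimensionless), `n`, `dt_ps`
#' @export
deconvolve <- function(sample_spec, reference_spec_, regularization = 1e-3) {
  stopifnot(inherits(sample_spec, "thz_spectrum"),
            inherits(reference_spec_, "thz_spectrum"))
  if (regularization < 0) stop("regularization must be nonnegative")
  if (sample_spec$n != reference_spec_$n ||
      abs(sample_spec$dt_ps - reference_spec_$dt_ps) > 1e-12)
    stop("sample and reference frequency grids differ")
  r <- reference_spec_$values[, 1]
  lam <- regularization * max(Mod(r))
  h <- sample_spec$values * Conj(r) / (Mod(r)^2 + lam^2)
  structure(list(freq_thz = sample_spec$freq_thz, values = h,
                 n = sample_spec$n, dt_ps = sample_spec$dt_ps),
            class = "transfer_spectrum")
}

#' Magnitude of a transfer spectrum
#' @param spec a `transfer_spectrum`
#' @return numeric matrix of `|H(f)|`
#' @export
transfer_magnitude <- function(spec) {
  stopifnot(inherits(spec, "transfer_spectrum"))
  Mod(spec$values)
}

#' Slope band
#' @param f_low,f_high band edges (THz), `0 < f_low < f_high`; both inclusive
#' @return an object of class `slope_band`
#' @export
slope_band <- function(f_low = 0.4, f_high = 0.8) {
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high), class = "slope_band")
}

#' Band-limited spectral slope
#'
#' Ordinary least-squares slope of `|H(f)|` (linear amplitude) versus
#' frequency over the bins with `f_low <= f <= f_high`. Units: dimensionless
#' per THz = ps. This is the tissue-hydration feature: a wetter cornea shows
#' a steeper (more negative) slope across 0.4–0.8 THz.
#'
#' @param spec a `transfer_spectrum` (one or more columns)
#' @param band a [slope_band()]
#' @return slope(s) in ps, one per column
#' @export
spectral_slope <- function(spec, band = slope_band()) {
  stopifnot(inherits(spec, "transfer_spectrum"), inherits(band, "slope_band"))
  idx <- which(spec$freq_thz >= band$f_low & spec$freq_thz <= band$f_high)
  if (length(idx) < 3) stop("fewer than 3 frequency bins in the slope band")
  f <- spec$freq_thz[idx]
  w <- (f - mean(f)) / sum((f - mean(f))^2) # OLS slope weights
  as.vector(crossprod(Mod(spec$values[idx, , drop = FALSE]), w))
}

# Per-frame path: trace matrix -> per-pixel band slopes. The high-pass gain
# is applied to sample and reference alike (the instrument pipeline filters
# every trace), so it cancels in H. slope_pipeline precomputes everything
# that does not depend on the frame.
slope_pipeline <- function(ref, cutoff_thz = 0.1, regularization = 1e-3,
                           band = slope_band()) {
  refp <- reference_pulse(ref)
  g <- hp_gain(ref_freq_axis(ref), cutoff_thz)
  rspec <- compute_spectrum(matrix(refp$amplitude, ncol = 1),
                            dt_ps = ref$dt_ps)
  rspec$values <- rspec$values * g
  function(traces) {
    sspec <- compute_spectrum(traces, dt_ps = ref$dt_ps)
    sspec$values <- sspec$values * g
    spectral_slope(deconvolve(sspec, rspec, regularization), band)
  }
}

frame_slopes <- function(traces, ref, cutoff_thz = 0.1,
                         regularization = 1e-3, band = slope_band()) {
  slope_pipeline(ref, cutoff_thz, regularization, band)(traces)
}
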