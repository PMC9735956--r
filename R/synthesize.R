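# Forward model: reference pulse through a reflectance channel, plus noise.

# Expand a one-sided complex spectrum (length n/2+1, DC..Nyquist) to the
# full Hermitian-symmetric length-n layout used by fft(). The one-sided
# values are taken in the physics (exp(-i*omega*t)) convention, so the
# positive-frequency fft bins receive their conjugates; DC and Nyquist are
# forced real to keep the synthesized trace exactly real.
onesided_to_full <- function(h, n) {
  if (length(h) != n / 2 + 1)
    stop("one-sided spectrum length does not match the trace length")
  full <- complex(n)
  full[1] <- Re(h[1])
  full[2:(n / 2)] <- Conj(h[2:(n / 2)])
  full[n / 2 + 1] <- Re(h[n / 2 + 1])
  full[(n / 2 + 2):n] <- rev(h[2:(n / 2)])
  full
}

#' Synthesize THz traces from a reflectance spectrum
#'
#' Passes the analytic reference pulse through a linear reflectance channel
#' and adds white detector noise: the trace is the inverse transform of
#' (reference pulse spectrum x reflectance) plus iid Gaussian noise. With
#' `reflectance` identically 1 and zero noise the output reproduces the
#' reference pulse sample-for-sample.
#'
#' @param reflectance complex reflection coefficient on the one-sided
#'   frequency grid of `ref` (length `n/2 + 1`, see [ref_freq_axis()])
#' @param ref a [reference_spec()]
#' @param noise_sd white-noise standard deviation, in units of the unit
#'   reference-pulse peak (>= 0)
#' @param n_pixels number of independent noisy realizations (columns)
#' @param seed optional integer seed for the noise draw
#' @return a numeric matrix `[n x n_pixels]` of traces (single pixel:
#'   still a 1-column matrix); time axis via [ref_time_axis()]
#' @export
synthesize_trace <- function(reflectance, ref, noise_sd = 0, n_pixels = 1,
                             seed = NULL) {
  stopifnot(inherits(ref, "reference_spec"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- ref$n
  if (length(reflectance) != n / 2 + 1)
    stop("reflectance grid does not match the reference trace length")
  p <- reference_pulse(ref)$amplitude
  pf <- stats::fft(p)
  sf <- pf * onesided_to_full(as.complex(reflectance), n)
  det <- Re(stats::fft(sf, inverse = TRUE)) / n
  out <- matrix(det, n, n_pixels)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + matrix(stats::rnorm(n * n_pixels, sd = noise_sd), n, n_pixels)
  }
  out
}
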