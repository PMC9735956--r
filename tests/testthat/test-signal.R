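# High-pass filtering, spectra, deconvolution and band slopes.

make_trace <- function(amp, dt = 0.0333) thz_trace((seq_along(amp) - 1) * dt, amp)

test_that("high-pass filter rejects DC and is calibrated to half gain at cutoff", {
  tr <- make_trace(rep(2.5, 512))
  out <- highpass_filter(tr, cutoff_thz = 0.1)
  expect_lt(max(abs(out$amplitude)), 1e-10 * 2.5)
  # closed-form gain at the cutoff
  sigma_f <- 0.1 / sqrt(2 * log(2))
  expect_equal(1 - exp(-0.1^2 / (2 * sigma_f^2)), 0.5, tolerance = 1e-12)
})

test_that("high-pass filter attenuates a bin-centered sinusoid by its closed-form gain", {
  n <- 512; dt <- 0.0333
  f1 <- round(1 * n * dt) / (n * dt) # bin frequency nearest 1 THz
  t <- (0:(n - 1)) * dt
  tr <- make_trace(sin(2 * pi * f1 * t))
  out <- highpass_filter(tr, cutoff_thz = 0.1)
  sigma_f <- 0.1 / sqrt(2 * log(2))
  gain <- 1 - exp(-f1^2 / (2 * sigma_f^2))
  expect_equal(out$amplitude, gain * tr$amplitude, tolerance = 1e-10)
  expect_error(highpass_filter(tr, cutoff_thz = 20), "Nyquist")
})

test_that("spectrum of an impulse is flat and a bin sinusoid is a single peak", {
  n <- 256; dt <- 0.0333
  imp <- make_trace(c(1, rep(0, n - 1)))
  sp <- compute_spectrum(imp)
  expect_equal(Mod(sp$values[, 1]), rep(1, n / 2 + 1))
  k <- 20
  t <- (0:(n - 1)) * dt
  sp2 <- compute_spectrum(make_trace(cos(2 * pi * k / (n * dt) * t)))
  mag <- Mod(sp2$values[, 1])
  expect_equal(which.max(mag), k + 1)
  expect_lt(max(mag[-(k + 1)]) / mag[k + 1], 1e-10)
})

test_that("spectrum conserves energy (Parseval)", {
  set.seed(42)
  n <- 512
  x <- rnorm(n)
  sp <- compute_spectrum(make_trace(x))
  full <- fft(x)
  expect_equal(sum(Mod(full)^2) / n, sum(x^2), tolerance = 1e-10)
  # one-sided layout carries the full transform's nonnegative half
  expect_equal(sp$values[, 1], full[1:(n / 2 + 1)])
  expect_error(compute_spectrum(thz_trace(c(0, 1, 3), c(1, 2, 3))), "uniform")
})

test_that("self-deconvolution yields unit transfer magnitude", {
  set.seed(7)
  x <- matrix(rnorm(256), ncol = 1)
  sp <- compute_spectrum(x, dt_ps = 0.0333)
  h <- deconvolve(sp, sp, regularization = 0)
  expect_equal(as.vector(transfer_magnitude(h)), rep(1, 129), tolerance = 1e-10)
  h0 <- deconvolve(compute_spectrum(matrix(0, 256, 1), dt_ps = 0.0333), sp, 0)
  expect_true(all(h0$values == 0))
  expect_error(deconvolve(sp, compute_spectrum(x, dt_ps = 0.05)), "grids")
  expect_error(deconvolve(sp, sp, regularization = -1), "nonnegative")
})

test_that("deconvolving a shifted copy recovers the delay", {
  ref <- reference_spec(n = 1024)
  p <- reference_pulse(ref)$amplitude
  kshift <- 7L
  shifted <- c(rep(0, kshift), p[1:(1024 - kshift)])
  # independent cross-correlation delay oracle
  cc <- vapply(0:20, function(k)
    sum(shifted * c(rep(0, k), p[1:(1024 - k)])), numeric(1))
  expect_equal(which.max(cc) - 1L, kshift)
  sp_s <- compute_spectrum(matrix(shifted, ncol = 1), dt_ps = ref$dt_ps)
  sp_r <- compute_spectrum(matrix(p, ncol = 1), dt_ps = ref$dt_ps)
  h <- deconvolve(sp_s, sp_r, regularization = 1e-6)
  band <- h$freq_thz > 0.2 & h$freq_thz < 1.5 # where the pulse has energy
  expect_equal(as.vector(transfer_magnitude(h))[band],
               rep(1, sum(band)), tolerance = 1e-3)
  # phase slope = 2*pi*f*k*dt across the energetic band
  ph <- Arg(h$values[band, 1])
  fit <- oracle_ols(h$freq_thz[band], unwrap_phase(ph))
  expect_equal(abs(fit[2]) / (2 * pi), kshift * ref$dt_ps, tolerance = 1e-3)
})

test_that("spectral slope recovers exact lines and scales linearly", {
  n <- 2048; dt <- 0.0333
  f <- (0:(n / 2)) / (n * dt)
  mk <- function(mag) structure(list(freq_thz = f,
                                     values = matrix(complex(real = mag)),
                                     n = n, dt_ps = dt),
                                class = "transfer_spectrum")
  expect_equal(spectral_slope(mk(rep(1, length(f)))), 0)
  expect_equal(spectral_slope(mk(1 - 0.5 * (f - 0.4))), -0.5, tolerance = 1e-12)
  set.seed(3)
  mag <- 1 + 0.1 * rnorm(length(f))
  expect_equal(spectral_slope(mk(3 * mag)), 3 * spectral_slope(mk(mag)),
               tolerance = 1e-12)
  # enumeration + normal-equations oracle over the in-band bins
  idx <- which(f >= 0.4 & f <= 0.8)
  expect_equal(spectral_slope(mk(mag)), oracle_ols(f[idx], mag[idx])[2],
               tolerance = 1e-8)
  expect_error(spectral_slope(mk(mag), slope_band(0.4, 0.405)), "3 frequency bins")
  expect_error(slope_band(0.8, 0.4), "f_low")
})

test_that("processing is deterministic for identical traces", {
  ref <- reference_spec(n = 512)
  set.seed(5)
  tr <- matrix(rnorm(512 * 4), 512, 4)
  s1 <- thzcornea:::frame_slopes(tr, ref)
  s2 <- thzcornea:::frame_slopes(tr, ref)
  expect_identical(s1, s2)
})
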