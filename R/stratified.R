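#' Layer stack for stratified-media reflectance
#'
#' Ordered finite layers (nearest the incident medium first) over a terminal
#' half-space, at normal incidence. Refractive indices may be dispersive:
#' `n` is a complex matrix with one row per frequency and one column per
#' finite layer; `n_out` is the half-space index per frequency.
#'
#' @param n complex matrix `[n_freq x n_layers]` of layer indices
#'   (0 columns for a bare interface)
#' @param d_um layer thicknesses (um, > 0), length `ncol(n)`
#' @param n_out terminal half-space index (length-1 or length-`n_freq`)
#' @param n_in incident medium index (default 1, air)
#' @return an object of class `layer_stack`
#' @export
layer_stack <- function(n, d_um, n_out, n_in = 1 + 0i) {
  n <- as.matrix(n)
  if (length(d_um) != ncol(n))
    stop("need one thickness per finite layer")
  if (length(d_um) && any(d_um <= 0))
    stop("finite-layer thicknesses must be positive")
  structure(list(n = n, d_um = d_um,
                 n_out = as.complex(n_out), n_in = as.complex(n_in)),
            class = "layer_stack")
}

#' Normal-incidence reflectance of a stratified medium
#'
#' Characteristic (transfer) matrix method. Each finite layer contributes
#' `M_j = [[cos(delta), i sin(delta)/n_j], [i n_j sin(delta), cos(delta)]]`
#' with phase thickness `delta = 2*pi*f*n_j*d_j/c`; the amplitude reflection
#' coefficient follows from the accumulated matrix and the bounding indices.
#' With the `exp(-i*omega*t)` convention (`Im(n) >= 0` for lossy layers),
#' `|r| <= 1` for passive stacks.
#'
#' @param stack a [layer_stack()]
#' @param freq_thz frequency vector (THz); must have `length == nrow(stack$n)`
#'   when the stack has finite layers
#' @return complex reflection coefficient per frequency
#' @export
stratified_reflectance <- function(stack, freq_thz) {
  stopifnot(inherits(stack, "layer_stack"))
  nf <- length(freq_thz)
  L <- length(stack$d_um)
  if (L > 0 && nrow(stack$n) != nf)
    stop("stack index table and frequency grid differ in length")
  n_in <- rep_len(stack$n_in, nf)
  n_out <- rep_len(stack$n_out, nf)
  # accumulate M = M_1 %*% ... %*% M_L, elementwise over frequency
  m11 <- rep(1 + 0i, nf); m12 <- rep(0i, nf)
  m21 <- rep(0i, nf);     m22 <- rep(1 + 0i, nf)
  for (j in seq_len(L)) {
    nj <- stack$n[, j]
    delta <- 2 * pi * freq_thz * nj * stack$d_um[j] / C_UM_PER_PS
    cd <- cos(delta); sd <- sin(delta)
    a11 <- cd;             a12 <- -1i * sd / nj
    a21 <- -1i * nj * sd;  a22 <- cd
    t11 <- m11 * a11 + m12 * a21
    t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21
    t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  num <- n_in * (m11 + m12 * n_out) - (m21 + m22 * n_out)
  den <- n_in * (m11 + m12 * n_out) + (m21 + m22 * n_out)
  num / den
}

#' Complex refractive index from permittivity
#'
#' Principal square root; with `Im(eps) >= 0` this yields `Im(n) >= 0`
#' (absorbing) under the package time convention.
#'
#' @param eps complex permittivity
#' @return complex refractive index
#' @export
index_from_permittivity <- function(eps) {
  n <- sqrt(as.complex(eps))
  ifelse(Im(n) < 0, -n, n)
}

#' Corneal layer stack at a given surface hydration
#'
#' Discretizes a Fickian water-fraction depth profile into equal-thickness
#' layers over a bulk half-space. Each layer's permittivity is the Bruggeman
#' mixture of double-Debye water and a nondispersive tissue background at the
#' water fraction of the layer midpoint; the half-space uses the bulk
#' fraction `C0`.
#'
#' @param freq_thz frequency grid (THz)
#' @param profile a [hydration_profile()] with the current surface fraction
#' @param t_diff_min effective diffusion time shaping the depth profile (min)
#' @param depth_um total discretized depth (um)
#' @param n_layers number of equal-thickness layers
#' @param eps_background real tissue background permittivity
#' @param debye water [water_debye_params()]
#' @return a [layer_stack()] (incident medium air)
#' @export
cornea_stack <- function(freq_thz, profile, t_diff_min = 120,
                         depth_um = 500, n_layers = 20,
                         eps_background = 4.0,
                         debye = water_debye_params()) {
  stopifnot(inherits(profile, "hydration_profile"), n_layers >= 1)
  d <- depth_um / n_layers
  z_mid <- (seq_len(n_layers) - 0.5) * d
  frac <- fick_profile(z_mid, t_diff_min, profile)
  eps_w <- debye_permittivity(freq_thz, debye)
  n <- matrix(0i, length(freq_thz), n_layers)
  for (j in seq_len(n_layers)) {
    n[, j] <- index_from_permittivity(
      bruggeman_mix(eps_w, eps_background, frac[j]))
  }
  n_out <- index_from_permittivity(
    bruggeman_mix(eps_w, eps_background, profile$C0))
  layer_stack(n, rep(d, n_layers), n_out)
}
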