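#' Double-Debye dielectric parameters
#'
#' Container for the two-relaxation-time Debye model used for liquid water in
#' the THz band. The defaults are a published literature parameterization of
#' water at room temperature (static permittivity 78.36 split into two
#' relaxation strengths over a fast and a slow process).
#'
#' @param eps_inf high-frequency permittivity (dimensionless, >= 1)
#' @param delta_eps1,delta_eps2 relaxation strengths (dimensionless, >= 0)
#' @param tau1_ps,tau2_ps relaxation times (ps, > 0)
#' @return an object of class `debye_params`
#' @examples
#' water_debye_params()
#' @export
water_debye_params <- function(eps_inf = 3.48,
                               delta_eps1 = 73.43,
                               delta_eps2 = 1.45,
                               tau1_ps = 8.24,
                               tau2_ps = 0.18) {
  stopifnot(eps_inf >= 1, delta_eps1 >= 0, delta_eps2 >= 0,
            tau1_ps > 0, tau2_ps > 0)
  structure(list(eps_inf = eps_inf,
                 delta_eps1 = delta_eps1, delta_eps2 = delta_eps2,
                 tau1_ps = tau1_ps, tau2_ps = tau2_ps),
            class = "debye_params")
}

#' Complex permittivity from the double-Debye model
#'
#' Evaluates `eps(f) = eps_inf + d1/(1 - i*2*pi*f*tau1) + d2/(1 - i*2*pi*f*tau2)`.
#' With the package's `exp(-i*omega*t)` time convention this form yields
#' `Im(eps) >= 0` for absorbing media.
#'
#' @param freq_thz frequency vector (THz, >= 0)
#' @param params a [water_debye_params()] object
#' @return complex permittivity, same length as `freq_thz`
#' @examples
#' debye_permittivity(0.5, water_debye_params())
#' @export
debye_permittivity <- function(freq_thz, params = water_debye_params()) {
  if (any(freq_thz < 0)) stop("frequencies must be nonnegative")
  w <- 2 * pi * freq_thz
  params$eps_inf +
    params$delta_eps1 / (1 - 1i * w * params$tau1_ps) +
    params$delta_eps2 / (1 - 1i * w * params$tau2_ps)
}

#' Bruggeman effective-medium permittivity
#'
#' Solves the symmetric two-phase Bruggeman mixing rule
#' `f*(ew - e)/(ew + 2e) + (1 - f)*(eb - e)/(eb + 2e) = 0`
#' for the effective permittivity `e`. The rule reduces to the quadratic
#' `2 e^2 - b e - ew*eb = 0` with `b = f*(2ew - eb) + (1-f)*(2eb - ew)`;
#' the physical root (positive real part, nonnegative imaginary part under
#' the `exp(-i*omega*t)` convention) is returned and its residual in the
#' mixing equation is checked against `1e-12`.
#'
#' @param eps_water complex permittivity of the inclusion phase (vector ok)
#' @param eps_background complex permittivity of the host phase
#' @param water_fraction volume fraction of the inclusion phase in `[0, 1]`
#' @return complex effective permittivity
#' @examples
#' bruggeman_mix(9, 4, 0.5)  # positive root of 4x^2 - 13x - 72 = 0
#' @export
bruggeman_mix <- function(eps_water, eps_background, water_fraction) {
  if (any(water_fraction < 0) || any(water_fraction > 1))
    stop("water_fraction must lie in [0, 1]")
  ew <- as.complex(eps_water)
  eb <- as.complex(eps_background)
  f <- water_fraction
  b <- f * (2 * ew - eb) + (1 - f) * (2 * eb - ew)
  disc <- sqrt(b^2 + 8 * ew * eb)
  r1 <- (b + disc) / 4
  r2 <- (b - disc) / 4
  # physical branch: Re > 0, Im >= 0 (tolerate rounding at the real axis)
  pick <- function(a, b2) {
    ok1 <- Re(a) > 0 & Im(a) >= -1e-12
    ok2 <- Re(b2) > 0 & Im(b2) >= -1e-12
    out <- ifelse(ok1, a, b2)
    if (any(!ok1 & !ok2)) stop("no physical Bruggeman root for these inputs")
    out
  }
  eps <- pick(r1, r2)
  res <- f * (ew - eps) / (ew + 2 * eps) +
    (1 - f) * (eb - eps) / (eb + 2 * eps)
  if (any(Mod(res) > 1e-12 * pmax(1, Mod(eps))))
    stop("Bruggeman residual exceeds tolerance")
  eps
}
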