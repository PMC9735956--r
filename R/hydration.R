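#' Hydration profile parameters
#'
#' Semi-infinite Fickian diffusion profile: a fixed boundary water fraction
#' `C1` at the surface, bulk fraction `C0` at depth, diffusion coefficient
#' `D` (um^2/min).
#'
#' @param C0 bulk water volume fraction in `[0, 1]`
#' @param C1 boundary (surface) water volume fraction in `[0, 1]`
#' @param D_um2_per_min diffusion coefficient (um^2/min, > 0)
#' @return an object of class `hydration_profile`
#' @export
hydration_profile <- function(C0 = 0.75, C1 = 0.75, D_um2_per_min = 500) {
  if (D_um2_per_min <= 0) stop("diffusion coefficient must be positive")
  stopifnot(C0 >= 0, C0 <= 1, C1 >= 0, C1 <= 1)
  structure(list(C0 = C0, C1 = C1, D = D_um2_per_min),
            class = "hydration_profile")
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Fickian water-fraction profile
#'
#' Solution of Fick's second law for a semi-infinite medium with a fixed
#' boundary concentration:
#' `C(z, t) = C0 + (C1 - C0) * erfc(z / (2*sqrt(D*t)))` for `t > 0`.
#' At `t = 0` the profile is the initial condition `C0` for `z > 0`
#' (and `C1` at the boundary `z = 0`).
#'
#' @param depth_um depth below the surface (um, >= 0); vector ok
#' @param t_min elapsed time (min, >= 0)
#' @param profile a [hydration_profile()]
#' @return water volume fraction(s) in `[0, 1]`
#' @export
fick_profile <- function(depth_um, t_min, profile) {
  stopifnot(inherits(profile, "hydration_profile"))
  if (profile$D <= 0) stop("diffusion coefficient must be positive")
  if (any(depth_um < 0) || t_min < 0) stop("depth and time must be nonnegative")
  if (t_min == 0) {
    return(ifelse(depth_um == 0, profile$C1, profile$C0))
  }
  arg <- depth_um / (2 * sqrt(profile$D * t_min))
  profile$C0 + (profile$C1 - profile$C0) * erfc_(arg)
}

#' Pump efficacy from endothelial cell density
#'
#' Monotone logistic map from ECD (cells/mm^2) to a dimensionless pump
#' efficacy in `[0, 1]`, centered at the intact/damaged ECD threshold:
#' a dense, functional endothelial monolayer (high ECD) pumps stromal fluid
#' out effectively (efficacy near 1); a sparse, damaged layer does not.
#'
#' @param ecd endothelial cell density (cells/mm^2, > 0)
#' @param midpoint ECD at which efficacy is 0.5 (default 3000)
#' @param scale logistic scale (cells/mm^2)
#' @return pump efficacy in `[0, 1]`
#' @export
pump_efficacy <- function(ecd, midpoint = 3000, scale = 300) {
  if (any(ecd <= 0)) stop("ECD must be positive")
  1 / (1 + exp(-(ecd - midpoint) / scale))
}

#' Surface-hydration dynamics under an IOP protocol
#'
#' Two-rate phenomenological model of the surface water fraction `C1(t)`:
#' pressure-driven influx at rate `k_in * (IOP - base)/10` toward a ceiling
#' `C1_max`, opposed by endothelial-pump efflux at rate `k_out * pump`
#' toward the bulk fraction `C0`. Integrated with a 1-min forward-Euler step;
#' intact samples (pump near 1) show small, reversible excursions while
#' damaged samples (pump near 0) show large, persistent ones.
#'
#' @param protocol a [protocol_spec()]
#' @param pump pump efficacy in `[0, 1]` (see [pump_efficacy()])
#' @param C0 baseline bulk water fraction
#' @param C1_max ceiling on the surface fraction
#' @param k_in influx rate constant (1/min per 10 mmHg above baseline)
#' @param k_out efflux rate constant (1/min at unit pump efficacy)
#' @return numeric vector of `C1` at the protocol's frame times
#' @export
hydration_series <- function(protocol, pump, C0 = 0.75, C1_max = 0.95,
                             k_in = 0.004, k_out = 0.05) {
  stopifnot(inherits(protocol, "protocol_spec"), pump >= 0, pump <= 1)
  times <- frame_times(protocol)
  t_end <- max(times)
  dt <- 1 # min
  c1 <- C0
  out <- numeric(length(times))
  out[times == 0] <- c1
  for (t in seq(dt, t_end, by = dt)) {
    iop <- protocol_iop(protocol, t)
    influx <- k_in * max(iop - protocol$base_iop, 0) / 10 * (C1_max - c1)
    efflux <- k_out * pump * (c1 - C0)
    c1 <- min(max(c1 + dt * (influx - efflux), C0), C1_max)
    hit <- which(times == t)
    if (length(hit)) out[hit] <- c1
  }
  out
}
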