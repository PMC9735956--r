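# Small, fast fixtures built in code: short traces, short protocol, 3x3 grid.

test_config <- function() {
  cfg <- default_config()
  cfg$reference$n <- 512L
  cfg$cohort$grid_size <- 3L
  cfg$cohort$noise_sd <- 0.005
  cfg$classify$n_iterations <- 25L
  cfg
}

test_protocol <- function(elevated_iop = 45) {
  protocol_spec(acclimation_min = 32, elevated_min = 32, recovery_min = 32,
                elevated_iop = elevated_iop, frame_interval_min = 4)
}

test_cohort <- function(n = 4, seed = 11, config = test_config(),
                        elevated_iop = 45) {
  sizes <- stats::setNames(as.integer(n), as.character(elevated_iop))
  generate_cohort(group_sizes = sizes, protocol = test_protocol(elevated_iop),
                  config = config, seed = seed)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# OLS slope by explicit normal equations (independent of stats::lm and of
# the weight formulation used in spectral_slope)
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}
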