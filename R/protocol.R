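#' IOP experiment protocol
#'
#' Three-period intraocular-pressure protocol: acclimation at the baseline
#' pressure, an elevated-pressure period, and a recovery period back at
#' baseline, with scans at a fixed frame interval. Defaults follow the
#' 9-h protocol: 1 h at 15 mmHg, 4 h elevated, 4 h at 15 mmHg, one frame
#' every 4 min.
#'
#' @param acclimation_min,elevated_min,recovery_min period durations (min)
#' @param base_iop baseline IOP (mmHg)
#' @param elevated_iop elevated IOP (mmHg), one of 25/35/45 in the default design
#' @param frame_interval_min time between scans (min); must divide every
#'   period duration evenly
#' @return an object of class `protocol_spec`
#' @export
protocol_spec <- function(acclimation_min = 60, elevated_min = 240,
                          recovery_min = 240, base_iop = 15,
                          elevated_iop = 45, frame_interval_min = 4) {
  durs <- c(acclimation_min, elevated_min, recovery_min)
  if (any(durs <= 0)) stop("period durations must be positive")
  if (frame_interval_min <= 0) stop("frame interval must be positive")
  if (any(durs %% frame_interval_min != 0))
    stop("frame interval must divide each period duration evenly")
  structure(list(acclimation_min = acclimation_min,
                 elevated_min = elevated_min,
                 recovery_min = recovery_min,
                 base_iop = base_iop, elevated_iop = elevated_iop,
                 frame_interval_min = frame_interval_min),
            class = "protocol_spec")
}

#' Frame timestamps of a protocol
#' @param protocol a [protocol_spec()]
#' @return times (min) from 0 to the protocol end, inclusive
#' @export
frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  total <- protocol$acclimation_min + protocol$elevated_min +
    protocol$recovery_min
  seq(0, total, by = protocol$frame_interval_min)
}

#' IOP at a given time
#'
#' The elevated period spans `(acclimation, acclimation + elevated]`;
#' outside it the baseline pressure applies.
#'
#' @param protocol a [protocol_spec()]
#' @param t_min time (min); vector ok
#' @return IOP (mmHg) per time point
#' @export
protocol_iop <- function(protocol, t_min) {
  stopifnot(inherits(protocol, "protocol_spec"))
  lo <- protocol$acclimation_min
  hi <- lo + protocol$elevated_min
  ifelse(t_min > lo & t_min <= hi, protocol$elevated_iop, protocol$base_iop)
}
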