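# Feature extraction: per-pixel slopes -> ROI means -> S_Start/S_Elev/S_Phys.

#' Mean slope over the central region of interest
#'
#' Arithmetic mean of the central 5x5 block of a 9x9 pixel grid (the
#' central 25 pixels); general odd grid sizes use the central block of side
#' `ceiling(m/2)` rounded up to odd. Pixels with `NA`/`NaN` slopes (failed
#' deconvolution) are excluded if they make up at most 20% of the ROI,
#' otherwise an error is raised.
#'
#' @param frame_slopes square numeric matrix of per-pixel slopes (ps)
#' @return ROI mean slope (ps)
#' @export
central_roi_mean <- function(frame_slopes) {
  m <- as.matrix(frame_slopes)
  if (nrow(m) != ncol(m)) stop("slope grid must be square")
  g <- nrow(m)
  if (g %% 2 == 0) stop("even-sized grid has no unique center")
  side <- ceiling(g / 2)
  if (side %% 2 == 0) side <- side + 1
  side <- min(side, g)
  half <- (side - 1) / 2
  c0 <- (g + 1) / 2
  block <- m[(c0 - half):(c0 + half), (c0 - half):(c0 + half)]
  bad <- sum(!is.finite(block))
  if (bad > 0.2 * length(block))
    stop("more than 20% of ROI pixels are invalid")
  mean(block[is.finite(block)])
}

#' Last-30-min analysis windows of a protocol
#'
#' Half-open windows `(T_end - w, T_end]` over the acclimation, elevated and
#' recovery periods. With the default 9-h protocol these are (30, 60],
#' (270, 300] and (510, 540] minutes.
#'
#' @param protocol a [protocol_spec()]
#' @param window_min window length (min, default 30); every period must be
#'   at least this long
#' @return list of three `c(lo, hi)` windows (lo exclusive, hi inclusive):
#'   `start`, `elev`, `phys`
#' @export
period_windows <- function(protocol, window_min = 30) {
  stopifnot(inherits(protocol, "protocol_spec"))
  ends <- cumsum(c(protocol$acclimation_min, protocol$elevated_min,
                   protocol$recovery_min))
  durs <- c(protocol$acclimation_min, protocol$elevated_min,
            protocol$recovery_min)
  if (any(durs < window_min))
    stop("a protocol period is shorter than the analysis window")
  w <- lapply(ends, function(e) c(e - window_min, e))
  names(w) <- c("start", "elev", "phys")
  w
}

#' Per-frame ROI slope series of one sample
#'
#' Collapses a per-pixel slope table (one sample) to one ROI-mean slope per
#' frame, with the frame timestamps and IOP annotations.
#'
#' @param slope_table slope table rows for a single sample
#'   (see [process_cohort()])
#' @return an object of class `slope_series`: data.frame
#'   `t_min, iop_mmHg, slope_ps`, ordered by time
#' @export
slope_series <- function(slope_table) {
  if (length(unique(slope_table$sample_id)) != 1)
    stop("slope_series expects rows of exactly one sample")
  frames <- sort(unique(slope_table$t_min))
  g <- max(slope_table$pixel_row) + 1L
  vals <- vapply(frames, function(tm) {
    rows <- slope_table[slope_table$t_min == tm, ]
    m <- matrix(NA_real_, g, g)
    m[cbind(rows$pixel_row + 1L, rows$pixel_col + 1L)] <- rows$slope_ps
    central_roi_mean(m)
  }, numeric(1))
  iop <- vapply(frames, function(tm)
    slope_table$iop_mmHg[slope_table$t_min == tm][1], numeric(1))
  structure(data.frame(t_min = frames, iop_mmHg = iop, slope_ps = vals),
            class = c("slope_series", "data.frame"))
}

#' Per-sample hydration features
#'
#' `S_Start`, `S_Elev`, `S_Phys`: the mean ROI slope over the last 30 min
#' of the acclimation, elevated-IOP and recovery periods, respectively.
#'
#' @param series a [slope_series()]
#' @param protocol the sample's [protocol_spec()]
#' @param window_min analysis window (min)
#' @return named numeric vector `c(S_Start_ps, S_Elev_ps, S_Phys_ps)`
#' @export
extract_features <- function(series, protocol, window_min = 30) {
  w <- period_windows(protocol, window_min)
  vals <- vapply(w, function(win) {
    sel <- series$t_min > win[1] & series$t_min <= win[2]
    if (!any(sel)) stop("no frames fall in the analysis window (",
                        win[1], ", ", win[2], "]")
    mean(series$slope_ps[sel])
  }, numeric(1))
  if (any(!is.finite(vals))) stop("non-finite feature value")
  c(S_Start_ps = unname(vals["start"]), S_Elev_ps = unname(vals["elev"]),
    S_Phys_ps = unname(vals["phys"]))
}

#' Feature table of a processed cohort
#'
#' @param slope_table full per-pixel slope table (all samples)
#' @param cohort the `thz_cohort` the table came from (for the per-group
#'   protocols), or a single [protocol_spec()] applying to all samples
#' @param window_min analysis window (min)
#' @return data.frame `sample_id, group_mmHg, S_Start_ps, S_Elev_ps, S_Phys_ps`
#' @export
feature_table <- function(slope_table, cohort, window_min = 30) {
  ids <- unique(slope_table$sample_id)
  rows <- lapply(ids, function(id) {
    st <- slope_table[slope_table$sample_id == id, ]
    if (inherits(cohort, "thz_cohort")) {
      grp <- cohort$samples$group_mmHg[cohort$samples$sample_id == id]
      prot <- cohort$protocols[[as.character(grp)]]
    } else {
      stopifnot(inherits(cohort, "protocol_spec"))
      grp <- NA_real_
      prot <- cohort
    }
    fv <- extract_features(slope_series(st), prot, window_min)
    data.frame(sample_id = id, group_mmHg = grp,
               S_Start_ps = fv[["S_Start_ps"]],
               S_Elev_ps = fv[["S_Elev_ps"]],
               S_Phys_ps = fv[["S_Phys_ps"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
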