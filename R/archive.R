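# Scan-archive and label I/O: plain-directory CSV dialect with a JSON manifest.
#
# Layout:
#   <dir>/manifest.json             protocol, seed, config hash, sample table
#   <dir>/time_ps.csv               time axis
#   <dir>/reference.csv             reference trace
#   <dir>/samples/<id>/frame_<k>.csv   one column per pixel (px_<row>_<col>)

#' Write a cohort's scan archive
#'
#' Materializes every frame's trace grid to a plain-directory archive
#' (CSV traces + JSON manifest). Intended for small cohorts — a full
#' default cohort is several GB as text; use [process_cohort()] to stream
#' instead.
#'
#' @param cohort a `thz_cohort`
#' @param dir output directory (created; must not exist or be empty)
#' @return `dir`, invisibly
#' @export
write_archive <- function(cohort, dir) {
  stopifnot(inherits(cohort, "thz_cohort"))
  if (file.exists(dir) && length(list.files(dir)))
    stop("archive directory exists and is not empty: ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create archive directory: ", dir)
  g <- cohort$config$cohort$grid_size
  px <- sprintf("px_%d_%d", rep(0:(g - 1), each = g), rep(0:(g - 1), g))
  manifest <- list(
    format = "thz-scan-archive-csv/1",
    seed = cohort$seed,
    config_hash = config_hash(cohort$config),
    protocol = unclass(cohort$protocol),
    n_frames = length(cohort$frame_times),
    frame_times_min = cohort$frame_times,
    grid_size = g,
    trace_length = cohort$reference$n,
    dt_ps = cohort$reference$dt_ps,
    samples = cohort$samples[, c("sample_id", "group_mmHg")])
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 15),
             file.path(dir, "manifest.json"))
  utils::write.csv(data.frame(t_ps = ref_time_axis(cohort$reference)),
                   file.path(dir, "time_ps.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(amplitude = reference_pulse(cohort$reference)$amplitude),
    file.path(dir, "reference.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort$samples))) {
    sdir <- file.path(dir, "samples", cohort$samples$sample_id[i])
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(cohort$frame_times)) {
      tr <- synthesize_frame(cohort, i, k)
      colnames(tr) <- px
      iop <- protocol_iop(
        cohort$protocols[[as.character(cohort$samples$group_mmHg[i])]],
        cohort$frame_times[k])
      f <- file.path(sdir, sprintf("frame_%03d.csv", k - 1L))
      con <- file(f, "w")
      writeLines(sprintf("# t_min=%g iop_mmHg=%g", cohort$frame_times[k], iop),
                 con)
      utils::write.csv(as.data.frame(tr), con, row.names = FALSE)
      close(con)
    }
  }
  invisible(dir)
}

#' Read a scan archive
#'
#' @param dir archive directory written by [write_archive()]
#' @return list with `manifest`, `t_ps`, `reference` (numeric trace),
#'   `frames` (per sample, a list of `[n x pixels]` matrices), and
#'   per-frame `t_min`/`iop_mmHg` tables
#' @export
read_archive <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a scan archive (no manifest.json): ", dir)
  manifest <- jsonlite::fromJSON(mf)
  t_ps <- utils::read.csv(file.path(dir, "time_ps.csv"))$t_ps
  reference <- utils::read.csv(file.path(dir, "reference.csv"))$amplitude
  ids <- manifest$samples$sample_id
  frames <- list(); meta <- list()
  for (id in ids) {
    sdir <- file.path(dir, "samples", id)
    files <- sort(list.files(sdir, pattern = "^frame_\\d+\\.csv$",
                             full.names = TRUE))
    if (!length(files)) stop("archive missing frames for sample ", id)
    fl <- lapply(files, function(f) {
      hdr <- readLines(f, n = 1)
      m <- as.matrix(utils::read.csv(f, comment.char = "#"))
      nums <- as.numeric(regmatches(hdr, gregexpr("[-0-9.]+", hdr))[[1]])
      attr(m, "t_min") <- nums[1]; attr(m, "iop_mmHg") <- nums[2]
      m
    })
    frames[[id]] <- fl
    meta[[id]] <- data.frame(
      t_min = vapply(fl, attr, numeric(1), "t_min"),
      iop_mmHg = vapply(fl, attr, numeric(1), "iop_mmHg"))
  }
  list(manifest = manifest, t_ps = t_ps, reference = reference,
       frames = frames, frame_meta = meta)
}

#' Process a scan archive into the per-pixel slope table
#'
#' Same signal path as [process_cohort()], but reading traces from disk.
#'
#' @param archive result of [read_archive()]
#' @param config configuration list (signal parameters)
#' @return slope table data.frame (see [process_cohort()])
#' @export
process_archive <- function(archive, config = default_config()) {
  dt <- archive$manifest$dt_ps
  n <- length(archive$reference)
  band <- do.call(slope_band, config$signal$band)
  g_ax <- hp_gain((0:(n / 2)) / (n * dt), config$signal$hp_cutoff_thz)
  rspec <- compute_spectrum(matrix(archive$reference, ncol = 1), dt_ps = dt)
  rspec$values <- rspec$values * g_ax
  out <- list()
  for (id in names(archive$frames)) {
    fl <- archive$frames[[id]]
    meta <- archive$frame_meta[[id]]
    for (k in seq_along(fl)) {
      tr <- fl[[k]]
      gsz <- sqrt(ncol(tr))
      sspec <- compute_spectrum(tr, dt_ps = dt)
      sspec$values <- sspec$values * g_ax
      sl <- spectral_slope(deconvolve(sspec, rspec,
                                      config$signal$regularization), band)
      out[[length(out) + 1]] <- data.frame(
        sample_id = id, frame_index = k - 1L,
        t_min = meta$t_min[k], iop_mmHg = meta$iop_mmHg[k],
        pixel_row = rep(0:(gsz - 1), each = gsz),
        pixel_col = rep(0:(gsz - 1), gsz),
        slope_ps = sl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write / read the labels table
#'
#' CSV with header `sample_id,group_mmHg,ecd_cells_per_mm2`.
#'
#' @param labels data.frame with those columns
#' @param path CSV path
#' @return `path` invisibly / the data.frame
#' @export
write_labels <- function(labels, path) {
  need <- c("sample_id", "group_mmHg", "ecd_cells_per_mm2")
  if (!all(need %in% names(labels)))
    stop("labels table missing column(s): ",
         paste(setdiff(need, names(labels)), collapse = ", "))
  utils::write.csv(labels[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group_mmHg", "ecd_cells_per_mm2")
  if (!all(need %in% names(lab)))
    stop("labels CSV missing column(s): ",
         paste(setdiff(need, names(lab)), collapse = ", "))
  lab
}
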