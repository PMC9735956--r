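# Synthetic cohort generation: ECD labels, hydration dynamics, scan synthesis.

MAX_SEED <- 2147483629L # largest prime below 2^31; keeps derived seeds valid

# deterministic per-frame seed stream
frame_seed <- function(sample_seed, frame_idx) {
  as.integer((as.numeric(sample_seed) + 7919 * frame_idx) %% MAX_SEED)
}

#' Draw endothelial cell densities from a two-component mixture
#'
#' Lognormal mixture with an intact mode well above and a damaged mode well
#' below the 3000 cells/mm^2 integrity threshold, matching the healthy
#' porcine range of roughly 3500–6500 cells/mm^2.
#'
#' @param n number of samples
#' @param intact_weight mixture weight of the intact component
#' @param intact_meanlog,intact_sdlog lognormal parameters, intact mode
#' @param damaged_meanlog,damaged_sdlog lognormal parameters, damaged mode
#' @return list with `ecd` (cells/mm^2) and `component` ("intact"/"damaged")
#' @export
draw_ecd <- function(n, intact_weight = 0.5,
                     intact_meanlog = log(5000), intact_sdlog = 0.15,
                     damaged_meanlog = log(1600), damaged_sdlog = 0.2) {
  comp <- stats::rbinom(n, 1, intact_weight)
  ecd <- ifelse(comp == 1,
                stats::rlnorm(n, intact_meanlog, intact_sdlog),
                stats::rlnorm(n, damaged_meanlog, damaged_sdlog))
  list(ecd = ecd, component = ifelse(comp == 1, "intact", "damaged"))
}

#' Generate a synthetic THz-TDS corneal cohort
#'
#' For each sample: draws an ECD from the two-component mixture, maps it to
#' an endothelial pump efficacy, and integrates the surface-hydration
#' dynamics over the sample's IOP protocol. The cohort object stores the
#' per-frame hydration states and per-sample RNG seeds; traces are
#' synthesized on demand (see [synthesize_frame()], [process_cohort()],
#' [write_archive()]) so that streamed and materialized paths are
#' bit-identical.
#'
#' @param group_sizes named integer vector: samples per elevated-IOP group
#'   (names are the pressures in mmHg); default the 7/6/6 design at
#'   25/35/45 mmHg
#' @param protocol a [protocol_spec()] template; each group uses it with its
#'   own elevated pressure
#' @param config full parameter list, see [default_config()]; entries under
#'   `cohort`, `hydration`, `dielectric`, `stack` and `reference` are used
#' @param seed master integer seed
#' @return an object of class `thz_cohort`
#' @export
generate_cohort <- function(group_sizes = c(`25` = 7L, `35` = 6L, `45` = 6L),
                            protocol = protocol_spec(),
                            config = default_config(),
                            seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be named by elevated IOP (mmHg)")
  n <- sum(group_sizes)
  if (n < 1) stop("empty cohort")
  co <- config$cohort
  hy <- config$hydration
  set.seed(as.integer(seed))
  mix <- draw_ecd(n, co$intact_weight,
                  log(co$ecd_intact_mode), co$ecd_intact_sdlog,
                  log(co$ecd_damaged_mode), co$ecd_damaged_sdlog)
  sample_seeds <- sample.int(MAX_SEED, n)
  groups <- rep(as.numeric(names(group_sizes)), times = group_sizes)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group_mmHg = groups,
    ecd_cells_per_mm2 = mix$ecd,
    pump = pump_efficacy(mix$ecd, co$pump_midpoint, co$pump_scale),
    seed = sample_seeds,
    stringsAsFactors = FALSE)
  protocols <- lapply(as.numeric(names(group_sizes)), function(p) {
    protocol_spec(protocol$acclimation_min, protocol$elevated_min,
                  protocol$recovery_min, protocol$base_iop,
                  elevated_iop = p, protocol$frame_interval_min)
  })
  names(protocols) <- names(group_sizes)
  times <- frame_times(protocol)
  hydr <- matrix(NA_real_, n, length(times))
  for (i in seq_len(n)) {
    prot_i <- protocols[[as.character(samples$group_mmHg[i])]]
    hydr[i, ] <- hydration_series(prot_i, samples$pump[i],
                                  C0 = hy$C0, C1_max = hy$C1_max,
                                  k_in = hy$k_in, k_out = hy$k_out)
  }
  ref <- do.call(reference_spec, config$reference)
  structure(list(samples = samples, hydration = hydr,
                 frame_times = times, protocols = protocols,
                 protocol = protocol, reference = ref,
                 config = config, seed = as.integer(seed)),
            class = "thz_cohort")
}

#' @export
print.thz_cohort <- function(x, ...) {
  lab <- label_from_ecd(x$samples$ecd_cells_per_mm2)
  cat(sprintf("<thz_cohort> %d samples (%d intact / %d damaged), %d frames each\n",
              nrow(x$samples), sum(lab == "intact"), sum(lab == "damaged"),
              length(x$frame_times)))
  cat("  groups:",
      paste(sprintf("%s mmHg x %d", names(x$protocols),
                    tabulate(factor(x$samples$group_mmHg,
                                    levels = as.numeric(names(x$protocols))))),
            collapse = ", "), "\n")
  invisible(x)
}

# reflectance spectrum of sample i at frame k on the given frequency grid
cohort_reflectance <- function(cohort, i, k, freq = NULL) {
  cfg <- cohort$config
  if (is.null(freq)) freq <- ref_freq_axis(cohort$reference)
  prof <- hydration_profile(cfg$hydration$C0, cohort$hydration[i, k],
                            cfg$hydration$D_um2_per_min)
  stack <- cornea_stack(freq, prof,
                        t_diff_min = cfg$hydration$t_diff_min,
                        depth_um = cfg$stack$depth_um,
                        n_layers = cfg$stack$n_layers,
                        eps_background = cfg$dielectric$eps_background,
                        debye = do.call(water_debye_params,
                                        cfg$dielectric$water))
  stratified_reflectance(stack, freq)
}

# full one-sided reflectance, band-limited to the simulated frequency range:
# bins above cohort$config$cohort$sim_f_max_thz (where the reference pulse
# carries no energy) are set to zero rather than computed.
cohort_reflectance_onesided <- function(cohort, i, k) {
  f_all <- ref_freq_axis(cohort$reference)
  act <- which(f_all <= cohort$config$cohort$sim_f_max_thz)
  r <- complex(length(f_all))
  r[act] <- cohort_reflectance(cohort, i, k, freq = f_all[act])
  r
}

#' Synthesize the trace grid of one frame
#'
#' Builds the layer stack for the sample's hydration state at the frame,
#' computes the stratified reflectance (band-limited to the simulated
#' frequency range), and synthesizes the angular grid of noisy pixel traces
#' with a deterministic per-frame seed.
#'
#' @param cohort a [generate_cohort()] object
#' @param i sample index
#' @param k frame index
#' @return numeric matrix `[n_samples_per_trace x n_pixels]`
#' @export
synthesize_frame <- function(cohort, i, k) {
  stopifnot(inherits(cohort, "thz_cohort"))
  cfg <- cohort$config
  npx <- cfg$cohort$grid_size^2
  r <- cohort_reflectance_onesided(cohort, i, k)
  synthesize_trace(r, cohort$reference, noise_sd = cfg$cohort$noise_sd,
                   n_pixels = npx,
                   seed = frame_seed(cohort$samples$seed[i], k))
}

#' Band slope predicted directly from the reflectance model
#'
#' Least-squares slope of `|r(f)|` over the analysis band, computed from the
#' layer-stack model without synthesizing or processing any trace. Used as
#' the noiseless ground truth that the full pipeline must recover.
#'
#' @param cohort a `thz_cohort`
#' @param i sample index
#' @param k frame index
#' @param band a [slope_band()]
#' @return model slope (ps)
#' @export
model_band_slope <- function(cohort, i, k, band = NULL) {
  cfg <- cohort$config
  if (is.null(band)) band <- do.call(slope_band, cfg$signal$band)
  f_all <- ref_freq_axis(cohort$reference)
  idx <- which(f_all >= band$f_low & f_all <= band$f_high)
  f <- f_all[idx]
  r <- cohort_reflectance(cohort, i, k, freq = f)
  unname(stats::coef(stats::lm(Mod(r) ~ f))[2])
}

#' Stream a cohort through the signal-processing stage
#'
#' Synthesizes each frame's trace grid, processes it (high-pass, FFT,
#' deconvolution against the metallic-sphere reference, band slope) and
#' discards the traces, returning the per-pixel slope table.
#'
#' @param cohort a `thz_cohort`
#' @param verbose print per-sample progress
#' @return data.frame with columns `sample_id, frame_index, t_min, iop_mmHg,
#'   pixel_row, pixel_col, slope_ps` (pixel indices 0-based)
#' @export
process_cohort <- function(cohort, verbose = FALSE) {
  stopifnot(inherits(cohort, "thz_cohort"))
  cfg <- cohort$config
  g <- cfg$cohort$grid_size
  npx <- g^2
  nfr <- length(cohort$frame_times)
  ns <- nrow(cohort$samples)
  band <- do.call(slope_band, cfg$signal$band)
  px_row <- rep(0:(g - 1), each = g)
  px_col <- rep(0:(g - 1), times = g)
  out_slope <- matrix(NA_real_, npx * nfr, ns)
  pipe <- slope_pipeline(cohort$reference,
                         cutoff_thz = cfg$signal$hp_cutoff_thz,
                         regularization = cfg$signal$regularization,
                         band = band)
  for (i in seq_len(ns)) {
    if (verbose) message("processing sample ", cohort$samples$sample_id[i])
    # frames sharing a hydration state share their reflectance spectrum
    key <- match(cohort$hydration[i, ], unique(cohort$hydration[i, ]))
    r_cache <- vector("list", max(key))
    for (k in seq_len(nfr)) {
      if (is.null(r_cache[[key[k]]]))
        r_cache[[key[k]]] <- cohort_reflectance_onesided(cohort, i, k)
      traces <- synthesize_trace(r_cache[[key[k]]], cohort$reference,
                                 noise_sd = cfg$cohort$noise_sd,
                                 n_pixels = npx,
                                 seed = frame_seed(cohort$samples$seed[i], k))
      out_slope[((k - 1) * npx + 1):(k * npx), i] <- pipe(traces)
    }
  }
  prot_of <- cohort$protocols[as.character(cohort$samples$group_mmHg)]
  data.frame(
    sample_id = rep(cohort$samples$sample_id, each = npx * nfr),
    frame_index = rep(rep(seq_len(nfr) - 1L, each = npx), times = ns),
    t_min = rep(rep(cohort$frame_times, each = npx), times = ns),
    iop_mmHg = unlist(lapply(seq_len(ns), function(i)
      rep(protocol_iop(prot_of[[i]], cohort$frame_times), each = npx))),
    pixel_row = rep(px_row, times = nfr * ns),
    pixel_col = rep(px_col, times = nfr * ns),
    slope_ps = as.vector(out_slope),
    stringsAsFactors = FALSE)
}

#' Sample labels of a cohort
#' @param cohort a `thz_cohort`
#' @return data.frame `sample_id, group_mmHg, ecd_cells_per_mm2`
#' @export
cohort_labels <- function(cohort) {
  cohort$samples[, c("sample_id", "group_mmHg", "ecd_cells_per_mm2")]
}
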