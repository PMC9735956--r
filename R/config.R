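# Run configuration: defaults, YAML loading, hashing.

#' Default pipeline configuration
#'
#' Every physical and statistical parameter of the pipeline, as a nested
#' list. A user YAML file (see [load_config()]) overrides any subset of
#' these keys.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    reference = list(radius_mm = 8.02, dt_ps = 0.0333, n = 2048L,
                     t0_ps = 10, sigma_ps = 0.25),
    dielectric = list(
      water = list(eps_inf = 3.48, delta_eps1 = 73.43, delta_eps2 = 1.45,
                   tau1_ps = 8.24, tau2_ps = 0.18),
      eps_background = 4.0),
    hydration = list(C0 = 0.75, C1_max = 0.95, D_um2_per_min = 500,
                     t_diff_min = 120, k_in = 0.004, k_out = 0.05),
    stack = list(depth_um = 500, n_layers = 20L),
    protocol = list(acclimation_min = 60, elevated_min = 240,
                    recovery_min = 240, base_iop = 15,
                    frame_interval_min = 4),
    cohort = list(group_sizes = c(`25` = 7L, `35` = 6L, `45` = 6L),
                  grid_size = 9L, noise_sd = 0.01, sim_f_max_thz = 4,
                  intact_weight = 0.5,
                  ecd_intact_mode = 5000, ecd_intact_sdlog = 0.15,
                  ecd_damaged_mode = 1600, ecd_damaged_sdlog = 0.2,
                  pump_midpoint = 3000, pump_scale = 300),
    signal = list(hp_cutoff_thz = 0.1, regularization = 1e-3,
                  band = list(f_low = 0.4, f_high = 0.8)),
    features = list(window_min = 30),
    classify = list(n_iterations = 300L, train_fraction = 0.7,
                    cost_grid = 10^seq(-3, 3), cv_folds = 5L,
                    stratify = TRUE))
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(override[[key]]) && is.list(base[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return full configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    # YAML 1.1 would read bare keys like `n` as booleans; only canonical
    # true/false are treated as logical, everything else stays a string
    strict_bool <- function(x)
      if (tolower(x) %in% c("true", "false")) tolower(x) == "true" else x
    user <- yaml::read_yaml(path, handlers = list("bool#yes" = strict_bool,
                                                  "bool#no" = strict_bool))
    if (!is.null(user$cohort$group_sizes))
      user$cohort$group_sizes <- unlist(user$cohort$group_sizes)
    cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every output file
#' so a run can be traced to its exact parameters.
#'
#' @param config configuration list
#' @return hex digest string
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 15), tmp)
  unname(tools::md5sum(tmp))
}
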