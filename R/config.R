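#' Default configuration schema
#'
#' Every numeric default used by the pipeline, grouped by stage. Values can
#' be overridden from a YAML file via [load_config()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  base <- wave_params()
  list(
    wave = unclass(base)[names(base)],
    presets = list(
      stiff = list(stiffness_gamma = 0.3, stiffness_onset = 0.5),
      compensated = list(stiffness_gamma = 0.3, stiffness_onset = 0.5,
                         standing_amp_rad = base$standing_amp_rad * 1.8,
                         standing_peak_pos = 0.35)),
    propulsion = unclass(propulsion_config()),
    model_compare = list(n_noise_reps = 20, jitter_cv = 0.1,
                         duration_s = 2, fps = 100),
    arena = list(width_mm = 300, height_mm = 100,
                 stream_speed_label = "medium", centre_band_frac = 1 / 3,
                 pull = 1.5, step_sd_wt = 25, step_sd_mut = 60,
                 duration_s = 30, fps = 10),
    video = list(cruise_fps = 200, cruise_duration_s = 30,
                 escape_fps = 936, escape_duration_s = 5,
                 px_per_mm = 5, bg_noise_sd = 8),
    tracking = list(threshold_method = "automatic", polarity = "dark-fish",
                    min_blob_px = 50, n_midline_points = 51,
                    smoothing_window = 5),
    features = list(rostral_window = c(0, 1 / 3),
                    caudal_window = c(2 / 3, 1),
                    heading_window = 5, occupancy_bins = c(30, 10)),
    ephys = list(fs = 25000, band_low_hz = 300, band_high_hz = 500,
                 notch_hz = 50, notch_q = 10, k_mad = 5,
                 refractory_s = 0.002,
                 psth_window = c(-0.1, 0.3), psth_bin_s = 0.01),
    morphometry = list(threshold = "otsu", min_area_px = 5, um_per_px = 1),
    stats = list(n_resamples = 200000, statistic = "median_diff",
                 bootstrap_level = 95, n_boot = 1000)
  )
}

# Range/type checks for user-supplied configuration values. Each rule:
# path, test function, message.
config_rules <- function() {
  pos <- function(v) is.numeric(v) && all(v > 0)
  frac <- function(v) is.numeric(v) && all(v >= 0 & v <= 1)
  list(
    list(c("wave", "stiffness_gamma"), frac, "must lie in [0, 1]"),
    list(c("wave", "stiffness_onset"), frac, "must lie in [0, 1]"),
    list(c("wave", "standing_peak_pos"), frac, "must lie in [0, 1]"),
    list(c("wave", "freq_hz"), pos, "must be > 0"),
    list(c("wave", "body_length_mm"), pos, "must be > 0"),
    list(c("wave", "wavelength_bl"), pos, "must be > 0"),
    list(c("propulsion", "drag_coeff"), pos, "must be > 0"),
    list(c("propulsion", "water_density"), pos, "must be > 0"),
    list(c("arena", "centre_band_frac"),
         function(v) is.numeric(v) && v > 0 && v <= 1,
         "must lie in (0, 1]"),
    list(c("ephys", "fs"), function(v) is.numeric(v) && v > 1000,
         "must exceed 1 kHz"),
    list(c("stats", "n_resamples"), pos, "must be > 0")
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [default_config()], and validates
#' types and ranges. Every offending key is reported in a single error. An
#' empty file yields all defaults; saving and re-loading is idempotent.
#'
#' @param path YAML file path (must exist).
#' @return Validated configuration list (class \code{finwave_config}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- modify_list_deep(default_config(), user)
  errs <- character(0)
  for (rule in config_rules()) {
    v <- cfg[[rule[[1]]]]
    if (!is.null(v) && !rule[[2]](v))
      errs <- c(errs, paste0(paste(rule[[1]], collapse = "."), ": ",
                             rule[[3]], " (got ",
                             paste(format(v), collapse = ", "), ")"))
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  structure(cfg, class = "finwave_config")
}

#' Save a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path, precision = 15)
  invisible(path)
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

config_wave_params <- function(cfg, preset = NULL) {
  w <- cfg$wave
  if (!is.null(preset) && preset != "flexible" && preset != "wildtype")
    w <- modify_list_deep(w, cfg$presets[[preset]])
  do.call(wave_params, w)
}

config_track_config <- function(cfg) do.call(track_config, cfg$tracking)

config_propulsion <- function(cfg) do.call(propulsion_config, cfg$propulsion)
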