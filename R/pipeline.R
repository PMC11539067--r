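#' Run a named pipeline stage and write its artifacts
#'
#' Config-driven orchestration binding the modules into reproducible runs.
#' Each invocation writes its outputs under \code{out_dir} together with a
#' JSON manifest (command, seed, configuration hash, package version,
#' output file hashes) so runs with the same seed and configuration are
#' byte-reproducible.
#'
#' Commands:
#' \describe{
#'   \item{simulate-arena}{wildtype + mutant arena trajectories (CSV).}
#'   \item{simulate-ephys}{a field-potential trace with ground truth
#'     (CSV + JSON).}
#'   \item{model}{steady-speed comparison across the three wave presets
#'     (\code{speeds.csv}).}
#'   \item{reproduce-compensation}{alias of \code{model} plus the compensation
#'     grid search (\code{compensation.csv}).}
#'   \item{stats}{permutation tests over a tidy feature table
#'     (\code{--table} in \code{args}).}
#' }
#'
#' @param command Stage name (see Details).
#' @param config A \code{finwave_config} (or path to one).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for all randomness in the stage.
#' @param args Optional named list of stage-specific inputs (e.g.
#'   \code{table} for \code{stats}).
#' @return Invisibly, a list of written file paths (including the
#'   manifest).
#' @export
run_pipeline <- function(command = c("simulate-arena", "simulate-ephys",
                                     "model", "reproduce-compensation", "stats"),
                         config = NULL, out_dir = ".", seed = 1,
                         args = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- load_config(config)
  if (is.null(config)) config <- structure(default_config(),
                                           class = "finwave_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  stage_error <- function(e) stop("[", command, "] ", conditionMessage(e),
                                  call. = FALSE)
  tryCatch({
    if (command %in% c("model", "reproduce-compensation")) {
      presets <- list(flexible = config_wave_params(config, "flexible"),
                      stiff = config_wave_params(config, "stiff"),
                      compensated = config_wave_params(config, "compensated"))
      mc <- config$model_compare
      tab <- compare_conditions(presets, config_propulsion(config),
                                n_noise_reps = mc$n_noise_reps,
                                jitter_cv = mc$jitter_cv, seed = seed,
                                duration_s = mc$duration_s, fps = mc$fps)
      p <- file.path(out_dir, "speeds.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      paths <- c(paths, p)
      if (command == "reproduce-compensation") {
        cs <- compensation_search(cfg = config_propulsion(config))
        p2 <- file.path(out_dir, "compensation.csv")
        utils::write.csv(cs$grid, p2, row.names = FALSE)
        paths <- c(paths, p2)
      }
    } else if (command == "simulate-arena") {
      spec <- do.call(arena_spec,
                      config$arena[c("width_mm", "height_mm",
                                     "stream_speed_label",
                                     "centre_band_frac")])
      a <- config$arena
      for (preset in c("wildtype", "mutant")) {
        tr <- simulate_arena_track(spec, preset, a$duration_s, a$fps,
                                   pull = a$pull, step_sd_wt = a$step_sd_wt,
                                   step_sd_mut = a$step_sd_mut,
                                   seed = seed + (preset == "mutant"))
        p <- file.path(out_dir, paste0("trajectory_", preset, ".csv"))
        utils::write.csv(as.data.frame(tr), p, row.names = FALSE)
        paths <- c(paths, p)
      }
    } else if (command == "simulate-ephys") {
      e <- config$ephys
      set.seed(seed)
      n_lg <- 8; n_sm <- 12
      tr <- simulate_field_potential(
        large_times = sort(stats::runif(n_lg, 0.95, 1.15)),
        small_times = sort(stats::runif(n_sm, 0.2, 1.8)),
        fs = e$fs, stim_time_s = 1, seed = seed)
      p <- file.path(out_dir, "field_potential.csv")
      write_ephys_csv(tr, p)
      gt <- attr(tr, "ground_truth")
      pj <- file.path(out_dir, "field_potential_truth.json")
      jsonlite::write_json(gt, pj, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p, pj)
    } else if (command == "stats") {
      if (is.null(args$table)) stop("missing input: args$table")
      tab <- if (is.character(args$table)) {
        if (!file.exists(args$table))
          stop("missing input file: ", args$table)
        utils::read.csv(args$table)
      } else args$table
      res <- feature_permutation_table(
        tab, statistic = config$stats$statistic,
        n_resamples = config$stats$n_resamples, seed = seed)
      p <- file.path(out_dir, "permutation_tests.csv")
      utils::write.csv(res, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }, error = stage_error)
  manifest <- list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("finwave")),
    config_hash = config_hash(config),
    outputs = lapply(stats::setNames(paths, basename(paths)),
                     function(p) unname(tools::md5sum(p))),
    timestamp = format(Sys.time(), tz = "UTC"))
  mp <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  invisible(c(paths, mp))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a frame stack as individual image files
#'
#' @param stack A \code{frame_stack}.
#' @param dir Output directory.
#' @param format \code{"tiff"} or \code{"png"} (requires the corresponding
#'   package).
#' @return Paths written, invisibly.
#' @export
write_frame_stack <- function(stack, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pkg <- if (format == "tiff") "tiff" else "png"
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required to write ", format, " frames")
  paths <- vapply(seq_along(stack$frames), function(i) {
    p <- file.path(dir, sprintf("frame_%05d.%s", i, format))
    img <- stack$frames[[i]] / 255
    if (format == "tiff") tiff::writeTIFF(img, p) else png::writePNG(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of grayscale frames into a list of matrices
#'
#' @param dir Directory of \code{.tif}/\code{.tiff}/\code{.png} files
#'   (sorted by name).
#' @return List of integer matrices (0-255).
#' @export
read_frame_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(tiff?|png)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stop("no frame images found in ", dir)
  lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' required")
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' required")
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
}
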