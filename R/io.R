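## File formats: point-track CSV with YAML sidecar, multi-page TIFF movies,
## run configuration, and provenance blocks. The on-disk frame column is
## 0-based (matching the acquisition software convention); in-memory R
## objects use 1-based indices throughout, and the readers/writers convert.

#' Write a body point track as CSV plus YAML sidecar
#'
#' Columns: `frame` (0-based), `t_ms`, then `x1,y1,...,x11,y11`. Missing
#' points are written as NaN. The sidecar (`<path>.yaml`) records
#' `frame_rate`, `stimulus_time_ms` and `pixel_scale`.
#'
#' @param track A `body_point_track`.
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_pointtrack_csv <- function(track, path) {
  n <- dim(track$points)[1]
  df <- data.frame(frame = seq_len(n) - 1L,
                   t_ms = (seq_len(n) - 1) / track$frame_rate * 1000)
  fmt <- function(x) {                  # 17 significant digits: lossless
    out <- formatC(x, digits = 17, format = "g")
    out[is.nan(x)] <- "NaN"
    out
  }
  for (j in seq_len(11)) {
    df[[paste0("x", j)]] <- fmt(track$points[, j, 1])
    df[[paste0("y", j)]] <- fmt(track$points[, j, 2])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(frame_rate = track$frame_rate,
               stimulus_time_ms = (track$stimulus_frame - 1) /
                 track$frame_rate * 1000,
               pixel_scale = track$pixel_scale)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a body point track from CSV plus YAML sidecar
#'
#' @param path CSV path written by [write_pointtrack_csv()] (sidecar
#'   expected at `<path>.yaml`).
#' @return A `body_point_track`.
#' @export
read_pointtrack_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side_path <- paste0(path, ".yaml")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  df <- read.csv(path)
  cols <- c("frame", "t_ms",
            as.vector(rbind(paste0("x", 1:11), paste0("y", 1:11))))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("point-track CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(diff(df$frame) != 1))
    stop("non-monotone frame index at row ",
         min(which(diff(df$frame) != 1)) + 1)
  side <- yaml::read_yaml(side_path)
  n <- nrow(df)
  pts <- array(NA_real_, dim = c(n, 11, 2))
  for (j in seq_len(11)) {
    pts[, j, 1] <- df[[paste0("x", j)]]
    pts[, j, 2] <- df[[paste0("y", j)]]
  }
  structure(list(
    points = pts, frame_rate = side$frame_rate,
    stimulus_frame = floor(side$stimulus_time_ms / 1000 *
                             side$frame_rate) + 1L,
    pixel_scale = if (is.null(side$pixel_scale)) 1 else side$pixel_scale),
    class = "body_point_track")
}

#' Write a channel movie as multi-page TIFF
#'
#' One 32-bit float page per frame. Intensities are stored as-is (the
#' generators produce unit-scale images).
#'
#' @param movie A `channel_movie`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(t) movie$frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(frame_rate = movie$frame_rate,
               channel_label = movie$channel_label,
               stimulus_frame0 = movie$stimulus_frame - 1L)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a channel movie from multi-page TIFF
#'
#' @param path TIFF path written by [write_movie_tiff()] (sidecar at
#'   `<path>.yaml`).
#' @return A `channel_movie`.
#' @export
read_movie_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  side_path <- paste0(path, ".yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else
    list(frame_rate = NA_real_, channel_label = NA_character_,
         stimulus_frame0 = NA_integer_)
  structure(list(frames = frames, frame_rate = side$frame_rate,
                 channel_label = side$channel_label,
                 stimulus_frame = side$stimulus_frame0 + 1L),
            class = "channel_movie")
}

#' Full run configuration with study defaults
#'
#' Collects every tunable of the pipeline, defaulting to the printed
#' acquisition and analysis constants of the emulated study: 650 frames/s
#' video with the stimulus 200 ms into a 1-s recording, 1 degree/frame
#' motion threshold, 10-frame morphological closing, 30-ms latency and
#' 60-degree C-bend inclusion criteria, 10-frame baselines, and 5/3-point
#' response windows with 4/1-frame gaps for the pressure and tail-free
#' imaging protocols respectively.
#'
#' @param ... Overrides of any default (unknown names are rejected).
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    frame_rate = 650, stimulus_time = 200,
    median_kernel = 5, spline_lambda = 1e-9, spline_lambda_vel = 1e-8,
    motion_threshold = 1, closing_block = 10, min_bout_frames = 10,
    peak_delta = 10, onset_threshold = 2,
    latency_max_ms = 30, cbend_min_deg = 60,
    corr_threshold = 0.7, search_radius = 20,
    n_baseline = 10, n_pre = 5, n_post = 5, gap = 4,
    bg_roi = c(1, 1, 8, 8),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected by name; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(default_config, vals)
}

#' Save a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a provenance block for a pipeline run
#'
#' Records the package version, the seed, and an MD5 hash of the serialized
#' configuration so deterministic stages can be reproduced bit-identically.
#'
#' @param config A `run_config`.
#' @param seed Seed used for the run.
#' @param dir Output directory (`provenance.yaml` is written there).
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(config, seed, dir) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  prov <- list(
    package = "escapekin",
    version = as.character(utils::packageVersion("escapekin")),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(prov, path)
  invisible(path)
}

#' Summarize a batch of tracks into a one-row-per-trial kinematics table
#'
#' Runs [run_kinematics_pipeline()] on each track and collects all
#' kinematic fields plus the rejection reason.
#'
#' @param tracks List of `body_point_track` objects (names become trial
#'   identifiers).
#' @param config From [kinematics_config()].
#' @return Data frame with one row per track.
#' @export
kinematics_table <- function(tracks, config = kinematics_config()) {
  rows <- lapply(seq_along(tracks), function(i) {
    a <- run_kinematics_pipeline(tracks[[i]], config)
    k <- a$kinematics
    data.frame(
      trial = if (!is.null(names(tracks))) names(tracks)[i] else
        as.character(i),
      accepted = a$accepted,
      reject_reason = if (a$accepted) NA_character_ else a$reject_reason,
      latency_ms = if (a$accepted) k$latency_ms else NA_real_,
      duration_ms = if (a$accepted) k$duration_ms else NA_real_,
      distance_mm = if (a$accepted) k$distance_mm else NA_real_,
      speed_mm_s = if (a$accepted) k$speed_mm_s else NA_real_,
      n_oscillations = if (a$accepted) k$n_oscillations else NA_real_,
      c_bend_amplitude = if (a$accepted) k$c_bend_amplitude else NA_real_,
      tbf_hz = if (a$accepted) k$tbf_hz else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
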