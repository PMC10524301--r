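#' Widefield movie container
#'
#' @param data numeric array `time x rows x cols`.
#' @param frame_rate frames per second, > 0.
#' @param channel `"signal"` or `"isosbestic"`.
#' @return object of class `widefield_movie`.
#' @export
widefield_movie <- function(data, frame_rate, channel = "signal") {
  stopifnot(length(dim(data)) == 3L, frame_rate > 0)
  structure(list(data = data, frame_rate = frame_rate, channel = channel),
            class = "widefield_movie")
}

#' @export
dim.widefield_movie <- function(x) dim(x$data)

#' @export
print.widefield_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<widefield_movie> %d frames of %dx%d px, %.3g Hz, channel %s\n",
              d[1], d[2], d[3], x$frame_rate, x$channel))
  invisible(x)
}

#' Read / write widefield movies as multi-page TIFF
#'
#' Round trips are lossless (pixel values and frame count) since frames are
#' stored as 64-bit floats. Frame rate and channel tag travel in a JSON
#' side-car `<path>.json`.
#'
#' @param movie a `widefield_movie`.
#' @param path TIFF path.
#' @return `read_movie` returns a `widefield_movie`; `write_movie` returns
#'   `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "widefield_movie"))
  write_tiff_stack(movie$data, path)
  jsonlite::write_json(
    list(frame_rate = movie$frame_rate, channel = movie$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param frame_rate,channel used when no side-car is present.
#' @export
read_movie <- function(path, frame_rate = NULL, channel = "signal") {
  if (!file.exists(path)) stop_param("movie file does not exist: %s", path)
  data <- read_tiff_stack(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    frame_rate <- meta$frame_rate
    channel <- meta$channel
  } else if (is.null(frame_rate)) {
    stop_param("no side-car %s and no frame_rate given", side)
  }
  widefield_movie(data, frame_rate, channel)
}

TRIAL_COLUMNS <- c("trial_id", "stim_type", "condition", "onset_s",
                   "offset_s", "link_id", "patch_index")
STIM_TYPES <- c("patch", "dot", "grating", "coupled", "uncoupled")

#' Validate a trial table
#'
#' @param trials data.frame with at least the columns `trial_id`,
#'   `stim_type`, `condition`, `onset_s`, `offset_s`, `link_id`,
#'   `patch_index`.
#' @return the validated table (typed).
#' @export
validate_trial_table <- function(trials) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing)) {
    stop_param("trial table missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(trials$stim_type), STIM_TYPES)
  if (length(bad)) {
    stop_param("unknown stim_type %s (allowed: %s)",
               paste(bad, collapse = ", "), paste(STIM_TYPES, collapse = ", "))
  }
  if (any(trials$offset_s <= trials$onset_s)) {
    stop_param("trial table has offset_s <= onset_s for trial(s) %s",
               paste(trials$trial_id[trials$offset_s <= trials$onset_s],
                     collapse = ", "))
  }
  trials$trial_id <- as.integer(trials$trial_id)
  trials$onset_s <- as.numeric(trials$onset_s)
  trials$offset_s <- as.numeric(trials$offset_s)
  trials
}

#' Read / write a trial table CSV
#'
#' @param path CSV path.
#' @return validated trial table data.frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop_param("trial table does not exist: %s", path)
  validate_trial_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_table
#' @param trials trial table.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(validate_trial_table(trials), path, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' All analysis constants in one place. Values mirror the experimental
#' protocol: the 25% visuo-motor-divergence threshold, 2-SD responsiveness
#' rule, top-50% pixel selection for moving dots, 0.5 s post-offset response
#' window, 1 s pre-onset baseline, 1.7 s time-course window, 50 ms PSTH bin,
#' 10 depth bins, alpha = 0.05, and the 0.5 patch-map binarisation fraction
#' (the delineation threshold is a package choice, config-exposed).
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    vmd_threshold = 0.25,
    responsiveness_sd = 2,
    top_pixel_fraction = 0.5,
    baseline_window_s = 1.0,
    response_pad_s = 0.5,
    timecourse_window_s = 1.7,
    psth_bin_s = 0.05,
    n_depth_bins = 10L,
    alpha = 0.05,
    delineation_threshold = 0.5,
    registration_min_cor = 0.2,
    fraction_on_corrected = TRUE
  )
}

#' Load an analysis configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#' An empty file (or `{}`) yields the full defaults.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_param("config file does not exist: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop_param("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, as.list(user))
}

#' Assemble and validate a session bundle
#'
#' A bundle ties together the on-disk pieces of one session: movie paths per
#' channel, trial table, optional traces and masks, and metadata.
#'
#' @param signal_path,trial_path required file paths.
#' @param isosbestic_path,running_path,stimulus_path,eye_path,mask_path
#'   optional file paths.
#' @param frame_rate acquisition rate (Hz).
#' @param hemisphere hemisphere tag.
#' @return validated `session_bundle` list.
#' @export
session_bundle <- function(signal_path, trial_path, isosbestic_path = NULL,
                           running_path = NULL, stimulus_path = NULL,
                           eye_path = NULL, mask_path = NULL,
                           frame_rate = 10, hemisphere = "left") {
  paths <- c(signal = signal_path, trials = trial_path,
             isosbestic = isosbestic_path, running = running_path,
             stimulus = stimulus_path, eye = eye_path, mask = mask_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_param("bundle references missing file(s): %s",
               paste(missing, collapse = ", "))
  }
  b <- list(paths = as.list(paths), frame_rate = frame_rate,
            hemisphere = hemisphere)
  sig <- read_movie(signal_path, frame_rate = frame_rate)
  trials <- read_trial_table(trial_path)
  if (max(trials$offset_s) * frame_rate > dim(sig)[1]) {
    stop_param("trial table extends past the end of the movie")
  }
  if (!is.null(isosbestic_path)) {
    iso <- read_movie(isosbestic_path, frame_rate = frame_rate)
    if (!identical(dim(iso), dim(sig))) {
      stop_param("signal and isosbestic channels differ in shape")
    }
  }
  structure(b, class = "session_bundle")
}

# one structured provenance line per pipeline stage
log_stage <- function(stage, ..., file = "") {
  msg <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste(sprintf("%s=%s", names(list(...)), list(...)),
                       collapse = " "))
  cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}
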