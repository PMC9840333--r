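#' Write a recording as flat binary + JSON sidecar
#'
#' Samples are stored as little-endian float32, channel-major (each channel's
#' samples consecutive); the sidecar `<basename>.json` records channel names,
#' rate, sample count, events and provenance.
#'
#' @param recording an `eeg_recording`.
#' @param basename path without extension; `.f32` and `.json` are appended.
#' @return invisibly, the two paths written.
#' @export
write_recording <- function(recording, basename) {
  stopifnot(inherits(recording, "eeg_recording"))
  bin <- paste0(basename, ".f32")
  side <- paste0(basename, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 4, endian = "little")
  meta <- list(
    container = "chirpent-recording-v1",
    dtype = "float32", byte_order = "little", layout = "channel_major",
    channels = recording$channel_names, rate = recording$rate,
    n_samples = ncol(recording$data),
    events = recording$events, provenance = recording$provenance)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, side))
}

#' Read a recording written by [write_recording()]
#'
#' @param basename path without extension.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(basename) {
  side <- paste0(basename, ".json")
  bin <- paste0(basename, ".f32")
  if (!file.exists(side) || !file.exists(bin)) {
    stopf("no recording container at '%s' (.json/.f32 pair missing)", basename)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$container, "chirpent-recording-v1")) {
    stopf("'%s' is not a chirpent recording sidecar", side)
  }
  n <- meta$n_samples * length(meta$channels)
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  data <- matrix(x, nrow = length(meta$channels), byrow = TRUE)
  ev <- meta$events
  if (is.null(ev) || !length(ev)) {
    ev <- data.frame(time_s = numeric(), label = character())
  }
  new_recording(data, meta$channels, meta$rate, events = as.data.frame(ev),
                provenance = unlist(meta$provenance) %||% character())
}

#' Export a stimulus as a 16-bit PCM WAV file
#'
#' @param stimulus a `chirp_stimulus`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_wav <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "chirp_stimulus"))
  pcm <- as.integer(round(pmax(-1, pmin(1, stimulus$samples)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(stimulus$rate), con, size = 4, endian = "little")
  writeBin(as.integer(stimulus$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write / read a trial schedule as CSV
#'
#' Columns: `onset_s`, `isi_ms` (the gap following each stimulus; NA for the
#' last trial).
#'
#' @param schedule a `trial_schedule`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  utils::write.csv(
    data.frame(onset_s = schedule$onsets,
               isi_ms = c(schedule$isi_ms, NA_real_)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  onsets <- df$onset_s
  structure(
    list(onsets = onsets, isi_ms = df$isi_ms[-nrow(df)],
         n_trials = length(onsets),
         isi_bounds_ms = range(df$isi_ms, na.rm = TRUE),
         stimulus_duration_s = NA_real_, seed = NA_integer_),
    class = "trial_schedule"
  )
}

#' Write a time-frequency map as long-format CSV
#'
#' Columns: `roi`, `freq_hz`, `time_s`, `value` (NA for invalid cells).
#'
#' @param map a `tf_map`.
#' @param path CSV path.
#' @param roi label recorded in the `roi` column.
#' @return invisibly, `path`.
#' @export
write_map_csv <- function(map, path, roi = "ROI") {
  stopifnot(inherits(map, "tf_map"))
  grid <- expand.grid(freq_hz = map$freqs_hz, time_s = map$times_s)
  grid$roi <- roi
  grid$value <- as.vector(map$values)
  utils::write.csv(grid[, c("roi", "freq_hz", "time_s", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a time-frequency map as flat binary + JSON metadata
#'
#' @param map a `tf_map`.
#' @param basename path without extension.
#' @return invisibly, the paths written.
#' @export
write_map_bin <- function(map, basename) {
  stopifnot(inherits(map, "tf_map"))
  bin <- paste0(basename, ".f32")
  con <- file(bin, "wb")
  on.exit(close(con))
  vals <- as.numeric(map$values)          # column-major freqs x times
  vals[is.na(vals)] <- NaN
  writeBin(vals, con, size = 4, endian = "little")
  meta <- list(container = "chirpent-map-v1", measure = map$measure,
               dtype = "float32", byte_order = "little",
               layout = "column_major_freq_by_time",
               freqs_hz = map$freqs_hz, times_s = map$times_s,
               n_trials = map$n_trials,
               baseline_window_s = map$baseline_window_s)
  jsonlite::write_json(meta, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(bin, paste0(basename, ".json")))
}

#' Write band summaries as CSV
#'
#' @param summaries data.frame from [extract_all()].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_band_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
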