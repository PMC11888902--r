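#' BCG recording container
#'
#' A `bcg_recording` holds a uniformly sampled multi-channel
#' ballistocardiogram: a time vector, a sample-by-channel matrix of sensor
#' values (arbitrary pressure units) and a class label.
#'
#' @param channels numeric matrix, one row per sample, one column per sensor
#'   channel.
#' @param sampling_rate_hz sampling rate in Hz (strictly positive).
#' @param label one of `"hypertensive"`, `"normotensive"`, `"unlabeled"`.
#' @param subject_id identifier of the source recording.
#' @param channel_names optional character vector of channel names; defaults
#'   to `ch1`, `ch2`, ...
#' @param meta optional list of extra metadata (e.g. ground-truth beat times
#'   from the synthetic generator).
#'
#' @return An object of class `bcg_recording` with fields `subject_id`,
#'   `label`, `sampling_rate_hz`, `time_s`, `channels`, `channel_names`,
#'   `meta`.
#' @export
bcg_recording <- function(channels, sampling_rate_hz, label = "unlabeled",
                          subject_id = "rec", channel_names = NULL,
                          meta = list()) {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (!label %in% c(BCG_CLASSES, "unlabeled"))
    stop_bcg("label must be 'hypertensive', 'normotensive' or 'unlabeled'")
  n <- nrow(channels)
  if (n < 1L) stop_bcg("recording must contain at least one sample")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(channels)))
  if (length(channel_names) != ncol(channels))
    stop_bcg("channel_names length must match channel count")
  colnames(channels) <- channel_names
  structure(
    list(
      subject_id = as.character(subject_id),
      label = label,
      sampling_rate_hz = sampling_rate_hz,
      time_s = (seq_len(n) - 1) / sampling_rate_hz,
      channels = channels,
      channel_names = channel_names,
      meta = meta
    ),
    class = "bcg_recording"
  )
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf(
    "<bcg_recording> %s [%s]: %d samples x %d channels @ %g Hz (%.1f s)\n",
    x$subject_id, x$label, nrow(x$channels), ncol(x$channels),
    x$sampling_rate_hz, nrow(x$channels) / x$sampling_rate_hz
  ))
  invisible(x)
}

# replace the channel matrix, keeping all other fields
set_channels <- function(rec, channels) {
  channels <- as.matrix(channels)
  colnames(channels) <- rec$channel_names
  rec$channels <- channels
  rec$time_s <- (seq_len(nrow(channels)) - 1) / rec$sampling_rate_hz
  rec
}

validate_recording <- function(rec) {
  if (!inherits(rec, "bcg_recording")) stop_bcg("expected a bcg_recording")
  dt <- diff(rec$time_s)
  step <- 1 / rec$sampling_rate_hz
  if (length(dt) && max(abs(dt - step)) > 1e-9)
    stop_bcg("recording is not uniformly sampled at its stated rate")
  if (length(rec$time_s) != nrow(rec$channels))
    stop_bcg("time vector and channel matrix disagree in length")
  invisible(rec)
}

#' Write / read a recording as delimited text
#'
#' Recordings are stored as CSV with header `time,<channel names...>`, one
#' row per sample. The class label is encoded in the filename
#' (`<subject>_<label>.csv`) and duplicated, with the sampling rate, in a
#' JSON sidecar (`<subject>_<label>.json`).
#'
#' @param rec a [bcg_recording()].
#' @param dir directory to write into (created if missing).
#' @return `write_recording` returns the CSV path invisibly;
#'   `read_recording` returns a [bcg_recording()].
#' @export
write_recording <- function(rec, dir) {
  validate_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", rec$subject_id, rec$label)
  csv <- file.path(dir, paste0(stem, ".csv"))
  df <- data.frame(time = rec$time_s, rec$channels, check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE)
  sidecar <- list(
    subject_id = rec$subject_id,
    label = rec$label,
    sampling_rate_hz = rec$sampling_rate_hz,
    channel_names = rec$channel_names
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' @param path path to a recording CSV written by [write_recording()].
#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "time"))
    stop_bcg("first column of a recording CSV must be 'time'")
  sidecar_path <- sub("\\.csv$", ".json", path)
  stem <- sub("\\.csv$", "", basename(path))
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    label <- side$label
    subject <- side$subject_id
    fs <- side$sampling_rate_hz
  } else {
    # fall back to filename convention <subject>_<label>.csv
    label <- sub("^.*_", "", stem)
    if (!label %in% c(BCG_CLASSES, "unlabeled")) label <- "unlabeled"
    subject <- sub(sprintf("_%s$", label), "", stem)
    dt <- diff(df$time)
    fs <- 1 / stats::median(dt)
  }
  bcg_recording(
    channels = as.matrix(df[, -1, drop = FALSE]),
    sampling_rate_hz = fs, label = label, subject_id = subject,
    channel_names = names(df)[-1]
  )
}
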