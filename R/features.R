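FEATURE_STATS <- c("mean", "sd", "median", "max", "min", "range",
                   "q1", "q3", "iqr", "kurtosis", "skewness")

#' Split a recording into fixed-length windows
#'
#' Consecutive non-overlapping windows from sample 0; a trailing remainder
#' shorter than one full window is dropped. At 100 Hz a 30-s window holds
#' exactly 3,000 samples. Each segment inherits the recording's label.
#'
#' @param rec a [bcg_recording()].
#' @param window_s window length in seconds (default 30).
#' @param overlap_s overlap between consecutive windows in seconds
#'   (default 0, i.e. non-overlapping).
#' @return A list of `bcg_segment` objects (possibly empty), each with
#'   fields `source_id`, `label`, `start_sample` (0-based), `samples`,
#'   `sampling_rate_hz`, `segment_id`.
#' @export
segment_recording <- function(rec, window_s = 30, overlap_s = 0) {
  validate_recording(rec)
  assert_scalar_num(window_s, "window_s", positive = TRUE)
  if (overlap_s < 0 || overlap_s >= window_s)
    stop_bcg("overlap_s must lie in [0, window_s)")
  fs <- rec$sampling_rate_hz
  win <- floor(window_s * fs)
  step <- win - floor(overlap_s * fs)
  n <- nrow(rec$channels)
  if (n < win) return(list())
  starts <- seq(0L, n - win, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    structure(list(
      source_id = rec$subject_id,
      label = rec$label,
      start_sample = as.integer(s),
      samples = rec$channels[(s + 1L):(s + win), , drop = FALSE],
      sampling_rate_hz = fs,
      segment_id = sprintf("%s_%03d_%s", rec$subject_id, i, rec$label)
    ), class = "bcg_segment")
  })
}

# Population (divisor-n) central moments; the moment conventions used for
# all distribution-shape features.
central_moment <- function(x, k) mean((x - mean(x))^k)

channel_stats <- function(x) {
  m2 <- central_moment(x, 2)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  # degenerate (constant) channel: shape statistics defined as 0
  skew <- if (m2 > 0) central_moment(x, 3) / m2^1.5 else 0
  kurt <- if (m2 > 0) central_moment(x, 4) / m2^2 - 3 else 0
  c(mean = mean(x), sd = sqrt(m2), median = qs[2],
    max = max(x), min = min(x), range = max(x) - min(x),
    q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
    kurtosis = kurt, skewness = skew)
}

#' Extract the 11 summary statistics of a segment
#'
#' Per channel: mean, population standard deviation, median, maximum,
#' minimum, range, first and third quartile (linear-interpolation
#' quantiles), interquartile range, excess kurtosis `m4/m2^2 - 3` and
#' Fisher-Pearson skewness `m3/m2^{3/2}`, with divisor-n central moments.
#' Constant channels get skewness = kurtosis = 0 by convention.
#'
#' @param seg a `bcg_segment` from [segment_recording()].
#' @return A named numeric vector of `n_channels * 11` features (named
#'   `<channel>_<stat>`), with attributes `label`, `source_id`,
#'   `start_sample`.
#' @export
extract_features <- function(seg) {
  if (!inherits(seg, "bcg_segment")) stop_bcg("expected a bcg_segment")
  if (nrow(seg$samples) == 0L) stop_bcg("empty segment")
  ch_names <- colnames(seg$samples) %||% paste0("ch", seq_len(ncol(seg$samples)))
  vals <- lapply(seq_len(ncol(seg$samples)), function(c) {
    v <- channel_stats(seg$samples[, c])
    names(v) <- paste(ch_names[c], FEATURE_STATS, sep = "_")
    v
  })
  out <- unlist(vals)
  attr(out, "label") <- seg$label
  attr(out, "source_id") <- seg$source_id
  attr(out, "start_sample") <- seg$start_sample
  out
}

#' Assemble the per-segment feature table
#'
#' @param segments a list of `bcg_segment`s with a consistent channel count.
#' @return A data frame, one row per segment in input order: the numeric
#'   feature columns (`<channel>_<stat>`), then `label` (hypertensive = 1,
#'   normotensive = 0), `source_id` and `start_sample`.
#' @export
build_feature_table <- function(segments) {
  if (length(segments) < 1L) stop_bcg("need at least one segment")
  ncs <- vapply(segments, function(s) ncol(s$samples), integer(1))
  if (length(unique(ncs)) != 1L)
    stop_bcg("segments have inconsistent channel counts")
  feats <- lapply(segments, extract_features)
  mat <- do.call(rbind, lapply(feats, as.numeric))
  colnames(mat) <- names(feats[[1]])
  df <- as.data.frame(mat)
  df$label <- vapply(segments, function(s) label_to_int(s$label), integer(1))
  df$source_id <- vapply(segments, function(s) s$source_id, character(1))
  df$start_sample <- vapply(segments, function(s) s$start_sample, integer(1))
  df
}

#' Numeric feature matrix of a feature table
#'
#' @param tbl a data frame from [build_feature_table()] (or any data frame
#'   whose non-feature columns are `label`, `source_id`, `start_sample`).
#' @return A numeric matrix of the feature columns only.
#' @export
feature_matrix <- function(tbl) {
  drop_cols <- intersect(c("label", "source_id", "start_sample"), names(tbl))
  as.matrix(tbl[, setdiff(names(tbl), drop_cols), drop = FALSE])
}

#' Standardise features with train-fitted parameters
#'
#' Columns are centred and scaled to zero mean and unit variance using the
#' training matrix only (population sd; a constant column's sd is treated
#' as 1). The same train-fitted parameters are applied to every additional
#' matrix, so no information leaks from test data.
#'
#' @param train numeric training matrix.
#' @param ... further matrices to transform with the train-fitted scaler.
#' @return A list with `train`, one transformed matrix per extra argument
#'   (named as passed, or `matrix2`, ... ), and `center`/`scale` vectors.
#' @export
standardize_features <- function(train, ...) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop_bcg("training matrix is empty")
  center <- colMeans(train)
  scale <- sqrt(colMeans(sweep(train, 2, center)^2))
  scale[scale == 0] <- 1
  tf <- function(m) sweep(sweep(as.matrix(m), 2, center), 2, scale, `/`)
  others <- list(...)
  if (length(others) && is.null(names(others)))
    names(others) <- paste0("matrix", seq_along(others) + 1L)
  c(list(train = tf(train)), lapply(others, tf),
    list(center = center, scale = scale))
}
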