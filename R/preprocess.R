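#' Butterworth filter specification
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward (zero-phase) filtering.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), cutoff_hz,
                        order = 4L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  assert_scalar_num(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (order < 1) stop_bcg("order must be >= 1")
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# A cutoff at or above Nyquist is unrealizable; clamp to 0.99*Nyquist with a
# warning (the stated 50 Hz low-pass equals Nyquist at 100 Hz sampling).
clamp_cutoff <- function(cutoff_hz, fs, clamp = TRUE) {
  nyq <- fs / 2
  if (cutoff_hz < nyq) return(cutoff_hz)
  if (!clamp)
    stop_bcg(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                     cutoff_hz, nyq))
  clamped <- 0.99 * nyq
  warning(sprintf("cutoff %g Hz >= Nyquist (%g Hz); clamped to %g Hz",
                  cutoff_hz, nyq, clamped), call. = FALSE)
  clamped
}

# zero-phase Butterworth on one channel, with odd-reflection padding to keep
# edge transients away from the data
filter_channel <- function(x, spec, fs) {
  cutoff <- clamp_cutoff(spec$cutoff_hz, fs)
  w <- cutoff / (fs / 2)
  bf <- signal::butter(spec$order, w,
                       type = if (spec$kind == "highpass") "high" else "low")
  n <- length(x)
  min_len <- 3L * (spec$order + 1L)
  if (n <= min_len)
    stop_bcg(sprintf("recording too short (%d samples) for the filter warm-up", n))
  pad <- min(n - 1L, as.integer(3 * fs))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  yp <- if (spec$zero_phase) signal::filtfilt(bf, xp)
        else as.numeric(signal::filter(bf, xp))
  yp[(pad + 1L):(pad + n)]
}

#' Apply a digital filter to every channel of a recording
#'
#' Each sensor channel is filtered independently with a Butterworth filter,
#' applied forward-backward by default so no phase lag is introduced. The
#' time column is untouched and output length equals input length.
#'
#' @param rec a [bcg_recording()].
#' @param spec a [filter_spec()].
#' @return The filtered recording.
#' @export
apply_filter <- function(rec, spec) {
  validate_recording(rec)
  if (!inherits(spec, "filter_spec")) stop_bcg("spec must be a filter_spec")
  out <- apply(rec$channels, 2, filter_channel, spec = spec,
               fs = rec$sampling_rate_hz)
  set_channels(rec, out)
}

#' Flag anomalous samples by the mean + k*sd rule
#'
#' Per channel, the threshold is `mean + k * sd` (population sd), computed
#' on the unmodified input; samples strictly above it are flagged. The rule
#' is one-sided: large negative excursions are not flagged.
#'
#' @param rec a [bcg_recording()].
#' @param k threshold multiplier (default 2).
#' @return A list of class `anomaly_mask` with a logical `flags` matrix,
#'   per-channel `threshold` and `k`.
#' @export
detect_anomalies <- function(rec, k = 2) {
  validate_recording(rec)
  if (nrow(rec$channels) < 2L) stop_bcg("need at least 2 samples per channel")
  mu <- colMeans(rec$channels)
  sdev <- sqrt(colMeans(sweep(rec$channels, 2, mu)^2))
  thr <- mu + k * sdev
  flags <- sweep(rec$channels, 2, thr, `>`)
  structure(list(flags = flags, threshold = thr, k = k),
            class = "anomaly_mask")
}

#' Remove flagged samples
#'
#' `mode = "interpolate"` (default) replaces flagged samples by linear
#' interpolation between the nearest unflagged neighbours (nearest-value
#' extension at the edges), preserving the uniform sampling grid that the
#' downstream filters require. `mode = "drop"` deletes flagged rows, which
#' breaks uniform sampling; such recordings are refused by later filter
#' stages.
#'
#' @param rec a [bcg_recording()].
#' @param mask an `anomaly_mask` from [detect_anomalies()].
#' @param mode `"interpolate"` or `"drop"`.
#' @return The cleaned recording (for `"drop"`, a plain data frame of the
#'   surviving rows since the result is no longer uniformly sampled).
#' @export
remove_anomalies <- function(rec, mask, mode = c("interpolate", "drop")) {
  mode <- match.arg(mode)
  validate_recording(rec)
  if (!identical(dim(mask$flags), dim(rec$channels)))
    stop_bcg("mask is not conformable with the recording")
  if (mode == "drop") {
    keep <- !apply(mask$flags, 1, any)
    if (!any(keep)) stop_bcg("all samples flagged")
    return(data.frame(time = rec$time_s[keep],
                      rec$channels[keep, , drop = FALSE],
                      check.names = FALSE))
  }
  ch <- rec$channels
  for (c in seq_len(ncol(ch))) {
    f <- mask$flags[, c]
    if (!any(f)) next
    if (all(f)) stop_bcg("all samples flagged in a channel")
    good <- which(!f)
    ch[f, c] <- stats::approx(good, ch[good, c], xout = which(f),
                              rule = 2)$y
  }
  set_channels(rec, ch)
}

#' Baseline correction
#'
#' Removes residual baseline wander with a 0.5 Hz high-pass Butterworth
#' filter (zero-phase, order 4 by default).
#'
#' @inheritParams apply_filter
#' @param cutoff_hz high-pass cutoff (default 0.5 Hz).
#' @param order filter order.
#' @return The baseline-corrected recording.
#' @export
baseline_correct <- function(rec, cutoff_hz = 0.5, order = 4L) {
  apply_filter(rec, filter_spec("highpass", cutoff_hz, order))
}

#' Min-max normalisation to `[0, 1]`
#'
#' Per channel, `x' = (x - min) / (max - min)`. A constant channel maps to
#' all zeros (declared convention).
#'
#' @param rec a [bcg_recording()].
#' @return The normalised recording.
#' @export
minmax_normalize <- function(rec) {
  validate_recording(rec)
  ch <- rec$channels
  for (c in seq_len(ncol(ch))) {
    rng <- range(ch[, c])
    ch[, c] <- if (rng[2] > rng[1]) (ch[, c] - rng[1]) / (rng[2] - rng[1]) else 0
  }
  set_channels(rec, ch)
}

#' The four-stage preprocessing chain
#'
#' Applies, in fixed order: high-pass 1 Hz, low-pass 50 Hz (clamped to
#' 0.99 x Nyquist when needed), anomaly detection/removal at mean + k*sd,
#' baseline high-pass 0.5 Hz, min-max normalisation to `[0, 1]`. The stage
#' list with its parameters is attached as the `stages` attribute.
#'
#' @param rec a [bcg_recording()].
#' @param hp_hz first-stage high-pass cutoff.
#' @param lp_hz low-pass cutoff (clamped if at/above Nyquist).
#' @param anomaly_k anomaly threshold multiplier.
#' @param anomaly_mode `"interpolate"` or `"drop"` (see [remove_anomalies()]).
#' @param baseline_hz baseline-correction high-pass cutoff.
#' @param order Butterworth order used by every filter stage.
#' @return The preprocessed recording, values in `[0, 1]`.
#' @export
preprocess_recording <- function(rec, hp_hz = 1, lp_hz = 50, anomaly_k = 2,
                                 anomaly_mode = "interpolate",
                                 baseline_hz = 0.5, order = 4L) {
  validate_recording(rec)
  out <- apply_filter(rec, filter_spec("highpass", hp_hz, order))
  out <- suppressWarnings(apply_filter(out, filter_spec("lowpass", lp_hz, order)))
  mask <- detect_anomalies(out, k = anomaly_k)
  out <- remove_anomalies(out, mask, mode = anomaly_mode)
  if (!inherits(out, "bcg_recording"))
    stop_bcg("anomaly mode 'drop' breaks uniform sampling; downstream filters refuse it")
  out <- baseline_correct(out, cutoff_hz = baseline_hz, order = order)
  out <- minmax_normalize(out)
  attr(out, "stages") <- list(
    list(stage = "highpass", cutoff_hz = hp_hz, order = order),
    list(stage = "lowpass", cutoff_hz = lp_hz, order = order,
         clamped_to = clamp_cutoff_quiet(lp_hz, rec$sampling_rate_hz)),
    list(stage = "anomaly", k = anomaly_k, mode = anomaly_mode,
         n_flagged = sum(mask$flags)),
    list(stage = "baseline", cutoff_hz = baseline_hz, order = order),
    list(stage = "minmax")
  )
  out
}

clamp_cutoff_quiet <- function(cutoff_hz, fs) {
  suppressWarnings(clamp_cutoff(cutoff_hz, fs))
}
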