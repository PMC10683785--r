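#' Onset-detection specification
#'
#' Perturbation onset is read from the platform accelerometer as the first
#' sustained burst of activity after each event marker: the earliest time in
#' the post-marker search window where the absolute deviation from the
#' pre-marker baseline mean exceeds `threshold_k` baseline standard
#' deviations for at least `min_consecutive_samples` consecutive samples.
#'
#' @param baseline_window_s Pre-marker window used to estimate accelerometer
#'   noise, seconds.
#' @param threshold_k Threshold in baseline standard deviations.
#' @param min_consecutive_samples Consecutive supra-threshold samples
#'   required to call a burst.
#' @param search_window_s Post-marker window in which the burst must occur.
#' @return A list of class `onset_detection_spec`.
#' @export
onset_detection_spec <- function(baseline_window_s = 1.0, threshold_k = 5,
                                 min_consecutive_samples = 3,
                                 search_window_s = 1.0) {
  stopifnot(baseline_window_s > 0, threshold_k > 0,
            min_consecutive_samples >= 1, search_window_s > 0)
  structure(list(baseline_window_s = baseline_window_s,
                 threshold_k = threshold_k,
                 min_consecutive_samples = as.integer(min_consecutive_samples),
                 search_window_s = search_window_s),
            class = "onset_detection_spec")
}

#' Detect perturbation onsets from the platform accelerometer
#'
#' @param acceleration Numeric vector of accelerometer samples (m/s^2).
#' @param marker_times_s Event-marker times in seconds from recording start
#'   (shared clock with the EEG).
#' @param spec An [onset_detection_spec].
#' @param sampling_rate Accelerometer sampling rate, Hz.
#' @return A tibble with one row per marker: `marker_time_s`,
#'   `onset_time_s` (NA when undetected), `detected`, and
#'   `degenerate_baseline` (TRUE when the baseline SD collapsed and the
#'   absolute fallback threshold of 0.05 x peak |acceleration| was used).
#'   Undetected events are flagged, never dropped.
#' @export
detect_onsets <- function(acceleration, marker_times_s, spec, sampling_rate) {
  stopifnot(inherits(spec, "onset_detection_spec"), sampling_rate > 0)
  n <- length(acceleration)
  dur <- n / sampling_rate
  if (any(marker_times_s < spec$baseline_window_s) ||
      any(marker_times_s + spec$search_window_s > dur)) {
    stop("marker baseline/search windows must lie within the recording")
  }
  m <- spec$min_consecutive_samples
  k <- length(marker_times_s)
  onset_time <- rep(NA_real_, k)
  degenerate <- logical(k)
  for (j in seq_len(k)) {
    tm <- marker_times_s[j]
    i_mark <- floor(tm * sampling_rate) + 1L
    i_base0 <- max(1L, i_mark - as.integer(round(spec$baseline_window_s * sampling_rate)))
    base <- acceleration[i_base0:(i_mark - 1L)]
    i_end <- min(n, i_mark + as.integer(round(spec$search_window_s * sampling_rate)))
    win <- acceleration[i_mark:i_end]
    mu <- mean(base)
    sdv <- stats::sd(base)
    degenerate[j] <- !is.finite(sdv) || sdv < 1e-12
    thr <- if (degenerate[j]) 0.05 * max(abs(win)) else spec$threshold_k * sdv
    if (thr <= 0) next
    above <- abs(win - mu) > thr
    hit <- NA_integer_
    if (m > 1L) {
      cs <- cumsum(above)
      rs <- cs - c(rep(0L, m), cs[seq_len(length(cs) - m)])
      idx <- which(rs >= m)              # run of m supra-threshold samples
      if (length(idx)) hit <- idx[1L] - m + 1L
    } else {
      idx <- which(above)
      if (length(idx)) hit <- idx[1L]
    }
    if (!is.na(hit)) onset_time[j] <- (i_mark + hit - 2L) / sampling_rate
  }
  tibble::tibble(marker_time_s = marker_times_s, onset_time_s = onset_time,
                 detected = !is.na(onset_time),
                 degenerate_baseline = degenerate)
}

#' Map an onset time to the EEG sample clock
#'
#' Nearest-sample rounding of a time in seconds to a sample offset on the
#' EEG clock. The offset is counted from recording start, with time zero
#' mapping to offset 0 (the first stored sample); R code indexing vectors
#' adds one.
#'
#' @param onset_time_s Onset time(s), seconds.
#' @param eeg_sampling_rate EEG sampling rate, Hz.
#' @param duration_s Optional recording duration for range validation.
#' @return Integer sample offset(s).
#' @export
onset_to_eeg_index <- function(onset_time_s, eeg_sampling_rate,
                               duration_s = NULL) {
  if (any(onset_time_s < 0)) stop("onset time must be non-negative")
  if (!is.null(duration_s) && any(onset_time_s > duration_s)) {
    stop("onset time lies outside the recording")
  }
  as.integer(round(onset_time_s * eeg_sampling_rate))
}
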