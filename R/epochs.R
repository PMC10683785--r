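#' Extract a post-onset EEG epoch with baseline statistics
#'
#' Cuts the 300 ms window following a perturbation onset out of a continuous
#' (already filtered) channel, together with the mean and SD of the baseline
#' window running from 300 ms to 100 ms before the onset. Windows are
#' half-open on the right; the onset sample belongs to the epoch, not the
#' baseline. An onset too close to either record edge yields an epoch marked
#' invalid (counted by [qc_accounting()]), never an error.
#'
#' @param x Numeric vector: one channel of the continuous recording.
#' @param onset_offset Integer sample offset of the onset
#'   (see [onset_to_eeg_index()]; 0 = first sample).
#' @param sampling_rate Sampling rate of `x`, Hz.
#' @param epoch_s Epoch length, seconds.
#' @param baseline_s Two-element vector: baseline window relative to onset,
#'   seconds (negative = before onset).
#' @param subject_id,trial_index,channel,analysis_label Metadata carried on
#'   the epoch.
#' @return A list of class `pep_epoch` with `samples`, `baseline_mean`,
#'   `baseline_sd`, `state` (`"raw"`), `valid`, and the metadata.
#' @export
extract_epoch <- function(x, onset_offset, sampling_rate,
                          epoch_s = 0.300, baseline_s = c(-0.300, -0.100),
                          subject_id = NA_character_, trial_index = NA_integer_,
                          channel = NA_character_,
                          analysis_label = NA_character_) {
  n_ep <- round(epoch_s * sampling_rate)
  i_on <- onset_offset + 1L                       # R index of onset sample
  i_b0 <- onset_offset + round(baseline_s[1] * sampling_rate) + 1L
  i_b1 <- onset_offset + round(baseline_s[2] * sampling_rate)  # half-open
  valid <- i_b0 >= 1L && (i_on + n_ep - 1L) <= length(x)
  if (valid) {
    samples <- x[i_on:(i_on + n_ep - 1L)]
    base <- x[i_b0:i_b1]
    bm <- mean(base)
    bs <- stats::sd(base)
  } else {
    samples <- rep(NA_real_, n_ep)
    bm <- NA_real_
    bs <- NA_real_
  }
  structure(list(samples = samples, baseline_mean = bm, baseline_sd = bs,
                 state = "raw", valid = valid, subject_id = subject_id,
                 trial_index = trial_index, channel = channel,
                 analysis_label = analysis_label,
                 sampling_rate = sampling_rate),
            class = "pep_epoch")
}

# least-squares removal of a linear trend from each row of a matrix
detrend_rows <- function(m) {
  n <- ncol(m)
  t_c <- seq_len(n) - (n + 1) / 2                 # centred time axis
  slope <- (m %*% t_c) / sum(t_c^2)
  m - rowMeans(m) - slope %*% t(t_c)
}

#' Detrend and baseline-correct an epoch
#'
#' Removes the least-squares linear trend from the epoch samples, then
#' expresses them relative to the pre-onset baseline: subtract the baseline
#' mean and (with `method = "z"`, the default) divide by the baseline SD, so
#' corrected samples are in baseline-SD units. `method = "mean"` subtracts
#' the baseline mean only. A degenerate baseline (SD below `tol`) marks the
#' epoch invalid. Epochs advance `raw -> corrected`; re-correcting is an
#' error.
#'
#' @param epoch A `pep_epoch` in state `"raw"`.
#' @param method `"z"` (subtract mean, divide by SD) or `"mean"`.
#' @param tol Degenerate-baseline tolerance on the baseline SD.
#' @return The epoch in state `"corrected"` (or marked invalid).
#' @export
detrend_and_baseline_correct <- function(epoch, method = c("z", "mean"),
                                         tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(epoch, "pep_epoch"))
  if (epoch$state != "raw") {
    stop("epoch is already ", epoch$state, "; correction applies to raw epochs")
  }
  if (!epoch$valid) {
    epoch$state <- "corrected"
    return(epoch)
  }
  if (method == "z" && (!is.finite(epoch$baseline_sd) || epoch$baseline_sd <= tol)) {
    warning("degenerate baseline (SD <= tol); epoch invalidated", call. = FALSE)
    epoch$valid <- FALSE
    epoch$state <- "corrected"
    return(epoch)
  }
  d <- drop(detrend_rows(matrix(epoch$samples, nrow = 1)))
  epoch$samples <- if (method == "z") {
    (d - epoch$baseline_mean) / epoch$baseline_sd
  } else {
    d - epoch$baseline_mean
  }
  epoch$state <- "corrected"
  epoch
}

#' Assemble one subject's epochs across channels
#'
#' Convenience constructor used by the pipeline: extracts and corrects all
#' analyzable-trial epochs of one subject on a set of (filtered) series.
#'
#' @param series Named list of numeric vectors (one per analysis channel).
#' @param onset_offsets Integer sample offsets, one per retained trial.
#' @param trial_index,analysis_label Per-trial metadata (same length as
#'   `onset_offsets`).
#' @param sampling_rate Sampling rate, Hz.
#' @param subject One-row data frame with `subject_id`, `age_group`, `sex`.
#' @param valid_events Logical per trial; FALSE marks events lost upstream
#'   (dropout, undetected onset) whose epochs are invalid from the start.
#' @param method,tol Passed to [detrend_and_baseline_correct()].
#' @inheritParams extract_epoch
#' @return A list of class `pep_epoch_set`: `samples` (named list of
#'   trials x samples matrices), `baseline_mean`, `baseline_sd`, `valid`
#'   (trials x channels matrices), `trial_index`, `analysis_label`,
#'   `state`, `subject`, plus normalization fields once
#'   [normalize_subject_epochs()] has run.
#' @export
build_epoch_set <- function(series, onset_offsets, trial_index, analysis_label,
                            sampling_rate, subject,
                            valid_events = rep(TRUE, length(onset_offsets)),
                            epoch_s = 0.300, baseline_s = c(-0.300, -0.100),
                            method = "z", tol = 1e-12) {
  channels <- names(series)
  n_tr <- length(onset_offsets)
  n_ep <- round(epoch_s * sampling_rate)
  b_lo <- round(baseline_s[1] * sampling_rate)
  b_hi <- round(baseline_s[2] * sampling_rate)
  n_series <- length(series[[1]])
  samples <- list()
  bm <- bs <- matrix(NA_real_, n_tr, length(channels),
                     dimnames = list(NULL, channels))
  valid <- matrix(FALSE, n_tr, length(channels),
                  dimnames = list(NULL, channels))
  usable <- valid_events & !is.na(onset_offsets) &
    (onset_offsets + b_lo >= 0) & (onset_offsets + n_ep <= n_series)
  ok <- which(usable)
  # vectorized equivalent of extract_epoch + detrend_and_baseline_correct
  # applied trial-wise (shared internals: detrend_rows)
  if (length(ok)) {
    on1 <- onset_offsets[ok] + 1L
    idx_ep <- outer(on1, 0:(n_ep - 1L), "+")
    idx_bl <- outer(on1, b_lo:(b_hi - 1L), "+")
    n_bl <- ncol(idx_bl)
  }
  for (ch in channels) {
    m <- matrix(NA_real_, n_tr, n_ep)
    if (length(ok)) {
      ep <- matrix(series[[ch]][idx_ep], nrow = length(ok))
      bl <- matrix(series[[ch]][idx_bl], nrow = length(ok))
      mu <- rowMeans(bl)
      sdv <- sqrt(rowSums((bl - mu)^2) / (n_bl - 1))
      good <- if (method == "z") is.finite(sdv) & sdv > tol else rep(TRUE, length(ok))
      d <- detrend_rows(ep)
      corr <- if (method == "z") (d - mu) / sdv else d - mu
      m[ok[good], ] <- corr[good, , drop = FALSE]
      bm[ok[good], ch] <- mu[good]
      bs[ok[good], ch] <- sdv[good]
      valid[ok[good], ch] <- TRUE
    }
    samples[[ch]] <- m
  }
  structure(list(samples = samples, baseline_mean = bm, baseline_sd = bs,
                 valid = valid, trial_index = as.integer(trial_index),
                 analysis_label = analysis_label, state = "corrected",
                 sampling_rate = sampling_rate, subject = subject),
            class = "pep_epoch_set")
}

#' Normalize a subject's epochs to the first event epoch
#'
#' Per channel, the reference scale is the maximum absolute (corrected)
#' sample of the subject's first valid analyzable epoch -- normally trial 1,
#' the first perturbation. Every epoch of that subject and channel is
#' divided by the reference, so the first epoch's maximum magnitude becomes
#' exactly 1 and all magnitudes are expressed relative to it. If trial 1 is
#' missing, the earliest valid epoch substitutes and the substitution is
#' recorded in `reference_trial`.
#'
#' @param epoch_set A `pep_epoch_set` in state `"corrected"`.
#' @return The set in state `"normalized"`, with `reference_scale` and
#'   `reference_trial` (named per channel) attached.
#' @export
normalize_subject_epochs <- function(epoch_set) {
  stopifnot(inherits(epoch_set, "pep_epoch_set"))
  if (epoch_set$state != "corrected") {
    stop("normalization applies to corrected epoch sets (state is ",
         epoch_set$state, ")")
  }
  channels <- names(epoch_set$samples)
  ref_scale <- ref_trial <- stats::setNames(rep(NA_real_, length(channels)),
                                            channels)
  for (ch in channels) {
    ok <- which(epoch_set$valid[, ch])
    if (!length(ok)) stop("no valid epoch to serve as normalization reference")
    first <- ok[which.min(epoch_set$trial_index[ok])]
    ref <- max(abs(epoch_set$samples[[ch]][first, ]))
    if (!is.finite(ref) || ref <= 0) {
      stop("degenerate normalization reference (max |epoch| = 0)")
    }
    epoch_set$samples[[ch]] <- epoch_set$samples[[ch]] / ref
    ref_scale[ch] <- ref
    ref_trial[ch] <- epoch_set$trial_index[first]
  }
  epoch_set$reference_scale <- ref_scale
  epoch_set$reference_trial <- ref_trial
  epoch_set$state <- "normalized"
  epoch_set
}

#' Event accounting across a cohort
#'
#' Tallies planned, missing and analyzed events over a list of subject
#' epoch sets. Missingness is event-level (an event is missing when no
#' channel has a valid epoch for it -- dropout and window violations affect
#' all channels alike).
#'
#' @param epoch_sets List of `pep_epoch_set`.
#' @param protocol The [pep_protocol] the sets were built from.
#' @return A list of class `pep_qc`: `planned_events`, `missing_events`,
#'   `analyzed_events` (= planned - missing) and `per_subject` tibble.
#' @export
qc_accounting <- function(epoch_sets, protocol) {
  n_analyzable <- length(analyzable_trials(protocol))
  per_subject <- dplyr::bind_rows(lapply(epoch_sets, function(es) {
    event_ok <- apply(es$valid, 1, any)
    tibble::tibble(subject_id = es$subject$subject_id,
                   planned = n_analyzable,
                   missing = n_analyzable - sum(event_ok),
                   analyzed = sum(event_ok))
  }))
  structure(list(planned_events = sum(per_subject$planned),
                 missing_events = sum(per_subject$missing),
                 analyzed_events = sum(per_subject$analyzed),
                 per_subject = per_subject),
            class = "pep_qc")
}

#' @export
print.pep_qc <- function(x, ...) {
  cat(sprintf("<pep_qc> planned %d, missing %d, analyzed %d events\n",
              x$planned_events, x$missing_events, x$analyzed_events))
  invisible(x)
}

#' Export epoch sets as one tidy table
#'
#' Flattens a cohort's epoch sets into a long-format table: one row per
#' subject x trial x channel with metadata, baseline statistics, state and
#' the epoch samples spread over `s1..sN` columns. The inverse convenience
#' for inspection, plotting and archiving; [qc_accounting()] is the
#' companion event bookkeeping.
#'
#' @param epoch_sets List of `pep_epoch_set`.
#' @param path Optional CSV path; when given the table is also written.
#' @return A tibble (invisibly when `path` is given).
#' @export
export_epoch_table <- function(epoch_sets, path = NULL) {
  rows <- lapply(epoch_sets, function(es) {
    out <- list()
    for (ch in names(es$samples)) {
      m <- es$samples[[ch]]
      colnames(m) <- paste0("s", seq_len(ncol(m)))
      out[[ch]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = es$subject$subject_id,
                       trial_index = es$trial_index,
                       channel = ch,
                       analysis_label = es$analysis_label,
                       state = es$state,
                       valid = es$valid[, ch],
                       baseline_mean = es$baseline_mean[, ch],
                       baseline_sd = es$baseline_sd[, ch]),
        tibble::as_tibble(m))
    }
    dplyr::bind_rows(out)
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Evoked-response onset latency within a corrected epoch
#'
#' Reads the response onset as the first post-perturbation sample whose
#' absolute corrected value exceeds `threshold` baseline SDs (corrected
#' epochs are already in baseline-SD units).
#'
#' @param epoch_samples Corrected (baseline-SD unit) epoch samples.
#' @param sampling_rate Sampling rate, Hz.
#' @param threshold Threshold in baseline SDs.
#' @return Latency in ms after perturbation onset, or `NA` if the epoch
#'   never crosses the threshold.
#' @export
detect_pep_onset <- function(epoch_samples, sampling_rate = 1000,
                             threshold = 3) {
  idx <- which(abs(epoch_samples) > threshold)
  if (!length(idx)) return(NA_real_)
  (idx[1] - 1) * 1000 / sampling_rate
}
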