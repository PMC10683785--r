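#' Root-mean-square of an epoch
#'
#' The magnitude statistic: the square root of the mean of the squared
#' samples.
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @examples
#' compute_rms(c(3, -4, 3, -4))  # sqrt(12.5)
#' @export
compute_rms <- function(x) {
  if (length(x) == 0) stop("cannot compute RMS of an empty vector")
  sqrt(mean(x^2))
}

#' Peak magnitude of an epoch
#'
#' The highest positive deflection in the analyzed window: the maximum
#' signed sample, without regard to component designation. If no sample is
#' positive, the (negative) maximum is still returned, flagged via the
#' `no_positive_peak` attribute.
#'
#' @param x Non-empty numeric vector.
#' @return Scalar with logical attribute `no_positive_peak`.
#' @export
compute_peak_magnitude <- function(x) {
  if (length(x) == 0) stop("cannot compute the peak of an empty vector")
  structure(max(x), no_positive_peak = all(x < 0))
}

#' Per-subject RMS summary table
#'
#' Computes per-epoch RMS (and peak magnitude) on the normalized epochs and
#' averages them within subject, channel and condition (unpredictable /
#' predictable). Excluded-label epochs never enter; a subject x channel x
#' condition cell with no valid epochs is dropped (that subject later leaves
#' the affected channel's ANOVA listwise).
#'
#' @param epoch_sets List of normalized `pep_epoch_set` (one per subject).
#' @return A tibble with columns `subject_id`, `age_group`, `sex`,
#'   `channel`, `condition`, `mean_rms`, `mean_peak`, `n_epochs`.
#' @export
summarize_rms <- function(epoch_sets) {
  rows <- lapply(epoch_sets, function(es) {
    stopifnot(inherits(es, "pep_epoch_set"))
    if (es$state != "normalized") {
      stop("summarize_rms expects normalized epoch sets")
    }
    out <- list()
    for (ch in names(es$samples)) {
      for (cond in c("unpredictable", "predictable")) {
        sel <- which(es$analysis_label == cond & es$valid[, ch])
        if (!length(sel)) next
        m <- es$samples[[ch]][sel, , drop = FALSE]
        out[[length(out) + 1L]] <- tibble::tibble(
          subject_id = es$subject$subject_id,
          age_group = es$subject$age_group,
          sex = es$subject$sex,
          channel = ch, condition = cond,
          mean_rms = mean(sqrt(rowMeans(m^2))),
          mean_peak = mean(apply(m, 1, max)),
          n_epochs = length(sel))
      }
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}
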