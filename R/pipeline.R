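#' Process one recording: filter, detect onsets, epoch, normalize
#'
#' Runs the single-session part of the pipeline. The analysis series are Fz,
#' Cz and the combined mastoid; the mastoid series is averaged before
#' filtering, which by linearity of the filters equals filtering the six ear
#' channels and averaging afterwards. Onsets are detected on the platform
#' accelerometer, mapped to the EEG clock, and a 300 ms epoch (with
#' 300-to-100 ms pre-onset baseline) is extracted per analyzable trial, then
#' detrended, baseline-corrected and normalized to the subject's first event
#' epoch. Events flagged incomplete in the recording, or with undetected
#' onsets, yield invalid epochs that the QC accounting picks up.
#'
#' @param recording A `pep_recording`.
#' @param protocol The [pep_protocol] that produced the recording.
#' @param filter A [filter_spec].
#' @param onset An [onset_detection_spec].
#' @param channels Analysis channels; `"mastoid"` denotes the combined ear
#'   series.
#' @param filter_method Passed to [apply_bandpass_notch()].
#' @param correction Baseline correction method, see
#'   [detrend_and_baseline_correct()].
#' @param pep_threshold Baseline-SD threshold for the per-epoch evoked-onset
#'   latency readout.
#' @return A list of class `pep_session`: `epochs` (normalized
#'   `pep_epoch_set`), `onsets` (detection tibble incl. ground truth when
#'   available), `pep_latency` (tibble of per-epoch response latencies, ms,
#'   from the corrected epochs), `subject`.
#' @export
process_recording <- function(recording, protocol,
                              filter = filter_spec(),
                              onset = onset_detection_spec(),
                              channels = c("Fz", "Cz", "mastoid"),
                              filter_method = "fft",
                              correction = "z",
                              pep_threshold = 3) {
  stopifnot(inherits(recording, "pep_recording"),
            inherits(protocol, "pep_protocol"))
  fs <- recording$eeg_sampling_rate

  series <- matrix(0, length(channels), ncol(recording$eeg),
                   dimnames = list(channels, NULL))
  for (ch in channels) {
    series[ch, ] <- if (ch == "mastoid") {
      average_mastoid_channels(recording$eeg)$combined
    } else {
      recording$eeg[ch, ]
    }
  }
  filtered <- apply_bandpass_notch(series, filter, fs, method = filter_method)
  series_list <- stats::setNames(
    lapply(channels, function(ch) filtered[ch, ]), channels)

  session_from_series(
    series_list, fs, recording$acceleration, recording$accel_sampling_rate,
    markers = recording$markers, protocol = protocol,
    subject = recording$subject,
    incomplete_trials = recording$incomplete_trials,
    true_onset_s = recording$true_onset_s, onset = onset,
    correction = correction, pep_threshold = pep_threshold)
}

# shared back half of the per-session pipeline: onset detection, epoching,
# correction, latency readout, normalization
session_from_series <- function(series_list, fs, acceleration, fs_accel,
                                markers, protocol, subject, incomplete_trials,
                                true_onset_s, onset, correction,
                                pep_threshold) {
  det <- detect_onsets(acceleration, markers$marker_time_s, onset, fs_accel)
  det$trial_index <- markers$trial_index
  if (!is.null(true_onset_s)) det$true_onset_s <- true_onset_s

  keep <- protocol$analysis_label != "excluded"
  trial_idx <- protocol$index[keep]
  labels <- protocol$analysis_label[keep]
  det_keep <- det[match(trial_idx, det$trial_index), ]
  valid_events <- det_keep$detected & !(trial_idx %in% incomplete_trials)
  offsets <- ifelse(is.na(det_keep$onset_time_s), NA_integer_,
                    as.integer(round(det_keep$onset_time_s * fs)))

  es <- build_epoch_set(series_list, offsets, trial_idx, labels, fs,
                        subject = subject, valid_events = valid_events,
                        method = correction)
  channels <- names(series_list)
  lat <- list()
  for (ch in channels) {
    ok <- which(es$valid[, ch])
    if (length(ok)) {
      lat[[ch]] <- tibble::tibble(
        subject_id = subject$subject_id,
        trial_index = es$trial_index[ok],
        analysis_label = es$analysis_label[ok],
        channel = ch,
        latency_ms = vapply(ok, function(i) {
          detect_pep_onset(es$samples[[ch]][i, ], fs, pep_threshold)
        }, numeric(1)))
    }
  }
  es <- normalize_subject_epochs(es)

  structure(list(epochs = es, onsets = det,
                 pep_latency = dplyr::bind_rows(lat), subject = subject),
            class = "pep_session")
}

#' Statistical analysis of an RMS summary table
#'
#' Per channel: the split-plot three-way ANOVA, the age x sex Tukey HSD
#' follow-up, and Cohen's d for the condition, age and sex effects.
#'
#' @param table A [summarize_rms()] table.
#' @param channels Channels to analyze.
#' @param alpha Significance level for the post-hoc tests.
#' @return A list of class `pep_stats`: `anova` (named list of
#'   [split_plot_anova()] tables), `posthoc` (named list), `effect_sizes`
#'   (tibble).
#' @export
analyze_rms_table <- function(table, channels = c("Cz", "Fz", "mastoid"),
                              alpha = 0.05) {
  channels <- intersect(channels, unique(table$channel))
  anova <- lapply(stats::setNames(channels, channels), function(ch) {
    split_plot_anova(table, ch)
  })
  posthoc <- lapply(stats::setNames(channels, channels), function(ch) {
    posthoc_age_sex(table, ch, alpha = alpha)
  })
  es <- dplyr::bind_rows(lapply(channels, function(ch) {
    dplyr::bind_rows(cohens_d(table, "condition", ch),
                     cohens_d(table, "age", ch),
                     cohens_d(table, "sex", ch))
  }))
  structure(list(anova = anova, posthoc = posthoc, effect_sizes = es),
            class = "pep_stats")
}

#' Simulate and analyze a whole cohort in memory
#'
#' The end-to-end analysis on a synthetic cohort: lays out the cohort
#' ([cohort_plan()]), then one subject at a time simulates the recording,
#' processes it ([process_recording()]) and discards the raw signals,
#' keeping epochs and summaries. Equivalent to
#' `simulate_cohort()` + per-recording processing, at a fraction of the
#' memory.
#'
#' @param config A [generator_config].
#' @param protocol A [pep_protocol].
#' @inheritParams process_recording
#' @param keep_epochs Keep the per-subject epoch sets in the result.
#' @param fast Use the fused simulate-and-filter path (equivalent by
#'   linearity of the synthesis and filters; see the package vignette) when
#'   the configuration allows it. `fast = FALSE` always materializes each
#'   raw recording and runs [process_recording()] on it.
#' @return A list of class `pep_analysis`: `rms_table`, `qc`
#'   ([qc_accounting()]), `stats` ([analyze_rms_table()]), `onsets`
#'   (detection + ground truth, all subjects), `pep_latency`, `plan`,
#'   and `epoch_sets` when `keep_epochs = TRUE`.
#' @export
run_cohort_analysis <- function(config, protocol = build_default_protocol(),
                                filter = filter_spec(),
                                onset = onset_detection_spec(),
                                channels = c("Fz", "Cz", "mastoid"),
                                filter_method = "fft", correction = "z",
                                keep_epochs = FALSE, fast = TRUE) {
  plan <- cohort_plan(config, protocol)
  use_fast <- fast && filter_method == "fft" &&
    fastpath_applicable(config, channels)
  sessions <- lapply(seq_len(nrow(plan$subjects)), function(i) {
    sub <- plan$subjects[i, ]
    inc <- plan$dropout$trial_index[plan$dropout$subject_id == sub$subject_id]
    out <- if (use_fast) {
      simulate_session_fast(sub, protocol, config, seed = sub$seed,
                            incomplete_trials = inc, filter = filter,
                            onset = onset, correction = correction)
    } else {
      rec <- simulate_subject_recording(sub, protocol, config,
                                        seed = sub$seed,
                                        incomplete_trials = inc)
      process_recording(rec, protocol, filter = filter, onset = onset,
                        channels = channels, filter_method = filter_method,
                        correction = correction)
    }
    out$onsets$subject_id <- sub$subject_id
    out
  })
  epoch_sets <- lapply(sessions, function(s) s$epochs)
  rms_table <- summarize_rms(epoch_sets)
  qc <- qc_accounting(epoch_sets, protocol)
  stats <- analyze_rms_table(rms_table, channels = channels)
  structure(list(
    rms_table = rms_table, qc = qc, stats = stats,
    onsets = dplyr::bind_rows(lapply(sessions, function(s) s$onsets)),
    pep_latency = dplyr::bind_rows(lapply(sessions, function(s) s$pep_latency)),
    plan = plan,
    epoch_sets = if (keep_epochs) epoch_sets),
    class = "pep_analysis")
}

#' Run the full pipeline and write a self-contained results directory
#'
#' Simulates (or analyzes) a cohort and writes the RMS table, ANOVA,
#' post-hoc and effect-size tables as CSV, the QC report and a combined
#' summary as JSON, boxplot figures, and the generating configuration as
#' YAML. Every CSV carries a header comment with the package version and
#' the configuration hash; runs with identical configuration are
#' bit-identical at the array level.
#'
#' @param config A [generator_config], or a [run_config()] bundle carrying
#'   its own filter, onset and channel settings (which then override the
#'   corresponding arguments).
#' @param out_dir Output directory (created if needed).
#' @param protocol A [pep_protocol].
#' @inheritParams run_cohort_analysis
#' @param figures Write boxplot figures (PNG).
#' @return The [run_cohort_analysis()] result, invisibly, with
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config, out_dir,
                         protocol = build_default_protocol(),
                         filter = filter_spec(),
                         onset = onset_detection_spec(),
                         channels = c("Fz", "Cz", "mastoid"),
                         figures = TRUE) {
  correction <- "z"
  if (inherits(config, "pep_run_config")) {
    filter <- config$filter
    onset <- config$onset
    channels <- config$channels
    correction <- config$correction
    config <- config$generator
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_cohort_analysis(config, protocol, filter = filter, onset = onset,
                             channels = channels, correction = correction)
  version <- as.character(utils::packageVersion("pepkit"))
  hash <- config_hash(config)
  stamp <- sprintf("# pepkit %s | config %s", version, hash)

  write_stamped_csv(res$rms_table, file.path(out_dir, "rms_table.csv"), stamp)
  anova_all <- dplyr::bind_rows(lapply(names(res$stats$anova), function(ch) {
    tab <- res$stats$anova[[ch]]
    tab$channel <- ch
    tab
  }))
  write_stamped_csv(anova_all, file.path(out_dir, "anova.csv"), stamp)
  posthoc_all <- dplyr::bind_rows(lapply(names(res$stats$posthoc), function(ch) {
    tab <- res$stats$posthoc[[ch]]
    tab$channel <- ch
    tab
  }))
  write_stamped_csv(posthoc_all, file.path(out_dir, "posthoc.csv"), stamp)
  write_stamped_csv(res$stats$effect_sizes,
                    file.path(out_dir, "effect_sizes.csv"), stamp)
  write_protocol(protocol, file.path(out_dir, "protocol.tsv"))
  write_generator_config(config, file.path(out_dir, "config.yaml"))

  qc <- list(planned_events = res$qc$planned_events,
             missing_events = res$qc$missing_events,
             analyzed_events = res$qc$analyzed_events,
             per_subject = res$qc$per_subject)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA)
  summary <- list(
    package_version = version, config_hash = hash, seed = config$seed,
    n_subjects = nrow(res$plan$subjects),
    qc = qc[1:3],
    anova = anova_all, effect_sizes = res$stats$effect_sizes,
    condition_means = condition_means(res$rms_table))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (figures) write_figures(res, file.path(out_dir, "figures"))
  attr(res, "out_dir") <- out_dir
  invisible(res)
}

condition_means <- function(table) {
  dplyr::summarise(dplyr::group_by(table, .data$channel, .data$condition),
                   mean_rms = mean(.data$mean_rms), .groups = "drop")
}

write_stamped_csv <- function(tab, path, stamp) {
  con <- file(path, "w")
  writeLines(stamp, con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
  close(con)
  invisible(path)
}

config_hash <- function(config) {
  x <- unclass(config)
  x$platform <- unclass(x$platform)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15)
  # small FNV-1a over the serialized config; stable across sessions
  bytes <- utf8ToInt(as.character(json))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), as.integer(b))) * 16777619) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Boxplot figures for the condition, age and age x sex contrasts
#'
#' @param res A `pep_analysis`.
#' @param dir Output directory for PNG files.
#' @return Invisibly, the written file paths.
#' @export
write_figures <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- res$rms_table
  p1 <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$channel, y = .data$mean_rms,
                                          fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "mean RMS (normalized)", x = NULL,
                  title = "Perturbation type by channel") +
    ggplot2::theme_minimal()
  avg <- dplyr::summarise(
    dplyr::group_by(tab, .data$subject_id, .data$age_group, .data$sex,
                    .data$channel),
    rms = mean(.data$mean_rms), .groups = "drop")
  p2 <- ggplot2::ggplot(avg, ggplot2::aes(x = .data$channel, y = .data$rms,
                                          fill = .data$age_group)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "mean RMS (normalized)", x = NULL,
                  title = "Age group by channel") +
    ggplot2::theme_minimal()
  p3 <- ggplot2::ggplot(avg[avg$channel == "mastoid", ],
                        ggplot2::aes(x = .data$sex, y = .data$rms,
                                     fill = .data$age_group)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "mean RMS (normalized)", x = NULL,
                  title = "Age x sex at the mastoid") +
    ggplot2::theme_minimal()
  paths <- file.path(dir, c("condition_by_channel.png", "age_by_channel.png",
                            "age_sex_mastoid.png"))
  ggplot2::ggsave(paths[1], p1, width = 6, height = 4, dpi = 120)
  ggplot2::ggsave(paths[2], p2, width = 6, height = 4, dpi = 120)
  ggplot2::ggsave(paths[3], p3, width = 6, height = 4, dpi = 120)
  invisible(paths)
}
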