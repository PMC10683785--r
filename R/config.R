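#' Synthetic-cohort generator configuration
#'
#' Bundles every parameter of the synthetic EEG + platform-acceleration
#' simulator. The default values encode the stock study conditions: 40
#' subjects (10 per age-group x sex cell), the 34-trial protocol with 7 s
#' between translations, EEG at 1000 Hz on Fz, Cz and three mastoid channels
#' per ear, platform acceleration at 150 Hz, an evoked deflection with onset
#' latency uniform in 90-140 ms, band-limited 1/f background noise plus a
#' 60 Hz line component, and 40 events lost to dropout across the cohort.
#'
#' Amplitude structure: the evoked deflection on a given trial and channel
#' has positive-peak amplitude
#' `pep_base_amplitude * subject_gain * trial_jitter * condition_gain^(unpredictable)
#'  * age_gain^(elder) * elder_male_mastoid_gain^(elder male, mastoid only)`.
#' `condition_gain` defaults are calibrated (by simulation, recorded in
#' `inst/extdata/default_config.yaml`) so the full pipeline recovers a
#' perturbation-type Cohen's d of about 0.5 at the combined mastoid, 0.3 at
#' Fz and 0.2 at Cz.
#'
#' @param eeg_sampling_rate EEG sampling rate, Hz.
#' @param channels Ordered channel names; mastoid channels are those named
#'   `L5`-`L7` / `R5`-`R7`.
#' @param pep_latency_range_ms Uniform bounds for per-trial onset latency of
#'   the evoked deflection, ms after perturbation onset.
#' @param pep_duration_ms Support of the biphasic deflection, ms.
#' @param pep_base_amplitude Named vector (`Fz`, `Cz`, `mastoid`): baseline
#'   positive-peak amplitude, microvolts.
#' @param condition_gain Named vector (`Fz`, `Cz`, `mastoid`): multiplier on
#'   unpredictable trials.
#' @param age_gain Named vector (`Fz`, `Cz`, `mastoid`): multiplier for
#'   elder subjects.
#' @param elder_male_mastoid_gain Extra multiplier for elder males on
#'   mastoid channels.
#' @param first_trial_boost Extra amplitude factor on trial 1, the
#'   first-ever perturbation, reproducing its pronounced startle response.
#'   The boost is not modulated by the age/sex gains (startle saturation),
#'   so group effects survive normalization to the first event epoch.
#' @param amplitude_jitter_sdlog Log-SD of the per-trial lognormal amplitude
#'   jitter (mean 1).
#' @param subject_gain_sdlog Log-SD of the per-subject lognormal recording
#'   scale (mean 1). The scale multiplies evoked activity and background
#'   alike -- the cross-subject amplitude differences (skull, impedance)
#'   that baseline z-correction and first-trial normalization are there to
#'   remove.
#' @param noise_alpha Spectral exponent of the 1/f^alpha background.
#' @param noise_sd Standard deviation of the synthesized band-limited
#'   background, microvolts.
#' @param noise_band Frequency band of the synthesized background, Hz.
#' @param line_noise_amplitude Amplitude of the 60 Hz line component,
#'   microvolts.
#' @param line_noise_freq Line frequency, Hz.
#' @param motion_delay_range_s Uniform bounds of the marker-to-motion delay
#'   (TTL command to platform movement), seconds.
#' @param inter_trial_interval_s Fixed interval between successive event
#'   markers, seconds.
#' @param lead_in_s,tail_s Quiet recording before the first marker and after
#'   the last.
#' @param accel_noise_sd Accelerometer sensor noise SD, m/s^2.
#' @param dropout_events Number of analyzable events, across the whole
#'   cohort, flagged incomplete (missing at random).
#' @param n_per_cell Subjects per age-group x sex cell.
#' @param seed Integer seed; together with the protocol it fully determines
#'   the generated cohort.
#' @param platform A [platform_profile].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(eeg_sampling_rate = 1000,
                             channels = c("Fz", "Cz", "L5", "L6", "L7",
                                          "R5", "R6", "R7"),
                             pep_latency_range_ms = c(90, 140),
                             pep_duration_ms = 120,
                             pep_base_amplitude = c(Fz = 18, Cz = 18, mastoid = 22),
                             condition_gain = c(Fz = 1.08, Cz = 1.045, mastoid = 1.156),
                             age_gain = c(Fz = 1.00, Cz = 1.25, mastoid = 1.20),
                             elder_male_mastoid_gain = 1.5,
                             first_trial_boost = 1.8,
                             amplitude_jitter_sdlog = 0.15,
                             subject_gain_sdlog = 0.3,
                             noise_alpha = 1,
                             noise_sd = 10,
                             noise_band = c(1, 45),
                             line_noise_amplitude = 5,
                             line_noise_freq = 60,
                             motion_delay_range_s = c(0, 0.03),
                             inter_trial_interval_s = 7,
                             lead_in_s = 3,
                             tail_s = 6,
                             accel_noise_sd = 0.01,
                             dropout_events = 40,
                             n_per_cell = 10,
                             seed = 1,
                             platform = NULL) {
  if (is.null(platform)) {
    # stock kinematics; the peak-velocity cap is documented in ?platform_profile
    platform <- suppressWarnings(platform_profile())
  }
  stopifnot(eeg_sampling_rate > 0, length(channels) >= 1,
            length(pep_latency_range_ms) == 2,
            pep_latency_range_ms[1] > 0, pep_latency_range_ms[2] <= 150,
            pep_latency_range_ms[1] <= pep_latency_range_ms[2],
            pep_duration_ms > 0,
            all(pep_base_amplitude > 0), all(condition_gain > 0),
            all(age_gain > 0), elder_male_mastoid_gain > 0,
            first_trial_boost > 0,
            amplitude_jitter_sdlog >= 0, subject_gain_sdlog >= 0,
            noise_sd >= 0, noise_band[1] > 0, noise_band[2] > noise_band[1],
            line_noise_amplitude >= 0,
            inter_trial_interval_s >= 7,
            dropout_events >= 0, n_per_cell >= 1,
            inherits(platform, "platform_profile"))
  for (nm in list(pep_base_amplitude, condition_gain, age_gain)) {
    stopifnot(all(c("Fz", "Cz", "mastoid") %in% names(nm)))
  }
  structure(list(
    eeg_sampling_rate = eeg_sampling_rate, channels = channels,
    pep_latency_range_ms = pep_latency_range_ms,
    pep_duration_ms = pep_duration_ms,
    pep_base_amplitude = pep_base_amplitude,
    condition_gain = condition_gain, age_gain = age_gain,
    elder_male_mastoid_gain = elder_male_mastoid_gain,
    first_trial_boost = first_trial_boost,
    amplitude_jitter_sdlog = amplitude_jitter_sdlog,
    subject_gain_sdlog = subject_gain_sdlog,
    noise_alpha = noise_alpha, noise_sd = noise_sd, noise_band = noise_band,
    line_noise_amplitude = line_noise_amplitude,
    line_noise_freq = line_noise_freq,
    motion_delay_range_s = motion_delay_range_s,
    inter_trial_interval_s = inter_trial_interval_s,
    lead_in_s = lead_in_s, tail_s = tail_s,
    accel_noise_sd = accel_noise_sd,
    dropout_events = dropout_events, n_per_cell = n_per_cell,
    seed = as.integer(seed), platform = platform),
    class = "generator_config")
}

#' Map channel names to amplitude classes
#'
#' `Fz` and `Cz` map to themselves; cEEGrid-style ear channels
#' (`L5`-`L7`, `R5`-`R7`) map to `mastoid`.
#' @param channels Character vector of channel names.
#' @return Character vector of classes (`Fz`, `Cz`, `mastoid`).
#' @export
channel_class <- function(channels) {
  ifelse(channels %in% c("Fz", "Cz"), channels,
         ifelse(grepl("^[LR][0-9]+$", channels), "mastoid", "other"))
}

#' Bundle a complete pipeline run configuration
#'
#' A run configuration ties together everything a reproducible run needs:
#' the generator configuration (or, for real data, the ingest paths), the
#' filter and onset-detection specifications, the analysis channels and the
#' global seed. A run is fully determined by its configuration: rerunning
#' [run_pipeline()] with the same `run_config` reproduces every output
#' array bit for bit.
#'
#' @param generator A [generator_config].
#' @param filter A [filter_spec].
#' @param onset An [onset_detection_spec].
#' @param channels Analysis channels.
#' @param seed Optional override of the generator seed.
#' @param correction Baseline correction method (`"z"` or `"mean"`).
#' @return A list of class `pep_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       filter = filter_spec(),
                       onset = onset_detection_spec(),
                       channels = c("Fz", "Cz", "mastoid"),
                       seed = NULL, correction = "z") {
  stopifnot(inherits(generator, "generator_config"),
            inherits(filter, "filter_spec"),
            inherits(onset, "onset_detection_spec"))
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, filter = filter, onset = onset,
                 channels = channels, correction = correction),
            class = "pep_run_config")
}

#' @rdname run_config
#' @param config A `pep_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "pep_run_config"))
  tmp <- tempfile()
  write_generator_config(config$generator, tmp)
  x <- list(generator = yaml::read_yaml(tmp),
            filter = unclass(config$filter),
            onset = unclass(config$onset),
            channels = config$channels,
            correction = config$correction)
  unlink(tmp)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  tmp <- tempfile()
  yaml::write_yaml(x$generator, tmp)
  gen <- read_generator_config(tmp)
  unlink(tmp)
  run_config(generator = gen,
             filter = do.call(filter_spec, x$filter),
             onset = do.call(onset_detection_spec, x$onset),
             channels = unlist(x$channels),
             correction = x$correction)
}

#' Serialize / load configurations as YAML
#'
#' `write_generator_config()` writes a [generator_config] (including the
#' platform profile) to YAML; `read_generator_config()` reads it back.
#'
#' @param config A [generator_config].
#' @param path YAML file path.
#' @return `read_generator_config` returns a [generator_config].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  for (nm in c("pep_base_amplitude", "condition_gain", "age_gain")) {
    x[[nm]] <- as.list(x[[nm]])                   # keep channel-class names
  }
  x$platform <- unclass(x$platform)[c("sampling_rate", "peak_acceleration",
                                      "target_displacement",
                                      "target_peak_velocity")]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  plat <- do.call(platform_profile, x$platform)
  x$platform <- NULL
  for (nm in c("pep_base_amplitude", "condition_gain", "age_gain")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  do.call(generator_config, c(x, list(platform = plat)))
}
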