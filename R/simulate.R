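#' Simulate a single-channel evoked deflection
#'
#' Generates the biphasic (negative-then-positive) perturbation-evoked
#' deflection used by the cohort simulator: a sharp early negative lobe
#' followed by a broader positive lobe, zero before `latency_ms`, whose
#' maximum positive excursion on the sample grid equals `amplitude` (the
#' negative excursion is 1.4 times larger, as the early negativity
#' dominates perturbation-evoked responses).
#'
#' @param latency_ms Onset latency after perturbation onset, ms; must lie in
#'   (0, 150].
#' @param amplitude Positive-peak amplitude, microvolts (0 gives an all-zero
#'   waveform).
#' @param duration_ms Support of the deflection, ms.
#' @param sampling_rate Sampling rate, Hz.
#' @return Numeric vector aligned to perturbation onset (element 1 is the
#'   onset sample), covering `[0, latency + duration)` ms.
#' @export
simulate_pep_waveform <- function(latency_ms, amplitude, duration_ms = 120,
                                  sampling_rate = 1000) {
  if (latency_ms <= 0 || latency_ms > 150) {
    stop("latency_ms must lie in (0, 150]")
  }
  if (amplitude < 0) stop("amplitude must be non-negative")
  stopifnot(duration_ms > 0)
  n_lat <- round(latency_ms * sampling_rate / 1000)
  c(rep(0, n_lat), amplitude * pep_atom(duration_ms, sampling_rate))
}

# unit-positive-peak biphasic atom (cached per duration/rate)
pep_atom <- function(duration_ms, sampling_rate) {
  key <- paste("atom", duration_ms, sampling_rate, sep = "|")
  shape <- .pep_cache[[key]]
  if (is.null(shape)) {
    # Negative lobe over the first 35% of the support with a fast attack
    # (~28% of the lobe) and slower decay -- the steep N1-like deflection
    # that marks response onset, 1.4x the positive peak -- followed by a
    # broader positive lobe.
    n_dur <- round(duration_ms * sampling_rate / 1000)
    tau <- seq_len(n_dur) / n_dur                 # (0, 1]
    r <- 0.35
    q <- 0.28
    tn <- tau / r
    neg <- ifelse(tn < q, sin(pi * tn / (2 * q))^2,
                  cos(pi * (tn - q) / (2 * (1 - q)))^2)
    shape <- ifelse(tau < r, -1.4 * neg,
                    sin(pi * (tau - r) / (1 - r))^2)
    shape <- shape / max(shape)
    .pep_cache[[key]] <- shape
  }
  shape
}

# Sparse band-limited spectra for one subject's EEG background + line noise.
#
# Channels are packed in pairs (1,2), (3,4), ...: each pair shares one
# complex spectrum whose inverse FFT carries channel 2p-1 in its real part
# and channel 2p in its imaginary part (independent complex coefficients on
# both frequency half-axes make the two parts independent). The 1/f^alpha
# amplitude profile is restricted to `band` and scaled so each channel's
# time-domain SD equals `sd`; the line component is injected at the DFT bin
# nearest `line_freq` with an independent uniform phase per channel.
#
# Returns list(idx = 1-based bin indices, pairs = list of complex coefficient
# vectors over idx, n = n). RNG order: per pair, rnorm(real), rnorm(imag);
# then runif(n_channels) line phases.
draw_eeg_spectra <- function(n, n_channels, sampling_rate, alpha, sd, band,
                             line_amplitude, line_freq) {
  key <- paste("spec", n, sampling_rate, alpha, band[1], band[2], line_freq,
               sep = "|")
  layout <- .pep_cache[[key]]
  if (is.null(layout)) {
    f <- (0:(n - 1)) * sampling_rate / n
    f <- pmin(f, sampling_rate - f)               # two-sided frequency axis
    noise_bins <- which(f >= band[1] & f <= band[2])
    a <- f[noise_bins]^(-alpha / 2)
    # Var(Re ifft) = sum(a^2)/n^2 for unit-variance complex coefficients
    a <- a * (n / sqrt(sum(a^2)))
    k_line <- round(line_freq * n / sampling_rate)
    line_bins <- unique(c(k_line, n - k_line)) + 1L
    idx <- sort(unique(c(noise_bins, line_bins)))
    layout <- list(idx = idx,
                   amp = replace(numeric(length(idx)),
                                 match(noise_bins, idx), a),
                   line_pos = match(k_line + 1L, idx),
                   line_neg = match(n - k_line + 1L, idx))
    .pep_cache[[key]] <- layout
  }
  n_pairs <- ceiling(n_channels / 2)
  nb <- length(layout$idx)
  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    pairs[[p]] <- complex(real = stats::rnorm(nb),
                          imaginary = stats::rnorm(nb)) * (layout$amp * sd)
  }
  if (line_amplitude > 0) {
    phase <- stats::runif(n_channels, 0, 2 * pi)
    for (p in seq_len(n_pairs)) {
      ph1 <- phase[2 * p - 1]
      ph2 <- if (2 * p <= n_channels) phase[2 * p] else NULL
      line <- (n / 2) * line_amplitude * exp(1i * ph1)
      conj_line <- Conj(line)
      if (!is.null(ph2)) {
        line <- line + 1i * (n / 2) * line_amplitude * exp(1i * ph2)
        conj_line <- conj_line + 1i * (n / 2) * line_amplitude * exp(-1i * ph2)
      }
      pairs[[p]][layout$line_pos] <- pairs[[p]][layout$line_pos] + line
      pairs[[p]][layout$line_neg] <- pairs[[p]][layout$line_neg] + conj_line
    }
  }
  list(idx = layout$idx, pairs = pairs, n = n)
}

# inverse FFT of one sparse pair spectrum (optionally gain-weighted)
ifft_pair <- function(spectra, coef) {
  s <- vector("complex", spectra$n)
  s[spectra$idx] <- coef
  stats::fft(s, inverse = TRUE) / spectra$n
}

# per-trial latencies/amplitudes/onsets for one subject (fixed RNG order:
# delay, latency, jitter)
draw_trial_schedule <- function(protocol, config) {
  n_tr <- nrow(protocol)
  marker_time <- config$lead_in_s +
    (seq_len(n_tr) - 1) * config$inter_trial_interval_s
  delay <- stats::runif(n_tr, config$motion_delay_range_s[1],
                        config$motion_delay_range_s[2])
  latency <- stats::runif(n_tr, config$pep_latency_range_ms[1],
                          config$pep_latency_range_ms[2])
  jitter <- stats::rlnorm(n_tr, meanlog = -config$amplitude_jitter_sdlog^2 / 2,
                          sdlog = config$amplitude_jitter_sdlog)
  list(marker_time = marker_time, onset = marker_time + delay,
       latency = latency, jitter = jitter)
}

# Per-trial evoked amplitude. Trial 1 -- the first-ever perturbation and the
# normalization reference -- carries the pronounced startle response: its
# amplitude is boosted by first_trial_boost and is NOT modulated by the
# age/sex gains (the startle saturates), which is what lets age and sex
# effects survive first-trial normalization downstream.
pep_trial_amplitude <- function(config, subject, label, class_names,
                                first_trial = FALSE) {
  base <- config$pep_base_amplitude[class_names] * subject$subject_gain
  if (label == "unpredictable") base <- base * config$condition_gain[class_names]
  if (first_trial) return(base * config$first_trial_boost)
  if (subject$age_group == "elder") {
    base <- base * config$age_gain[class_names]
    if (subject$sex == "male") {
      base[class_names == "mastoid"] <-
        base[class_names == "mastoid"] * config$elder_male_mastoid_gain
    }
  }
  base
}

# accelerometer channel for one schedule (RNG: rnorm sensor noise)
draw_acceleration <- function(protocol, config, schedule, duration) {
  fs_a <- config$platform$sampling_rate
  n_a <- round(duration * fs_a)
  accel <- stats::rnorm(n_a, sd = config$accel_noise_sd)
  burst <- lapply(c(posterior = "posterior", anterior = "anterior"),
                  function(d) suppressWarnings(
                    simulate_platform_motion(config$platform, d)))
  for (i in seq_len(nrow(protocol))) {
    b <- burst[[protocol$direction[i]]]
    j0 <- round(schedule$onset[i] * fs_a) + 1L
    span <- j0:(j0 + length(b) - 1L)
    accel[span] <- accel[span] + b
  }
  accel
}

recording_duration <- function(protocol, config) {
  config$lead_in_s + (nrow(protocol) - 1) * config$inter_trial_interval_s +
    config$tail_s
}

#' Simulate one subject's synchronized EEG + accelerometer session
#'
#' Builds a continuous multi-channel EEG record (band-limited 1/f^alpha
#' background, a line-frequency component, and evoked deflections) and the
#' platform accelerometer channel (sensor noise + translation bursts),
#' synchronized by event markers on a shared clock. Event markers fire every
#' `inter_trial_interval_s`; the platform starts moving a small random delay
#' after each marker, and the evoked deflection follows motion onset by a
#' per-trial latency drawn uniformly from `pep_latency_range_ms`.
#' Ground-truth onsets and latencies are stored. Output is fully determined
#' by `(subject, protocol, config, seed)`.
#'
#' @param subject One-row data frame with `subject_id`, `age_group`
#'   (`young`/`elder`), `sex` (`male`/`female`), `subject_gain`.
#' @param protocol A [pep_protocol].
#' @param config A [generator_config].
#' @param seed Optional integer seed applied before drawing.
#' @param incomplete_trials Integer trial indices flagged incomplete
#'   (technical dropout).
#' @return A list of class `pep_recording`: `eeg` (channels x samples,
#'   microvolts, with row names), `eeg_sampling_rate`, `acceleration`,
#'   `accel_sampling_rate`, `markers` (tibble: `trial_index`,
#'   `marker_time_s`, `marker_sample`), `true_onset_s`, `true_latency_ms`,
#'   `incomplete_trials`, `subject`.
#' @export
simulate_subject_recording <- function(subject, protocol, config, seed = NULL,
                                       incomplete_trials = integer(0)) {
  stopifnot(inherits(protocol, "pep_protocol"),
            inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$eeg_sampling_rate
  n_tr <- nrow(protocol)
  duration <- recording_duration(protocol, config)
  n <- round(duration * fs)
  nch <- length(config$channels)
  classes <- channel_class(config$channels)

  sched <- draw_trial_schedule(protocol, config)
  # subject_gain is an overall recording scale: it multiplies background
  # and evoked activity alike (and is what first-trial normalization removes)
  spectra <- draw_eeg_spectra(n, nch, fs, config$noise_alpha,
                              config$noise_sd * subject$subject_gain,
                              config$noise_band,
                              config$line_noise_amplitude * subject$subject_gain,
                              config$line_noise_freq)
  eeg <- matrix(0, nch, n)
  for (p in seq_along(spectra$pairs)) {
    z <- ifft_pair(spectra, spectra$pairs[[p]])
    eeg[2 * p - 1, ] <- Re(z)
    if (2 * p <= nch) eeg[2 * p, ] <- Im(z)
  }
  for (i in seq_len(n_tr)) {
    wave <- simulate_pep_waveform(sched$latency[i], 1, config$pep_duration_ms,
                                  fs)
    amp <- pep_trial_amplitude(config, subject, protocol$analysis_label[i],
                               classes,
                               first_trial = protocol$index[i] == 1L) *
      sched$jitter[i]
    i0 <- onset_to_eeg_index(sched$onset[i], fs) + 1L
    span <- i0:(i0 + length(wave) - 1L)
    eeg[, span] <- eeg[, span] + outer(unname(amp), wave)
  }
  rownames(eeg) <- config$channels

  accel <- draw_acceleration(protocol, config, sched, duration)

  structure(list(
    subject = subject,
    eeg = eeg, eeg_sampling_rate = fs,
    acceleration = accel,
    accel_sampling_rate = config$platform$sampling_rate,
    markers = tibble::tibble(trial_index = protocol$index,
                             marker_time_s = sched$marker_time,
                             marker_sample = onset_to_eeg_index(sched$marker_time, fs)),
    true_onset_s = sched$onset, true_latency_ms = sched$latency,
    incomplete_trials = as.integer(incomplete_trials)),
    class = "pep_recording")
}

#' Lay out a cohort: subjects, per-subject seeds and dropout assignment
#'
#' Draws the cohort structure from the master seed without synthesizing any
#' signals, so recordings can be generated one subject at a time (streaming)
#' or all at once ([simulate_cohort()]) with identical results.
#'
#' @param config A [generator_config].
#' @param protocol A [pep_protocol].
#' @return A list of class `pep_cohort_plan`: `subjects` (tibble with
#'   `subject_id`, `age_group`, `sex`, `subject_gain`, `seed`), `dropout`
#'   (tibble `subject_id`, `trial_index` of incomplete events), `seed`.
#' @export
cohort_plan <- function(config, protocol) {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "pep_protocol"))
  set.seed(config$seed)
  cells <- expand.grid(sex = c("male", "female"),
                       age_group = c("young", "elder"),
                       stringsAsFactors = FALSE)
  n_sub <- 4L * config$n_per_cell
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_sub)),
    age_group = rep(cells$age_group, each = config$n_per_cell),
    sex = rep(cells$sex, each = config$n_per_cell),
    subject_gain = stats::rlnorm(n_sub,
                                 meanlog = -config$subject_gain_sdlog^2 / 2,
                                 sdlog = config$subject_gain_sdlog),
    seed = sample.int(.Machine$integer.max - 1L, n_sub))
  analyzable <- analyzable_trials(protocol)
  slots <- expand.grid(trial_index = analyzable,
                       subject_id = subjects$subject_id,
                       stringsAsFactors = FALSE)
  if (config$dropout_events > nrow(slots)) {
    stop("dropout_events exceeds the number of analyzable events")
  }
  pick <- sample.int(nrow(slots), config$dropout_events)
  dropout <- tibble::as_tibble(slots[sort(pick), c("subject_id", "trial_index")])
  structure(list(subjects = subjects, dropout = dropout, seed = config$seed),
            class = "pep_cohort_plan")
}

#' Simulate a full synthetic cohort
#'
#' Generates one [simulate_subject_recording()] per subject of the
#' [cohort_plan()], with `dropout_events` analyzable events across the
#' cohort flagged incomplete, chosen uniformly at random. Identical
#' `(config, protocol)` (the seed lives in the config) give bit-identical
#' output.
#'
#' @param config A [generator_config].
#' @param protocol A [pep_protocol].
#' @return A list of class `pep_cohort`: `recordings` (list of
#'   `pep_recording`), `manifest` (list: `seed`, `config`, `subjects`,
#'   `dropout`).
#' @export
simulate_cohort <- function(config, protocol = build_default_protocol()) {
  plan <- cohort_plan(config, protocol)
  recordings <- lapply(seq_len(nrow(plan$subjects)), function(i) {
    sub <- plan$subjects[i, ]
    inc <- plan$dropout$trial_index[plan$dropout$subject_id == sub$subject_id]
    simulate_subject_recording(sub, protocol, config, seed = sub$seed,
                               incomplete_trials = inc)
  })
  manifest <- list(seed = config$seed, config = config,
                   subjects = plan$subjects, dropout = plan$dropout)
  structure(list(recordings = recordings, manifest = manifest),
            class = "pep_cohort")
}

#' @export
print.pep_recording <- function(x, ...) {
  cat(sprintf("<pep_recording %s> %d EEG channels x %d samples @ %g Hz; accel %d samples @ %g Hz; %d markers (%d incomplete)\n",
              x$subject$subject_id %||% "?", nrow(x$eeg), ncol(x$eeg),
              x$eeg_sampling_rate, length(x$acceleration),
              x$accel_sampling_rate, nrow(x$markers),
              length(x$incomplete_trials)))
  invisible(x)
}
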