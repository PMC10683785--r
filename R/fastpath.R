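# Fused simulate-and-process path for Monte-Carlo work.
#
# process_recording() filters the synthesized record and epochs it. Both the
# background synthesis and the zero-phase filter are linear and
# time-invariant, so the filtered analysis series can be assembled directly:
#
#   * filtered background: apply the zero-phase gain to the sparse
#     band-limited spectra before the inverse FFT (one inverse FFT yields
#     Fz and Cz; one more yields the combined mastoid via the identity
#     mean(Re z + Im z) over channel pairs = Re((1 - i) * sum z) / n);
#   * filtered deflections: add a pre-filtered copy of the biphasic atom
#     (computed once, padded so truncated filter tails are ~1e-7 of peak)
#     at each trial's onset + latency;
#   * the accelerometer channel and every downstream stage (onset
#     detection, epoching, correction, normalization, summaries) are the
#     unchanged pipeline code.
#
# RNG draws occur in exactly the order of simulate_subject_recording(), so
# for a given seed this path and the reference path agree to filter-tail
# truncation error (~1e-6 relative); the equivalence is covered by tests.

# zero-phase-filtered atom with `pad_s` of ring-down kept on each side
filtered_pep_atom <- function(config, filter, pad_s = 1.5) {
  fs <- config$eeg_sampling_rate
  key <- paste("fatom", config$pep_duration_ms, fs, pad_s,
               filter$bandpass_order, filter$bandpass_low,
               filter$bandpass_high, filter$notch_freq, filter$notch_quality,
               sep = "|")
  out <- .pep_cache[[key]]
  if (is.null(out)) {
    atom <- pep_atom(config$pep_duration_ms, fs)
    pad <- round(pad_s * fs)
    x <- c(numeric(pad), atom, numeric(pad))
    out <- list(wave = apply_bandpass_notch(x, filter, fs, method = "fft"),
                pad = pad)
    .pep_cache[[key]] <- out
  }
  out
}

fastpath_applicable <- function(config, channels) {
  cls <- channel_class(config$channels)
  identical(channels, c("Fz", "Cz", "mastoid")) &&
    length(config$channels) %% 2 == 0 && length(config$channels) >= 4 &&
    identical(cls[1:2], c("Fz", "Cz")) && all(cls[-(1:2)] == "mastoid")
}

# simulate + filter + epoch one subject without materializing the raw record
simulate_session_fast <- function(subject, protocol, config, seed,
                                  incomplete_trials, filter, onset,
                                  correction = "z", pep_threshold = 3) {
  set.seed(seed)
  fs <- config$eeg_sampling_rate
  n_tr <- nrow(protocol)
  duration <- recording_duration(protocol, config)
  n <- round(duration * fs)
  nch <- length(config$channels)
  n_mast <- nch - 2L

  sched <- draw_trial_schedule(protocol, config)
  spectra <- draw_eeg_spectra(n, nch, fs, config$noise_alpha,
                              config$noise_sd * subject$subject_gain,
                              config$noise_band,
                              config$line_noise_amplitude * subject$subject_gain,
                              config$line_noise_freq)
  g <- zero_phase_gain(filter, n, fs)[spectra$idx]
  z_fc <- ifft_pair(spectra, spectra$pairs[[1]] * g)
  mast_sum <- Reduce(`+`, spectra$pairs[-1])
  z_m <- ifft_pair(spectra, mast_sum * g)
  series <- list(Fz = Re(z_fc), Cz = Im(z_fc),
                 mastoid = Re((1 - 1i) * z_m) / n_mast)

  fat <- filtered_pep_atom(config, filter)
  classes <- c("Fz", "Cz", "mastoid")
  for (i in seq_len(n_tr)) {
    amp <- pep_trial_amplitude(config, subject, protocol$analysis_label[i],
                               classes,
                               first_trial = protocol$index[i] == 1L) *
      sched$jitter[i]
    n_lat <- round(sched$latency[i] * fs / 1000)
    i0 <- onset_to_eeg_index(sched$onset[i], fs) + 1L + n_lat - fat$pad
    span <- i0:(i0 + length(fat$wave) - 1L)
    inside <- span >= 1L & span <= n
    for (k in seq_along(classes)) {
      series[[k]][span[inside]] <- series[[k]][span[inside]] +
        amp[k] * fat$wave[inside]
    }
  }

  accel <- draw_acceleration(protocol, config, sched, duration)
  markers <- tibble::tibble(trial_index = protocol$index,
                            marker_time_s = sched$marker_time,
                            marker_sample = onset_to_eeg_index(sched$marker_time, fs))
  session_from_series(series, fs, accel, config$platform$sampling_rate,
                      markers = markers, protocol = protocol,
                      subject = subject,
                      incomplete_trials = incomplete_trials,
                      true_onset_s = sched$onset, onset = onset,
                      correction = correction, pep_threshold = pep_threshold)
}
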