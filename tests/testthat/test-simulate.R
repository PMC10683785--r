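prot <- build_default_protocol()

test_that("subject recordings have the expected structure and timing", {
  cfg <- small_config(seed = 3)
  rec <- simulate_subject_recording(one_subject(), prot, cfg, seed = 9)
  expect_s3_class(rec, "pep_recording")
  expect_equal(nrow(rec$markers), 34L)
  expect_equal(rownames(rec$eeg), cfg$channels)
  expect_equal(ncol(rec$eeg),
               round((cfg$lead_in_s + 33 * 7 + cfg$tail_s) * 1000))
  # markers every 7 s; EEG and accel cover the same wall-clock span
  expect_equal(diff(rec$markers$marker_time_s), rep(7, 33))
  expect_lt(abs(ncol(rec$eeg) / rec$eeg_sampling_rate -
                  length(rec$acceleration) / rec$accel_sampling_rate),
            1 / rec$accel_sampling_rate)
  # ground-truth onsets follow markers by the configured delay
  expect_true(all(rec$true_onset_s >= rec$markers$marker_time_s))
  expect_true(all(rec$true_onset_s - rec$markers$marker_time_s <= 0.03))
  expect_true(all(rec$true_latency_ms >= 90 & rec$true_latency_ms <= 140))
})

test_that("recordings are deterministic in the seed", {
  cfg <- small_config(seed = 3)
  r1 <- simulate_subject_recording(one_subject(), prot, cfg, seed = 11)
  r2 <- simulate_subject_recording(one_subject(), prot, cfg, seed = 11)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$acceleration, r2$acceleration)
  r3 <- simulate_subject_recording(one_subject(), prot, cfg, seed = 12)
  expect_false(identical(r1$eeg, r3$eeg))
})

test_that("each simulated translation integrates to 20 cm", {
  cfg <- small_config(seed = 4, accel_noise_sd = 0)
  rec <- simulate_subject_recording(one_subject(), prot, cfg, seed = 13)
  fs_a <- rec$accel_sampling_rate
  for (i in c(1, 16, 30)) {
    j0 <- round(rec$true_onset_s[i] * fs_a) + 1
    burst <- rec$acceleration[j0:(j0 + 200)]
    expect_equal(abs(platform_displacement(burst, fs_a)), 0.20,
                 tolerance = 1e-6)
  }
})

test_that("gain structure: elder males exceed young females at the mastoid", {
  cfg <- small_config(seed = 5)
  classes <- channel_class(cfg$channels)
  a_em <- pepkit:::pep_trial_amplitude(cfg, one_subject("elder", "male"),
                                       "unpredictable", classes)
  a_yf <- pepkit:::pep_trial_amplitude(cfg, one_subject("young", "female"),
                                       "unpredictable", classes)
  expect_true(all(a_em[classes == "mastoid"] > a_yf[classes == "mastoid"]))
  expect_equal(a_em[classes == "Fz"], a_yf[classes == "Fz"])  # age_gain Fz = 1
  # null configuration: unpredictable equals predictable
  cfg0 <- small_config(seed = 5, condition_gain = c(Fz = 1, Cz = 1, mastoid = 1))
  expect_equal(
    pepkit:::pep_trial_amplitude(cfg0, one_subject(), "unpredictable", classes),
    pepkit:::pep_trial_amplitude(cfg0, one_subject(), "predictable", classes))
})

test_that("cohort layout: 40 subjects, balanced cells, seeded dropout", {
  cfg <- generator_config(seed = 17)
  plan <- cohort_plan(cfg, prot)
  expect_equal(nrow(plan$subjects), 40L)
  expect_equal(unname(table(plan$subjects$age_group, plan$subjects$sex)),
               matrix(10L, 2, 2))
  expect_equal(nrow(plan$dropout), 40L)
  expect_true(all(plan$dropout$trial_index %in% analyzable_trials(prot)))
  # deterministic layout
  expect_identical(plan, cohort_plan(cfg, prot))

  expect_equal(nrow(cohort_plan(generator_config(seed = 1, dropout_events = 0),
                                prot)$dropout), 0L)
  expect_error(cohort_plan(generator_config(seed = 1, dropout_events = 1300),
                           prot), "exceeds")
})

test_that("simulate_cohort flags exactly the planned incomplete events", {
  cfg <- small_config(seed = 19, dropout_events = 5, n_per_cell = 1)
  ch <- simulate_cohort(cfg, prot)
  expect_length(ch$recordings, 4L)
  expect_equal(sum(lengths(lapply(ch$recordings,
                                  function(r) r$incomplete_trials))), 5L)
  expect_true(all(vapply(ch$recordings,
                         function(r) nrow(r$markers) == 34L, logical(1))))
  # bit-identical manifests under the same config
  ch2 <- simulate_cohort(cfg, prot)
  expect_identical(ch$manifest, ch2$manifest)
  expect_identical(ch$recordings[[2]]$eeg, ch2$recordings[[2]]$eeg)
})

test_that("latencies stay inside 150 ms over many waveform draws", {
  set.seed(20)
  lat <- runif(1000, 90, 140)
  expect_true(all(lat <= 150))
  w <- simulate_pep_waveform(max(lat), 5)
  expect_true(all(w[seq_len(round(max(lat)))] == 0))
})
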