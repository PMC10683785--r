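test_that("a clean burst is localized to within one sample", {
  set.seed(7)
  fs <- 150
  prof <- suppressWarnings(platform_profile())
  burst <- simulate_platform_motion(prof, "posterior")
  acc <- numeric(10 * fs)
  true_onset <- 5.0
  i0 <- round(true_onset * fs) + 1
  acc[i0:(i0 + length(burst) - 1)] <- burst
  acc <- acc + rnorm(length(acc), sd = 0.005)    # mild sensor noise
  det <- detect_onsets(acc, 4.5, onset_detection_spec(), fs)
  expect_true(det$detected)
  expect_lt(abs(det$onset_time_s - true_onset), 1 / fs + 1e-9)
})

test_that("events with no burst are flagged undetected, not dropped", {
  set.seed(8)
  fs <- 150
  acc <- rnorm(10 * fs, sd = 0.01)
  det <- detect_onsets(acc, c(2, 6), onset_detection_spec(), fs)
  expect_equal(nrow(det), 2L)
  expect_false(any(det$detected))
  expect_true(all(is.na(det$onset_time_s)))
})

test_that("an all-zero baseline falls back to the absolute threshold", {
  fs <- 150
  prof <- suppressWarnings(platform_profile())
  burst <- simulate_platform_motion(prof, "anterior")
  acc <- numeric(8 * fs)
  i0 <- round(4.1 * fs) + 1
  acc[i0:(i0 + length(burst) - 1)] <- burst
  det <- detect_onsets(acc, 4, onset_detection_spec(), fs)
  expect_true(det$degenerate_baseline)
  expect_true(det$detected)
  expect_lt(abs(det$onset_time_s - 4.1), 2 / fs)
})

test_that("onset detection is translation-equivariant", {
  fs <- 150
  set.seed(21)
  prof <- suppressWarnings(platform_profile())
  burst <- simulate_platform_motion(prof, "posterior")
  noise <- rnorm(20 * fs, sd = 0.01)
  make <- function(shift_samples) {
    acc <- noise
    i0 <- round(5 * fs) + 1 + shift_samples
    acc[i0:(i0 + length(burst) - 1)] <- acc[i0:(i0 + length(burst) - 1)] + burst
    acc
  }
  d0 <- detect_onsets(make(0), 4.8, onset_detection_spec(), fs)
  d3 <- detect_onsets(make(3), 4.8 + 3 / fs, onset_detection_spec(), fs)
  expect_equal(d3$onset_time_s - d0$onset_time_s, 3 / fs, tolerance = 1e-9)
})

test_that("detector accuracy on simulated sessions: median error < 10 ms, all detected", {
  prot <- build_default_protocol()
  cfg <- small_config(seed = 5)
  errs <- c()
  for (s in 1:3) {                               # 3 subjects x 34 events
    rec <- simulate_subject_recording(one_subject(), prot, cfg, seed = s)
    det <- detect_onsets(rec$acceleration, rec$markers$marker_time_s,
                         onset_detection_spec(), rec$accel_sampling_rate)
    expect_true(all(det$detected))
    errs <- c(errs, abs(det$onset_time_s - rec$true_onset_s))
  }
  expect_length(errs, 102L)
  expect_lt(stats::median(errs) * 1000, 10)
})

test_that("onset times map to the EEG clock by nearest-sample rounding", {
  expect_identical(onset_to_eeg_index(1.234, 1000), 1234L)
  expect_identical(onset_to_eeg_index(0, 1000), 0L)
  expect_identical(onset_to_eeg_index(0.9997, 1000), 1000L)
  expect_error(onset_to_eeg_index(-0.1, 1000), "non-negative")
  expect_error(onset_to_eeg_index(11, 1000, duration_s = 10), "outside")
})

test_that("marker windows outside the recording are rejected", {
  expect_error(
    detect_onsets(rnorm(150), 0.5, onset_detection_spec(), 150),
    "within the recording")
})
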