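fs <- 1000

test_that("epochs are 300 samples with baseline stats from -300..-100 ms", {
  x <- sin(2 * pi * 3 * seq(0, 10, by = 1/fs))
  ep <- extract_epoch(x, onset_offset = 5000, sampling_rate = fs)
  expect_s3_class(ep, "pep_epoch")
  expect_length(ep$samples, 300L)
  expect_equal(ep$state, "raw")
  expect_true(ep$valid)
  base <- x[(5000 - 299):(5000 - 100)]           # half-open window, 200 samples
  expect_equal(ep$baseline_mean, mean(base))
  expect_equal(ep$baseline_sd, sd(base))
  expect_equal(ep$samples, x[5001:5300])
})

test_that("onsets too close to the record edge give invalid epochs", {
  x <- rnorm(2000)
  ep <- extract_epoch(x, onset_offset = 10, sampling_rate = fs)
  expect_false(ep$valid)
  ep2 <- extract_epoch(x, onset_offset = 1900, sampling_rate = fs)
  expect_false(ep2$valid)
})

test_that("a constant baseline invalidates z-correction (degenerate SD)", {
  x <- c(rep(5, 1000), rnorm(1000))
  ep <- extract_epoch(x, onset_offset = 700, sampling_rate = fs)
  expect_equal(ep$baseline_mean, 5)
  expect_equal(ep$baseline_sd, 0)
  expect_warning(ep2 <- detrend_and_baseline_correct(ep), "degenerate")
  expect_false(ep2$valid)
})

test_that("correction removes linear trends and z-scores by the baseline", {
  set.seed(31)
  x <- rnorm(5000)
  ep <- extract_epoch(x, onset_offset = 2000, sampling_rate = fs)
  # replace the epoch with a pure ramp: corrected = -bm/bs + ~0 residual
  ep$samples <- 2 + 0.01 * seq_len(300)
  out <- detrend_and_baseline_correct(ep)
  expect_equal(out$state, "corrected")
  expect_equal(out$samples,
               rep(-ep$baseline_mean / ep$baseline_sd, 300), tolerance = 1e-9)

  # constant epoch equal to the baseline mean maps to exactly -0 after
  # detrending then baseline z-scoring when the baseline mean is zero
  ep$samples <- rep(ep$baseline_mean, 300)
  out2 <- detrend_and_baseline_correct(ep)
  expect_equal(out2$samples + ep$baseline_mean / ep$baseline_sd,
               rep(0, 300), tolerance = 1e-12)

  # state machine: re-correction is rejected
  expect_error(detrend_and_baseline_correct(out), "already corrected")
})

test_that("mean-only correction is available as a switch", {
  set.seed(32)
  x <- rnorm(5000)
  ep <- extract_epoch(x, onset_offset = 2000, sampling_rate = fs)
  out <- detrend_and_baseline_correct(ep, method = "mean")
  d <- ep$samples - mean(ep$samples) -
    stats::lm.fit(cbind(1, seq_len(300)), ep$samples)$coefficients[2] *
    (seq_len(300) - mean(seq_len(300)))
  expect_equal(out$samples, unname(d - ep$baseline_mean), tolerance = 1e-9)
})

test_that("vectorized epoch building equals the per-epoch functions", {
  set.seed(33)
  x <- rnorm(20000)
  y <- rnorm(20000)
  offsets <- c(2000L, 6000L, 11000L, 15000L)
  es <- build_epoch_set(list(a = x, b = y), offsets,
                        trial_index = 1:4,
                        analysis_label = rep("predictable", 4),
                        sampling_rate = fs, subject = one_subject())
  for (i in 1:4) {
    ep <- detrend_and_baseline_correct(
      extract_epoch(x, offsets[i], fs))
    expect_equal(es$samples[["a"]][i, ], ep$samples, tolerance = 1e-12)
    expect_equal(unname(es$baseline_mean[i, "a"]), ep$baseline_mean)
    expect_equal(unname(es$baseline_sd[i, "a"]), ep$baseline_sd)
  }
})

test_that("normalization pins the first epoch's max magnitude to 1", {
  set.seed(34)
  x <- rnorm(30000)
  offsets <- c(2000L, 9000L, 16000L, 23000L)
  es <- build_epoch_set(list(a = x), offsets, 1:4,
                        rep(c("unpredictable", "predictable"), 2),
                        fs, one_subject())
  ns <- normalize_subject_epochs(es)
  expect_equal(ns$state, "normalized")
  expect_equal(max(abs(ns$samples[["a"]][1, ])), 1)
  expect_equal(unname(ns$reference_trial["a"]), 1)
  expect_gt(ns$reference_scale[["a"]], 0)
  # positive scaling preserves ordering of magnitudes
  expect_equal(order(abs(es$samples[["a"]][2, ])),
               order(abs(ns$samples[["a"]][2, ])))
  # idempotence guard
  expect_error(normalize_subject_epochs(ns), "corrected epoch sets")
})

test_that("normalization is invariant to a global amplitude rescale", {
  set.seed(35)
  x <- rnorm(30000)
  offsets <- c(2000L, 9000L, 16000L)
  mk <- function(z) normalize_subject_epochs(
    build_epoch_set(list(a = z), offsets, 1:3,
                    c("unpredictable", "predictable", "predictable"),
                    fs, one_subject()))
  n1 <- mk(x)
  n2 <- mk(2 * x)
  # doubling every raw sample doubles baseline SD and the reference alike
  expect_equal(n1$samples[["a"]], n2$samples[["a"]], tolerance = 1e-12)
})

test_that("a missing first trial substitutes the earliest valid epoch", {
  set.seed(36)
  x <- rnorm(30000)
  offsets <- c(2000L, 9000L, 16000L)
  es <- build_epoch_set(list(a = x), offsets, trial_index = c(1L, 6L, 7L),
                        analysis_label = c("unpredictable", "predictable",
                                           "predictable"),
                        sampling_rate = fs, subject = one_subject(),
                        valid_events = c(FALSE, TRUE, TRUE))
  ns <- normalize_subject_epochs(es)
  expect_equal(unname(ns$reference_trial["a"]), 6)
  expect_equal(max(abs(ns$samples[["a"]][2, ])), 1)
})

test_that("event accounting: planned = analyzed + missing", {
  set.seed(37)
  prot <- build_default_protocol()
  x <- rnorm(300000)
  offsets <- as.integer(seq(2000, by = 9000, length.out = 30))
  mk_set <- function(id, n_invalid) {
    valid <- rep(TRUE, 30)
    if (n_invalid > 0) valid[sample(2:30, n_invalid)] <- FALSE
    es <- build_epoch_set(list(a = x), offsets, analyzable_trials(prot),
                          prot$analysis_label[prot$analysis_label != "excluded"],
                          fs, tibble::tibble(subject_id = id,
                                             age_group = "young",
                                             sex = "male", subject_gain = 1),
                          valid_events = valid)
    normalize_subject_epochs(es)
  }
  sets <- list(mk_set("A", 0), mk_set("B", 3), mk_set("C", 1))
  qc <- qc_accounting(sets, prot)
  expect_equal(qc$planned_events, 90L)
  expect_equal(qc$missing_events, 4L)
  expect_equal(qc$analyzed_events, 86L)
  expect_equal(qc$analyzed_events, qc$planned_events - qc$missing_events)
  expect_equal(qc$per_subject$analyzed, c(30L, 27L, 29L))
})
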