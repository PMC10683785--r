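fs <- 1000
spec <- filter_spec()

test_that("the notch removes a pure 60 Hz sinusoid", {
  t <- seq(0, 4 - 1/fs, by = 1/fs)
  x <- sin(2 * pi * 60 * t)
  for (method in c("fft", "filtfilt")) {
    y <- apply_bandpass_notch(x, spec, fs, method = method)
    # ignore the edge transients of the time-domain route
    core <- y[(fs):(length(y) - fs)]
    expect_lt(compute_rms(core), 0.05 * compute_rms(x))
  }
})

test_that("DC is annihilated and a 10 Hz tone passes at the design gain", {
  y <- apply_bandpass_notch(rep(5, 4000), spec, fs)
  expect_lt(max(abs(y)), 1e-8)

  t <- seq(0, 8 - 1/fs, by = 1/fs)
  x <- sin(2 * pi * 10 * t)
  y <- apply_bandpass_notch(x, spec, fs)
  core <- (fs):(length(y) - fs)
  # zero-phase application realizes the squared single-pass magnitude
  gain_design <- Mod(filter_frequency_response(spec, 10, fs))^2
  measured <- compute_rms(y[core]) / compute_rms(x[core])
  expect_equal(measured, gain_design, tolerance = 1e-3)
  expect_gt(measured, 0.9)                       # within 10% of unity
})

test_that("filtering is linear and shape-preserving", {
  set.seed(11)
  x <- matrix(rnorm(3 * 2000), 3, 2000,
              dimnames = list(c("a", "b", "c"), NULL))
  y1 <- apply_bandpass_notch(x, spec, fs)
  y2 <- apply_bandpass_notch(3.7 * x, spec, fs)
  expect_equal(dim(y1), dim(x))
  expect_equal(y2, 3.7 * y1, tolerance = 1e-10)
  # additivity
  z <- matrix(rnorm(3 * 2000), 3, 2000)
  dimnames(z) <- dimnames(x)
  expect_equal(apply_bandpass_notch(x + z, spec, fs),
               y1 + apply_bandpass_notch(z, spec, fs), tolerance = 1e-10)
})

test_that("frequency-domain and forward-backward routes agree away from edges", {
  set.seed(12)
  n <- 20000
  x <- as.numeric(stats::filter(rnorm(n), rep(1, 5), sides = 1))
  x[is.na(x)] <- 0
  y_fft <- apply_bandpass_notch(x, spec, fs, method = "fft")
  y_ff <- apply_bandpass_notch(x, spec, fs, method = "filtfilt")
  core <- 3000:(n - 3000)
  expect_equal(y_fft[core], y_ff[core], tolerance = 5e-3)
})

test_that("invalid band edges and sampling rates are rejected", {
  expect_error(apply_bandpass_notch(rnorm(100), spec, 50),
               "twice the band-pass upper edge")
  expect_error(filter_spec(bandpass_low = 30, bandpass_high = 10))
  bad <- filter_spec(bandpass_high = 600)
  expect_error(apply_bandpass_notch(rnorm(100), bad, 1000),
               "twice the band-pass upper edge")
})

test_that("mastoid averaging matches direct recomputation", {
  nm <- c("Fz", "Cz", "L5", "L6", "L7", "R5", "R6", "R7")
  eeg <- matrix(0, 8, 100, dimnames = list(nm, NULL))
  eeg[c("L5", "L6", "L7"), ] <- 3
  eeg[c("R5", "R6", "R7"), ] <- 5
  m <- average_mastoid_channels(eeg)
  expect_true(all(m$left == 3))
  expect_true(all(m$right == 5))
  expect_true(all(m$combined == 4))

  set.seed(3)
  eeg[] <- rnorm(length(eeg))
  m <- average_mastoid_channels(eeg)
  expect_equal(m$combined,
               (colMeans(eeg[c("L5", "L6", "L7"), ]) +
                  colMeans(eeg[c("R5", "R6", "R7"), ])) / 2)
  # 3 + 3 channels: two-stage mean equals the grand mean
  expect_equal(m$combined, colMeans(eeg[3:8, ]))

  expect_error(average_mastoid_channels(eeg[1:5, ]), "missing mastoid")
})
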