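#' EEG filter specification
#'
#' Band-pass plus mains-notch filtering applied to the continuous EEG before
#' epoching. The band-pass is a Butterworth design (order `bandpass_order`,
#' pass band `bandpass_low`..`bandpass_high` Hz); the notch is a second-order
#' IIR (biquad) notch at `notch_freq` with quality factor `notch_quality`.
#' Both are applied zero-phase (forward-backward), so the effective
#' attenuation is the squared magnitude response and no group delay is
#' introduced into epoch latencies.
#'
#' @param bandpass_order Butterworth order (per pass).
#' @param bandpass_low,bandpass_high Pass-band edges, Hz.
#' @param notch_freq Notch centre frequency, Hz.
#' @param notch_quality Notch quality factor Q (centre / -3 dB bandwidth).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_order = 2, bandpass_low = 2.5,
                        bandpass_high = 30, notch_freq = 60,
                        notch_quality = 30) {
  stopifnot(bandpass_order >= 1, bandpass_low > 0,
            bandpass_high > bandpass_low, notch_freq > 0, notch_quality > 0)
  structure(list(bandpass_order = as.integer(bandpass_order),
                 bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch_freq = notch_freq, notch_quality = notch_quality),
            class = "filter_spec")
}

# biquad notch coefficients (RBJ audio-EQ cookbook form), normalized a0 = 1
notch_coefficients <- function(freq, quality, sampling_rate) {
  w0 <- 2 * pi * freq / sampling_rate
  alpha <- sin(w0) / (2 * quality)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

butter_coefficients <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (spec$bandpass_high >= nyq) {
    stop("band-pass upper edge must lie below the Nyquist frequency")
  }
  bf <- signal::butter(spec$bandpass_order,
                       c(spec$bandpass_low, spec$bandpass_high) / nyq,
                       type = "pass")
  list(b = bf$b, a = bf$a)
}

# complex single-pass frequency response of B(z)/A(z) at angular freqs w
iir_response <- function(b, a, w) {
  e <- exp(-1i * w)
  horner <- function(coef) { # coef[k] multiplies e^-(k-1)iw
    acc <- rep(coef[length(coef)] + 0i, length(w))
    for (k in rev(seq_len(length(coef) - 1L))) acc <- acc * e + coef[k]
    acc
  }
  horner(b) / horner(a)
}

#' Single-pass frequency response of the combined band-pass + notch design
#'
#' @param spec A [filter_spec].
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @param sampling_rate Sampling rate, Hz.
#' @return Complex response; `Mod()` of it is the single-pass gain
#'   (zero-phase application realizes the square of this magnitude).
#' @export
filter_frequency_response <- function(spec, freqs, sampling_rate) {
  w <- 2 * pi * freqs / sampling_rate
  bp <- butter_coefficients(spec, sampling_rate)
  nc <- notch_coefficients(spec$notch_freq, spec$notch_quality, sampling_rate)
  iir_response(bp$b, bp$a, w) * iir_response(nc$b, nc$a, w)
}

# memo cache for per-length zero-phase gain vectors
.pep_cache <- new.env(parent = emptyenv())

zero_phase_gain <- function(spec, n, sampling_rate) {
  key <- paste("gain", n, sampling_rate, spec$bandpass_order, spec$bandpass_low,
               spec$bandpass_high, spec$notch_freq, spec$notch_quality,
               sep = "|")
  g <- .pep_cache[[key]]
  if (is.null(g)) {
    w <- 2 * pi * (0:(n - 1)) / n
    h <- filter_frequency_response(spec, w * sampling_rate / (2 * pi),
                                   sampling_rate)
    g <- Mod(h)^2
    .pep_cache[[key]] <- g
  }
  g
}

#' Zero-phase band-pass and notch filtering of multi-channel EEG
#'
#' Applies the [filter_spec] design without phase distortion. Two equivalent
#' routes are provided. `method = "fft"` (default) multiplies the discrete
#' spectrum of each channel by the squared magnitude response of the cascade
#' -- the frequency-domain expression of forward-backward filtering, with
#' circular boundary treatment; it is the fast path for long continuous
#' recordings. `method = "filtfilt"` runs [signal::filtfilt()] for the
#' band-pass and the notch in sequence. The two agree away from the record
#' edges; epochs are never taken near the edges.
#'
#' @param eeg Numeric matrix (channels x samples) or a single numeric vector.
#' @param spec A [filter_spec].
#' @param sampling_rate Sampling rate, Hz; must exceed twice the band-pass
#'   upper edge.
#' @param method `"fft"` or `"filtfilt"`.
#' @return Filtered data with the shape of the input.
#' @export
apply_bandpass_notch <- function(eeg, spec, sampling_rate,
                                 method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "filter_spec"), sampling_rate > 0)
  if (sampling_rate <= 2 * spec$bandpass_high) {
    stop("sampling_rate must exceed twice the band-pass upper edge")
  }
  vec_in <- is.null(dim(eeg))
  x <- if (vec_in) matrix(eeg, nrow = 1) else eeg
  out <- if (method == "fft") {
    filter_fft(x, spec, sampling_rate)
  } else {
    filter_filtfilt(x, spec, sampling_rate)
  }
  if (vec_in) drop(out) else {
    dimnames(out) <- dimnames(eeg)
    out
  }
}

filter_fft <- function(x, spec, sampling_rate) {
  n <- ncol(x)
  g <- zero_phase_gain(spec, n, sampling_rate)
  nch <- nrow(x)
  out <- matrix(0, nch, n)
  ch <- 1L
  while (ch <= nch) {
    if (ch + 1L <= nch) {
      z <- stats::fft(complex(real = x[ch, ], imaginary = x[ch + 1L, ]))
      y <- stats::fft(g * z, inverse = TRUE) / n
      out[ch, ] <- Re(y)
      out[ch + 1L, ] <- Im(y)
      ch <- ch + 2L
    } else {
      z <- stats::fft(complex(real = x[ch, ], imaginary = 0))
      out[ch, ] <- Re(stats::fft(g * z, inverse = TRUE)) / n
      ch <- ch + 1L
    }
  }
  out
}

filter_filtfilt <- function(x, spec, sampling_rate) {
  bp <- butter_coefficients(spec, sampling_rate)
  nc <- notch_coefficients(spec$notch_freq, spec$notch_quality, sampling_rate)
  out <- x
  for (ch in seq_len(nrow(x))) {
    y <- signal::filtfilt(bp$b, bp$a, x[ch, ])
    out[ch, ] <- signal::filtfilt(nc$b, nc$a, y)
  }
  out
}

#' Average mastoid (ear) channels
#'
#' Computes the per-ear mean of the three mastoid channels and a combined
#' series. The combined series is the mean of the two per-ear means; with
#' equally sized ear sets this equals the grand mean of all six channels, but
#' the two-stage definition stays balanced for asymmetric montages.
#'
#' @param eeg Numeric matrix (channels x samples) with channel row names.
#' @param channel_map List with character vectors `left` and `right` naming
#'   the mastoid channels on each ear; defaults to the cEEGrid-style montage
#'   `L5`-`L7` / `R5`-`R7`.
#' @return List with numeric vectors `left`, `right`, `combined`.
#' @export
average_mastoid_channels <- function(eeg,
                                     channel_map = list(left = c("L5", "L6", "L7"),
                                                        right = c("R5", "R6", "R7"))) {
  stopifnot(is.matrix(eeg), !is.null(rownames(eeg)))
  missing <- setdiff(c(channel_map$left, channel_map$right), rownames(eeg))
  if (length(missing)) {
    stop("missing mastoid channels: ", paste(missing, collapse = ", "))
  }
  left <- colMeans(eeg[channel_map$left, , drop = FALSE])
  right <- colMeans(eeg[channel_map$right, , drop = FALSE])
  list(left = left, right = right, combined = (left + right) / 2)
}
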