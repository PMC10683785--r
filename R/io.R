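#' Write signals to an EDF file
#'
#' Minimal European Data Format writer supporting one sampling rate per
#' signal (multi-rate sessions store EEG and accelerometer signals side by
#' side). Values are scaled to 16-bit integers over a symmetric physical
#' range per signal, so a round trip quantizes at range/32767.
#'
#' @param path Output file.
#' @param signals Named list of numeric vectors.
#' @param sampling_rates Numeric vector (one per signal), Hz.
#' @param units Character vector of physical dimensions (recycled).
#' @param record_duration Data-record length, seconds; every
#'   `sampling_rate * record_duration` must be a whole number.
#' @param patient,recording_id Free-text header fields.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, signals, sampling_rates, units = "uV",
                      record_duration = 1, patient = "X", recording_id = "X") {
  ns <- length(signals)
  stopifnot(ns >= 1, length(sampling_rates) == ns)
  units <- rep_len(units, ns)
  spr <- sampling_rates * record_duration
  if (any(abs(spr - round(spr)) > 1e-9)) {
    stop("sampling_rate * record_duration must be integer for every signal")
  }
  spr <- as.integer(round(spr))
  durations <- lengths(signals) / sampling_rates
  n_rec <- as.integer(ceiling(max(durations) / record_duration))

  pmax_ <- vapply(signals, function(x) max(abs(x), 1e-6) * 1.0001, numeric(1))
  pad <- function(x, w) {
    x <- substr(format(x, trim = TRUE, scientific = FALSE), 1, w)
    formatC(x, width = w, flag = "-")
  }
  num8 <- function(x) pad(signif(x, 7), 8)

  header <- paste0(
    pad("0", 8), pad(patient, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8),
    num8(record_duration), pad(ns, 4),
    paste(pad(names(signals), 16), collapse = ""),
    paste(pad(rep("", ns), 80), collapse = ""),
    paste(pad(units, 8), collapse = ""),
    paste(num8(-pmax_), collapse = ""),
    paste(num8(pmax_), collapse = ""),
    paste(pad(rep(-32767L, ns), 8), collapse = ""),
    paste(pad(rep(32767L, ns), 8), collapse = ""),
    paste(pad(rep("", ns), 80), collapse = ""),
    paste(pad(spr, 8), collapse = ""),
    paste(pad(rep("", ns), 32), collapse = ""))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  digital <- lapply(seq_len(ns), function(i) {
    x <- signals[[i]]
    x <- c(x, numeric(n_rec * spr[i] - length(x)))      # zero-pad tail
    as.integer(round(x / pmax_[i] * 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @return List with `signals` (named list of numeric vectors in physical
#'   units), `sampling_rates`, `record_duration`, `patient`,
#'   `recording_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8)                               # version
  patient <- rd(80)
  recording_id <- rd(80)
  rd(8); rd(8)                        # date, time
  rd(8); rd(44)                       # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  raw_sig <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      raw_sig[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    (raw_sig[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i]
  })
  names(signals) <- labels
  list(signals = signals, sampling_rates = spr / rec_dur,
       record_duration = rec_dur, units = units, patient = patient,
       recording_id = recording_id)
}

#' Read a BrainVision session (.vhdr / .eeg / .vmrk)
#'
#' Supports the common layout: binary multiplexed data in INT_16 or
#' IEEE_FLOAT_32, channel resolutions from the header, markers from the
#' .vmrk file.
#'
#' @param vhdr Path to the .vhdr header file.
#' @return List with `eeg` (channels x samples matrix, physical units),
#'   `sampling_rate`, `channels`, `markers` (tibble: `marker`, `type`,
#'   `description`, `position` sample index, 1-based).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    if (is.na(ln)) stop("BrainVision header lacks ", key)
    sub(paste0("^", key, "="), "", ln)
  }
  data_file <- file.path(dirname(vhdr), get("DataFile"))
  marker_file <- file.path(dirname(vhdr), get("MarkerFile"))
  n_ch <- as.integer(get("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get("SamplingInterval"))
  fmt <- get("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channels <- vapply(ch_parts, `[`, character(1), 1)
  resolution <- vapply(ch_parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  sz <- file.info(data_file)$size
  if (fmt == "INT_16") {
    n <- sz / 2
    raw <- readBin(data_file, "integer", n, size = 2, endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw <- readBin(data_file, "numeric", n, size = 4, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  eeg <- matrix(raw, nrow = n_ch)            # multiplexed: channels fastest
  eeg <- eeg * resolution
  rownames(eeg) <- channels

  if (!file.exists(marker_file)) {
    stop("marker stream missing: expected ", marker_file,
         "; supply a .vmrk file with the event markers")
  }
  mlines <- grep("^Mk[0-9]+=", readLines(marker_file, warn = FALSE),
                 value = TRUE)
  mparts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
  markers <- tibble::tibble(
    marker = seq_along(mparts),
    type = vapply(mparts, `[`, character(1), 1),
    description = vapply(mparts, `[`, character(1), 2),
    position = vapply(mparts, function(p) as.integer(p[3]), integer(1)))
  list(eeg = eeg, sampling_rate = fs, channels = channels, markers = markers)
}

#' Ingest a real session into the pipeline's recording model
#'
#' Maps an EDF or BrainVision session onto the `pep_recording` structure.
#' EDF sessions carry markers as a TTL pulse channel (any channel named
#' `TTL`, `Trigger` or `Status`; rising edges become markers) and may carry
#' the platform accelerometer as a channel named `ACC`. BrainVision
#' sessions take markers from the .vmrk file; they carry no accelerometer,
#' so onset detection needs an externally attached acceleration trace.
#' Ground-truth fields stay empty. Required EEG channels that cannot be
#' mapped abort the ingest naming the missing channel.
#'
#' @param path EDF file or BrainVision .vhdr.
#' @param format `"edf"` or `"brainvision"`.
#' @param required_channels Channels that must be present.
#' @param subject Optional one-row data frame of subject metadata.
#' @return A `pep_recording` (with `acceleration = NULL` when the session
#'   carries none); `unmapped_channels` lists channels not used.
#' @export
ingest_real_session <- function(path, format = c("edf", "brainvision"),
                                required_channels = c("Fz", "Cz", "L5", "L6",
                                                      "L7", "R5", "R6", "R7"),
                                subject = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    edf <- read_edf(path)
    chans <- names(edf$signals)
    missing <- setdiff(required_channels, chans)
    if (length(missing)) {
      stop("ingest failure: EEG channel(s) missing from ", path, ": ",
           paste(missing, collapse = ", "))
    }
    ttl_name <- intersect(c("TTL", "Trigger", "Status"), chans)[1]
    if (is.na(ttl_name)) {
      stop("ingest failure: no marker stream; expected a TTL/Trigger ",
           "channel carrying the synchronization pulses")
    }
    fs <- edf$sampling_rates[match(required_channels[1], chans)]
    eeg <- do.call(rbind, edf$signals[required_channels])
    rownames(eeg) <- required_channels
    ttl <- edf$signals[[ttl_name]]
    fs_ttl <- edf$sampling_rates[match(ttl_name, chans)]
    thr <- max(ttl) / 2
    edges <- which(ttl[-1] > thr & ttl[-length(ttl)] <= thr) + 1L
    markers <- tibble::tibble(trial_index = seq_along(edges),
                              marker_time_s = (edges - 1) / fs_ttl,
                              marker_sample = as.integer(
                                round((edges - 1) / fs_ttl * fs)))
    acc_name <- intersect(c("ACC", "Accel"), chans)[1]
    accel <- if (!is.na(acc_name)) edf$signals[[acc_name]]
    fs_a <- if (!is.na(acc_name)) edf$sampling_rates[match(acc_name, chans)]
    unmapped <- setdiff(chans, c(required_channels, ttl_name, acc_name))
    subj <- subject %||% tibble::tibble(subject_id = edf$patient,
                                        age_group = NA_character_,
                                        sex = NA_character_, subject_gain = NA_real_)
    rec <- structure(list(subject = subj, eeg = eeg, eeg_sampling_rate = fs,
                          acceleration = accel, accel_sampling_rate = fs_a,
                          markers = markers, true_onset_s = NULL,
                          true_latency_ms = NULL,
                          incomplete_trials = integer(0)),
                     class = "pep_recording")
  } else {
    bv <- read_brainvision(path)
    missing <- setdiff(required_channels, bv$channels)
    if (length(missing)) {
      stop("ingest failure: EEG channel(s) missing from ", path, ": ",
           paste(missing, collapse = ", "))
    }
    markers <- tibble::tibble(
      trial_index = seq_len(nrow(bv$markers)),
      marker_time_s = (bv$markers$position - 1) / bv$sampling_rate,
      marker_sample = bv$markers$position - 1L)
    subj <- subject %||% tibble::tibble(subject_id = basename(path),
                                        age_group = NA_character_,
                                        sex = NA_character_, subject_gain = NA_real_)
    rec <- structure(list(subject = subj,
                          eeg = bv$eeg[required_channels, , drop = FALSE],
                          eeg_sampling_rate = bv$sampling_rate,
                          acceleration = NULL, accel_sampling_rate = NULL,
                          markers = markers, true_onset_s = NULL,
                          true_latency_ms = NULL,
                          incomplete_trials = integer(0)),
                     class = "pep_recording")
    unmapped <- setdiff(bv$channels, required_channels)
  }
  attr(rec, "unmapped_channels") <- unmapped
  rec
}

#' Write / read a synthetic session directory
#'
#' On-disk session layout: `eeg.edf` holding the EEG channels plus a `TTL`
#' marker-pulse channel at the EEG rate and the platform accelerometer as an
#' `ACC` signal at its own rate, and `sidecar.json` with the subject
#' profile, markers, ground truth and incomplete-trial flags.
#'
#' @param recording A `pep_recording`.
#' @param dir Session directory (created).
#' @return `write_session` invisibly returns `dir`; `read_session` returns
#'   a `pep_recording` (signals equal to the originals within EDF 16-bit
#'   quantization).
#' @export
write_session <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- recording$eeg_sampling_rate
  n <- ncol(recording$eeg)
  ttl <- numeric(n)
  for (s in recording$markers$marker_sample) {
    ttl[(s + 1):min(n, s + round(0.01 * fs))] <- 1
  }
  signals <- c(stats::setNames(
    lapply(seq_len(nrow(recording$eeg)), function(i) recording$eeg[i, ]),
    rownames(recording$eeg)),
    list(TTL = ttl, ACC = recording$acceleration))
  write_edf(file.path(dir, "eeg.edf"), signals,
            sampling_rates = c(rep(fs, nrow(recording$eeg)), fs,
                               recording$accel_sampling_rate),
            units = c(rep("uV", nrow(recording$eeg)), "logic", "m/s2"),
            patient = recording$subject$subject_id)
  sidecar <- list(subject = recording$subject,
                  eeg_sampling_rate = fs,
                  accel_sampling_rate = recording$accel_sampling_rate,
                  markers = recording$markers,
                  true_onset_s = recording$true_onset_s,
                  true_latency_ms = recording$true_latency_ms,
                  incomplete_trials = recording$incomplete_trials)
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  edf <- read_edf(file.path(dir, "eeg.edf"))
  ch <- setdiff(names(edf$signals), c("TTL", "ACC"))
  eeg <- do.call(rbind, edf$signals[ch])
  rownames(eeg) <- ch
  structure(list(subject = tibble::as_tibble(side$subject),
                 eeg = eeg, eeg_sampling_rate = side$eeg_sampling_rate,
                 acceleration = edf$signals$ACC,
                 accel_sampling_rate = side$accel_sampling_rate,
                 markers = tibble::as_tibble(side$markers),
                 true_onset_s = side$true_onset_s,
                 true_latency_ms = side$true_latency_ms,
                 incomplete_trials = as.integer(side$incomplete_trials %||%
                                                  integer(0))),
            class = "pep_recording")
}

#' Write a whole synthetic cohort to disk
#'
#' One directory per subject ([write_session()]) plus a root
#' `manifest.json` recording the seed, configuration, subject table and
#' dropout assignment. Two runs with the same configuration produce
#' bit-identical manifests.
#'
#' @param cohort A `pep_cohort` from [simulate_cohort()].
#' @param dir Root directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pep_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    write_session(rec, file.path(dir, rec$subject$subject_id))
  }
  man <- cohort$manifest
  man$config$platform <- unclass(man$config$platform)
  man$config <- unclass(man$config)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
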