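# Minimal EDF (European Data Format, 16-bit) reader/writer.
#
# Only the standard continuous layout is handled: an ASCII header of
# 256 + 256*ns bytes followed by data records of little-endian int16 samples,
# one block per signal per record. This covers scalp-EEG corpora such as
# CHB-MIT (23 channels, 256 Hz). Physical values are reconstructed with the
# per-signal linear gain/offset from the header.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) edf_pad(trimws(formatC(x, format = "fg", digits = 7)), width)

read_chunk <- function(con, n, width) {
  raw <- readChar(con, n * width, useBytes = TRUE)
  trimws(substring(raw, (seq_len(n) - 1L) * width + 1L, seq_len(n) * width))
}

#' Read an EDF file into a recording
#'
#' Reads a 16-bit EDF file and returns an [new_recording()] object with
#' channels in file order and physical units restored from the header
#' calibration. All signals must share one sampling rate; files mixing rates
#' (e.g. an extra low-rate annotation channel) are rejected with an error
#' naming the offending channels.
#'
#' @param path path to an EDF file.
#' @return an `eeg_recording`.
#' @seealso [write_edf()], [read_annotations()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_seizr(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  version <- trimws(readChar(con, 8, useBytes = TRUE))
  if (!identical(version, "0")) {
    stop_seizr(sprintf("unsupported EDF version field: '%s'", version))
  }
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)          # patient/recording ids, date, time
  header_bytes <- as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  readChar(con, 44, useBytes = TRUE)                        # reserved
  n_records <- as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  record_dur <- as.numeric(trimws(readChar(con, 8, useBytes = TRUE)))
  ns <- as.integer(trimws(readChar(con, 4, useBytes = TRUE)))
  if (is.na(ns) || ns < 1L) stop_seizr("EDF header: invalid signal count")
  if (is.na(header_bytes) || header_bytes != 256L + 256L * ns) {
    stop_seizr("EDF header: inconsistent header size")
  }

  labels <- read_chunk(con, ns, 16)
  read_chunk(con, ns, 80)                                   # transducer
  read_chunk(con, ns, 8)                                    # physical dimension
  phys_min <- as.numeric(read_chunk(con, ns, 8))
  phys_max <- as.numeric(read_chunk(con, ns, 8))
  dig_min <- as.numeric(read_chunk(con, ns, 8))
  dig_max <- as.numeric(read_chunk(con, ns, 8))
  read_chunk(con, ns, 80)                                   # prefiltering
  nr <- as.integer(read_chunk(con, ns, 8))                  # samples per record
  read_chunk(con, ns, 32)                                   # reserved

  fs_all <- nr / record_dur
  if (length(unique(fs_all)) != 1L) {
    bad <- labels[fs_all != fs_all[[1]]]
    stop_seizr(sprintf(
      "EDF signals have mixed sampling rates; channels at odds with '%s': %s",
      labels[[1]], paste(bad, collapse = ", ")
    ))
  }
  fs <- fs_all[[1]]

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - scale * dig_min

  data <- matrix(0, nrow = ns, ncol = n_records * nr[[1]])
  for (rec_i in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nr[[sig]], size = 2,
                      signed = TRUE, endian = "little")
      cols <- ((rec_i - 1L) * nr[[sig]] + 1L):(rec_i * nr[[sig]])
      data[sig, cols] <- scale[[sig]] * vals + offset[[sig]]
    }
  }

  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  new_recording(data, fs = fs, labels = labels)
}

#' Write a recording to an EDF file
#'
#' Writes a 16-bit EDF file with one-second data records (padding the last
#' partial second with zeros is avoided by truncating to whole records).
#' Each channel is calibrated to its own physical range, so the round-trip
#' error through [read_edf()] is at most one digitization step,
#' `(max - min) / 65535` per channel.
#'
#' @param rec an [new_recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  record_dur <- 1
  nr <- rec$fs * record_dur
  if (abs(nr - round(nr)) > 1e-9) {
    stop_seizr("write_edf requires an integer number of samples per second")
  }
  nr <- as.integer(round(nr))
  n_records <- floor(ncol(rec$data) / nr)
  if (n_records < 1) stop_seizr("recording shorter than one data record")

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(edf_pad("0", 8), con, eos = NULL)
  writeChar(edf_pad("X X X X", 80), con, eos = NULL)
  writeChar(edf_pad("Startdate X X X X", 80), con, eos = NULL)
  writeChar(edf_pad("01.01.00", 8), con, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, eos = NULL)
  writeChar(edf_num(256 + 256 * ns, 8), con, eos = NULL)
  writeChar(edf_pad("", 44), con, eos = NULL)
  writeChar(edf_num(n_records, 8), con, eos = NULL)
  writeChar(edf_num(record_dur, 8), con, eos = NULL)
  writeChar(edf_num(ns, 4), con, eos = NULL)

  writeChar(paste(edf_pad(rec$labels, 16), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(rep("uV", ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_num(signif(phys_min, 7), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_num(signif(phys_max, 7), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_num(dig_min, 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_num(dig_max, 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(rep("", ns), 80), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_num(rep(nr, ns), 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(rep("", ns), 32), collapse = ""), con, eos = NULL)

  # Header floats are truncated to 8 ASCII chars; recompute the gains actually
  # stored so writer and reader agree to quantization precision.
  pm_lo <- as.numeric(edf_num(signif(phys_min, 7), 8))
  pm_hi <- as.numeric(edf_num(signif(phys_max, 7), 8))
  scale <- (pm_hi - pm_lo) / (dig_max - dig_min)

  for (rec_i in seq_len(n_records)) {
    cols <- ((rec_i - 1L) * nr + 1L):(rec_i * nr)
    for (sig in seq_len(ns)) {
      dig <- round((rec$data[sig, cols] - pm_lo[[sig]]) / scale[[sig]]) + dig_min[[sig]]
      dig <- pmin(pmax(dig, dig_min[[sig]]), dig_max[[sig]])
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
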