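#' Write a recording to an EDF file
#'
#' Writes a 16-bit European Data Format file (one data record per second,
#' physical units microvolts). The physical range is set per channel from the
#' data range so quantization error is below 2^-15 of the signal span.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  fs <- recording$fs
  if (fs != round(fs))
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  ns <- nrow(x)
  # whole seconds only; trailing partial second dropped
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)", call. = FALSE)
  x <- x[, seq_len(n_rec * fs), drop = FALSE]

  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    sprintf(paste0("%-", n, "s"), s)
  }
  phys_min <- apply(x, 1, min)
  phys_max <- apply(x, 1, max)
  span <- phys_max - phys_min
  phys_min <- phys_min - pmax(span, 1) * 0.01 - 1e-6
  phys_max <- phys_max + pmax(span, 1) * 0.01 + 1e-6
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(paste("X X X", recording$subject_id), 80),
    pad(paste("Startdate 01-JAN-2000", recording$subject_id), 80),
    "01.01.00", "00.00.00",
    pad(256 * (1 + ns), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad("1", 8),
    pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad, "", n = width), collapse = ""),
              con, eos = NULL)
  field(recording$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(sprintf("%.6g", phys_min), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] - phys_min[ch]) * scale[ch]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads 16-bit EDF files in which all signals share one sampling rate
#' (the only layout this package writes and consumes). Channel labels are
#' trimmed; physical values are reconstructed from the per-signal
#' physical/digital ranges.
#'
#' @param path EDF file path.
#' @param subject_id Optional subject id; defaults to the recording field.
#' @return An [eeg_recording()] with provenance `"edf"`.
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdf <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- rdf(16)
  rdf(80)
  rdf(8)
  phys_min <- as.numeric(rdf(8))
  phys_max <- as.numeric(rdf(8))
  dig_min <- as.numeric(rdf(8))
  dig_max <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8))
  rdf(32)
  if (length(unique(spr)) != 1)
    stop("EDF signals with heterogeneous sampling rates are not supported",
         call. = FALSE)
  fs <- spr[1] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      x[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        phys_min[ch] + (dig - dig_min[ch]) * scale[ch]
    }
  }
  if (is.null(subject_id)) {
    parts <- strsplit(patient, " +")[[1]]
    subject_id <- if (length(parts) >= 4) parts[4] else "edf_subject"
  }
  eeg_recording(x, labels, fs, subject_id = subject_id, provenance = "edf")
}
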