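#' Standardize a recording for cross-site analysis
#'
#' Harmonizes recordings from heterogeneous acquisition setups: resamples to
#' 256 Hz, band-pass filters 0.1-45 Hz with zero-phase (forward-backward)
#' Butterworth filters, and re-references to the common average. Recordings
#' sampled below 256 Hz are rejected, matching the minimum acquisition
#' standard of the harmonized protocol.
#'
#' @param recording An [eeg_recording()], `fs >= 256`, at least 2 channels.
#' @param montage Optional montage name; if given, channel labels are checked
#'   (case-insensitively) against [montage_positions()].
#' @return An [eeg_recording()] at 256 Hz, filtered and average-referenced.
#' @export
standardize_recording <- function(recording, montage = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$fs < 256)
    stop("sampling rate ", recording$fs,
         " Hz is below the 256 Hz minimum standard", call. = FALSE)
  if (nrow(recording$data) < 2)
    stop("at least 2 channels required", call. = FALSE)
  if (!is.null(montage)) {
    want <- tolower(montage_positions(montage)$label)
    have <- tolower(recording$channel_labels)
    missing <- setdiff(want, have)
    if (length(missing) > 0)
      stop("channels missing from declared montage: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  x <- recording$data
  fs <- recording$fs
  if (fs != 256) {
    if (fs %% 256 == 0) {
      # integer factor: zero-phase anti-alias then subsample, which keeps
      # passband amplitudes exact
      m <- fs %/% 256
      aa <- signal::butter(8, 0.8 * 128 / (fs / 2), type = "low")
      x <- t(apply(x, 1, function(ch) signal::filtfilt(aa, ch)))
      x <- x[, seq(1, ncol(x), by = m), drop = FALSE]
    } else {
      rat <- .rational_ratio(256 / fs)
      x <- t(apply(x, 1, function(ch) signal::resample(ch, rat[1], rat[2])))
    }
    fs <- 256
  }
  # zero-phase band-pass: 2nd-order high-pass at 0.1 Hz and 10th-order
  # low-pass at 45 Hz, each applied forward-backward
  hp <- signal::butter(2, 0.1 / (fs / 2), type = "high")
  lp <- signal::butter(10, 45 / (fs / 2), type = "low")
  x <- t(apply(x, 1, function(ch) {
    ch <- signal::filtfilt(hp, ch)
    signal::filtfilt(lp, ch)
  }))
  # common average reference
  x <- sweep(x, 2, colMeans(x))
  eeg_recording(x, recording$channel_labels, fs,
                subject_id = recording$subject_id,
                provenance = recording$provenance,
                ground_truth = recording$ground_truth)
}

.rational_ratio <- function(r, max_den = 64) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), as.integer(q)) }
  }
  if (err > 1e-9)
    stop("cannot resample: 256/fs is not a small rational ratio", call. = FALSE)
  best
}

#' Split a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs; a trailing
#' partial epoch is discarded. At the standard 256 Hz a 2-s epoch holds
#' exactly 512 samples, so 5 minutes of recording yields 150 epochs.
#'
#' @param recording A standardized [eeg_recording()].
#' @param epoch_length Epoch duration in seconds (default 2).
#' @return An `eeg_epochs` object: `data` is an n_epochs x channels x samples
#'   array; `kept_mask` tracks survivors of later screening.
#' @export
epoch_recording <- function(recording, epoch_length = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  spe <- round(recording$fs * epoch_length)
  n <- floor(ncol(recording$data) / spe)
  if (n < 1)
    stop("recording (", round(recording_duration(recording), 2),
         " s) shorter than one epoch (", epoch_length, " s)", call. = FALSE)
  a <- array(0, dim = c(n, nrow(recording$data), spe))
  for (e in seq_len(n))
    a[e, , ] <- recording$data[, ((e - 1) * spe + 1):(e * spe)]
  structure(
    list(subject_id = recording$subject_id,
         channel_labels = recording$channel_labels,
         data = a, fs = recording$fs, epoch_length = epoch_length,
         kept_mask = rep(TRUE, n),
         ground_truth = recording$ground_truth),
    class = "eeg_epochs"
  )
}

#' Epoch screening criteria
#'
#' Thresholds for the programmatic artifact screen standing in for expert
#' visual scoring: peak-to-peak amplitude, epoch-variance z-score, and a
#' high-frequency (EMG proxy) power-ratio criterion on the 30-45 Hz over
#' 1-30 Hz band power (the standardized data are low-passed at 45 Hz, so
#' the EMG band is truncated there).
#'
#' @param a_max Maximum peak-to-peak amplitude on any channel, microvolts.
#' @param z_max Maximum z-score of the epoch's mean channel variance relative
#'   to the subject's epoch distribution.
#' @param r_max Maximum 30-45/1-30 Hz power ratio, expressed as a multiple of
#'   the subject's median epoch ratio.
#' @return A list of thresholds for [reject_epochs()].
#' @export
reject_criteria <- function(a_max = 100, z_max = 3, r_max = 2) {
  stopifnot(a_max > 0, z_max > 0, r_max > 0)
  list(a_max = a_max, z_max = z_max, r_max = r_max)
}

#' Screen epochs for artifacts
#'
#' Removes epochs failing any of the [reject_criteria()]. The kept fraction
#' is recorded on the result and a warning is raised when it drops below
#' 75%, the study's minimum acceptable share of artifact-free data.
#'
#' @param epochs An `eeg_epochs` object.
#' @param criteria A [reject_criteria()] list.
#' @return The epochs object with rejected epochs dropped, `kept_mask`
#'   updated, and attributes `kept_fraction` and `rejection_counts`.
#' @export
reject_epochs <- function(epochs, criteria = reject_criteria()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- dim(epochs$data)[1]
  if (n < 1) stop("no epochs to screen", call. = FALSE)

  ptp <- vapply(seq_len(n), function(e) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    max(apply(m, 1, function(ch) diff(range(ch))))
  }, 0)
  fail_amp <- ptp > criteria$a_max

  v <- vapply(seq_len(n), function(e) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    mean(apply(m, 1, var))
  }, 0)
  z <- if (n > 1 && sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, n)
  fail_var <- z > criteria$z_max

  ratio <- vapply(seq_len(n), function(e) {
    m <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    p <- .epoch_band_power(m, epochs$fs)
    p["high"] / p["low"]
  }, 0)
  med <- median(ratio)
  fail_emg <- if (is.finite(med) && med > 0)
    ratio > criteria$r_max * med else rep(FALSE, n)

  fail <- fail_amp | fail_var | fail_emg
  if (all(fail)) {
    counts <- c(amplitude = sum(fail_amp), variance = sum(fail_var),
                emg = sum(fail_emg))
    stop("all epochs rejected; dominating criterion: ",
         names(which.max(counts)), call. = FALSE)
  }
  keep <- !fail
  kept_fraction <- mean(keep)
  if (kept_fraction < 0.75)
    warning(sprintf("subject %s: only %.0f%% of epochs kept (< 75%%)",
                    epochs$subject_id, 100 * kept_fraction), call. = FALSE)

  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$kept_mask <- epochs$kept_mask
  out$kept_mask[epochs$kept_mask] <- keep
  attr(out, "kept_fraction") <- kept_fraction
  attr(out, "rejection_counts") <- c(amplitude = sum(fail_amp),
                                     variance = sum(fail_var),
                                     emg = sum(fail_emg))
  out
}

# mean channel power in the 30-45 ("high") and 1-30 Hz ("low") ranges of a
# single epoch, via the raw periodogram
.epoch_band_power <- function(m, fs) {
  ns <- ncol(m)
  f <- (seq_len(ns) - 1) * fs / ns
  p <- abs(stats::mvfft(t(m)))^2
  lo <- f >= 1 & f < 30
  hi <- f >= 30 & f <= 45
  c(low = mean(p[lo, ]), high = mean(p[hi, ]))
}
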