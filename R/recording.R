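#' Construct an EEG recording object
#'
#' A recording bundles a channels-by-samples voltage matrix (microvolts) with
#' its montage labels, sampling rate and optional subject metadata. Synthetic
#' recordings additionally carry their generating ground-truth profile, which
#' the analysis stages never read.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param provenance `"synthetic"` or `"edf"`.
#' @param ground_truth Optional list: the generating subject profile.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, fs, subject_id = "s1",
                          provenance = c("synthetic", "edf"),
                          ground_truth = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (nrow(data) != length(channel_labels))
    stop("channel count (", nrow(data), ") != label count (",
         length(channel_labels), ")", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples", call. = FALSE)
  structure(
    list(subject_id = subject_id,
         channel_labels = as.character(channel_labels),
         fs = fs,
         data = data,
         provenance = provenance,
         ground_truth = ground_truth),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, ": ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 1), " s, ", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", x$subject_id, ": ", dim(x$data)[1], " epochs x ",
      dim(x$data)[2], " channels x ", dim(x$data)[3], " samples @ ",
      x$fs, " Hz (", x$epoch_length, " s epochs)\n", sep = "")
  invisible(x)
}

recording_duration <- function(recording) ncol(recording$data) / recording$fs
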