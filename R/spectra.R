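#' Welch power spectral density of epoched EEG
#'
#' Computes the per-channel power spectral density as the average over epochs
#' of Hann-windowed periodograms, one segment per 2-s epoch (512 samples at
#' 256 Hz gives exactly the 0.5 Hz analysis resolution). Periodograms are
#' corrected for the window power so white-noise levels are unbiased. The
#' grid is restricted to 0.5-45 Hz.
#'
#' @param epochs An `eeg_epochs` object with at least one kept epoch.
#' @return An `eeg_psd` object with fields `freq` (Hz), `psd`
#'   (channels x bins, uV^2/Hz), and `global_psd` (mean over channels).
#' @export
welch_psd <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("no kept epochs", call. = FALSE)
  ns <- d[3]
  df <- epochs$fs / ns
  if (abs(df - 0.5) > 1e-9)
    stop("epoch length incompatible with the 0.5 Hz resolution: ",
         "fs/samples = ", signif(df, 4), " Hz", call. = FALSE)
  cs <- .cross_spectra_core(epochs)
  keep <- cs$keep_bins
  psd <- t(vapply(seq_len(d[2]),
                  function(ch) Re(cs$csd[ch, ch, ]), numeric(sum(keep))))
  structure(
    list(subject_id = epochs$subject_id,
         channel_labels = epochs$channel_labels,
         freq = cs$freq,
         psd = psd,
         global_psd = colMeans(psd)),
    class = "eeg_psd"
  )
}

#' Per-bin sensor cross-spectral matrices
#'
#' For every 0.5 Hz bin in 0.5-45 Hz, the Hermitian channel cross-spectral
#' matrix averaged over Hann-windowed epoch FFTs, scaled identically to
#' [welch_psd()] so that its diagonal equals the Welch PSD bin-by-bin. This
#' is the sensor-level input to the inverse solution: source power from a
#' linear spatial filter requires the full covariance, not only the PSD
#' diagonal.
#'
#' @param epochs An `eeg_epochs` object with at least 2 channels.
#' @return An `eeg_csd` object: `csd` is a channels x channels x bins complex
#'   array, `freq` the bin centers in Hz.
#' @export
sensor_cross_spectra <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[2] < 2)
    stop("cross-spectra require at least 2 channels", call. = FALSE)
  cs <- .cross_spectra_core(epochs)
  structure(
    list(subject_id = epochs$subject_id,
         channel_labels = epochs$channel_labels,
         freq = cs$freq, csd = cs$csd),
    class = "eeg_csd"
  )
}

.cross_spectra_core <- function(epochs) {
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; ns <- d[3]
  fs <- epochs$fs
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(ns - 1)) / ns)  # periodic Hann
  u <- sum(w^2)
  f_all <- (0:(ns / 2)) * fs / ns
  keep <- f_all >= 0.5 - 1e-9 & f_all <= 45 + 1e-9
  idx <- which(keep)
  csd <- array(0 + 0i, dim = c(n_ch, n_ch, length(idx)))
  for (e in seq_len(n_ep)) {
    m <- matrix(epochs$data[e, , ], nrow = n_ch)
    xf <- stats::mvfft(t(m * rep(w, each = n_ch)))   # ns x n_ch
    xf <- xf[idx, , drop = FALSE]
    # one-sided scaling with window-power correction
    sc <- sqrt(2 / (fs * u))
    xf <- xf * sc
    for (b in seq_along(idx))
      csd[, , b] <- csd[, , b] + tcrossprod(xf[b, ], Conj(xf[b, ]))
  }
  list(freq = f_all[idx], csd = csd / n_ep, keep_bins = keep)
}

#' Detect per-subject frequency landmarks
#'
#' The transition frequency (TF) is the frequency of the minimum of the
#' channel-mean power density between 3 and 8 Hz; the individual alpha
#' frequency (IAF) is the frequency of the maximum local power-density peak
#' between 6 and 14 Hz. When no interior local peak exists in 6-14 Hz, the
#' plain maximum is used and the `no_peak` flag is set; `boundary_hit` marks
#' extrema sitting on a search-range edge; `invalid` is set when TF >= IAF
#' (no valid alpha partition).
#'
#' @param spectrum An `eeg_psd` object (grid must cover 3-14 Hz) or a
#'   numeric spectrum with a `freq` attribute.
#' @param channels Optional channel subset (labels) on which to average the
#'   spectrum instead of the global mean, e.g. a posterior subset.
#' @return A one-row tibble: `subject_id`, `tf`, `iaf`, logical flags
#'   `no_minimum`, `no_peak`, `boundary_hit`, `invalid`.
#' @export
detect_landmarks <- function(spectrum, channels = NULL) {
  stopifnot(inherits(spectrum, "eeg_psd"))
  freq <- spectrum$freq
  g <- if (is.null(channels)) {
    spectrum$global_psd
  } else {
    sel <- match(tolower(channels), tolower(spectrum$channel_labels))
    if (anyNA(sel))
      stop("unknown channels: ",
           paste(channels[is.na(sel)], collapse = ", "), call. = FALSE)
    colMeans(spectrum$psd[sel, , drop = FALSE])
  }
  if (!all(is.finite(g))) stop("non-finite spectrum", call. = FALSE)
  if (min(freq) > 3 || max(freq) < 14)
    stop("frequency grid must cover 3-14 Hz", call. = FALSE)

  tf_win <- which(freq >= 3 - 1e-9 & freq <= 8 + 1e-9)
  i_tf <- tf_win[which.min(g[tf_win])]
  tf <- freq[i_tf]

  iaf_win <- which(freq >= 6 - 1e-9 & freq <= 14 + 1e-9)
  interior <- iaf_win[iaf_win > 1 & iaf_win < length(g)]
  is_peak <- vapply(interior,
                    function(i) g[i] > g[i - 1] && g[i] >= g[i + 1],
                    logical(1))
  peaks <- interior[is_peak]
  no_peak <- length(peaks) == 0
  i_iaf <- if (no_peak) iaf_win[which.max(g[iaf_win])]
           else peaks[which.max(g[peaks])]
  iaf <- freq[i_iaf]

  boundary_hit <- i_tf == tf_win[1] || i_tf == tf_win[length(tf_win)] ||
    i_iaf == iaf_win[1] || i_iaf == iaf_win[length(iaf_win)]

  tibble::tibble(
    subject_id = spectrum$subject_id,
    tf = tf, iaf = iaf,
    no_minimum = FALSE,
    no_peak = no_peak,
    boundary_hit = boundary_hit,
    invalid = tf >= iaf
  )
}

#' Individualized frequency-band scheme
#'
#' Builds the eight analysis bands from a subject's TF and IAF: delta
#' \[TF-4, TF-2), theta \[TF-2, TF), alpha1 \[TF, mid), alpha2 \[mid, IAF)
#' with mid the TF-IAF midpoint, alpha3 \[IAF, IAF+2), and the fixed bands
#' beta1 \[14, 20), beta2 \[20, 30), gamma \[30, 40). All intervals are
#' half-open \[low, high): a spectral bin belongs to the band whose interval
#' contains its center frequency. When TF-4 falls below the 0.5 Hz analysis
#' floor the delta low edge is clipped there and flagged.
#'
#' @param landmarks A one-row data frame from [detect_landmarks()], or `NULL`
#'   if `tf` and `iaf` are given directly.
#' @param tf,iaf Landmarks in Hz (alternative to `landmarks`).
#' @return A tibble with columns `band`, `low`, `high` (Hz), 8 rows in
#'   canonical band order; attribute `delta_clipped` records edge clipping.
#' @examples
#' individual_band_scheme(tf = 6, iaf = 10)
#' @export
individual_band_scheme <- function(landmarks = NULL, tf = NULL, iaf = NULL) {
  if (!is.null(landmarks)) {
    tf <- landmarks$tf[1]
    iaf <- landmarks$iaf[1]
    if (isTRUE(landmarks$invalid[1]))
      stop("landmarks flagged invalid (tf >= iaf)", call. = FALSE)
  }
  stopifnot(is.numeric(tf), is.numeric(iaf))
  if (tf >= iaf)
    stop("tf (", tf, ") must be below iaf (", iaf,
         "): no valid alpha partition", call. = FALSE)
  mid <- (tf + iaf) / 2
  delta_low <- tf - 4
  clipped <- delta_low < 0.5
  if (clipped) delta_low <- 0.5
  out <- tibble::tibble(
    band = factor(.bands, levels = .bands),
    low  = c(delta_low, tf - 2, tf, mid, iaf, 14, 20, 30),
    high = c(tf - 2, tf, mid, iaf, iaf + 2, 20, 30, 40)
  )
  if (any(out$high <= out$low))
    stop("degenerate band scheme: some band has non-positive width",
         call. = FALSE)
  attr(out, "delta_clipped") <- clipped
  attr(out, "tf") <- tf
  attr(out, "iaf") <- iaf
  out
}

#' Tidy a power spectrum
#'
#' @param x An `eeg_psd` object.
#' @param ... Unused.
#' @return A long tibble (subject_id, channel, frequency, psd) including a
#'   `"global"` channel row per bin.
#' @importFrom generics tidy
#' @method tidy eeg_psd
#' @export
tidy.eeg_psd <- function(x, ...) {
  per_ch <- tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(x$channel_labels, each = length(x$freq)),
    frequency = rep(x$freq, times = length(x$channel_labels)),
    psd = as.vector(t(x$psd))
  )
  dplyr::bind_rows(
    per_ch,
    tibble::tibble(subject_id = x$subject_id, channel = "global",
                   frequency = x$freq, psd = x$global_psd)
  )
}
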