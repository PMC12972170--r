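#' eLORETA inverse operator
#'
#' Computes the eLORETA (exact low-resolution electromagnetic tomography)
#' spatial filter by the standard fixed-point iteration on the per-voxel
#' symmetric weight blocks: with leadfield `K`, block-diagonal weights `W`
#' and average-reference centering matrix `H`,
#' `W_v <- sqrtm( K_v' (K W^-1 K' + alpha H)^+ K_v )`,
#' iterated until the maximum relative change of the weights falls below
#' `tol`. The Moore-Penrose pseudo-inverse handles the rank deficiency of
#' average-referenced data (rank = channels - 1). eLORETA's defining
#' property, zero localization error for single point sources in the
#' noiseless unregularized case, is the module's correctness oracle.
#'
#' @param leadfield A `leadfield` from [compute_leadfield()].
#' @param alpha_reg Regularization as a fraction of the mean eigenvalue of
#'   the model sensor covariance `K W^-1 K'` (default 1e-4); 0 disables
#'   regularization.
#' @param tol Convergence tolerance on the relative weight change.
#' @param max_iter Maximum fixed-point iterations; exceeded is an error.
#' @return An `inverse_operator`: `filters` (3*voxels x channels), the
#'   per-voxel 3 x channels blocks stacked voxel-major; `alpha` (absolute
#'   value used); `convergence` (iterations, final relative change).
#' @export
eloreta_operator <- function(leadfield, alpha_reg = 1e-4, tol = 1e-6,
                             max_iter = 100) {
  stopifnot(inherits(leadfield, "leadfield"))
  K <- leadfield$gain
  if (!all(is.finite(K))) stop("leadfield contains non-finite gains", call. = FALSE)
  if (max(abs(K)) == 0) stop("degenerate all-zero leadfield", call. = FALSE)
  if (alpha_reg < 0) stop("alpha_reg must be >= 0", call. = FALSE)
  n_e <- nrow(K)
  nv <- ncol(K) / 3
  H <- diag(n_e) - matrix(1 / n_e, n_e, n_e)

  # per-voxel 3x3 weight blocks, started at identity
  W <- rep(list(diag(3)), nv)
  rel <- Inf
  iter <- 0
  alpha_abs <- 0
  repeat {
    iter <- iter + 1
    # C = K W^-1 K' accumulated over voxels
    KWK <- matrix(0, n_e, n_e)
    for (v in seq_len(nv)) {
      Kv <- K[, (3 * v - 2):(3 * v), drop = FALSE]
      KWK <- KWK + Kv %*% solve(W[[v]], t(Kv))
    }
    alpha_abs <- alpha_reg * mean(diag(KWK))
    M <- .sym_pinv(KWK + alpha_abs * H)
    rel <- 0
    for (v in seq_len(nv)) {
      Kv <- K[, (3 * v - 2):(3 * v), drop = FALSE]
      Wnew <- .sym_sqrt(crossprod(Kv, M %*% Kv))
      rel <- max(rel, max(abs(Wnew - W[[v]])) / max(max(abs(W[[v]])), 1e-300))
      W[[v]] <- Wnew
    }
    if (rel < tol) break
    if (iter >= max_iter)
      stop("eLORETA fixed point did not converge in ", max_iter,
           " iterations (relative change ", signif(rel, 3), ")",
           call. = FALSE)
  }

  filters <- matrix(0, 3 * nv, n_e)
  for (v in seq_len(nv)) {
    Kv <- K[, (3 * v - 2):(3 * v), drop = FALSE]
    filters[(3 * v - 2):(3 * v), ] <- solve(W[[v]], crossprod(Kv, M))
  }
  structure(
    list(filters = filters, alpha = alpha_abs, n_voxels = nv,
         channel_labels = leadfield$channel_labels,
         convergence = list(iterations = iter, final_rel_change = rel)),
    class = "inverse_operator"
  )
}

.sym_pinv <- function(S, rtol = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  pos <- e$values > rtol * max(abs(e$values))
  if (!any(pos)) stop("matrix has no positive eigenvalues", call. = FALSE)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

.sym_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(v))
}

#' Apply an inverse operator to sensor cross-spectra
#'
#' Per voxel and frequency bin, source power is
#' `trace(T_v C(f) T_v^H)` with `T_v` the voxel's 3 x channels filter block:
#' the squared current-density magnitude summed over the three dipole
#' orientations, non-negative by construction.
#'
#' @param cross_spectra An `eeg_csd` from [sensor_cross_spectra()].
#' @param op An `inverse_operator`.
#' @return A `source_spectrum`: `power` (voxels x bins), `freq`,
#'   `normalized = FALSE`.
#' @export
apply_inverse <- function(cross_spectra, op) {
  stopifnot(inherits(cross_spectra, "eeg_csd"),
            inherits(op, "inverse_operator"))
  n_e <- ncol(op$filters)
  if (dim(cross_spectra$csd)[1] != n_e)
    stop("channel dimension mismatch: operator has ", n_e,
         ", cross-spectra have ", dim(cross_spectra$csd)[1], call. = FALSE)
  nb <- dim(cross_spectra$csd)[3]
  nv <- op$n_voxels
  Tm <- op$filters
  power <- matrix(0, nv, nb)
  grp <- rep(seq_len(nv), each = 3)
  for (b in seq_len(nb)) {
    C <- cross_spectra$csd[, , b]
    if (max(abs(C - Conj(t(C)))) > 1e-8 * max(abs(C), 1e-300))
      stop("cross-spectral matrix at bin ", b, " is not Hermitian",
           call. = FALSE)
    B <- Tm %*% C
    rowpow <- Re(rowSums(B * Conj(Tm)))
    power[, b] <- as.vector(rowsum(rowpow, grp))
  }
  power[power < 0] <- 0
  structure(
    list(subject_id = cross_spectra$subject_id,
         power = power, freq = cross_spectra$freq, normalized = FALSE),
    class = "source_spectrum"
  )
}

#' Grand-mean normalization of a source spectrum
#'
#' Divides every voxel-by-bin source power by the grand mean over all voxels
#' and all frequency bins in 0.5-45 Hz, so relative topographic and spectral
#' structure is retained while overall signal scale (amplifier gain, skull
#' conductivity, dipole strength units) cancels. The normalized solution has
#' grand mean exactly 1.
#'
#' @param source A `source_spectrum` with `normalized = FALSE`.
#' @return The normalized `source_spectrum`.
#' @export
normalize_solution <- function(source) {
  stopifnot(inherits(source, "source_spectrum"))
  if (isTRUE(source$normalized))
    stop("solution is already normalized", call. = FALSE)
  gm <- mean(source$power)
  if (!is.finite(gm) || gm <= 0)
    stop("grand mean of the solution is not positive", call. = FALSE)
  source$power <- source$power / gm
  source$normalized <- TRUE
  source
}

#' Collapse a source spectrum into region-by-band activity
#'
#' Averages the normalized source power over the voxels of each macro-region
#' and the bins of each individualized band, and log10-transforms the mean,
#' yielding the 6 x 8 table that is the unit of all downstream statistics.
#'
#' @param source A normalized `source_spectrum`.
#' @param bands A band scheme from [individual_band_scheme()].
#' @param space The `source_space` the inverse operator was built on.
#' @return A tibble with columns `subject_id`, `roi`, `band`, `activity`
#'   (log10 mean normalized power), 48 rows.
#' @export
collapse_band_roi <- function(source, bands, space) {
  stopifnot(inherits(source, "source_spectrum"),
            inherits(space, "source_space"))
  if (!isTRUE(source$normalized))
    stop("source spectrum must be normalized first", call. = FALSE)
  if (nrow(source$power) != space$n_voxels)
    stop("voxel dimension mismatch between solution and source space",
         call. = FALSE)
  out <- vector("list", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    sel <- source$freq >= bands$low[i] - 1e-9 & source$freq < bands$high[i] - 1e-9
    if (!any(sel))
      stop("band ", as.character(bands$band[i]),
           " contains no frequency bins", call. = FALSE)
    m <- rowMeans(source$power[, sel, drop = FALSE])
    out[[i]] <- tibble::tibble(
      subject_id = source$subject_id,
      roi = factor(.rois, levels = .rois),
      band = factor(as.character(bands$band[i]), levels = .bands),
      activity = log10(vapply(split(m, space$roi), mean, 0))
    )
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$roi, .data$band)
  attr(res, "band_scheme") <- bands
  res
}
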