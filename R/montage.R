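#' Idealized scalp electrode positions
#'
#' Electrode positions on a unit sphere for the two montages supported by the
#' pipeline: the 30-channel 10-10 montage used for the main cohort and the
#' 19-channel 10-20 montage of the cross-validation cohort. Positions follow
#' the idealized spherical construction of the 10-20/10-10 systems: the
#' nasion-inion and preauricular arcs span 180 degrees, the outer
#' circumferential ring sits at 72 degrees of inclination from the vertex,
#' and intermediate electrodes are placed by spherical interpolation along
#' their row arc.
#'
#' Coordinates are right-handed: +x toward the right ear, +y toward the
#' nasion, +z toward the vertex.
#'
#' @param montage `"10-10-30"` (default) or `"10-20-19"`.
#' @return A tibble with columns `label`, `x`, `y`, `z` (unit sphere).
#' @examples
#' montage_positions()
#' montage_positions("10-20-19")
#' @export
montage_positions <- function(montage = c("10-10-30", "10-20-19")) {
  montage <- match.arg(montage)
  deg <- pi / 180

  # point at inclination `incl` from vertex, azimuth `az` measured from the
  # anterior midline toward the right ear
  pt <- function(incl, az) {
    c(x = sin(incl * deg) * sin(az * deg),
      y = sin(incl * deg) * cos(az * deg),
      z = cos(incl * deg))
  }
  # spherical linear interpolation between two unit vectors
  slerp <- function(a, b, t) {
    o <- acos(max(-1, min(1, sum(a * b))))
    if (o < 1e-12) return(a)
    (sin((1 - t) * o) * a + sin(t * o) * b) / sin(o)
  }

  # midline electrodes (azimuth 0 anterior, 180 posterior)
  mid <- list(
    Fpz = pt(72, 0), AFz = pt(54, 0), Fz = pt(36, 0), FCz = pt(18, 0),
    Cz = pt(0, 0), CPz = pt(18, 180), Pz = pt(36, 180), POz = pt(54, 180),
    Oz = pt(72, 180)
  )
  # outer ring at 72 degrees inclination; azimuth in degrees from anterior
  # midline, positive to the right
  ring_az <- c(Fp1 = -18, Fp2 = 18, F7 = -54, F8 = 54, T7 = -90, T8 = 90,
               P7 = -126, P8 = 126, O1 = -162, O2 = 162,
               FT7 = -72, FT8 = 72, TP7 = -108, TP8 = 108)
  ring <- lapply(ring_az, function(a) pt(72, a))

  # intermediate electrodes: halfway along the row arc between the midline
  # electrode and the outer-ring electrode of the same row
  rows <- list(
    F3 = list(mid$Fz, ring$F7), F4 = list(mid$Fz, ring$F8),
    FC3 = list(mid$FCz, ring$FT7), FC4 = list(mid$FCz, ring$FT8),
    C3 = list(mid$Cz, ring$T7), C4 = list(mid$Cz, ring$T8),
    CP3 = list(mid$CPz, ring$TP7), CP4 = list(mid$CPz, ring$TP8),
    P3 = list(mid$Pz, ring$P7), P4 = list(mid$Pz, ring$P8)
  )
  inter <- lapply(rows, function(ab) slerp(ab[[1]], ab[[2]], 0.5))

  all_pos <- c(mid, ring, inter)

  labels <- switch(montage,
    "10-10-30" = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "FT7", "FC3", "FCz", "FC4", "FT8",
                   "T7", "C3", "Cz", "C4", "T8",
                   "TP7", "CP3", "CPz", "CP4", "TP8",
                   "P7", "P3", "Pz", "P4", "P8",
                   "O1", "Oz", "O2"),
    "10-20-19" = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T7", "C3", "Cz", "C4", "T8",
                   "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
  )
  m <- do.call(rbind, all_pos[labels])
  tibble::tibble(label = labels,
                 x = unname(m[, "x"]),
                 y = unname(m[, "y"]),
                 z = unname(m[, "z"]))
}
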