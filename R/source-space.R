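#' Three-shell spherical head model
#'
#' Concentric-sphere volume conductor with scalp, skull and brain
#' compartments. Defaults are the conventional values used with spherical
#' EEG forward models: radii 100/92/87 mm and conductivities 0.33/0.0042/0.33
#' S/m (skull about 80 times more resistive than soft tissue). Electrodes
#' sit on the scalp sphere at the montage's unit-sphere directions.
#'
#' @param radii Named numeric vector `c(scalp=, skull=, brain=)` in mm,
#'   strictly decreasing.
#' @param conductivities Named numeric vector, same names, in S/m, all > 0.
#' @param montage Montage name passed to [montage_positions()].
#' @return A `head_model` list with electrode positions in mm on the scalp
#'   sphere.
#' @export
head_model <- function(radii = c(scalp = 100, skull = 92, brain = 87),
                       conductivities = c(scalp = 0.33, skull = 0.0042,
                                          brain = 0.33),
                       montage = "10-10-30") {
  stopifnot(all(c("scalp", "skull", "brain") %in% names(radii)),
            all(c("scalp", "skull", "brain") %in% names(conductivities)))
  if (!(radii["scalp"] > radii["skull"] && radii["skull"] > radii["brain"]))
    stop("radii must satisfy scalp > skull > brain", call. = FALSE)
  if (any(conductivities <= 0))
    stop("conductivities must be positive", call. = FALSE)
  pos <- montage_positions(montage)
  electrodes <- as.matrix(pos[, c("x", "y", "z")]) * radii[["scalp"]]
  rownames(electrodes) <- pos$label
  structure(
    list(radii = radii, conductivities = conductivities,
         montage = montage, electrodes = electrodes),
    class = "head_model"
  )
}

#' Build a cortical source space on a spherical shell
#'
#' Places dipole voxels on a uniform grid restricted to a spherical cortical
#' shell (default 60-80 mm radius, upper portion of the brain sphere) and
#' labels each voxel with one of the six macro-regions by an angular sector
#' rule: superior voxels are frontal (anterior), parietal (posterior),
#' limbic (medial ring) or central; inferior voxels are occipital
#' (posterior) or temporal (lateral). Alternatively a user parcellation can
#' be supplied as a data frame of voxel coordinates and labels, preserving
#' fidelity when an externally computed source space is available.
#'
#' @param spacing Grid spacing in mm (default 5).
#' @param shell Inner/outer shell radii in mm.
#' @param z_min Lowest voxel z (mm); the cortex occupies the upper part of
#'   the brain sphere.
#' @param parcellation Optional data frame with columns `x`, `y`, `z` (mm)
#'   and `roi`; overrides the geometric construction.
#' @return A `source_space` list: `pos` (n x 3 mm), `roi` (factor),
#'   `n_voxels`, `spacing`.
#' @export
build_source_space <- function(spacing = 5, shell = c(60, 80), z_min = -30,
                               parcellation = NULL) {
  if (!is.null(parcellation)) {
    req <- c("x", "y", "z", "roi")
    if (!all(req %in% names(parcellation)))
      stop("parcellation must have columns x, y, z, roi", call. = FALSE)
    bad <- setdiff(unique(as.character(parcellation$roi)), .rois)
    if (length(bad) > 0)
      stop("unknown ROI label(s) in parcellation: ",
           paste(bad, collapse = ", "), call. = FALSE)
    pos <- as.matrix(parcellation[, c("x", "y", "z")])
    roi <- factor(as.character(parcellation$roi), levels = .rois)
  } else {
    stopifnot(spacing > 0, shell[1] < shell[2])
    g <- seq(-shell[2], shell[2], by = spacing)
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    r <- sqrt(rowSums(grid^2))
    keep <- r >= shell[1] & r <= shell[2] & grid[, "z"] >= z_min
    pos <- grid[keep, , drop = FALSE]
    roi <- .sector_roi(pos, shell[2])
  }
  if (nrow(pos) < 6)
    stop("source space has fewer than 6 voxels; decrease spacing",
         call. = FALSE)
  empty <- setdiff(.rois, unique(as.character(roi)))
  if (length(empty) > 0)
    stop("parcellation leaves empty ROI(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  structure(
    list(pos = unname(pos), roi = roi, n_voxels = nrow(pos),
         spacing = spacing),
    class = "source_space"
  )
}

# angular sector parcellation into the six macro-regions
.sector_roi <- function(pos, R) {
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  roi <- character(nrow(pos))
  superior <- z >= 0.15 * R
  roi[superior & y > 0.30 * R] <- "frontal"
  roi[superior & y < -0.30 * R] <- "parietal"
  mid <- superior & abs(y) <= 0.30 * R
  roi[mid & abs(x) < 0.22 * R] <- "limbic"
  roi[mid & abs(x) >= 0.22 * R] <- "central"
  inferior <- !superior
  roi[inferior & y < -0.30 * R] <- "occipital"
  roi[inferior & y >= -0.30 * R] <- "temporal"
  factor(roi, levels = .rois)
}

#' @export
print.source_space <- function(x, ...) {
  cat("<source_space> ", x$n_voxels, " voxels, spacing ", x$spacing,
      " mm\n", sep = "")
  print(table(x$roi))
  invisible(x)
}

#' Read and write source-space/leadfield exchange files
#'
#' The exchange format is a CSV pair: a voxel table (`x`, `y`, `z`, `roi`)
#' and a gain-matrix CSV whose first column is the channel label and whose
#' remaining columns are `v<voxel>_<x|y|z>` gains.
#'
#' @param space A `source_space`.
#' @param leadfield A `leadfield` object from [compute_leadfield()].
#' @param voxel_path,gain_path File paths.
#' @return Paths, invisibly; readers return the reconstructed objects.
#' @export
write_source_space <- function(space, voxel_path) {
  df <- data.frame(x = space$pos[, 1], y = space$pos[, 2],
                   z = space$pos[, 3], roi = as.character(space$roi))
  write.csv(df, voxel_path, row.names = FALSE)
  invisible(voxel_path)
}

#' @rdname write_source_space
#' @export
read_source_space <- function(voxel_path) {
  build_source_space(parcellation = read.csv(voxel_path))
}

#' @rdname write_source_space
#' @export
write_leadfield <- function(leadfield, gain_path) {
  g <- leadfield$gain
  nv <- ncol(g) / 3
  cn <- paste0("v", rep(seq_len(nv), each = 3), "_", c("x", "y", "z"))
  df <- data.frame(channel = leadfield$channel_labels, g,
                   check.names = FALSE)
  names(df) <- c("channel", cn)
  write.csv(df, gain_path, row.names = FALSE)
  invisible(gain_path)
}

#' @rdname write_source_space
#' @export
read_leadfield <- function(gain_path) {
  df <- read.csv(gain_path, check.names = FALSE)
  g <- as.matrix(df[, -1])
  structure(
    list(gain = unname(g), channel_labels = df$channel,
         average_referenced = max(abs(colSums(g))) <
           1e-6 * max(abs(g)) * nrow(g)),
    class = "leadfield"
  )
}
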