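#' Three-shell spherical EEG leadfield
#'
#' Computes the gain matrix mapping dipole moments at each source voxel
#' (free 3-D orientation) to average-referenced scalp potentials, using the
#' truncated Legendre-series solution of the Poisson problem for three
#' concentric spheres. For each harmonic degree the radial two-point
#' boundary-value problem (continuity of potential and radial current at the
#' brain/skull and skull/scalp interfaces, zero current through the scalp
#' surface) is solved exactly; the series is truncated adaptively once the
#' worst-case tail bound over all voxels falls below `tol` of the
#' accumulated transfer, and an error is raised if `max_order` is reached
#' first.
#'
#' @param space A `source_space` from [build_source_space()]; voxels must lie
#'   strictly inside the brain sphere.
#' @param head A [head_model()].
#' @param tol Relative tail tolerance for series truncation (default 1e-6).
#' @param max_order Maximum harmonic degree (default 200).
#' @return A `leadfield` list: `gain` (channels x 3*voxels, average
#'   referenced, columns ordered voxel-major x/y/z), `channel_labels`,
#'   `n_order` (series order used).
#' @export
compute_leadfield <- function(space, head, tol = 1e-6, max_order = 200) {
  stopifnot(inherits(space, "source_space"), inherits(head, "head_model"))
  rsc <- head$radii[["scalp"]]
  rb <- head$radii[["brain"]] / rsc
  rsk <- head$radii[["skull"]] / rsc
  sig <- head$conductivities
  elec <- head$electrodes / rsc               # unit sphere
  n_e <- nrow(elec)
  pos <- space$pos / rsc
  b <- sqrt(rowSums(pos^2))
  if (any(b >= rb))
    stop("voxel(s) outside the brain compartment (|r| >= brain radius)",
         call. = FALSE)

  trans <- .shell_transfer(rb, rsk, sig[["brain"]], sig[["skull"]],
                           sig[["scalp"]], max(b), tol, max_order)
  t_n <- trans$t_n
  n_max <- length(t_n)
  nn <- seq_len(n_max)

  # physical scale: radii in mm -> meters so gains are V per (A m) dipole
  scale <- 1 / (4 * pi * sig[["brain"]] * (rsc / 1000)^2)

  gain <- matrix(0, n_e, 3 * space$n_voxels)
  for (v in seq_len(space$n_voxels)) {
    rv <- pos[v, ] / b[v]
    cosg <- pmin(pmax(drop(elec %*% rv) / sqrt(rowSums(elec^2)), -1), 1)
    # tangential unit vectors from voxel toward each electrode
    ehat <- elec / sqrt(rowSums(elec^2))
    tv <- ehat - outer(cosg, rv)
    tn_norm <- sqrt(rowSums(tv^2))
    ok <- tn_norm > 1e-12
    tv[ok, ] <- tv[ok, ] / tn_norm[ok]
    tv[!ok, ] <- 0

    leg <- .legendre_pair(cosg, n_max)        # P_n and P_n^1, n_e x n_max
    bpow <- b[v]^(nn - 1)
    s_r <- drop(leg$p %*% (t_n * nn * bpow))
    s_t <- drop(leg$p1 %*% (t_n * bpow))
    block <- scale * (outer(s_r, rv) + s_t * tv)
    gain[, (3 * v - 2):(3 * v)] <- block
  }
  gain <- sweep(gain, 2, colMeans(gain))      # average reference
  structure(
    list(gain = gain, channel_labels = rownames(head$electrodes),
         average_referenced = TRUE, n_order = n_max),
    class = "leadfield"
  )
}

# Per-degree transfer coefficient T_n: scalp-surface value of the harmonic
# solution for unit source coefficient, radii normalized to the scalp.
# Unknowns (A1, A2, B2, A3, B3) solve the five boundary conditions.
.shell_transfer <- function(rb, rsk, s1, s2, s3, bmax, tol, max_order) {
  t_n <- numeric(0)
  acc <- 0
  for (n in seq_len(max_order)) {
    f <- function(r) r^n
    fp <- function(r) n * r^(n - 1)
    g <- function(r) r^(-(n + 1))
    gp <- function(r) -(n + 1) * r^(-(n + 2))
    A <- rbind(
      c(f(rb), -f(rb), -g(rb), 0, 0),
      c(s1 * fp(rb), -s2 * fp(rb), -s2 * gp(rb), 0, 0),
      c(0, f(rsk), g(rsk), -f(rsk), -g(rsk)),
      c(0, s2 * fp(rsk), s2 * gp(rsk), -s3 * fp(rsk), -s3 * gp(rsk)),
      c(0, 0, 0, fp(1), gp(1))
    )
    rhs <- c(-g(rb), -s1 * gp(rb), 0, 0, 0)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol))
      stop("shell-series system singular at degree ", n, call. = FALSE)
    t_n[n] <- sol[4] + sol[5]                 # A3 + B3 at the scalp surface
    term <- abs(t_n[n]) * n^2 * bmax^(n - 1)  # bound: |P_n|<=1, |P_n^1|<=n^2
    acc <- acc + term
    if (n >= 10 && term < tol * acc) return(list(t_n = t_n, converged = TRUE))
  }
  stop("shell series did not converge within max_order = ", max_order,
       "; tail term still ", signif(term / acc, 3), call. = FALSE)
}

# Legendre P_n(x) and associated P_n^1(x) (no Condon-Shortley phase) for
# n = 1..n_max, vectorized over x; returns length(x) x n_max matrices.
.legendre_pair <- function(x, n_max) {
  m <- length(x)
  p <- matrix(0, m, n_max)
  p1 <- matrix(0, m, n_max)
  sx <- sqrt(pmax(1 - x^2, 0))
  pm1 <- rep(1, m)      # P_0
  pc <- x               # P_1
  dm1 <- rep(0, m)      # P_0'
  dc <- rep(1, m)       # P_1'
  p[, 1] <- pc
  p1[, 1] <- sx * dc
  if (n_max > 1) for (n in 1:(n_max - 1)) {
    pn <- ((2 * n + 1) * x * pc - n * pm1) / (n + 1)
    dn <- dm1 + (2 * n + 1) * pc
    pm1 <- pc; pc <- pn
    dm1 <- dc; dc <- dn
    p[, n + 1] <- pc
    p1[, n + 1] <- sx * dc
  }
  list(p = p, p1 = p1)
}
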