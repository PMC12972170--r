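# Shared small fixtures, built once per test run.

.fx <- new.env()

fx_head <- function() {
  if (is.null(.fx$head)) .fx$head <- head_model()
  .fx$head
}

# coarse source space + leadfield (fast; ~150 voxels)
fx_space <- function() {
  if (is.null(.fx$space)) .fx$space <- build_source_space(spacing = 18)
  .fx$space
}

fx_leadfield <- function() {
  if (is.null(.fx$lf)) .fx$lf <- compute_leadfield(fx_space(), fx_head())
  .fx$lf
}

fx_operator <- function() {
  if (is.null(.fx$op)) .fx$op <- eloreta_operator(fx_leadfield(), alpha_reg = 0)
  .fx$op
}

# a tiny simulated subject shared across spectral/source tests
fx_subject <- function() {
  if (is.null(.fx$subj)) {
    cfg <- cohort_config(
      sizes = data.frame(group = "Healthy", edu = "low", n = 1),
      n_epochs = 30, blink_rate = 0, emg_rate = 0)
    prof <- generate_profiles(cfg, seed = 7)
    rec <- simulate_subject(prof[1, ], fx_leadfield(), fx_space(), cfg,
                            seed = 7)
    .fx$subj <- list(config = cfg, profile = prof, recording = rec)
  }
  .fx$subj
}

# pure-sinusoid recording helper
sine_recording <- function(freq, fs = 256, dur = 4, n_ch = 3, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch),
              nrow = n_ch, byrow = TRUE)
  eeg_recording(x, paste0("ch", seq_len(n_ch)), fs)
}

# long activity table with a known cell-mean structure plus iid noise
make_activity_table <- function(n_per_group = 10, effect = 0,
                                effect_bands = c("alpha2", "alpha3"),
                                sigma = 0.1, seed = 1,
                                n_bands = 8, n_rois = 6) {
  set.seed(seed)
  bands <- band_labels()[seq_len(n_bands)]
  rois <- roi_labels()[seq_len(n_rois)]
  subs <- expand.grid(edu = c("low", "high"), k = seq_len(n_per_group),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(subs))) {
    sid <- sprintf("s_%s_%02d", subs$edu[i], subs$k[i])
    g <- expand.grid(roi = rois, band = bands, stringsAsFactors = FALSE)
    g$subject_id <- sid
    g$edu <- subs$edu[i]
    g$activity <- rnorm(nrow(g), 0, sigma) +
      ifelse(subs$edu[i] == "high" & g$band %in% effect_bands, effect, 0)
    g$sex <- sample(c("M", "F"), 1)
    g$mmse <- rnorm(1, 25, 3)
    g$unit <- sample(c("u1", "u2"), 1)
    rows[[i]] <- g
  }
  out <- do.call(rbind, rows)
  out$band <- factor(out$band, levels = band_labels())
  out$roi <- factor(out$roi, levels = roi_labels())
  tibble::as_tibble(out)
}

# analytic surface potential for a dipole in a homogeneous conducting
# sphere (series solution of the insulated-sphere boundary-value problem),
# used as an independent oracle for the degenerate three-shell model
homogeneous_sphere_potential <- function(elec, dipole_pos, dipole_mom,
                                         radius, sigma, n_max = 120) {
  b <- sqrt(sum(dipole_pos^2))
  rv <- dipole_pos / b
  e_hat <- elec / sqrt(sum(elec^2))
  cosg <- sum(e_hat * rv)
  tv <- e_hat - cosg * rv
  if (sqrt(sum(tv^2)) > 1e-12) tv <- tv / sqrt(sum(tv^2))
  q_r <- sum(dipole_mom * rv)
  q_t <- sum(dipole_mom * tv)
  bb <- b / radius
  # Legendre P_n and P_n^1 at cosg
  p <- numeric(n_max); p1 <- numeric(n_max)
  pm1 <- 1; pc <- cosg; dm1 <- 0; dc <- 1
  sx <- sqrt(max(1 - cosg^2, 0))
  p[1] <- pc; p1[1] <- sx * dc
  for (n in 1:(n_max - 1)) {
    pn <- ((2 * n + 1) * cosg * pc - n * pm1) / (n + 1)
    dn <- dm1 + (2 * n + 1) * pc
    pm1 <- pc; pc <- pn; dm1 <- dc; dc <- dn
    p[n + 1] <- pc; p1[n + 1] <- sx * dc
  }
  nn <- seq_len(n_max)
  coef <- (2 * nn + 1) / nn * bb^(nn - 1)
  v <- sum(coef * (nn * q_r * p + q_t * p1))
  v / (4 * pi * sigma * radius^2)
}
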