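#' Draw synthetic subject profiles
#'
#' Samples per-subject ground truth for a synthetic cohort: frequency
#' landmarks (TF/IAF) from the configured group distributions (truncated so
#' that 3.2 <= TF <= 7.8, 6 <= IAF <= 13.5 and IAF - TF >= 1), demographics
#' and clinical covariates from the configured subgroup distributions, raw
#' cognitive domain scores, and the (roi, rhythm) source amplitude map that
#' both the signal simulator and the activity archive realize.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical (config, seed) gives an identical
#'   cohort.
#' @return A tibble, one row per subject, with list-column `amplitudes`.
#' @export
generate_profiles <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  demo <- .demographic_defaults()
  rows <- list()
  sid <- 0
  for (i in seq_len(nrow(config$sizes))) {
    g <- config$sizes$group[i]
    e <- config$sizes$edu[i]
    n <- config$sizes$n[i]
    lm_row <- config$landmarks[config$landmarks$group == g &
                                 config$landmarks$edu == e, ]
    d <- demo[demo$group == g & demo$edu == e, ]
    if (nrow(lm_row) != 1)
      stop("no landmark configuration for subgroup ", g, "/", e, call. = FALSE)
    eff <- config$edu_alpha_effect[[g]]
    for (k in seq_len(n)) {
      sid <- sid + 1
      lk <- .draw_landmarks(lm_row)
      eduy <- if (e == "low") {
        .rtrunc(d$eduy_mean, d$eduy_sd, 0.5, d$edu_threshold)
      } else {
        .rtrunc(d$eduy_mean, d$eduy_sd, d$edu_threshold + 0.5, 22)
      }
      amp <- .amplitude_template(g)
      if (e == "high" && eff != 0)
        amp$amplitude[amp$rhythm == "alpha"] <-
          amp$amplitude[amp$rhythm == "alpha"] * (1 + eff)
      jit <- 10^rnorm(nrow(amp), 0, config$sigma_rhythm)
      amp$amplitude <- amp$amplitude * jit * 10^rnorm(1, 0, config$sigma_subject)
      off <- config$domain_offset_sd
      is_pat <- g %in% c("PDD", "DLB")
      dom <- rnorm(4, 50 - if (is_pat) 10 * off else rep(0, 4), 10)
      # PDD attention carries the alpha coupling; its residual scatter is
      # tighter than the between-domain spread
      if (g == "PDD")
        dom[3] <- rnorm(1, 50 - 10 * off[["attention"]],
                        config$attention_resid_sd)
      rows[[sid]] <- tibble::tibble(
        subject_id = sprintf("%s_%s_%03d", tolower(g), e, k),
        group = g, edu = e,
        tf_true = lk[1], iaf_true = lk[2],
        age = round(.rtrunc(d$age_mean, d$age_sd, 50, 95), 1),
        sex = if (runif(1) < d$male_p) "M" else "F",
        education_years = round(eduy, 1),
        mmse = round(.rtrunc(d$mmse_mean, d$mmse_sd, 0, 30), 1),
        mmse_c = round(.rtrunc(d$mmsec_mean, d$mmsec_sd, 0, 30), 1),
        unit = sample(c("unit_1", "unit_2", "unit_3"), 1,
                      prob = c(0.5, 0.3, 0.2)),
        led_mg = if (is_pat) round(.rtrunc(d$led_mean, d$led_sd, 25, 2500)) else NA_real_,
        updrs3 = if (is_pat) round(.rtrunc(d$updrs_mean, d$updrs_sd, 0, 108), 1) else NA_real_,
        duration_y = if (is_pat) round(.rtrunc(d$dur_mean, d$dur_sd, 0.2, 30), 1) else NA_real_,
        vh = is_pat && runif(1) < d$vh_p,
        rbd = is_pat && runif(1) < d$rbd_p,
        language = dom[1], visuospatial = dom[2],
        attention = dom[3], memory = dom[4],
        amplitudes = list(amp)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = .groups)
  out$edu <- factor(out$edu, levels = .edu_levels)
  out
}

.draw_landmarks <- function(lm_row) {
  for (try in 1:200) {
    tf <- rnorm(1, lm_row$tf_mean, lm_row$tf_sd)
    iaf <- rnorm(1, lm_row$iaf_mean, lm_row$iaf_sd)
    if (tf >= 3.2 && tf <= 7.8 && iaf >= 6 && iaf <= 13.5 && iaf - tf >= 1)
      return(c(tf, iaf))
  }
  tf <- min(max(lm_row$tf_mean, 3.2), 7.8)
  c(tf, max(tf + 1, lm_row$iaf_mean))
}

.rtrunc <- function(mean, sd, lo, hi) {
  for (try in 1:200) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Simulate the regional-activity archive of a cohort
#'
#' Realizes each profile's ground-truth amplitude map directly as the
#' 6-region x 8-band log10 normalized activity table, without passing
#' through signal simulation and source estimation. Oscillator power enters
#' the individualized bands of the subject's own TF/IAF scheme (the alpha
#' oscillator splits 8/46/46% across alpha1-3, beta 60/40% across
#' beta1-2), a 1/f background fills all bands, multiplicative log-normal
#' cell noise is added, and each subject's cells are divided by their
#' bin-count-weighted grand mean, mirroring the pipeline's grand-mean
#' normalization. This is the fast path used for statistical power and
#' calibration work at full cohort sizes.
#'
#' @param profiles From [generate_profiles()].
#' @param config The same [cohort_config()].
#' @param seed Integer seed.
#' @return A long cohort tibble, one row per (subject, roi, band), with
#'   demographics joined — the unit of analysis for all statistics.
#' @export
simulate_activity_cohort <- function(profiles, config = cohort_config(),
                                     seed = 1) {
  set.seed(seed + 1L)
  n_sub <- nrow(profiles)
  acts <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    p <- profiles[s, ]
    cp <- .expected_cell_power(p$amplitudes[[1]], p$tf_true, p$iaf_true,
                               config$pink_exponent)
    band_re <- rnorm(8, 0, config$sigma_band)
    noise <- matrix(rnorm(48, 0, config$sigma_cell), 6, 8) +
      matrix(band_re, 6, 8, byrow = TRUE)
    pw <- cp$power * 10^noise
    gm <- (sum(sweep(pw, 2, cp$weight, `*`)) / 6 +
             cp$rest_power * cp$rest_bins) /
      (sum(cp$weight) + cp$rest_bins)
    acts[[s]] <- as.vector(log10(pw / gm))    # roi-major within band
  }
  act <- tibble::tibble(
    subject_id = rep(profiles$subject_id, each = 48),
    roi = factor(rep(rep(.rois, 8), n_sub), levels = .rois),
    band = factor(rep(rep(.bands, each = 6), n_sub), levels = .bands),
    activity = unlist(acts)
  )
  meta <- dplyr::select(profiles, -"amplitudes")
  out <- dplyr::left_join(act, meta, by = "subject_id")

  # compensation coupling: in PDD, the attention/executive score tracks
  # occipital alpha3 activity with an education-dependent slope
  occ_a3 <- dplyr::filter(out, .data$roi == "occipital",
                          .data$band == "alpha3")
  sl <- config$attention_slope
  occ_a3$att_adj <- ifelse(
    occ_a3$group == "PDD",
    sl[as.character(occ_a3$edu)] * occ_a3$activity, 0)
  out <- dplyr::left_join(
    out, occ_a3[, c("subject_id", "att_adj")], by = "subject_id")
  out$attention <- out$attention + out$att_adj
  out$att_adj <- NULL
  out
}

# Expected (roi, band) source power for one subject as a 6 x 8 matrix
# (rois x bands), with per-band bin counts (0.5 Hz bins) used as
# normalization weights, plus the background power of the analysis-grid
# bins outside the eight bands.
.expected_cell_power <- function(amp, tf, iaf, pink_exponent,
                                 bg_level = 1.4) {
  sch <- individual_band_scheme(tf = tf, iaf = iaf)
  centers <- (sch$low + sch$high) / 2
  bins <- pmax(1, (sch$high - sch$low) * 2)   # continuous bin weight
  amp_m <- matrix(amp$amplitude, nrow = 6,
                  dimnames = list(as.character(amp$roi[1:6]), NULL))
  colnames(amp_m) <- unique(amp$rhythm)
  bg <- bg_level^2 / centers^pink_exponent
  power <- matrix(bg, 6, 8, byrow = TRUE,
                  dimnames = list(.rois, .bands))
  # oscillator band power spread over the band's bins (per-bin density);
  # the alpha oscillator splits 15/45/40% across alpha1-3, beta 60/40%
  frac <- list(delta = c(delta = 1), theta = c(theta = 1),
               alpha = c(alpha1 = 0.08, alpha2 = 0.46, alpha3 = 0.46),
               beta = c(beta1 = 0.6, beta2 = 0.4))
  for (rh in names(frac)) {
    a2 <- amp_m[.rois, rh]^2
    for (b in names(frac[[rh]]))
      power[, b] <- power[, b] + a2 * frac[[rh]][[b]] / bins[match(b, .bands)]
  }
  # analysis-grid bins below the delta edge and above 40 Hz carry only
  # background, but count toward the grand mean as in the pipeline
  lo_bins <- max(0, (sch$low[1] - 0.5) * 2)
  lo_f <- if (lo_bins > 0) (0.5 + sch$low[1]) / 2 else 1
  hi_bins <- 10                       # 40.5 .. 45 Hz
  rest_power <- if (lo_bins + hi_bins > 0)
    (lo_bins * bg_level^2 / lo_f^pink_exponent +
       hi_bins * bg_level^2 / 42.5^pink_exponent) / (lo_bins + hi_bins)
  else 0
  list(power = power, weight = bins,
       rest_power = rest_power, rest_bins = lo_bins + hi_bins)
}
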