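test_that("profile generation matches configured sizes and is reproducible", {
  cfg <- cohort_config()
  profs <- generate_profiles(cfg, seed = 9)
  counts <- table(profs$group)
  expect_equal(unname(counts[c("Healthy", "PDD", "DLB")]),
               c(54, 75, 50), ignore_attr = TRUE)
  expect_equal(sum(profs$group == "PDD" & profs$edu == "low"), 30)
  expect_equal(sum(profs$group == "DLB" & profs$edu == "high"), 29)

  # landmark ordering invariant
  expect_true(all(profs$tf_true < profs$iaf_true))
  expect_true(all(profs$tf_true >= 3 & profs$iaf_true <= 14))
  expect_true(all(profs$mmse >= 0 & profs$mmse <= 30))
  expect_true(all(vapply(profs$amplitudes,
                         function(a) all(a$amplitude >= 0), TRUE)))

  # bit-identical reproduction under the same (config, seed)
  profs2 <- generate_profiles(cfg, seed = 9)
  expect_identical(profs, profs2)
  tab1 <- simulate_activity_cohort(profs, cfg, seed = 9)
  tab2 <- simulate_activity_cohort(profs2, cfg, seed = 9)
  expect_identical(tab1, tab2)

  expect_error(cohort_config(sizes = data.frame(group = "PDD", edu = "low",
                                                n = 0)), "positive")
  bad_lm <- cohort_config()$landmarks
  bad_lm$tf_mean[1] <- 10
  expect_error(cohort_config(landmarks = bad_lm), "below IAF")
})

test_that("configured education effects appear in the drawn amplitudes", {
  # 200-subject PDD cohort with a -30% alpha effect: Edu-/Edu+ amplitude
  # ratio ~ 1/0.7
  cfg <- cohort_config(sizes = tibble::tibble(group = "PDD",
                                              edu = c("low", "high"),
                                              n = c(200, 200)))
  profs <- generate_profiles(cfg, seed = 10)
  mean_alpha <- function(e) {
    mean(vapply(profs$amplitudes[profs$edu == e], function(a)
      mean(a$amplitude[a$rhythm == "alpha"]), 0))
  }
  expect_equal(mean_alpha("low") / mean_alpha("high"), 1 / 0.7,
               tolerance = 0.05)

  # all-zero effects: subgroup alpha means differ only by sampling noise
  cfg0 <- cohort_config(sizes = cfg$sizes,
                        edu_alpha_effect = c(Healthy = 0, PDD = 0, DLB = 0))
  p0 <- generate_profiles(cfg0, seed = 10)
  m <- vapply(p0$amplitudes, function(a)
    mean(log10(a$amplitude[a$rhythm == "alpha"])), 0)
  tt <- t.test(m[p0$edu == "low"], m[p0$edu == "high"])
  expect_gt(tt$p.value, 0.01)
})

test_that("alpha amplitude maps monotonically to downstream alpha activity", {
  cfg <- cohort_config(sigma_subject = 0, sigma_rhythm = 0,
                       sigma_band = 0, sigma_cell = 0,
                       sizes = data.frame(group = "Healthy", edu = "low",
                                          n = 1))
  base <- generate_profiles(cfg, seed = 11)
  ladder <- seq(0.5, 3, length.out = 10)
  occ_a3 <- vapply(ladder, function(k) {
    p <- base
    a <- p$amplitudes[[1]]
    a$amplitude[a$rhythm == "alpha"] <- a$amplitude[a$rhythm == "alpha"] * k
    p$amplitudes[[1]] <- a
    tab <- simulate_activity_cohort(p, cfg, seed = 11)
    tab$activity[tab$roi == "occipital" & tab$band == "alpha3"]
  }, 0)
  expect_gt(cor(ladder, occ_a3, method = "spearman"), 0.9)
  expect_true(all(diff(occ_a3) > 0))
})

test_that("sensor power scales quadratically with source amplitude", {
  cfg <- cohort_config(n_epochs = 10, sensor_snr = 1e6,
                       sigma_subject = 0, sigma_rhythm = 0,
                       sizes = data.frame(group = "Healthy", edu = "low",
                                          n = 1))
  prof <- generate_profiles(cfg, seed = 12)
  alpha_band_power <- function(k, seeds = 1:6) {
    p <- prof
    a <- p$amplitudes[[1]]
    # isolate the occipital alpha contribution
    a$amplitude <- 0
    a$amplitude[a$rhythm == "alpha" & a$roi == "occipital"] <- 2 * k
    p$amplitudes[[1]] <- a
    mean(vapply(seeds, function(s) {
      rec <- simulate_subject(p, fx_leadfield(), fx_space(), cfg, seed = s)
      psd <- welch_psd(epoch_recording(rec))
      sel <- psd$freq >= p$iaf_true - 1 & psd$freq <= p$iaf_true + 1
      mean(psd$global_psd[sel])
    }, 0))
  }
  # doubling amplitude quadruples the oscillator's band power above the
  # pink background (linear projection => power scales with amplitude^2)
  p0 <- alpha_band_power(0)
  p1 <- alpha_band_power(1)
  p2 <- alpha_band_power(2)
  expect_equal((p2 - p0) / (p1 - p0), 4, tolerance = 0.4)
})

test_that("zero alpha amplitude leaves no alpha peak at the sensors", {
  cfg <- cohort_config(n_epochs = 20, blink_rate = 0, emg_rate = 0,
                       sizes = data.frame(group = "Healthy", edu = "low",
                                          n = 1))
  prof <- generate_profiles(cfg, seed = 13)
  a <- prof$amplitudes[[1]]
  a$amplitude[a$rhythm == "alpha"] <- 0
  prof$amplitudes[[1]] <- a
  rec <- simulate_subject(prof, fx_leadfield(), fx_space(), cfg, seed = 13)
  psd <- welch_psd(epoch_recording(standardize_recording(rec)))
  g <- psd$global_psd
  win <- psd$freq >= 6 & psd$freq <= 14
  # no prominent interior peak: max in 6-14 Hz barely above its neighbors
  prominence <- max(g[win]) / median(g[win])
  expect_lt(prominence, 3)
})

test_that("cohort export writes EDF, metadata CSV and ground-truth JSON", {
  cfg <- cohort_config(n_epochs = 5, sizes = data.frame(
    group = c("Healthy", "PDD"), edu = c("low", "high"), n = c(2, 2)))
  cohort <- generate_cohort(cfg, seed = 14, spacing = 25)
  expect_length(cohort$recordings, 4)
  dir <- tempfile()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort_metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  edfs <- list.files(dir, pattern = "\\.edf$")
  expect_length(edfs, 4)
  back <- read_edf(file.path(dir, edfs[1]))
  expect_equal(nrow(back$data), 30)
  expect_equal(back$fs, 256)
  meta <- read.csv(file.path(dir, "cohort_metadata.csv"))
  expect_equal(nrow(meta), 4)
  unlink(dir, recursive = TRUE)
})
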