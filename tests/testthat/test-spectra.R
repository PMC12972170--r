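test_that("Welch PSD localizes on-grid sinusoids and conserves energy", {
  ep <- epoch_recording(sine_recording(10, dur = 8, n_ch = 3))
  psd <- welch_psd(ep)
  expect_equal(diff(psd$freq)[1], 0.5)
  expect_true(all(diff(psd$freq) == 0.5))
  expect_equal(range(psd$freq), c(0.5, 45))
  for (ch in 1:3)
    expect_equal(psd$freq[which.max(psd$psd[ch, ])], 10)

  # Parseval: integrated PSD ~ time-domain variance (band-limited signal)
  set.seed(1)
  x <- matrix(rnorm(2 * 256 * 40), nrow = 2)
  bf <- signal::butter(4, c(2, 40) / 128, "pass")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  rec <- eeg_recording(x, c("a", "b"), 256)
  psd <- welch_psd(epoch_recording(rec))
  for (ch in 1:2) {
    e_spec <- sum(psd$psd[ch, ]) * 0.5
    expect_equal(e_spec, var(x[ch, ]), tolerance = 0.05)
  }
})

test_that("Welch PSD is flat for white noise and obeys scaling/order laws", {
  set.seed(2)
  x <- matrix(rnorm(2 * 512 * 300), nrow = 2)
  rec <- eeg_recording(x, c("a", "b"), 256)
  ep <- epoch_recording(rec)
  psd <- welch_psd(ep)
  sel <- psd$freq >= 1 & psd$freq <= 40
  expect_lt(max(psd$global_psd[sel]) / min(psd$global_psd[sel]), 1.5)

  # scaling: PSD(k x) = k^2 PSD(x)
  rec2 <- eeg_recording(3 * x, c("a", "b"), 256)
  psd2 <- welch_psd(epoch_recording(rec2))
  expect_equal(psd2$psd, 9 * psd$psd, tolerance = 1e-12)

  # epoch order invariance
  ep_rev <- ep
  ep_rev$data <- ep$data[rev(seq_len(dim(ep$data)[1])), , , drop = FALSE]
  expect_equal(welch_psd(ep_rev)$psd, psd$psd, tolerance = 1e-12)

  # wrong epoch length for the 0.5 Hz grid
  bad <- epoch_recording(rec, epoch_length = 1)
  expect_error(welch_psd(bad), "0.5 Hz resolution")
})

test_that("cross-spectra are Hermitian with Welch PSD on the diagonal", {
  fx <- fx_subject()
  ep <- epoch_recording(standardize_recording(fx$recording))
  psd <- welch_psd(ep)
  csd <- sensor_cross_spectra(ep)
  for (b in c(1, 20, 60)) {
    C <- csd$csd[, , b]
    expect_lt(max(abs(C - Conj(t(C)))), 1e-10 * max(abs(C)))
  }
  for (ch in c(1, 15, 30))
    expect_equal(Re(csd$csd[ch, ch, ]), psd$psd[ch, ],
                 tolerance = 1e-10)

  # duplicated channels: coherence 1
  x <- matrix(rnorm(512 * 20), nrow = 1)
  two <- eeg_recording(rbind(x, x), c("a", "b"), 256)
  c2 <- sensor_cross_spectra(epoch_recording(two))
  coh <- abs(c2$csd[1, 2, ])^2 /
    (Re(c2$csd[1, 1, ]) * Re(c2$csd[2, 2, ]))
  expect_equal(unname(coh), rep(1, length(coh)), tolerance = 1e-9)

  # independent channels: coherence vanishes with many epochs
  set.seed(3)
  xm <- matrix(rnorm(2 * 512 * 1000), nrow = 2)
  ind <- sensor_cross_spectra(epoch_recording(eeg_recording(xm, c("a", "b"),
                                                            256)))
  coh <- abs(ind$csd[1, 2, ])^2 /
    (Re(ind$csd[1, 1, ]) * Re(ind$csd[2, 2, ]))
  expect_lt(median(coh), 0.01)
  expect_lt(max(coh), 0.1)
})

test_that("landmark detection finds constructed extrema and flags edge cases", {
  freq <- seq(0.5, 45, by = 0.5)
  mk_psd <- function(g) structure(
    list(subject_id = "c", channel_labels = "a", freq = freq,
         psd = matrix(g, nrow = 1), global_psd = g), class = "eeg_psd")

  g <- 1 / freq + 2 * exp(-(freq - 9)^2 / 0.5) - 0.15 * exp(-(freq - 5.5)^2 / 0.5)
  lmk <- detect_landmarks(mk_psd(g))
  expect_equal(lmk$tf, 5.5)
  expect_equal(lmk$iaf, 9)
  expect_false(lmk$no_peak)
  expect_false(lmk$invalid)

  # monotone 1/f: no alpha peak, IAF pinned to the window edge with flags
  g2 <- 1 / freq
  lmk2 <- detect_landmarks(mk_psd(g2))
  expect_equal(lmk2$iaf, 6)
  expect_true(lmk2$no_peak)
  expect_true(lmk2$boundary_hit)

  # scale invariance
  lmk3 <- detect_landmarks(mk_psd(17 * g))
  expect_equal(lmk3$tf, lmk$tf)
  expect_equal(lmk3$iaf, lmk$iaf)

  g[3] <- NA
  expect_error(detect_landmarks(mk_psd(g)), "non-finite")
})

test_that("individual band scheme reproduces the defining arithmetic", {
  # TF = 6, IAF = 10: equal-width alpha1/alpha2 around the midpoint 8
  sch <- individual_band_scheme(tf = 6, iaf = 10)
  expect_equal(sch$low[sch$band == "alpha1"], 6)
  expect_equal(sch$high[sch$band == "alpha1"], 8)
  expect_equal(sch$low[sch$band == "alpha2"], 8)
  expect_equal(sch$high[sch$band == "alpha2"], 10)
  expect_equal(sch$low[sch$band == "alpha3"], 10)
  expect_equal(sch$high[sch$band == "alpha3"], 12)

  # published Healthy-Edu- means
  sch2 <- individual_band_scheme(tf = 5.6, iaf = 8.9)
  expect_equal(sch2$low, c(1.6, 3.6, 5.6, 7.25, 8.9, 14, 20, 30))
  expect_equal(sch2$high, c(3.6, 5.6, 7.25, 8.9, 10.9, 20, 30, 40))

  # delta clipping below the analysis floor
  sch3 <- individual_band_scheme(tf = 4.2, iaf = 8)
  expect_equal(sch3$low[1], 0.5)
  expect_true(attr(sch3, "delta_clipped"))

  expect_error(individual_band_scheme(tf = 9, iaf = 8), "no valid alpha")
})

test_that("band partition properties hold for random valid landmark pairs", {
  set.seed(4)
  for (k in 1:200) {
    tf <- runif(1, 3.2, 7.8)
    iaf <- runif(1, tf + 0.6, 13.5)
    sch <- individual_band_scheme(tf = tf, iaf = iaf)
    # contiguity delta..alpha3
    expect_equal(sch$high[1:4], sch$low[2:5], tolerance = 1e-12)
    # equal-width alpha1/alpha2
    w <- sch$high - sch$low
    expect_equal(w[3], w[4], tolerance = 1e-12)
    expect_true(all(w > 0))
    # fixed upper bands
    expect_equal(sch$low[6:8], c(14, 20, 30))
    expect_equal(sch$high[6:8], c(20, 30, 40))
  }
})

test_that("generated subjects' landmarks are recovered through the spectral stage", {
  # 30 subjects across groups at default SNR; spec'd recovery: >= 90%
  # within one 0.5 Hz bin
  cfg <- cohort_config(n_epochs = 40, blink_rate = 0, emg_rate = 0,
    sizes = tibble::tibble(group = rep(c("Healthy", "PDD", "DLB"), 2),
                           edu = rep(c("low", "high"), each = 3), n = 5))
  profs <- generate_profiles(cfg, seed = 42)
  ok_tf <- ok_iaf <- 0
  for (s in seq_len(nrow(profs))) {
    rec <- simulate_subject(profs[s, ], fx_leadfield(), fx_space(), cfg,
                            seed = 500 + s)
    lmk <- detect_landmarks(welch_psd(epoch_recording(
      standardize_recording(rec))))
    ok_tf <- ok_tf + (abs(lmk$tf - profs$tf_true[s]) <= 0.5)
    ok_iaf <- ok_iaf + (abs(lmk$iaf - profs$iaf_true[s]) <= 0.5)
  }
  expect_gte(ok_tf / nrow(profs), 0.9)
  expect_gte(ok_iaf / nrow(profs), 0.9)
})
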