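test_that("the mixed ANCOVA collapses to the two-sample t test", {
  # one band, one ROI, no covariates: F(1, n-2) = t^2 exactly
  tab <- make_activity_table(n_per_group = 12, n_bands = 1, n_rois = 1,
                             effect = 0.3, effect_bands = "delta", seed = 21)
  res <- rm_ancova(tab, covariates = character(0))
  sm <- tab[!duplicated(tab$subject_id), ]
  tt <- t.test(activity ~ edu, data = tab, var.equal = TRUE)
  f_row <- res$terms[res$terms$term == "edu", ]
  expect_equal(f_row$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f_row$p.value, tt$p.value, tolerance = 1e-10)
  expect_equal(f_row$df2, nrow(sm) - 2)
})

test_that("the ANCOVA recovers a band-confined education effect structure", {
  tab <- make_activity_table(n_per_group = 20, effect = 0.25,
                             effect_bands = c("alpha2", "alpha3"),
                             sigma = 0.15, seed = 22)
  res <- rm_ancova(tab)
  t_int <- res$terms[res$terms$term == "edu:band", ]
  t_3way <- res$terms[res$terms$term == "edu:band:roi", ]
  expect_lt(t_int$p.value, 0.001)
  expect_gt(t_3way$p.value, 0.05)    # no ROI modulation was generated
  expect_true(all(res$terms$p.value >= 0 & res$terms$p.value <= 1))
  expect_true(all(res$terms$pes >= 0 & res$terms$pes <= 1, na.rm = TRUE))

  # partial eta squared invariant to affine rescaling of the DV
  tab2 <- tab
  tab2$activity <- 3 * tab$activity + 5
  res2 <- rm_ancova(tab2)
  expect_equal(res2$terms$pes, res$terms$pes, tolerance = 1e-8)

  # incomplete grid errors
  expect_error(rm_ancova(tab[-1, ]), "incomplete within-subject grid")
})

test_that("Duncan with two groups equals the pooled t test and flags bands", {
  tab <- make_activity_table(n_per_group = 15, effect = 0.4,
                             effect_bands = "alpha3", sigma = 0.12,
                             seed = 123)
  ph <- duncan_posthoc(tab)
  expect_equal(nrow(ph), 8)
  expect_equal(unique(ph$threshold), 0.05 / 8)
  # per band, the Duncan p equals the two-sample pooled t p on subject
  # band means (range of two means)
  for (b in c("delta", "alpha3")) {
    sub <- tab[tab$band == b, ]
    bm <- stats::aggregate(activity ~ subject_id + edu, sub, mean)
    tt <- t.test(activity ~ edu, bm, var.equal = TRUE)
    expect_equal(ph$p.value[ph$band == b], tt$p.value, tolerance = 1e-6)
  }
  expect_true(ph$significant[ph$band == "alpha3"])
  expect_false(any(ph$significant[ph$band != "alpha3"]))

  # identical group means: nothing significant
  tab0 <- make_activity_table(n_per_group = 15, effect = 0, seed = 24)
  expect_false(any(duncan_posthoc(tab0)$significant))
})

test_that("band-wise Bonferroni keeps the familywise error at bay under null", {
  set.seed(25)
  fw <- vapply(1:300, function(r) {
    tab <- make_activity_table(n_per_group = 8, effect = 0, sigma = 0.2,
                               n_rois = 2, seed = 1000 + r)
    any(duncan_posthoc(tab)$significant)
  }, TRUE)
  rate <- mean(fw)
  # familywise error after correction <= 5% (upper binomial bound)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the Grubbs statistic, critical value and power behave as specified", {
  x <- c(1, 2, 3, 4, 100)
  g <- grubbs_test(x, alpha = 0.05)
  expect_equal(g$g, (100 - mean(x)) / sd(x), tolerance = 1e-12)
  expect_equal(g$outlier, 100)

  # zero variance: degenerate flag, not an error
  z <- grubbs_test(rep(1, 10))
  expect_true(z$degenerate)
  expect_equal(z$p.value, 1)

  # injected 10-SD outlier in n = 27 is detected essentially always
  set.seed(26)
  hits <- vapply(1:200, function(r) {
    x <- rnorm(27)
    x[1] <- 10
    grubbs_test(x, alpha = 0.001)$g > grubbs_test(x, alpha = 0.001)$critical
  }, TRUE)
  expect_gte(mean(hits), 0.99)

  # screening over table cells returns one row per complete cell
  tab <- make_activity_table(n_per_group = 10, seed = 27)
  scr <- grubbs_screen(tab)
  expect_equal(nrow(scr), 8 * 6 * 2)
  expect_true(all(scr$p.value >= 0 & scr$p.value <= 1))
})

test_that("demographic tests dispatch correctly and match exact oracles", {
  # Fisher against full hypergeometric enumeration for [[5,5],[1,9]]
  tab22 <- matrix(c(5, 1, 5, 9), 2)
  margins <- c(rs = 10, cs = 6)
  enum_p <- function(m) {
    # all tables with the observed margins; two-sided by probability mass
    rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
    pr <- function(a) {
      b <- rs[1] - a; cc <- cs[1] - a; d <- n - a - b - cc
      if (min(b, cc, d) < 0) return(NA_real_)
      exp(lchoose(rs[1], a) + lchoose(rs[2], cc) - lchoose(n, cs[1]))
    }
    ps <- vapply(0:min(rs[1], cs[1]), pr, 0)
    ps <- ps[!is.na(ps)]
    sum(ps[ps <= pr(m[1, 1]) * (1 + 1e-7)])
  }
  expect_equal(fisher.test(tab22)$p.value, enum_p(tab22), tolerance = 1e-9)

  meta <- tibble::tibble(
    edu = rep(c("low", "high"), each = 10),
    age = rnorm(20, 70, 5),
    sex = rep(c("M", "F"), 10),
    mmse = c(1:10 / 2, 11:20 / 2),
    education_years = c(rnorm(10, 5, 1), rnorm(10, 13, 1))
  )
  res <- demographic_tests(meta)
  expect_setequal(res$variable, c("age", "education_years", "sex", "mmse"))
  expect_equal(res$test[res$variable == "sex"], "Fisher exact")
  expect_equal(res$test[res$variable == "mmse"], "Mann-Whitney U")

  # Mann-Whitney on fully separated samples: U = 0 and the minimal normal
  # approximation p for n1 = n2 = 10
  wt <- wilcox.test(mmse ~ edu, meta, exact = FALSE, correct = FALSE)
  sep <- res[res$variable == "mmse", ]
  # groups fully separated and tie-free: U at its extreme (0 or n1*n2)
  expect_true(unname(wt$statistic) %in% c(0, 100))
  z <- (0 - 50) / sqrt(10 * 10 * 21 / 12)
  expect_equal(sep$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-6)

  # identical groups: p = 1 for t and Mann-Whitney
  meta2 <- meta
  meta2$age <- rep(c(60, 65, 70, 75, 80), 4)
  meta2$mmse <- rep(c(20, 22, 24, 26, 28), 4)
  res2 <- demographic_tests(meta2)
  expect_equal(res2$p.value[res2$variable == "age"], 1)
  expect_equal(res2$p.value[res2$variable == "mmse"], 1)
})

test_that("composite z-scores standardize against the healthy reference", {
  sc <- tibble::tibble(
    group = c(rep("Healthy", 20), rep("PDD", 10)),
    language = c(rnorm(20, 50, 10), rnorm(10, 50, 10)),
    visuospatial = c(rnorm(20, 50, 10), rnorm(10, 50, 10)),
    attention = c(rnorm(20, 50, 10), rnorm(10, 50, 10)),
    memory = c(rnorm(20, 50, 10), rnorm(10, 30, 10))
  )
  z <- composite_zscores(sc)
  ref <- z[z$group == "Healthy", ]
  expect_equal(mean(ref$z_language), 0, tolerance = 1e-10)
  expect_equal(sd(ref$z_language), 1, tolerance = 1e-10)

  # a (patient) subject exactly at the healthy mean scores 0 everywhere;
  # patient rows leave the healthy reference untouched
  at_mean <- sc[1, ]
  at_mean$group <- "PDD"
  for (d in c("language", "visuospatial", "attention", "memory"))
    at_mean[[d]] <- mean(sc[[d]][sc$group == "Healthy"])
  z1 <- composite_zscores(rbind(sc, at_mean))
  expect_equal(unlist(z1[nrow(z1), c("z_language", "z_visuospatial",
                                     "z_attention", "z_memory", "z_global")]),
               rep(0, 5), ignore_attr = TRUE, tolerance = 1e-10)

  # one healthy SD below the mean: z = -1
  below <- at_mean
  below$memory <- below$memory - sd(sc$memory[sc$group == "Healthy"])
  z2 <- composite_zscores(rbind(sc, below))
  expect_equal(z2$z_memory[nrow(z2)], -1, tolerance = 1e-10)

  # generator recovery: patients 2 SD below in memory only
  set.seed(28)
  sc3 <- sc
  sc3$memory[sc3$group == "PDD"] <-
    rnorm(10, mean(sc$memory[sc$group == "Healthy"]) -
            2 * sd(sc$memory[sc$group == "Healthy"]), 5)
  z3 <- composite_zscores(sc3)
  expect_equal(mean(z3$z_memory[z3$group == "PDD"]), -2, tolerance = 0.6)

  sc_bad <- sc
  sc_bad$language[sc_bad$group == "Healthy"] <- 50
  expect_error(composite_zscores(sc_bad), "language")
})

test_that("Kruskal-Wallis ties out against the Mann-Whitney z for k = 2", {
  set.seed(29)
  x <- c(rnorm(15), rnorm(12, 1))
  g <- factor(rep(c("a", "b"), c(15, 12)))
  kw <- kruskal_multigroup(x, g)
  # z from tie-corrected mean-rank comparison
  rk <- rank(x)
  n <- length(x)
  s2 <- n * (n + 1) / 12
  z <- (mean(rk[g == "a"]) - mean(rk[g == "b"])) /
    sqrt(s2 * (1 / 15 + 1 / 12))
  expect_equal(kw$h, z^2, tolerance = 1e-9)

  # all observations identical: H = 0 path with p = 1
  kw0 <- kruskal_multigroup(rep(7, 18), factor(rep(c("a", "b", "c"), 6)))
  expect_equal(kw0$h, 0, tolerance = 1e-12)
  expect_equal(kw0$p.value, 1)

  # three-group structure recovery: patients below healthy, PDD ~ DLB
  set.seed(30)
  sc <- c(rnorm(30, 0), rnorm(25, -2), rnorm(20, -2))
  gg <- factor(rep(c("Healthy", "PDD", "DLB"), c(30, 25, 20)),
               levels = c("Healthy", "PDD", "DLB"))
  kw3 <- kruskal_multigroup(sc, gg)
  expect_lt(kw3$p.value, 0.01)
  ph <- kw3$posthoc
  expect_lt(ph$p.adjusted[ph$group1 == "Healthy" & ph$group2 == "PDD"], 0.05)
  expect_lt(ph$p.adjusted[ph$group1 == "Healthy" & ph$group2 == "DLB"], 0.05)
  expect_gt(ph$p.adjusted[ph$group1 == "PDD" & ph$group2 == "DLB"], 0.05)
})

test_that("correlations handle monotone data, reversals and ties exactly", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(correlate(x, x^3)$estimate, 1)
  expect_equal(correlate(x, -x)$estimate, -1)

  # ties: matches rank-average Pearson computed by hand
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 6, 6)
  rho <- correlate(xt, yt)$estimate
  expect_equal(rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)

  expect_error(correlate(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_error(correlate(1:3, 1:3), "at least 4")

  p <- correlate(rnorm(30), rnorm(30), "pearson")
  expect_true(p$p.value >= 0 && p$p.value <= 1)
})

test_that("interaction regression recovers noiseless coefficients exactly", {
  set.seed(31)
  d <- tibble::tibble(
    edu = factor(rep(c("low", "high"), each = 20), levels = c("low", "high")),
    act = rnorm(40),
    age = rnorm(40, 70, 5),
    sex = rep(c("M", "F"), 20),
    unit = rep(c("u1", "u2"), each = 2, length.out = 40)
  )
  d$y <- 2 + 3 * d$act            # no education or interaction effect
  res <- regress_interaction(d, "y", "act",
                             covariates = character(0))
  co <- res$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 2, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "act"], 3, tolerance = 1e-10)
  expect_equal(co$estimate[grepl(":", co$term)], 0, tolerance = 1e-10)
  expect_equal(res$fit$r.squared, 1, tolerance = 1e-10)
  # both simple slopes are 3
  expect_equal(res$simple_slopes$slope, c(3, 3), tolerance = 1e-10)

  # aliased design is rejected with the offending column named
  d2 <- d
  d2$act2 <- d2$act
  expect_error(
    regress_interaction(dplyr::mutate(d2, y = y + act2), "y", "act",
                        covariates = c("age", "act2", "act")),
    "aliased")
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  # by hand: cummin from the largest of p * n/i
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  set.seed(32)
  for (k in 1:20) {
    pr <- sort(runif(10))
    adj <- p.adjust(pr, "BH")
    expect_true(all(diff(adj) >= -1e-12))
    expect_true(all(adj >= pr - 1e-12))
  }
})

test_that("education-year trends recover configured couplings per group", {
  set.seed(33)
  n <- 60
  d <- tibble::tibble(
    group = rep(c("Healthy", "PDD"), each = n),
    education_years = c(runif(n, 3, 18), runif(n, 3, 18)),
    age = rnorm(2 * n, 72, 6),
    sex = sample(c("M", "F"), 2 * n, TRUE),
    unit = sample(c("u1", "u2"), 2 * n, TRUE)
  )
  d$occ_alpha3 <- ifelse(d$group == "Healthy",
                         0.015 * d$education_years,
                         -0.014 * d$education_years) + rnorm(2 * n, 0, 0.05)
  tr <- education_trend(d, "occ_alpha3", by = "group")
  expect_gt(tr$slope[tr$group == "Healthy"], 0)
  expect_lt(tr$slope[tr$group == "PDD"], 0)
  expect_lt(tr$p.value[tr$group == "Healthy"], 0.05)

  # degenerate design: education constant
  d0 <- d[d$group == "Healthy", ]
  d0$education_years <- 10
  expect_error(education_trend(d0, "occ_alpha3"), "zero variance")
})
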