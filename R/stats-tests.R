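#' Demographic and clinical subgroup comparisons
#'
#' Dispatches the variable-appropriate two-group test used in the cohort
#' description tables: t test for age, education years, UPDRS-III, disease
#' duration and LED; Fisher exact test (two-sided) for sex, visual
#' hallucinations and RBD; Mann-Whitney U (normal approximation with tie
#' correction) for raw and corrected MMSE.
#'
#' @param metadata Subject-level tibble with a 2-level `group_var` column.
#' @param group_var Grouping column (default `"edu"`).
#' @param var_equal Use the pooled-variance Student t test (default `TRUE`,
#'   the classical reporting convention); `FALSE` gives Welch.
#' @return A tibble: `variable`, `test`, `statistic`, `p.value`, per-group
#'   summaries.
#' @export
demographic_tests <- function(metadata, group_var = "edu",
                              var_equal = TRUE) {
  df <- as.data.frame(metadata)
  g <- droplevels(factor(df[[group_var]]))
  if (nlevels(g) != 2) stop("exactly 2 groups required", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  plan <- list(
    age = "t", education_years = "t", updrs3 = "t",
    duration_y = "t", led_mg = "t",
    sex = "fisher", vh = "fisher", rbd = "fisher",
    mmse = "mannwhitney", mmse_c = "mannwhitney"
  )
  out <- list()
  for (v in names(plan)) {
    if (!v %in% names(df)) next
    x <- df[[v]]
    ok <- !is.na(x)
    if (sum(ok) < 4 || length(unique(g[ok])) < 2) next
    res <- switch(plan[[v]],
      t = {
        tt <- t.test(x[ok] ~ g[ok], var.equal = var_equal)
        c(stat = unname(tt$statistic), p = tt$p.value)
      },
      fisher = {
        tab <- table(factor(x[ok]), g[ok])
        if (nrow(tab) < 2) c(stat = NA_real_, p = 1) else {
          ft <- fisher.test(tab)
          c(stat = NA_real_, p = ft$p.value)
        }
      },
      mannwhitney = {
        wt <- wilcox.test(x[ok] ~ g[ok], exact = FALSE, correct = FALSE)
        c(stat = unname(wt$statistic), p = wt$p.value)
      })
    lv <- levels(g)
    summ <- if (is.numeric(x)) {
      sprintf("%.1f / %.1f", mean(x[ok & g == lv[1]]),
              mean(x[ok & g == lv[2]]))
    } else {
      paste(round(100 * mean(x[ok & g == lv[1]] %in% c(TRUE, "M"))), "%/",
            round(100 * mean(x[ok & g == lv[2]] %in% c(TRUE, "M"))), "%")
    }
    out[[v]] <- tibble::tibble(
      variable = v,
      test = c(t = "t-test", fisher = "Fisher exact",
               mannwhitney = "Mann-Whitney U")[[plan[[v]]]],
      statistic = res[["stat"]], p.value = res[["p"]],
      group_summary = summ
    )
  }
  dplyr::bind_rows(out)
}

#' Composite cognitive z-scores against a healthy reference
#'
#' Standardizes each cognitive domain score against the Healthy group's mean
#' and SD and averages the available domain z-scores into a global composite.
#' Missing domains propagate as `NA` and are skipped in the global average.
#'
#' @param scores Subject-level tibble with `group` and domain columns.
#' @param domains Domain column names.
#' @param reference_group Level of `group` defining the reference.
#' @return `scores` with added `z_<domain>` columns and `z_global`.
#' @export
composite_zscores <- function(scores,
                              domains = c("language", "visuospatial",
                                          "attention", "memory"),
                              reference_group = "Healthy") {
  df <- scores
  ref <- df[df$group == reference_group, , drop = FALSE]
  if (nrow(ref) < 2) stop("healthy reference too small", call. = FALSE)
  zcols <- character(0)
  for (d in domains) {
    mu <- mean(ref[[d]], na.rm = TRUE)
    sdev <- sd(ref[[d]], na.rm = TRUE)
    if (!is.finite(sdev) || sdev == 0)
      stop("zero healthy SD in domain ", d, call. = FALSE)
    zc <- paste0("z_", d)
    df[[zc]] <- (df[[d]] - mu) / sdev
    zcols <- c(zcols, zc)
  }
  df$z_global <- rowMeans(as.data.frame(df[zcols]), na.rm = TRUE)
  df$z_global[!is.finite(df$z_global)] <- NA_real_
  df
}

#' Kruskal-Wallis test with rank-based post hocs
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (df = k - 1)
#' and pairwise Dunn-type z tests on mean ranks, Bonferroni-adjusted for
#' the number of pairwise comparisons (the "multiple comparisons z-value
#' test").
#'
#' @param scores Numeric vector.
#' @param groups Factor of group membership, aligned with `scores`.
#' @return A `kruskal_result` list: `h`, `df`, `p.value`, `n`, and a
#'   `posthoc` tibble (`group1`, `group2`, `z`, `p.value`, `p.adjusted`).
#' @export
kruskal_multigroup <- function(scores, groups) {
  ok <- is.finite(scores) & !is.na(groups)
  x <- scores[ok]
  g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs >= 2 observations", call. = FALSE)
  if (length(unique(x)) == 1) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2)
    ph <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = 0, p.value = 1, p.adjusted = 1)
    return(structure(list(h = 0, df = nlevels(g) - 1, p.value = 1,
                          n = length(x), posthoc = ph),
                     class = "kruskal_result"))
  }
  kt <- kruskal.test(x, g)
  n <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_corr
  lv <- levels(g)
  ph <- list()
  for (i in seq_len(nlevels(g) - 1)) {
    for (j in (i + 1):nlevels(g)) {
      ri <- mean(rk[g == lv[i]]); rj <- mean(rk[g == lv[j]])
      ni <- sum(g == lv[i]); nj <- sum(g == lv[j])
      z <- (ri - rj) / sqrt(s2 * (1 / ni + 1 / nj))
      ph[[paste(i, j)]] <- tibble::tibble(
        group1 = lv[i], group2 = lv[j], z = z,
        p.value = 2 * pnorm(-abs(z)))
    }
  }
  ph <- dplyr::bind_rows(ph)
  ph$p.adjusted <- pmin(1, ph$p.value * nrow(ph))
  structure(
    list(h = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value, n = n, posthoc = ph),
    class = "kruskal_result"
  )
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H(%d, n=%d) = %.2f, p = %.3g\n",
              x$df, x$n, x$h, x$p.value))
  print(as.data.frame(x$posthoc), digits = 3)
  invisible(x)
}

#' Correlation with explicit tie handling
#'
#' Pearson correlation, or Spearman computed as the Pearson correlation of
#' mid-ranks (average ranks for ties) with the t approximation for the
#' p-value.
#'
#' @param x,y Paired numeric vectors, `n >= 4` complete pairs.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `estimate`, `statistic`, `p.value`, `n`,
#'   `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  tibble::tibble(estimate = r, statistic = tstat, p.value = p, n = n,
                 method = method)
}
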