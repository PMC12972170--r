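#' Mixed-design ANCOVA on regional band activity
#'
#' Fits the study's core design on a long cohort table: a univariate
#' general linear model with Education as the between-subject factor, Band
#' and ROI as within-subject (repeated) factors with subject error strata,
#' and subject-constant covariates (sex and clinical unit dummy-coded, MMSE
#' centered) absorbed in the between-subject stratum — the classical ANCOVA
#' treatment of covariates in a repeated-measures design. Returns every main
#' effect and interaction with partial eta squared
#' (SS_effect / (SS_effect + SS_error of its stratum)). Greenhouse-Geisser
#' epsilons are reported for within terms, but the uncorrected F is the
#' headline statistic.
#'
#' @param table Long cohort tibble with one row per (subject, roi, band):
#'   columns `subject_id`, `activity`, the `between` factor, `band`, `roi`
#'   and any covariates.
#' @param between Between-subject factor name (default `"edu"`).
#' @param within Within-subject factor names present in the table.
#' @param covariates Covariate column names (character); numeric covariates
#'   are centered, categorical ones dummy-coded. Use `character(0)` for none.
#' @param dv Dependent-variable column (default `"activity"`).
#' @return An `anova_result`: tibble of terms (`term`, `stratum`, `df1`,
#'   `df2`, `statistic`, `p.value`, `pes`, `gg_epsilon`, `p.gg`) plus the
#'   design descriptor; supports [tidy()] and [glance()].
#' @export
rm_ancova <- function(table, between = "edu", within = c("band", "roi"),
                      covariates = c("sex", "mmse", "unit"),
                      dv = "activity") {
  df <- as.data.frame(table)
  need <- c("subject_id", dv, between, within, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$subject_id <- factor(df$subject_id)
  df[[between]] <- droplevels(factor(df[[between]]))
  if (nlevels(df[[between]]) < 2)
    stop("between factor needs at least 2 levels", call. = FALSE)
  grp_n <- table(unique(df[, c("subject_id", between)])[[between]])
  if (any(grp_n < 2))
    stop("each level of ", between, " needs at least 2 subjects", call. = FALSE)

  # complete within-grid check
  within <- within[vapply(within, function(w) length(unique(df[[w]])) > 1,
                          TRUE)]
  if (length(within) > 0) {
    for (w in within) df[[w]] <- droplevels(factor(df[[w]]))
    grid <- do.call(expand.grid, lapply(df[within], levels))
    counts <- stats::aggregate(df[[dv]],
                               by = df[c("subject_id", within)], FUN = length)
    full <- nlevels(df$subject_id) * nrow(unique(grid))
    if (nrow(counts) < full || anyDuplicated(df[, c("subject_id", within)])) {
      have <- interaction(counts[within])
      missing_cells <- setdiff(levels(interaction(grid)), unique(as.character(have)))
      stop("incomplete within-subject grid",
           if (length(missing_cells) > 0)
             paste0("; missing cells: ",
                    paste(head(missing_cells, 5), collapse = ", ")),
           call. = FALSE)
    }
  }

  # covariates: center numeric, factor-code categorical; singularity check
  cov_terms <- character(0)
  for (cv in covariates) {
    if (is.numeric(df[[cv]])) {
      df[[paste0(".c_", cv)]] <- df[[cv]] - mean(df[[cv]], na.rm = TRUE)
    } else {
      f <- droplevels(factor(df[[cv]]))
      if (nlevels(f) < 2) next   # constant covariate carries no information
      sub_tab <- table(unique(df[, c("subject_id", between, cv)])[[between]],
                       unique(df[, c("subject_id", between, cv)])[[cv]])
      if (any(rowSums(sub_tab > 0) == 1) && nlevels(f) > 1 &&
          all(colSums(sub_tab > 0) == 1))
        stop("covariate ", cv, " is confounded with ", between, call. = FALSE)
      df[[paste0(".c_", cv)]] <- f
    }
    cov_terms <- c(cov_terms, paste0(".c_", cv))
  }

  rhs <- paste(c(cov_terms,
                 paste(c(between, within), collapse = " * ")),
               collapse = " + ")
  if (length(within) > 0) {
    # strata: subject, subject:each within factor; the highest-order
    # subject-by-within interaction is the Within residual stratum (same
    # tests as the fully nested error model, far smaller projections)
    err <- paste0("Error(subject_id/(", paste(within, collapse = " + "), "))")
    fml <- as.formula(paste(dv, "~", rhs, "+", err))
  } else {
    fml <- as.formula(paste(dv, "~", rhs))
  }
  fit <- aov(fml, data = df)

  terms_tbl <- .extract_aov(fit)
  # partial eta squared is undefined for the residual rows
  gg <- if (length(within) > 0)
    .gg_epsilons(df, dv, within, between) else NULL
  if (!is.null(gg)) {
    # the Within residual stratum hosts the highest-order within interaction
    terms_tbl$within_key[terms_tbl$within_key == "__within__"] <-
      paste(within, collapse = ":")
    terms_tbl$gg_epsilon <- gg$eps[match(terms_tbl$within_key, gg$key)]
    terms_tbl$p.gg <- ifelse(
      is.na(terms_tbl$gg_epsilon), NA_real_,
      pf(terms_tbl$statistic,
         terms_tbl$df1 * terms_tbl$gg_epsilon,
         terms_tbl$df2 * terms_tbl$gg_epsilon, lower.tail = FALSE))
  } else {
    terms_tbl$gg_epsilon <- NA_real_
    terms_tbl$p.gg <- NA_real_
  }
  terms_tbl$within_key <- NULL
  structure(
    list(terms = terms_tbl,
         design = list(between = between, within = within,
                       covariates = covariates, dv = dv),
         data = df, fit = fit),
    class = "anova_result"
  )
}

# pull F tables out of all aov strata, with partial eta squared
.extract_aov <- function(fit) {
  strata <- if (inherits(fit, "aovlist")) fit else list(model = fit)
  out <- list()
  for (s in names(strata)) {
    if (s == "(Intercept)") next
    sm <- summary(strata[[s]])
    tab <- if (is.list(sm)) sm[[1]] else sm
    tab <- as.data.frame(tab)
    rn <- trimws(rownames(tab))
    res_row <- which(rn == "Residuals")
    if (length(res_row) == 0) next
    ss_err <- tab[res_row, "Sum Sq"]
    df_err <- tab[res_row, "Df"]
    eff <- setdiff(seq_len(nrow(tab)), res_row)
    if (length(eff) == 0) next
    out[[s]] <- tibble::tibble(
      term = gsub("\\.c_", "", rn[eff]),
      stratum = s,
      df1 = tab[eff, "Df"],
      df2 = df_err,
      sumsq = tab[eff, "Sum Sq"],
      statistic = tab[eff, "F value"],
      p.value = tab[eff, "Pr(>F)"],
      pes = tab[eff, "Sum Sq"] / (tab[eff, "Sum Sq"] + ss_err),
      within_key = if (s == "Within") "__within__" else
        gsub("^subject_id:?", "", s)
    )
  }
  dplyr::bind_rows(out)
}

# Greenhouse-Geisser epsilon per within stratum from the per-subject cell
# matrix (orthonormal contrast covariance)
.gg_epsilons <- function(df, dv, within, between) {
  keys <- c(within,
            if (length(within) > 1)
              apply(utils::combn(within, 2), 2, paste, collapse = ":"))
  eps <- vapply(keys, function(k) {
    facs <- strsplit(k, ":")[[1]]
    cell <- interaction(df[facs], drop = TRUE)
    wide <- tapply(df[[dv]], list(df$subject_id, cell), mean)
    if (any(is.na(wide)) || ncol(wide) < 2) return(NA_real_)
    S <- stats::cov(wide)
    k_lev <- ncol(S)
    C <- stats::contr.helmert(k_lev)
    C <- qr.Q(qr(C))
    V <- t(C) %*% S %*% C
    sum(diag(V))^2 / ((k_lev - 1) * sum(V^2))
  }, 0)
  list(key = keys, eps = eps)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed-design ANCOVA:", x$design$dv, "~",
      paste(x$design$between, collapse = "*"), "x (",
      paste(x$design$within, collapse = " x "), ") | covariates:",
      if (length(x$design$covariates)) paste(x$design$covariates,
                                             collapse = ", ") else "none",
      "\n")
  print(as.data.frame(x$terms[, c("term", "df1", "df2", "statistic",
                                  "p.value", "pes")]), digits = 4)
  invisible(x)
}

#' @rdname rm_ancova
#' @param x An `anova_result`.
#' @param ... Unused.
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) x$terms

#' @rdname rm_ancova
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  key <- x$terms[which.max(x$terms$statistic *
                             grepl(":", x$terms$term)), ]
  tibble::tibble(n_terms = nrow(x$terms),
                 largest_interaction = key$term,
                 statistic = key$statistic, p.value = key$p.value)
}

#' Duncan post-hoc education contrasts per band
#'
#' For each frequency band, compares the two education subgroup means of the
#' subject-level band activity (averaged over regions) with the Duncan
#' multiple-range test. With two means the Duncan range (r = 2) reduces to
#' the unprotected t comparison; p-values come from the studentized-range
#' distribution with the pooled within-group error of the subject band
#' means. Each band's p is then compared against the band-wise Bonferroni
#' threshold 0.05/8 = 0.00625.
#'
#' @param table Long cohort tibble (as for [rm_ancova()]).
#' @param between Between-subject factor (2 levels).
#' @param alpha Familywise level before Bonferroni division (default 0.05).
#' @param dv,band_var Column names.
#' @return A `posthoc_result` tibble: per band, group means, mean
#'   difference, `q`, Duncan `p.value`, the corrected threshold and
#'   `significant` flag.
#' @export
duncan_posthoc <- function(table, between = "edu", alpha = 0.05,
                           dv = "activity", band_var = "band") {
  df <- as.data.frame(table)
  df[[between]] <- droplevels(factor(df[[between]]))
  lv <- levels(df[[between]])
  if (length(lv) != 2)
    stop("duncan_posthoc expects exactly 2 education levels", call. = FALSE)
  bands <- levels(droplevels(factor(df[[band_var]])))
  n_bands <- length(bands)
  out <- list()
  for (b in bands) {
    sub <- df[df[[band_var]] == b, ]
    sm <- stats::aggregate(sub[[dv]],
                           by = list(subject_id = sub$subject_id,
                                     g = sub[[between]]), FUN = mean)
    x1 <- sm$x[sm$g == lv[1]]
    x2 <- sm$x[sm$g == lv[2]]
    n1 <- length(x1); n2 <- length(x2)
    ms <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    if (!is.finite(ms) || ms <= 0)
      stop("zero error variance in band ", b, call. = FALSE)
    nh <- 2 / (1 / n1 + 1 / n2)
    q <- abs(mean(x1) - mean(x2)) / sqrt(ms / nh)
    p_range <- ptukey(q, nmeans = 2, df = n1 + n2 - 2, lower.tail = FALSE)
    # Duncan protection level for r means: 1 - (1 - alpha)^(r - 1); with
    # r = 2 the Duncan p equals the range (= t test) p
    r <- 2
    p_duncan <- 1 - (1 - p_range)^(1 / (r - 1))
    out[[b]] <- tibble::tibble(
      band = b,
      mean_low = mean(x1), mean_high = mean(x2),
      diff = mean(x1) - mean(x2),
      q = q, p.value = p_duncan,
      threshold = alpha / n_bands,
      significant = p_duncan < alpha / n_bands
    )
  }
  res <- dplyr::bind_rows(out)
  res$band <- factor(res$band, levels = bands)
  class(res) <- c("posthoc_result", class(res))
  res
}

#' Grubbs outlier test
#'
#' Two-sided single-outlier Grubbs test: `G = max|x - mean| / sd`, compared
#' to the t-based critical value at level `alpha`. Used as a detection
#' screen (no removal), matching its role as a check on the ANOVA results.
#'
#' @param x Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.001).
#' @return A one-row tibble: `g`, `critical`, `p.value`, `outlier`
#'   (the flagged value or `NA`), `degenerate` (zero variance).
#' @export
grubbs_test <- function(x, alpha = 0.001) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("Grubbs test needs n >= 3", call. = FALSE)
  s <- sd(x)
  if (s == 0)
    return(tibble::tibble(g = 0, critical = NA_real_, p.value = 1,
                          outlier = NA_real_, degenerate = TRUE))
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  tc <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  crit <- (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
  # p-value by inverting the critical-value relation
  arg <- (n * (n - 2) * g^2) / ((n - 1)^2 - n * g^2)
  p <- if (arg <= 0 || g >= (n - 1) / sqrt(n)) 0 else
    min(1, 2 * n * pt(sqrt(arg), n - 2, lower.tail = FALSE))
  tibble::tibble(g = g, critical = crit, p.value = p,
                 outlier = if (g > crit) x[which.max(dev)] else NA_real_,
                 degenerate = FALSE)
}

#' Grubbs screening over table cells
#'
#' Applies [grubbs_test()] to the activity values of every (roi, band,
#' education) cell of a cohort table.
#'
#' @param table Long cohort tibble.
#' @param alpha Significance level (default 0.001).
#' @param by Cell-defining columns.
#' @return A tibble with one row per cell and the Grubbs results.
#' @export
grubbs_screen <- function(table, alpha = 0.001,
                          by = c("roi", "band", "edu")) {
  df <- as.data.frame(table)
  cells <- split(df$activity, df[by], drop = TRUE)
  res <- purrr::imap(cells, function(v, key) {
    if (sum(is.finite(v)) < 3) return(NULL)
    r <- grubbs_test(v, alpha)
    r$cell <- key
    r
  })
  dplyr::bind_rows(res)
}
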