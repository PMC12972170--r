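#' Subject-level activity extraction
#'
#' Averages the long cohort table's activity over a chosen set of regions
#' and bands, yielding one value per subject alongside the subject metadata.
#' `rois = c("parietal", "occipital", "temporal", "limbic")` with the alpha2
#' and alpha3 bands gives the "posterior alpha" predictor used in the
#' cognition regressions.
#'
#' @param table Long cohort tibble.
#' @param rois,bands Region and band subsets (defaults: posterior regions,
#'   alpha2+alpha3).
#' @param name Name of the resulting activity column.
#' @return A subject-level tibble with metadata and the named column.
#' @export
subject_activity <- function(table,
                             rois = c("parietal", "occipital",
                                      "temporal", "limbic"),
                             bands = c("alpha2", "alpha3"),
                             name = "alpha_activity") {
  sel <- dplyr::filter(table, .data$roi %in% rois, .data$band %in% bands)
  agg <- dplyr::summarise(dplyr::group_by(sel, .data$subject_id),
                          value = mean(.data$activity), .groups = "drop")
  meta_cols <- setdiff(names(table), c("roi", "band", "activity"))
  meta <- dplyr::distinct(table[, meta_cols])
  out <- dplyr::left_join(meta, agg, by = "subject_id")
  names(out)[names(out) == "value"] <- name
  out
}

#' Interaction regression with FDR-corrected simple slopes
#'
#' Ordinary least squares of a cognitive target on an Education-by-activity
#' interaction with covariates: `target ~ edu * activity + covariates`.
#' Reports the coefficient table, model fit (R-squared, adjusted R-squared,
#' residual SE, model F), residual diagnostics (studentized Breusch-Pagan
#' for heteroscedasticity, Shapiro-Wilk for normality, Cook's-distance
#' influence flags), and the simple slope of the activity within each
#' education level with confidence limits and Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param data Subject-level tibble (e.g. from [subject_activity()]).
#' @param target Response column name.
#' @param activity Activity predictor column name.
#' @param education Education factor column (default `"edu"`).
#' @param covariates Covariate columns (default age, sex, unit).
#' @return A `regression_result` with `coefficients`, `fit`, `diagnostics`,
#'   `simple_slopes` and the underlying `lm` object; supports [tidy()]
#'   and [glance()].
#' @export
regress_interaction <- function(data, target, activity, education = "edu",
                                covariates = c("age", "sex", "unit")) {
  df <- as.data.frame(data)
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(df[[cv]][!is.na(df[[cv]])])) > 1, TRUE)]
  df[[education]] <- droplevels(factor(df[[education]]))
  fml <- as.formula(paste(
    target, "~", education, "*", activity,
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  df <- df[complete.cases(df[, c(target, education, activity, covariates)]), ]
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    std.error = unname(sm$coefficients[, 2]),
    statistic = unname(sm$coefficients[, 3]),
    p.value = unname(sm$coefficients[, 4])
  )
  fstat <- sm$fstatistic
  fit_tbl <- tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    statistic = unname(fstat[1]),
    df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p.value = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n = nrow(df)
  )
  bp <- lmtest::bptest(fit, studentize = TRUE)
  swp <- tryCatch(stats::shapiro.test(residuals(fit))$p.value,
                  error = function(e) NA_real_)
  cd <- cooks.distance(fit)
  diagnostics <- tibble::tibble(
    heteroscedasticity_p = unname(bp$p.value),
    normality_p = swp,
    n_influential = sum(cd > 4 / nrow(df), na.rm = TRUE)
  )
  # simple slopes of activity within each education level
  tr <- emmeans::emtrends(fit, stats::reformulate(education), var = activity)
  ss <- as.data.frame(summary(tr, infer = c(TRUE, TRUE)))
  slope_col <- grep("trend$", names(ss), value = TRUE)[1]
  slopes <- tibble::tibble(
    level = as.character(ss[[1]]),
    slope = ss[[slope_col]],
    std.error = ss$SE,
    conf.low = ss$lower.CL,
    conf.high = ss$upper.CL,
    p.value = ss$p.value
  )
  slopes$p.adjusted <- p.adjust(slopes$p.value, method = "BH")
  structure(
    list(coefficients = coefs, fit = fit_tbl, diagnostics = diagnostics,
         simple_slopes = slopes, model = fit,
         design = list(target = target, activity = activity,
                       education = education, covariates = covariates)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS:", x$design$target, "~", x$design$education, "*",
      x$design$activity, "+", paste(x$design$covariates, collapse = " + "),
      "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, RSE = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$fit$r.squared, x$fit$adj.r.squared, x$fit$sigma,
              x$fit$df1, x$fit$df2, x$fit$statistic, x$fit$p.value))
  cat("Simple slopes (BH-adjusted):\n")
  print(as.data.frame(x$simple_slopes), digits = 3)
  invisible(x)
}

#' @rdname regress_interaction
#' @param x A `regression_result`.
#' @param ... Unused.
#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) x$coefficients

#' @rdname regress_interaction
#' @method glance regression_result
#' @export
glance.regression_result <- function(x, ...) x$fit

#' Education-years trend on activity
#'
#' Per-group ordinary least squares of an activity measure on continuous
#' education years with covariates, reporting the education slope, its SE,
#' confidence limits and p-value — the design used to test neuroprotective
#' (positive slope, Healthy) versus compensatory (negative slope, PDD)
#' associations.
#'
#' @param data Subject-level tibble.
#' @param target Activity column name.
#' @param predictor Continuous education column (default `"education_years"`).
#' @param covariates Covariate columns.
#' @param by Optional grouping column; fits one model per level.
#' @return A tibble with one row per group: slope, SE, CI, t, p, model fit.
#' @export
education_trend <- function(data, target, predictor = "education_years",
                            covariates = c("age", "sex", "unit"),
                            by = NULL) {
  groups <- if (is.null(by)) list(all = data) else
    split(data, data[[by]], drop = TRUE)
  out <- purrr::imap(groups, function(df, gname) {
    df <- as.data.frame(df)
    covs <- covariates[vapply(covariates, function(cv)
      length(unique(df[[cv]][!is.na(df[[cv]])])) > 1, TRUE)]
    if (length(unique(df[[predictor]])) < 2 || sd(df[[predictor]]) == 0)
      stop("zero variance in ", predictor, " for group ", gname,
           call. = FALSE)
    fml <- as.formula(paste(
      target, "~", predictor,
      if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""))
    fit <- lm(fml, data = df)
    sm <- summary(fit)
    est <- sm$coefficients[predictor, ]
    ci <- stats::confint(fit)[predictor, ]
    tibble::tibble(
      group = gname,
      slope = est[1], std.error = est[2],
      conf.low = ci[1], conf.high = ci[2],
      statistic = est[3], p.value = est[4],
      r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
      sigma = sm$sigma, n = nrow(df)
    )
  })
  dplyr::bind_rows(out)
}
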