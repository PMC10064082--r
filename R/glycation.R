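#' Apply the observational cohort inclusion filters
#'
#' Keeps participants aged 18-65 with fasting glucose below 7 mmol/L,
#' HbA1c below 6.5% and hemoglobin inside the sex-specific normal range;
#' records flagged as having attended a diabetes clinic in the prior two
#' years (optional `diabetes_clinic_2y` column) are excluded first. Each
#' excluded record is tallied under its first matching reason, in the
#' order: diabetes clinic, fasting glucose, HbA1c, age, unclassifiable
#' sex, hemoglobin.
#'
#' The sex-specific hemoglobin reference intervals default to 130-170 g/L
#' (male) and 120-160 g/L (female); laboratories differ, so they are
#' configurable.
#'
#' @param cohort Data frame with columns `age`, `sex` (`"female"`/`"male"`),
#'   `fg` (mmol/L), `hba1c` (%), `hb` (g/L), optionally
#'   `diabetes_clinic_2y` (logical).
#' @param age_range Inclusive age bounds in years.
#' @param fg_max Exclusive upper bound on fasting glucose (mmol/L).
#' @param hba1c_max Exclusive upper bound on HbA1c (%).
#' @param hb_ranges Named list of inclusive (low, high) hemoglobin bounds
#'   in g/L per sex.
#' @return A list: `kept` (filtered data frame) and `exclusions` (named
#'   integer tally of exclusion reasons).
#' @export
apply_cohort_filters <- function(cohort, age_range = c(18, 65), fg_max = 7.0,
                                 hba1c_max = 6.5,
                                 hb_ranges = list(male = c(130, 170),
                                                 female = c(120, 160))) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  reason <- rep(NA_character_, nrow(cohort))
  if ("diabetes_clinic_2y" %in% names(cohort))
    reason[is.na(reason) & cohort$diabetes_clinic_2y %in% TRUE] <- "diabetes_clinic"
  reason[is.na(reason) & cohort$fg >= fg_max] <- "fasting_glucose"
  reason[is.na(reason) & cohort$hba1c >= hba1c_max] <- "hba1c"
  reason[is.na(reason) &
           (cohort$age < age_range[1] | cohort$age > age_range[2])] <- "age"
  known_sex <- cohort$sex %in% names(hb_ranges)
  reason[is.na(reason) & !known_sex] <- "unclassifiable"
  hb_ok <- rep(FALSE, nrow(cohort))
  for (s in names(hb_ranges)) {
    idx <- cohort$sex == s
    hb_ok[idx] <- cohort$hb[idx] >= hb_ranges[[s]][1] &
      cohort$hb[idx] <= hb_ranges[[s]][2]
  }
  reason[is.na(reason) & known_sex & !hb_ok] <- "hemoglobin"

  kept <- cohort[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  tally <- table(factor(reason[!is.na(reason)],
                        levels = c("diabetes_clinic", "fasting_glucose",
                                   "hba1c", "age", "unclassifiable",
                                   "hemoglobin")))
  list(kept = kept, exclusions = stats::setNames(as.integer(tally), names(tally)))
}

#' Classify filtered participants as normoglycemic or pre-T2D
#'
#' Normoglycemia is HbA1c below 6% and fasting glucose below 6 mmol/L.
#' Under `rule = "either"` (the default) everyone else in the filtered
#' cohort is pre-T2D (HbA1c 6-6.4% or fasting glucose 6-6.9 mmol/L), so
#' the two classes partition the cohort. Under `rule = "both"` pre-T2D
#' requires both bands; mixed records (one marker elevated, not the other)
#' are labelled `"indeterminate"`.
#'
#' @param cohort Data frame that already passed [apply_cohort_filters()]
#'   (so HbA1c < 6.5 and fasting glucose < 7 hold).
#' @param rule `"either"` or `"both"`.
#' @return A factor with levels `normoglycemia`, `preT2D` (and
#'   `indeterminate` under `rule = "both"`).
#' @export
classify_glycemic_status <- function(cohort, rule = c("either", "both")) {
  rule <- match.arg(rule)
  normo <- cohort$hba1c < 6.0 & cohort$fg < 6.0
  if (rule == "either") {
    factor(ifelse(normo, "normoglycemia", "preT2D"),
           levels = c("normoglycemia", "preT2D"))
  } else {
    pre <- cohort$hba1c >= 6.0 & cohort$hba1c < 6.5 &
      cohort$fg >= 6.0 & cohort$fg < 7.0
    out <- ifelse(normo, "normoglycemia",
                  ifelse(pre, "preT2D", "indeterminate"))
    factor(out, levels = c("normoglycemia", "preT2D", "indeterminate"))
  }
}

#' Triglyceride-glucose index
#'
#' `ln(triglyceride(mg/dL) * fasting glucose(mg/dL) / 2)`, a surrogate
#' measure of insulin resistance and compensatory hyperinsulinemia.
#' Inputs are in the mmol/L units clinical laboratories report; the
#' standard conversion factors 88.57 (triglyceride) and 18 (glucose) to
#' mg/dL are applied internally.
#'
#' @param tg_mmol Fasting triglyceride, mmol/L.
#' @param fg_mmol Fasting plasma glucose, mmol/L.
#' @return The index (dimensionless, natural-log scale).
#' @examples
#' tgi(1.16, 5.10) # ~8.46
#' @export
tgi <- function(tg_mmol, fg_mmol) {
  if (any(!is.finite(tg_mmol)) || any(!is.finite(fg_mmol)) ||
      any(tg_mmol <= 0) || any(fg_mmol <= 0))
    stop("triglyceride and glucose must be positive and finite", call. = FALSE)
  log((tg_mmol * 88.57) * (fg_mmol * 18) / 2)
}

#' Fit the predicted-HbA1c regression on fasting glucose
#'
#' Ordinary least squares of measured HbA1c on fasting glucose, adjusted
#' for age and sex; the fasting-glucose-only reduced model is fitted
#' alongside and is the default prediction equation (its two printed
#' coefficients are what the glycation gap is usually quoted against).
#'
#' @param cohort Data frame with `hba1c`, `fg` and the covariate columns.
#' @param covariates Adjustment covariates for the full model.
#' @return An object of class `"hba1c_model"`: list with `full` and
#'   `reduced` `lm` fits and `equation`, the reduced model's
#'   (intercept, slope) pair.
#' @export
fit_predicted_hba1c <- function(cohort, covariates = c("age", "sex")) {
  if (nrow(cohort) < 10)
    stop("need at least 10 records to fit the prediction model", call. = FALSE)
  if ("sex" %in% covariates && length(unique(cohort$sex)) < 2)
    stop("both sexes required to fit the sex-adjusted model", call. = FALSE)
  rhs <- paste(c("fg", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("hba1c ~", rhs)), data = cohort)
  reduced <- stats::lm(hba1c ~ fg, data = cohort)
  structure(list(full = full, reduced = reduced,
                 equation = stats::setNames(stats::coef(reduced),
                                            c("intercept", "fg"))),
            class = "hba1c_model")
}

#' @export
print.hba1c_model <- function(x, digits = 3, ...) {
  eq <- x$equation
  cat(sprintf("Predicted HbA1c = %.3f + %.3f * fasting glucose (mmol/L)\n",
              eq[1], eq[2]))
  cat(sprintf("Full model (adjusted): hba1c ~ %s\n",
              paste(attr(stats::terms(x$full), "term.labels"), collapse = " + ")))
  invisible(x)
}

#' @export
predict.hba1c_model <- function(object, newdata = NULL,
                                model = c("reduced", "full"), ...) {
  model <- match.arg(model)
  stats::predict(object[[model]], newdata = newdata, ...)
}

#' @export
coef.hba1c_model <- function(object, model = c("reduced", "full"), ...) {
  stats::coef(object[[match.arg(model)]])
}

#' Glycation gap
#'
#' Measured HbA1c minus the HbA1c predicted from fasting glucose. A
#' negative gap means HbA1c is lower than glycemia alone predicts,
#' consistent with non-glycemic lowering (e.g. via erythrocytosis).
#'
#' @param measured_hba1c,predicted_hba1c HbA1c values in percent.
#' @return `measured - predicted`.
#' @export
glycation_gap <- function(measured_hba1c, predicted_hba1c) {
  stopifnot(is.finite(measured_hba1c), is.finite(predicted_hba1c))
  measured_hba1c - predicted_hba1c
}

# Ensure tgi/gap columns exist on a cohort, deriving them when absent.
.with_gap_columns <- function(cohort, prediction = NULL) {
  if (!"tgi" %in% names(cohort)) cohort$tgi <- tgi(cohort$tg, cohort$fg)
  if (!"gap" %in% names(cohort)) {
    if (is.null(prediction)) prediction <- fit_predicted_hba1c(cohort)
    cohort$gap <- cohort$hba1c - predict(prediction, newdata = cohort)
  }
  cohort
}

# Default Table-5-style strata: glycemic classes plus HbA1c bands within
# normoglycemia. Returns a named list of logical index vectors.
.default_strata <- function(cohort) {
  cls <- if ("stratum" %in% names(cohort)) {
    factor(cohort$stratum, levels = c("normoglycemia", "preT2D"))
  } else classify_glycemic_status(cohort)
  normo <- cls == "normoglycemia"
  list(
    "preT2D" = cls == "preT2D",
    "healthy" = normo,
    "hba1c<5" = normo & cohort$hba1c < 5.0,
    "hba1c 5-5.4" = normo & cohort$hba1c >= 5.0 & cohort$hba1c < 5.5,
    "hba1c 5.5-5.9" = normo & cohort$hba1c >= 5.5 & cohort$hba1c < 6.0
  )
}

#' Stratified regression of the glycation gap on the triglyceride-glucose index
#'
#' Per stratum, ordinary least squares of the glycation gap on the
#' triglyceride-glucose index. The default strata are the pre-T2D and
#' normoglycemic classes plus HbA1c bands (<5, 5-5.4, 5.5-5.9%) within
#' normoglycemia. If the cohort carries a `stratum` column (as simulated
#' cohorts do) it is used for the class split; otherwise records are
#' classified by [classify_glycemic_status()]. `tgi` and `gap` columns are
#' derived on the fly when absent. Strata with fewer than `min_n` records
#' are skipped (listed in the `"skipped"` attribute).
#'
#' @param cohort Cohort data frame.
#' @param strata Named list of logical vectors selecting each stratum;
#'   `NULL` for the defaults described above.
#' @param min_n Minimum records per stratum.
#' @param prediction Optional `"hba1c_model"` used to derive `gap` when
#'   that column is absent.
#' @return A data frame of class `"gap_regression"`: one row per stratum
#'   with `stratum`, `n`, `beta`, `se`, `intercept`, `intercept_se`,
#'   `pval`, `r2`, `r2_adj`.
#' @export
regress_gap_on_tgi <- function(cohort, strata = NULL, min_n = 20,
                               prediction = NULL) {
  cohort <- .with_gap_columns(cohort, prediction)
  if (is.null(strata)) strata <- .default_strata(cohort)
  .stratified_ols(cohort, strata, outcome = "gap", min_n = min_n)
}

#' Regression of hemoglobin on the triglyceride-glucose index
#'
#' Ordinary least squares of hemoglobin (g/L) on the triglyceride-glucose
#' index over the whole cohort (sex is not required).
#'
#' @inheritParams regress_gap_on_tgi
#' @return A one-row `"gap_regression"` data frame.
#' @export
regress_hb_on_tgi <- function(cohort, min_n = 20) {
  if (!"tgi" %in% names(cohort)) cohort$tgi <- tgi(cohort$tg, cohort$fg)
  .stratified_ols(cohort, list(all = rep(TRUE, nrow(cohort))),
                  outcome = "hb", min_n = min_n)
}

.stratified_ols <- function(cohort, strata, outcome, min_n) {
  skipped <- character(0)
  rows <- list()
  for (nm in names(strata)) {
    d <- cohort[strata[[nm]], , drop = FALSE]
    if (nrow(d) < min_n) {
      skipped <- c(skipped, nm)
      next
    }
    fit <- stats::lm(stats::as.formula(paste(outcome, "~ tgi")), data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    rows[[nm]] <- data.frame(
      stratum = nm, n = nrow(d),
      beta = co["tgi", 1], se = co["tgi", 2],
      intercept = co["(Intercept)", 1], intercept_se = co["(Intercept)", 2],
      pval = max(co["tgi", 4], .Machine$double.xmin),
      r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no stratum reached the minimum size", call. = FALSE)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, skipped = skipped,
            class = c("gap_regression", "data.frame"))
}

#' Regression diagnostics as plot-ready tables
#'
#' Emits the three diagnostic views used to assess linearity and
#' normality: sorted standardized residuals against normal quantiles
#' (Q-Q), residuals against fitted values, and residuals against the
#' triglyceride-glucose index when available. No figures are rendered;
#' each element is a plain data frame. The Q-Q correlation summarizes
#' normality; a runs test on the fitted-value-ordered residual signs
#' flags curvature.
#'
#' @param model An `lm` fit (or `"hba1c_model"`, whose reduced fit is used).
#' @param cohort Data frame the model was fitted on (for the `tgi` view).
#' @return A list: `qq` (data frame `theoretical`, `sample`), `qq_cor`,
#'   `vs_fitted` (data frame `fitted`, `residual`), `runs_p`, and
#'   `vs_tgi` (or `NULL`).
#' @export
diagnostics <- function(model, cohort = NULL) {
  if (inherits(model, "hba1c_model")) model <- model$reduced
  res <- stats::residuals(model)
  fitted <- stats::fitted(model)
  sdres <- stats::sd(res)
  std <- if (sdres > 0) res / sdres else res
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(std))),
                   sample = sort(std))
  qq_cor <- if (sdres > 0) stats::cor(qq$theoretical, qq$sample) else 1
  ord <- order(fitted)
  runs <- .runs_test(res[ord])
  vs_tgi <- NULL
  if (!is.null(cohort) && "tgi" %in% names(cohort) &&
      nrow(cohort) == length(res))
    vs_tgi <- data.frame(tgi = cohort$tgi, residual = res)
  list(qq = qq, qq_cor = qq_cor,
       vs_fitted = data.frame(fitted = fitted, residual = res),
       runs_p = runs$p, vs_tgi = vs_tgi)
}

#' 0.632-bootstrap validation of a linear model
#'
#' Estimates optimism-corrected fit statistics by the 0.632 bootstrap:
#' each replicate refits the model on a bootstrap resample and evaluates
#' it on the out-of-bag records; corrected statistics combine the
#' apparent and out-of-bag values with weights 0.368 and 0.632. Reported
#' are apparent and corrected R-squared, their difference (the optimism),
#' the percent change in mean squared error, the percent change in the
#' g-index (Gini mean difference of the model predictions), and the
#' calibration-slope shrinkage (1 minus the corrected slope of observed
#' on predicted). Optimism above 0.1 flags overfitting.
#'
#' @param formula Model formula.
#' @param data Data frame with at least 50 rows.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional integer seed.
#' @param optimism_limit Overfitting threshold on the R-squared optimism.
#' @return An object of class `"validation_632"`: list with
#'   `r2_apparent`, `r2_corrected`, `optimism`, `mse_apparent`,
#'   `mse_corrected`, `mse_change_pct`, `g_apparent`, `g_corrected`,
#'   `g_index_change_pct`, `slope_shrinkage`, `overfit`, `n_boot`,
#'   `n_redrawn`.
#' @export
bootstrap_validate_632 <- function(formula, data, n_boot = 200, seed = NULL,
                                   optimism_limit = 0.1) {
  if (nrow(data) < 50)
    stop("validation needs at least 50 records", call. = FALSE)
  fit <- stats::lm(formula, data = data)
  pred <- stats::fitted(fit)
  y <- stats::model.response(stats::model.frame(fit))
  n <- length(y)
  r2_app <- summary(fit)$r.squared
  mse_app <- mean((y - pred)^2)
  g_app <- .gini_mean_difference(pred)

  .with_seed(seed, {
    oob_r2 <- oob_mse <- oob_g <- oob_slope <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) >= 2) break
        redrawn <- redrawn + 1L
      }
      fb <- stats::lm(formula, data = data[idx, , drop = FALSE])
      po <- stats::predict(fb, newdata = data[oob, , drop = FALSE])
      yo <- y[oob]
      sse <- sum((yo - po)^2)
      sst <- sum((yo - mean(yo))^2)
      oob_r2[b] <- if (sst > 0) 1 - sse / sst else 1
      oob_mse[b] <- sse / length(oob)
      oob_g[b] <- .gini_mean_difference(po)
      oob_slope[b] <- if (stats::var(po) > 0)
        stats::cov(yo, po) / stats::var(po) else 1
    }
    r2_corr <- 0.368 * r2_app + 0.632 * mean(oob_r2)
    mse_corr <- 0.368 * mse_app + 0.632 * mean(oob_mse)
    g_corr <- 0.368 * g_app + 0.632 * mean(oob_g)
    slope_corr <- 0.368 * 1 + 0.632 * mean(oob_slope)
    optimism <- r2_app - r2_corr
    structure(list(
      r2_apparent = r2_app, r2_corrected = r2_corr, optimism = optimism,
      mse_apparent = mse_app, mse_corrected = mse_corr,
      mse_change_pct = 100 * (mse_corr - mse_app) / mse_app,
      g_apparent = g_app, g_corrected = g_corr,
      g_index_change_pct = if (g_app > 0) 100 * (g_corr - g_app) / g_app else 0,
      slope_shrinkage = 1 - slope_corr,
      overfit = optimism > optimism_limit,
      n_boot = n_boot, n_redrawn = redrawn),
      class = "validation_632")
  })
}

#' @export
print.validation_632 <- function(x, digits = 4, ...) {
  cat("0.632 bootstrap validation (", x$n_boot, " replicates)\n", sep = "")
  cat(sprintf("  R2 apparent %.4f -> corrected %.4f (optimism %.4f)\n",
              x$r2_apparent, x$r2_corrected, x$optimism))
  cat(sprintf("  MSE change %+.2f%%, g-index change %+.2f%%, slope shrinkage %.4f\n",
              x$mse_change_pct, x$g_index_change_pct, x$slope_shrinkage))
  cat(if (x$overfit) "  Optimism > 0.1: model looks overfit\n"
      else "  No evidence of overfitting\n")
  invisible(x)
}

#' Table-2-style descriptive summary by glycemic class
#'
#' Median and interquartile range per stratum for the continuous
#' characteristics, counts for sex, with Wilcoxon rank-sum (continuous)
#' or Pearson chi-squared (sex) p-values comparing the classes.
#'
#' @param cohort Cohort data frame (columns among `age`, `hba1c`, `fg`,
#'   `tg`, `hdl`, `hb`, `tgi`, `gap`, `sex` are summarized when present).
#' @param class Factor splitting the cohort (defaults to
#'   [classify_glycemic_status()] or the `stratum` column when present).
#' @return A data frame with one row per characteristic.
#' @export
cohort_summary <- function(cohort, class = NULL) {
  cohort <- .with_gap_columns(cohort)
  if (is.null(class)) {
    class <- if ("stratum" %in% names(cohort))
      factor(cohort$stratum) else classify_glycemic_status(cohort)
  }
  lv <- levels(class)
  num_vars <- intersect(c("age", "hba1c", "fg", "tg", "hdl", "hb", "tgi", "gap"),
                        names(cohort))
  fmt <- function(x) sprintf("%.2f (%.2f, %.2f)",
                             stats::median(x), stats::quantile(x, 0.25),
                             stats::quantile(x, 0.75))
  rows <- lapply(num_vars, function(v) {
    a <- cohort[[v]][class == lv[1]]; b <- cohort[[v]][class == lv[2]]
    p <- stats::wilcox.test(a, b)$p.value
    data.frame(characteristic = v, g1 = fmt(a), g2 = fmt(b), pval = p,
               stringsAsFactors = FALSE)
  })
  if ("sex" %in% names(cohort)) {
    tab <- table(cohort$sex, class)
    p <- stats::chisq.test(tab)$p.value
    rows <- c(rows, list(data.frame(
      characteristic = "sex (n female)",
      g1 = as.character(tab["female", lv[1]]),
      g2 = as.character(tab["female", lv[2]]),
      pval = p, stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv[1:2]
  out
}
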