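make_cohort <- function(n = 200, age = 45, sex = NULL, fg = 5.1, hba1c = 5.4,
                        hb = NULL, tg = 1.2, hdl = 1.3) {
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  if (is.null(hb)) hb <- ifelse(sex == "female", 140, 150)
  data.frame(age = rep(age, length.out = n), sex = sex,
             fg = rep(fg, length.out = n), tg = rep(tg, length.out = n),
             hdl = rep(hdl, length.out = n),
             hba1c = rep(hba1c, length.out = n), hb = hb,
             stringsAsFactors = FALSE)
}

test_that("cohort filters enforce the inclusion boundaries", {
  base <- make_cohort(8)
  base$age <- c(50, 66, 17, 50, 50, 50, 50, 50)
  base$fg <- c(5.1, 5.1, 5.1, 7.0, 5.1, 5.1, 5.1, 5.1) # 7.0 excluded (>=)
  base$hba1c <- c(5.4, 5.4, 5.4, 5.4, 6.5, 5.4, 5.4, 5.4) # 6.5 excluded (>=)
  base$sex <- c("female", "male", "female", "male", "female", "other",
                "female", "male")
  base$hb <- c(140, 150, 140, 150, 140, 140, 119, 150) # 119 < female low
  out <- apply_cohort_filters(base)
  expect_equal(nrow(out$kept), 2L)
  expect_equal(unname(out$exclusions[c("age", "fasting_glucose", "hba1c",
                                       "unclassifiable", "hemoglobin")]),
               c(2L, 1L, 1L, 1L, 1L))
  # boundary checks: age 18 and 65 are kept, hb bounds inclusive
  edge <- make_cohort(4)
  edge$age <- c(18, 65, 40, 40)
  edge$sex <- c("male", "male", "male", "male")
  edge$hb <- c(150, 150, 130, 170)
  expect_equal(nrow(apply_cohort_filters(edge)$kept), 4L)
  # optional diabetes-clinic flag is applied first
  flagged <- make_cohort(3)
  flagged$diabetes_clinic_2y <- c(TRUE, FALSE, FALSE)
  flagged$fg[1] <- 7.5 # would also fail fg, but clinic reason wins
  out2 <- apply_cohort_filters(flagged)
  expect_equal(unname(out2$exclusions["diabetes_clinic"]), 1L)
  expect_equal(unname(out2$exclusions["fasting_glucose"]), 0L)
})

test_that("glycemic classification partitions under 'either' and not under 'both'", {
  d <- data.frame(hba1c = c(5.4, 6.1, 5.9, 6.2), fg = c(5.1, 5.7, 6.5, 6.2))
  either <- classify_glycemic_status(d)
  expect_equal(as.character(either),
               c("normoglycemia", "preT2D", "preT2D", "preT2D"))
  both <- classify_glycemic_status(d, rule = "both")
  expect_equal(as.character(both),
               c("normoglycemia", "indeterminate", "indeterminate", "preT2D"))
  # partition property on filtered simulated data
  coh <- simulate_cohort(n = 1500, seed = 8)
  cls <- classify_glycemic_status(coh)
  expect_equal(sum(cls == "normoglycemia") + sum(cls == "preT2D"), nrow(coh))
})

test_that("the triglyceride-glucose index matches its closed form", {
  expect_equal(round(tgi(1.16, 5.10), 2), 8.46)
  expect_equal(round(tgi(1.33, 5.70), 2), 8.71)
  expect_equal(tgi(1, 1), log(88.57 * 18 / 2), tolerance = 1e-12)
  expect_error(tgi(-1, 5), "positive")
  expect_error(tgi(1, 0), "positive")
  # monotone in each argument, and a function of the product only
  expect_gt(tgi(1.3, 5), tgi(1.2, 5))
  expect_gt(tgi(1.2, 5.5), tgi(1.2, 5))
  expect_equal(tgi(2, 3), tgi(3, 2), tolerance = 1e-12)
  expect_equal(tgi(1.5, 4), tgi(6, 1), tolerance = 1e-12)
})

test_that("the HbA1c prediction model recovers a planted glucose slope", {
  set.seed(71)
  n <- 800
  d <- data.frame(fg = runif(n, 4, 6.5), age = sample(18:65, n, TRUE),
                  sex = sample(c("female", "male"), n, TRUE))
  d$hba1c <- 4.163 + 0.172 * d$fg + rnorm(n, 0, 0.1)
  m <- fit_predicted_hba1c(d)
  co <- summary(m$reduced)$coefficients
  expect_lt(abs(co["fg", 1] - 0.172), 3 * co["fg", 2])
  expect_equal(unname(predict(m, data.frame(fg = 5))),
               unname(m$equation[1] + 5 * m$equation[2]), tolerance = 1e-10)
  # degenerate designs are refused
  expect_error(fit_predicted_hba1c(d[1:5, ]), "at least 10")
  d_one_sex <- d; d_one_sex$sex <- "female"
  expect_error(fit_predicted_hba1c(d_one_sex), "both sexes")
})

test_that("glycation gap is the exact difference of measured and predicted", {
  expect_equal(glycation_gap(5.40, 5.04), 0.36, tolerance = 1e-10)
  expect_equal(round(glycation_gap(5.40, 4.163 + 0.172 * 5.10), 2), 0.36)
  expect_equal(glycation_gap(6.2, 6.2), 0)
  expect_equal(glycation_gap(6.10, 5.14), 0.96)
  # identity: gap + predicted == measured
  m <- runif(10, 5, 6.4); p <- runif(10, 5, 6.4)
  expect_equal(glycation_gap(m, p) + p, m, tolerance = 1e-14)
})

test_that("stratified gap regressions recover the planted slopes", {
  coh <- simulate_cohort(n = 7600, seed = 72)
  res <- regress_gap_on_tgi(coh)
  pre <- res[res$stratum == "preT2D", ]
  hea <- res[res$stratum == "healthy", ]
  expect_lt(abs(pre$beta - (-0.087)), 3 * pre$se)
  expect_lt(abs(hea$beta - 0.023), 3 * hea$se)
  expect_lt(pre$beta, 0)
  expect_gt(hea$beta, 0)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_equal(res$stratum[1:2], c("preT2D", "healthy"))
  # small strata are skipped, not fitted
  tiny <- regress_gap_on_tgi(coh, strata = list(big = rep(TRUE, nrow(coh)),
                                                small = seq_len(nrow(coh)) <= 5))
  expect_equal(attr(tiny, "skipped"), "small")
})

test_that("the hemoglobin regression recovers its planted slope", {
  coh <- simulate_cohort(n = 7600, seed = 73)
  res <- regress_hb_on_tgi(coh)
  expect_lt(abs(res$beta - 1.88), 3 * res$se)
  # a slope-free cohort shows no association
  set.seed(74)
  coh$hb <- rnorm(nrow(coh), 145, 12)
  res0 <- regress_hb_on_tgi(coh)
  expect_lt(abs(res0$beta), 3 * res0$se)
  # runs on a single-sex cohort
  one <- coh[coh$sex == "female", ]
  expect_s3_class(regress_hb_on_tgi(one), "gap_regression")
})

test_that("a pure-noise gap is declared non-significant at the nominal rate", {
  set.seed(75)
  reps <- 200
  p <- numeric(reps)
  n <- 150
  for (i in seq_len(reps)) {
    d <- data.frame(tgi = rnorm(n, 8.5, 0.5), gap = rnorm(n, 0, 0.3))
    p[i] <- regress_gap_on_tgi(d, strata = list(all = rep(TRUE, n)))$pval
  }
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("diagnostics expose normality and curvature in plot-ready form", {
  set.seed(76)
  n <- 400
  d <- data.frame(tgi = runif(n, 7.5, 9.5))
  d$gap <- 0.2 + 0.05 * d$tgi + rnorm(n, 0, 0.2)
  m <- lm(gap ~ tgi, data = d)
  diag_ok <- diagnostics(m, d)
  expect_gt(diag_ok$qq_cor, 0.99)
  expect_gt(diag_ok$runs_p, 0.05)
  expect_equal(nrow(diag_ok$vs_fitted), n)
  expect_equal(nrow(diag_ok$vs_tgi), n)

  # cubic signal fitted linearly: runs test flags the curvature
  d$gap <- 0.05 * (d$tgi - 8.5)^3 + rnorm(n, 0, 0.01)
  diag_bad <- diagnostics(lm(gap ~ tgi, data = d), d)
  expect_lt(diag_bad$runs_p, 0.05)

  # perfect fit: all residuals zero
  d$gap <- 1 + 2 * d$tgi
  diag_perfect <- diagnostics(lm(gap ~ tgi, data = d), d)
  expect_true(all(abs(diag_perfect$vs_fitted$residual) < 1e-10))
})

test_that("0.632 bootstrap validation separates honest fits from overfits", {
  set.seed(77)
  # large, well-specified: negligible optimism
  n <- 2000
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n, 0, 0.5)
  v <- bootstrap_validate_632(y ~ x, d, n_boot = 100, seed = 1)
  expect_lt(v$optimism, 0.02)
  expect_false(v$overfit)
  expect_equal(v$optimism, v$r2_apparent - v$r2_corrected, tolerance = 1e-12)

  # n = 60 with 20 noise covariates: clear overfitting
  n2 <- 60
  noise <- as.data.frame(matrix(rnorm(n2 * 20), n2, 20))
  names(noise) <- paste0("z", 1:20)
  d2 <- cbind(data.frame(y = rnorm(n2)), noise)
  v2 <- bootstrap_validate_632(y ~ ., d2, n_boot = 100, seed = 2)
  expect_gt(v2$optimism, 0.1)
  expect_true(v2$overfit)

  # noiseless linear data: no optimism at all
  d3 <- data.frame(x = rnorm(60))
  d3$y <- 2 + 3 * d3$x
  v3 <- suppressWarnings(bootstrap_validate_632(y ~ x, d3, n_boot = 50, seed = 3))
  expect_equal(v3$r2_apparent, 1, tolerance = 1e-10)
  expect_equal(v3$r2_corrected, 1, tolerance = 1e-8)
  expect_equal(v3$optimism, 0, tolerance = 1e-8)
  expect_equal(v3$slope_shrinkage, 0, tolerance = 1e-8)
})

test_that("cohort summaries report stratum medians in publication form", {
  coh <- simulate_cohort(n = 3000, seed = 78)
  s <- cohort_summary(coh)
  expect_true(all(c("hba1c", "fg", "tgi", "gap") %in% s$characteristic))
  expect_true(all(s$pval >= 0 & s$pval <= 1))
  expect_match(s[s$characteristic == "fg", 2], "^\\d+\\.\\d+ \\(")
})
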