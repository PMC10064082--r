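test_that("Wald ratio is the delta-method quotient", {
  est <- wald_ratio(0.5, 0.05, 0.25, 0.05)
  expect_equal(est$b, 0.5)
  expect_equal(est$se, 0.1)
  est <- wald_ratio(-0.5, 0.05, 0.25, 0.05)
  expect_equal(est$b, -0.5)
  expect_equal(est$se, 0.1)
  est <- wald_ratio(1, 0.03, 0.42, 0.07) # identity denominator
  expect_equal(est$b, 0.42)
  expect_equal(est$se, 0.07)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.05), "non-zero")
})

test_that("IVW matches the hand-computed closed form on the 3-SNP set", {
  set <- hand_set()
  est <- mr_ivw(set, effects_model = "fixed")
  expect_equal(est$b, 0.6)
  expect_equal(est$se, sqrt(1 / 300))
  expect_equal(attr(est, "Q"), 2)
  # Q = 2 = df, so the random-effects scale factor is exactly 1
  est_re <- mr_ivw(set, effects_model = "multiplicative_random")
  expect_equal(est_re$se, est$se)
})

test_that("IVW on a single SNP degenerates to the Wald ratio", {
  set <- harmonized_set(0.5, 0.05, 0.25, 0.05)
  expect_equal(mr_ivw(set)$b, wald_ratio(0.5, 0.05, 0.25, 0.05)$b)
  expect_equal(mr_ivw(set)$se, wald_ratio(0.5, 0.05, 0.25, 0.05)$se)
})

test_that("IVW agrees with weighted zero-intercept least squares", {
  set.seed(4)
  set <- harmonized_set(rnorm(20, 0.1, 0.03), rep(0.01, 20),
                        rnorm(20, 0.05, 0.02), runif(20, 0.005, 0.02))
  est <- mr_ivw(set)
  ref <- lm(beta_out ~ 0 + beta_exp, data = set, weights = 1 / set$se_out^2)
  expect_equal(est$b, unname(coef(ref)), tolerance = 1e-12)
  # lm's residual scaling equals the multiplicative random-effects model
  # whenever Q > df, which holds here
  expect_equal(est$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-10)
})

test_that("MR-Egger reproduces the exact two-point line and the WLS oracle", {
  two <- harmonized_set(c(1, 2), c(0.01, 0.01), c(0.6, 1.0), c(0.1, 0.1))
  est <- mr_egger(two)
  expect_equal(est$b, 0.4, tolerance = 1e-12)
  expect_equal(est$intercept, 0.2, tolerance = 1e-12)
  expect_equal(attr(est, "Q"), 0, tolerance = 1e-20)

  set.seed(7)
  set <- harmonized_set(runif(15, 0.05, 0.2), rep(0.01, 15),
                        rnorm(15, 0.05, 0.03), runif(15, 0.01, 0.03))
  est <- mr_egger(set)
  ref <- lm(beta_out ~ beta_exp, data = set, weights = 1 / set$se_out^2)
  expect_equal(est$b, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(est$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(est$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-10)
})

test_that("constraining the Egger intercept to zero recovers the IVW slope", {
  set.seed(8)
  set <- harmonized_set(runif(12, 0.05, 0.2), rep(0.01, 12),
                        rnorm(12, 0.08, 0.02), runif(12, 0.01, 0.03))
  through_origin <- lm(beta_out ~ 0 + beta_exp, data = set,
                       weights = 1 / set$se_out^2)
  expect_equal(mr_ivw(set)$b, unname(coef(through_origin)), tolerance = 1e-12)
})

test_that("Egger recovers a planted intercept and leaves the slope alone", {
  set.seed(21)
  J <- 50
  bx <- runif(J, 0.05, 0.25)
  sy <- runif(J, 0.005, 0.02)
  by0 <- 0.5 * bx + rnorm(J, 0, sy)
  base <- mr_egger(harmonized_set(bx, rep(0.001, J), by0, sy))
  shifted <- mr_egger(harmonized_set(bx, rep(0.001, J), by0 + 0.03, sy))
  expect_equal(shifted$intercept, base$intercept + 0.03, tolerance = 1e-10)
  expect_equal(shifted$b, base$b, tolerance = 1e-10)
  expect_lt(abs(base$intercept), 3 * base$intercept_se)
})

test_that("weighted median interpolates the weighted ratio quantile", {
  # equal weights, odd J: plain sample median
  set <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(0.4, 0.5, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(set, n_boot = 0)$b, 0.5)

  # hand-interpolated example: weights (0.6, 0.2, 0.2) on ratios
  # (0.4, 0.5, 0.9) -> cumulative midpoints (0.3, 0.7, 0.9) -> 0.45
  se_out <- 0.1 / sqrt(c(0.6, 0.2, 0.2)) # so 1/se(r)^2 gives those weights
  set <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(0.4, 0.5, 0.9), se_out)
  expect_equal(mr_weighted_median(set, n_boot = 0)$b, 0.45, tolerance = 1e-12)

  # equal weights == sample median for larger odd J
  set.seed(31)
  r <- rnorm(11, 0.5, 0.2)
  set <- harmonized_set(rep(1, 11), rep(0.01, 11), r, rep(0.1, 11))
  expect_equal(mr_weighted_median(set, n_boot = 0)$b, median(r),
               tolerance = 1e-12)
})

test_that("the weighted median resists large-ratio contamination that moves IVW", {
  set.seed(12)
  J <- 30
  bx <- runif(J, 0.1, 0.3)
  sy <- rep(0.01, J)
  by <- 0.5 * bx + rnorm(J, 0, sy)
  bad <- 1:12 # 40% invalid
  by[bad] <- by[bad] + 0.12
  set <- harmonized_set(bx, rep(0.005, J), by, sy)
  wm <- mr_weighted_median(set, n_boot = 200, seed = 1)
  iv <- mr_ivw(set)
  expect_lt(abs(wm$b - 0.5), 0.1)
  expect_gt(abs(iv$b - 0.5), abs(wm$b - 0.5))
  expect_gt(wm$se, 0)
})

test_that("mode-based estimates find the densest ratio cluster", {
  # degenerate: identical ratios
  set <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(0.7, 0.7, 0.7), rep(0.1, 3))
  expect_equal(mr_mode(set, n_boot = 0)$b, 0.7)

  # 3 ratios at 0.5, one at 2.0, small bandwidth: mode at 0.5, confirmed
  # by an independent dense-grid kernel-density oracle
  set <- harmonized_set(rep(1, 4), rep(0.01, 4), c(0.5, 0.5, 0.5, 2.0),
                        rep(0.1, 4))
  est <- mr_mode(set, weighted = FALSE, phi = 0.25, n_boot = 0)
  r <- c(0.5, 0.5, 0.5, 2.0)
  bw <- 0.25 * 0.9 * min(sd(r), IQR(r) / 1.349) * length(r)^(-0.2)
  grid <- seq(-1, 3, length.out = 20001)
  dens <- sapply(grid, function(g) sum(dnorm((g - r) / bw)))
  expect_equal(est$b, grid[which.max(dens)], tolerance = 1e-2)
  expect_lt(abs(est$b - 0.5), 0.05)

  # weighted mode tracks the high-precision cluster in a bimodal set
  set.seed(13)
  r2 <- c(rnorm(18, 0.5, 0.01), rnorm(9, 1.5, 0.01))
  set <- harmonized_set(rep(1, 27), rep(0.01, 27), r2,
                        c(rep(0.05, 18), rep(0.05, 9)))
  expect_lt(abs(mr_mode(set, n_boot = 0)$b - 0.5), 0.05)
})

test_that("Cochran's Q, I-squared and F follow their closed forms", {
  set <- hand_set()
  h <- cochran_q(set, beta_ref = 0.6)
  expect_equal(h$Q, 2)
  expect_equal(h$df, 2L)
  expect_equal(h$I2, 0) # Q == df
  # identical ratios: no heterogeneity
  same <- harmonized_set(c(1, 2), c(0.01, 0.01), c(0.5, 1.0), c(0.1, 0.1))
  expect_equal(cochran_q(same, beta_ref = 0.5)$Q, 0)
  expect_equal(cochran_q(same, beta_ref = 0.5)$I2, 0)

  expect_equal(f_statistic(make_stats("rs1", beta = 0.4, se = 0.1)), 16)
  expect_equal(f_statistic(make_stats(c("a", "b"), beta = c(0.3, 0.5),
                                      se = 0.1)), 17)
  weak <- make_stats(c("a", "b"), beta = c(0.02, 0.01), se = 0.01)
  expect_warning(f_statistic(weak), "weak instrument")
})

test_that("I-squared reproduces published heterogeneity values to 3 decimals", {
  # (Q, df) -> printed I2, spanning univariable and multivariable fits
  cases <- rbind(
    c(857.625, 47, 94.520), c(864.803, 48, 94.450),
    c(1520.582, 47, 96.909), c(1633.210, 48, 97.061),
    c(1744.044, 47, 97.305), c(1902.129, 48, 97.477),
    c(2610.360, 47, 98.199), c(2610.361, 48, 98.161),
    c(1111.614, 82, 92.623), c(1211.384, 112, 90.754),
    c(8336.312, 403, 95.166))
  expect_equal(round(i_squared(cases[, 1], cases[, 2]), 3), cases[, 3])
})

test_that("leave-one-out flags exactly a single influential outlier", {
  # identical ratios: every leave-one-out estimate equals the full one
  set <- harmonized_set(c(1, 2, 4), rep(0.01, 3), c(0.5, 1.0, 2.0),
                        rep(0.1, 3))
  loo <- leave_one_out(set)
  expect_equal(loo$b, rep(0.5, 3), tolerance = 1e-12)

  # dropping the third SNP of the hand set leaves IVW of (0.5, 0.7) = 0.6
  loo <- leave_one_out(hand_set())
  expect_equal(loo$b[3], 0.6)

  # one gross outlier: only its removal moves the estimate appreciably
  set.seed(41)
  J <- 20
  bx <- runif(J, 0.1, 0.3)
  by <- 0.5 * bx + rnorm(J, 0, 0.005)
  by[7] <- by[7] + 0.4
  set <- harmonized_set(bx, rep(0.005, J), by, rep(0.005, J))
  loo <- leave_one_out(set)
  full <- mr_ivw(set)
  shift <- abs(loo$b - full$b)
  expect_equal(which.max(shift), 7L)
  expect_gt(shift[7], 3 * loo$se[7])
  expect_true(all(shift[-7] < shift[7] / 3))
})

test_that("random-effects IVW standard errors never undercut fixed effects", {
  for (s in 1:10) {
    set.seed(s)
    J <- 15
    set <- harmonized_set(runif(J, 0.05, 0.3), rep(0.01, J),
                          rnorm(J, 0.1, 0.05), runif(J, 0.01, 0.05))
    re <- mr_ivw(set, "multiplicative_random")
    fe <- mr_ivw(set, "fixed")
    expect_gte(re$se, fe$se)
    if (attr(re, "Q") <= attr(re, "Q_df")) expect_equal(re$se, fe$se)
  }
})

test_that("the fitted suite keeps the reporting order and supports its methods", {
  sim <- simulate_two_sample_gwas(J = 30, seed = 9)
  set <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(set, n_boot = 50, seed = 2)
  expect_s3_class(fit, "mr_fit")
  expect_equal(fit$estimates$method,
               c("MR Egger", "Weighted median", "Inverse variance weighted",
                 "Simple mode", "Weighted mode"))
  expect_equal(fit$heterogeneity$method,
               c("MR Egger", "Inverse variance weighted"))
  expect_true(all(fit$estimates$se > 0))
  expect_true(all(fit$estimates$pval > 0 & fit$estimates$pval <= 1))
  # intercept fields only for Egger
  expect_equal(is.finite(fit$estimates$intercept),
               fit$estimates$method == "MR Egger")

  expect_named(coef(fit), fit$estimates$method)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_length(residuals(fit), nrow(set))
  expect_output(print(summary(fit)), "Heterogeneity")
  expect_equal(nrow(mr_scatter_data(fit)), nrow(set))
  expect_equal(nrow(mr_funnel_data(fit)), nrow(set))

  # identical-ratio set: all five estimators agree exactly
  same <- harmonized_set(c(1, 2, 3, 4), rep(0.01, 4), c(0.5, 1, 1.5, 2),
                         rep(0.1, 4))
  fit0 <- mr_fit(same, n_boot = 20, seed = 1)
  expect_equal(fit0$estimates$b, rep(0.5, 5), tolerance = 1e-6)

  # same seed, same answer
  fit2 <- mr_fit(set, n_boot = 50, seed = 2)
  expect_identical(fit$estimates, fit2$estimates)
})
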