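# Univariable two-sample MR estimators. Each works from per-SNP harmonized
# exposure/outcome effects (beta_exp, se_exp, beta_out, se_out) and returns
# an "mr_estimate" row: method, b, se, pval, nsnp (+ intercept fields for
# MR-Egger). All p-values are two-sided; MR-Egger uses a t reference with
# J - 2 df, the others a normal reference.

.mr_estimate <- function(method, b, se, pval, nsnp,
                         intercept = NA_real_, intercept_se = NA_real_,
                         intercept_p = NA_real_) {
  data.frame(method = method, b = b, se = se, pval = pval, nsnp = nsnp,
             intercept = intercept, intercept_se = intercept_se,
             intercept_p = intercept_p, stringsAsFactors = FALSE)
}

.ratio_parts <- function(set) {
  if (any(set$beta_exp == 0))
    stop("beta_exp = 0 for SNP(s) ", paste(set$snp[set$beta_exp == 0], collapse = ", "),
         "; exclude upstream", call. = FALSE)
  list(r = set$beta_out / set$beta_exp,
       se_r = set$se_out / abs(set$beta_exp))
}

#' Wald ratio estimate for a single SNP
#'
#' The per-SNP causal estimate: SNP-outcome effect divided by SNP-exposure
#' effect, with the first-order delta-method standard error
#' `se_out / |beta_exp|`.
#'
#' @param beta_exp,se_exp SNP-exposure effect and its standard error.
#' @param beta_out,se_out SNP-outcome effect and its standard error.
#' @return A one-row `mr_estimate` data frame.
#' @examples
#' wald_ratio(0.5, 0.05, 0.25, 0.05)
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("beta_exp must be non-zero", call. = FALSE)
  b <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  .mr_estimate("Wald ratio", b, se, .p_from_z(b / se), 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Meta-analysis of the per-SNP Wald ratios with weights `1/se_out^2`,
#' equivalently a zero-intercept weighted regression of outcome effects on
#' exposure effects. Under the multiplicative random-effects model (the
#' default) the fixed-effects standard error is inflated by
#' `sqrt(max(1, Q/df))`, so it never falls below the fixed-effects one.
#'
#' @param set A `"harmonized_set"` data frame (or anything with columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return A one-row `mr_estimate` data frame; Cochran's Q and its df are
#'   attached as attributes `Q` and `Q_df`.
#' @export
mr_ivw <- function(set, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  J <- nrow(set)
  if (J == 0) stop("empty harmonized set", call. = FALSE)
  if (J == 1)
    return(wald_ratio(set$beta_exp, set$se_exp, set$beta_out, set$se_out))
  w <- 1 / set$se_out^2
  b <- sum(w * set$beta_exp * set$beta_out) / sum(w * set$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * set$beta_exp^2))
  Q <- sum(w * (set$beta_out - b * set$beta_exp)^2)
  df <- J - 1
  se <- if (effects_model == "multiplicative_random")
    se_fixed * sqrt(max(1, Q / df)) else se_fixed
  est <- .mr_estimate("Inverse variance weighted", b, se, .p_from_z(b / se), J)
  attr(est, "Q") <- Q
  attr(est, "Q_df") <- df
  est
}

#' MR-Egger regression estimate
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`). The slope is the causal estimate; the
#' intercept estimates the average directional pleiotropic effect, so a
#' non-zero intercept is evidence of directional pleiotropy. Effects are
#' first oriented so every exposure effect is positive (the usual Egger
#' convention; the slope is invariant, the intercept is not). Standard
#' errors are inflated by `sqrt(max(1, Q/(J-2)))` and p-values use a t
#' reference with `J - 2` df.
#'
#' @inheritParams mr_ivw
#' @return A one-row `mr_estimate` data frame with intercept fields; Q and
#'   df attached as attributes.
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 2) stop("MR-Egger needs at least 2 SNPs", call. = FALSE)
  flip <- sign(set$beta_exp)
  flip[flip == 0] <- 1
  bx <- set$beta_exp * flip
  by <- set$beta_out * flip
  w <- 1 / set$se_out^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  denom <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / denom
  inter <- (swy - slope * swx) / sw
  resid <- by - inter - slope * bx
  Q <- sum(w * resid^2)
  df <- J - 2
  scale2 <- if (df > 0) max(1, Q / df) else 1
  se_slope <- sqrt(sw / denom * scale2)
  se_inter <- sqrt(sxx / denom * scale2)
  p_slope <- if (df > 0) .p_from_t(slope / se_slope, df) else NA_real_
  p_inter <- if (df > 0) .p_from_t(inter / se_inter, df) else NA_real_
  est <- .mr_estimate("MR Egger", slope, se_slope, p_slope, J,
                      intercept = inter, intercept_se = se_inter,
                      intercept_p = p_inter)
  attr(est, "Q") <- Q
  attr(est, "Q_df") <- df
  est
}

# Weighted quantile of the ratio estimates at probability p, with the
# standardized cumulative weights p_j = S_j - w_j/2 (weights sum to 1) and
# linear interpolation between adjacent order statistics.
.weighted_quantile <- function(r, w, p = 0.5) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (p <= cw[1]) return(r[1])
  if (p >= cw[length(cw)]) return(r[length(r)])
  stats::approx(cw, r, xout = p, ties = "ordered")$y
}

.wm_point <- function(bx, by, se_r_inv2, r = by / bx) {
  .weighted_quantile(r, se_r_inv2)
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP Wald ratios, with weights equal to
#' the inverse variance of each ratio (delta-method
#' `se_out/|beta_exp|`). Consistent when SNPs contributing at least half
#' of the weight are valid instruments, so it tolerates up to (but not
#' including) 50% invalid SNPs. The standard error comes from a seeded
#' parametric bootstrap that resamples the summary statistics from their
#' reported normal sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Parametric bootstrap replicates for the standard error;
#'   `0` skips the bootstrap and returns `NA` for `se` and `pval`.
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row `mr_estimate` data frame.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL) {
  J <- nrow(set)
  if (J < 3) stop("weighted median needs at least 3 SNPs", call. = FALSE)
  rp <- .ratio_parts(set)
  w <- 1 / rp$se_r^2
  b <- .weighted_quantile(rp$r, w)
  se <- .boot_se(set, n_boot, seed, function(bx, by) {
    .weighted_quantile(by / bx, (abs(bx) / set$se_out)^2)
  })
  .mr_estimate("Weighted median", b, se,
               if (is.na(se)) NA_real_ else .p_from_z(b / se), J)
}

# Parametric bootstrap SE: resample beta_exp and beta_out from their
# reported sampling distributions, recompute the point estimate.
.boot_se <- function(set, n_boot, seed, point_fun) {
  if (n_boot <= 0) return(NA_real_)
  .with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(set), set$beta_exp, set$se_exp)
      by <- stats::rnorm(nrow(set), set$beta_out, set$se_out)
      bx[bx == 0] <- .Machine$double.eps
      point_fun(bx, by)
    }, numeric(1))
    stats::sd(ests)
  })
}

# Modified Silverman bandwidth on the ratio estimates.
.mode_bandwidth <- function(r, phi) {
  s <- stats::sd(r)
  iqr <- stats::IQR(r) / 1.349
  spread <- if (iqr > 0) min(s, iqr) else s
  phi * 0.9 * spread * length(r)^(-1 / 5)
}

# Argmax of the (optionally weighted) normal-kernel density of the ratios
# on a regular grid spanning the ratios +/- 3 bandwidths.
.mode_point <- function(r, w, bw, grid_n = 512) {
  if (!is.finite(bw) || bw <= 0) return(r[1])
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = grid_n)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / bw)) # / (bw sum w): argmax-invariant
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Clusters the per-SNP Wald ratios by smoothing them with a normal kernel
#' and takes the causal estimate from the largest cluster: the argmax of
#' the kernel density, located on a 512-point grid spanning the ratios
#' plus/minus three bandwidths. The bandwidth is `phi` times the modified
#' Silverman rule `0.9 min(sd, IQR/1.349) J^(-1/5)`. The weighted variant
#' weights each ratio by its inverse variance. Consistent when the valid
#' SNPs form the largest cluster, a weaker condition than the median's.
#' If all ratios coincide the bandwidth degenerates and that common ratio
#' is returned. Bootstrap standard errors as for [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param phi Bandwidth multiplier.
#' @param grid_n Number of grid points for the density argmax.
#' @return A one-row `mr_estimate` data frame.
#' @export
mr_mode <- function(set, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = NULL, grid_n = 512) {
  J <- nrow(set)
  if (J < 3) stop("mode-based estimation needs at least 3 SNPs", call. = FALSE)
  rp <- .ratio_parts(set)
  w <- if (weighted) 1 / rp$se_r^2 else rep(1, J)
  bw <- .mode_bandwidth(rp$r, phi)
  b <- .mode_point(rp$r, w, bw, grid_n)
  se <- .boot_se(set, n_boot, seed, function(bx, by) {
    r <- by / bx
    wb <- if (weighted) (abs(bx) / set$se_out)^2 else rep(1, J)
    .mode_point(r, wb, .mode_bandwidth(r, phi), grid_n)
  })
  .mr_estimate(if (weighted) "Weighted mode" else "Simple mode", b, se,
               if (is.na(se)) NA_real_ else .p_from_z(b / se), J)
}

#' Cochran's Q heterogeneity statistic about a reference slope
#'
#' `Q = sum w_j (beta_out_j - beta_ref * beta_exp_j)^2` with weights
#' `1/se_out^2`. `I2 = max(0, (Q - df)/Q) * 100` percent (0 when Q is 0).
#' For the IVW fit `df = J - 1`; MR-Egger loses one more df to its
#' intercept.
#'
#' @inheritParams mr_ivw
#' @param beta_ref Slope about which heterogeneity is measured.
#' @param df Degrees of freedom (default `J - 1`).
#' @param intercept Optional intercept subtracted from the residuals
#'   (MR-Egger case).
#' @return A list of class `"heterogeneity"`: `Q`, `df`, `pval`, `I2`.
#' @export
cochran_q <- function(set, beta_ref, df = nrow(set) - 1L, intercept = 0) {
  if (nrow(set) < 2) stop("heterogeneity needs at least 2 SNPs", call. = FALSE)
  w <- 1 / set$se_out^2
  Q <- sum(w * (set$beta_out - intercept - beta_ref * set$beta_exp)^2)
  structure(list(Q = Q, df = as.integer(df),
                 pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = i_squared(Q, df)),
            class = "heterogeneity")
}

#' I-squared from Cochran's Q and its degrees of freedom
#'
#' The percentage of variability across per-SNP estimates attributable to
#' heterogeneity rather than sampling error: `max(0, (Q - df)/Q) * 100`,
#' reported in percent (0 when `Q = 0`).
#'
#' @param Q Cochran's Q statistic (non-negative).
#' @param df Its degrees of freedom.
#' @return I-squared in percent.
#' @examples
#' i_squared(857.625, 47) # 94.520...
#' @export
i_squared <- function(Q, df) {
  ifelse(Q > 0, pmax(0, (Q - df) / Q) * 100, 0)
}

#' Mean F-statistic of an instrument
#'
#' Instrument strength summarized as the mean squared z-statistic of the
#' SNP-exposure associations, `mean((beta_exp/se_exp)^2)`. Values below 10
#' conventionally flag a weak instrument and raise a warning.
#'
#' @param x An `mr_instrument` or `harmonized_set` data frame with columns
#'   `beta` / `se` or `beta_exp` / `se_exp`.
#' @param warn Emit the weak-instrument warning when F < 10.
#' @return The mean F-statistic (numeric scalar).
#' @export
f_statistic <- function(x, warn = TRUE) {
  if (all(c("beta_exp", "se_exp") %in% names(x))) {
    z <- x$beta_exp / x$se_exp
  } else if (all(c("beta", "se") %in% names(x))) {
    z <- x$beta / x$se
  } else stop("need beta/se or beta_exp/se_exp columns", call. = FALSE)
  if (length(z) == 0) stop("empty instrument", call. = FALSE)
  f <- mean(z^2)
  if (warn && f < 10)
    warning(sprintf("mean F-statistic %.3f < 10: weak instrument", f),
            call. = FALSE)
  f
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits the IVW estimate J times, dropping one SNP each time, to check
#' whether any single SNP (potentially with a horizontal pleiotropic
#' effect) drives the pooled estimate.
#'
#' @inheritParams mr_ivw
#' @return A data frame with one row per dropped SNP: `snp`, `b`, `se`,
#'   `pval`, `nsnp`.
#' @export
leave_one_out <- function(set, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  J <- nrow(set)
  if (J < 3) stop("leave-one-out needs at least 3 SNPs", call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(set[-j, , drop = FALSE], effects_model)
    data.frame(snp = set$snp[j], b = est$b, se = est$se, pval = est$pval,
               nsnp = J - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
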