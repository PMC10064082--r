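#' Fit the univariable two-sample MR estimator suite
#'
#' The central fitting function for univariable MR. Given a harmonized set
#' of per-SNP exposure/outcome effects it runs, in fixed order, MR-Egger,
#' weighted median, inverse-variance weighted (IVW), simple mode and
#' weighted mode, and computes Cochran's Q / I-squared heterogeneity for
#' the Egger and IVW fits together with the instrument's mean F-statistic.
#' Results are reproducible for a given `seed` (which drives only the
#' bootstrap standard errors of the median and mode estimators).
#'
#' @param set A `"harmonized_set"` data frame (see [harmonize()] or
#'   [harmonized_set()]).
#' @param methods Subset of
#'   `c("egger", "weighted_median", "ivw", "simple_mode", "weighted_mode")`;
#'   the fixed reporting order is kept regardless of the order given.
#' @param effects_model IVW error model, `"multiplicative_random"`
#'   (default) or `"fixed"`.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param phi Mode bandwidth multiplier.
#' @param seed Optional integer seed.
#' @return An object of class `"mr_fit"`: a list with elements
#'   `estimates` (data frame, one row per method), `heterogeneity`
#'   (data frame for MR Egger and IVW), `f_statistic`, `set`, and the call.
#' @examples
#' sim <- simulate_two_sample_gwas(mr_scenario("fi_hb_like"), seed = 1)
#' set <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(set, n_boot = 100, seed = 1)
#' summary(fit)
#' @seealso [mr_ivw()], [mr_egger()], [mr_weighted_median()], [mr_mode()],
#'   [leave_one_out()], [mvmr_fit()]
#' @export
mr_fit <- function(set,
                   methods = c("egger", "weighted_median", "ivw",
                               "simple_mode", "weighted_mode"),
                   effects_model = c("multiplicative_random", "fixed"),
                   n_boot = 1000, phi = 1, seed = NULL) {
  effects_model <- match.arg(effects_model)
  order_all <- c("egger", "weighted_median", "ivw", "simple_mode", "weighted_mode")
  methods <- order_all[order_all %in% match.arg(methods, order_all, several.ok = TRUE)]
  if (nrow(set) == 0) stop("empty harmonized set", call. = FALSE)

  seeds <- if (is.null(seed)) vector("list", 3) else as.list(seed + 0:2)
  rows <- list(); het <- list()
  for (m in methods) {
    est <- switch(m,
      egger = mr_egger(set),
      weighted_median = mr_weighted_median(set, n_boot, seeds[[1]]),
      ivw = mr_ivw(set, effects_model),
      simple_mode = mr_mode(set, weighted = FALSE, phi = phi,
                            n_boot = n_boot, seed = seeds[[2]]),
      weighted_mode = mr_mode(set, weighted = TRUE, phi = phi,
                              n_boot = n_boot, seed = seeds[[3]]))
    if (m %in% c("egger", "ivw") && nrow(set) >= 2) {
      Q <- attr(est, "Q"); Qdf <- attr(est, "Q_df")
      het[[est$method]] <- data.frame(
        method = est$method, Q = Q, Q_df = Qdf,
        Q_pval = stats::pchisq(Q, Qdf, lower.tail = FALSE),
        I2 = i_squared(Q, Qdf), stringsAsFactors = FALSE)
    }
    rows[[m]] <- est
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  fstat <- f_statistic(set, warn = TRUE)

  structure(list(estimates = estimates,
                 heterogeneity = if (length(het)) do.call(rbind, c(het, make.row.names = FALSE)) else NULL,
                 f_statistic = fstat,
                 set = set,
                 effects_model = effects_model,
                 exposure = attr(set, "exposure_name"),
                 outcome = attr(set, "outcome_name"),
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample MR fit:",
      paste0(x$exposure %||% "exposure", " -> ", x$outcome %||% "outcome"),
      sprintf("(%d SNPs)\n", nrow(x$set)))
  est <- x$estimates
  out <- data.frame(method = est$method,
                    b = round(est$b, digits),
                    se = round(est$se, digits),
                    p = signif(est$pval, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  if (!is.null(fit$heterogeneity)) {
    cat("\nHeterogeneity:\n")
    h <- fit$heterogeneity
    print(data.frame(method = h$method, Q = round(h$Q, digits),
                     df = h$Q_df, p = signif(h$Q_pval, digits),
                     `I2(%)` = round(h$I2, digits), check.names = FALSE),
          row.names = FALSE)
  }
  cat(sprintf("\nMean instrument F-statistic: %.3f%s\n", fit$f_statistic,
              if (fit$f_statistic < 10) " (weak instrument)" else ""))
  egger <- fit$estimates[fit$estimates$method == "MR Egger", ]
  if (nrow(egger) == 1 && is.finite(egger$intercept))
    cat(sprintf("MR-Egger intercept: %.4f (se %.4f, p = %.3g)\n",
                egger$intercept, egger$intercept_se, egger$intercept_p))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$b, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est$b - z * est$se, est$b + z * est$se)
  dimnames(ci) <- list(est$method,
                       sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  ci
}

#' @export
residuals.mr_fit <- function(object, method = "Inverse variance weighted", ...) {
  est <- object$estimates[object$estimates$method == method, ]
  if (nrow(est) != 1) stop("method not in fit: ", method, call. = FALSE)
  inter <- if (is.finite(est$intercept)) est$intercept else 0
  stats::setNames(object$set$beta_out - inter - est$b * object$set$beta_exp,
                  object$set$snp)
}

#' Scatter-plot data for an MR fit
#'
#' Per-SNP exposure and outcome effects with their standard errors, the
#' raw material of the usual MR scatter plot (points with 95% CI bars and
#' one fitted line per method).
#'
#' @param fit An `"mr_fit"` object.
#' @return A data frame with columns `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @export
mr_scatter_data <- function(fit) {
  as.data.frame(fit$set)[c("snp", "beta_exp", "se_exp", "beta_out", "se_out")]
}

#' Funnel-plot data for an MR fit
#'
#' Per-SNP Wald ratios against the inverse of their standard errors;
#' asymmetry about the pooled estimate suggests directional pleiotropy.
#'
#' @param fit An `"mr_fit"` object.
#' @return A data frame with columns `snp`, `ratio`, `precision`
#'   (`1/se(ratio)`).
#' @export
mr_funnel_data <- function(fit) {
  rp <- .ratio_parts(fit$set)
  data.frame(snp = fit$set$snp, ratio = rp$r, precision = 1 / rp$se_r,
             stringsAsFactors = FALSE)
}

#' @export
plot.mr_fit <- function(x, ...) {
  d <- mr_scatter_data(x)
  graphics::plot(d$beta_exp, d$beta_out,
                 xlab = "SNP effect on exposure", ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(d$beta_exp, d$beta_out - 1.96 * d$se_out,
                     d$beta_exp, d$beta_out + 1.96 * d$se_out, col = "grey60")
  graphics::segments(d$beta_exp - 1.96 * d$se_exp, d$beta_out,
                     d$beta_exp + 1.96 * d$se_exp, d$beta_out, col = "grey60")
  est <- x$estimates
  cols <- seq_len(nrow(est)) + 1
  for (i in seq_len(nrow(est))) {
    inter <- if (is.finite(est$intercept[i])) est$intercept[i] else 0
    graphics::abline(inter, est$b[i], col = cols[i])
  }
  graphics::legend("topleft", legend = est$method, col = cols, lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}
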