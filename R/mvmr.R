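#' Build a multivariable MR set from several exposures and one outcome
#'
#' Takes the union of the exposures' instruments (membership requires
#' genome-wide significance for at least one exposure), harmonizes every
#' exposure and the outcome to the first exposure's effect allele, and
#' keeps the SNPs for which every exposure reports an effect. SNPs missing
#' any exposure's beta, or with irreconcilable or ambiguous-palindromic
#' alleles, are dropped and listed in the `"dropped"` attribute.
#'
#' @param exposures Named list (length K >= 2) of `summary_stats` data
#'   frames, one per exposure.
#' @param outcome_records Summary statistics for the outcome.
#' @param p_threshold Instrument-membership threshold applied per exposure.
#' @param palindrome_policy,eaf_ambiguity_band As in [harmonize()].
#' @return An object of class `"mvmr_set"`: a data frame with columns
#'   `snp`, `beta_x.<name>` and `se_x.<name>` for each exposure, `beta_out`,
#'   `se_out`; exposure names in the `"exposure_names"` attribute.
#' @export
build_mvmr_set <- function(exposures, outcome_records, p_threshold = 5e-8,
                           palindrome_policy = c("infer_by_eaf", "drop_all"),
                           eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  K <- length(exposures)
  if (K < 2) stop("multivariable MR needs at least 2 exposures", call. = FALSE)
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- sprintf("X%d", seq_len(K))

  union_snps <- unique(unlist(lapply(exposures, function(e) {
    e$snp[!is.na(e$pval) & e$pval < p_threshold]
  })))
  if (length(union_snps) == 0)
    stop(sprintf("no SNPs pass p < %g in any exposure", p_threshold), call. = FALSE)

  ref <- exposures[[1]]
  ref <- ref[ref$snp %in% union_snps, , drop = FALSE]
  dropped <- character(0)

  # harmonize each non-reference exposure and the outcome to the reference
  aligned <- list()
  keep_snps <- ref$snp
  for (k in 2:K) {
    h <- harmonize(ref, exposures[[k]], palindrome_policy = palindrome_policy,
                   eaf_ambiguity_band = eaf_ambiguity_band)
    aligned[[names(exposures)[k]]] <- h
    keep_snps <- intersect(keep_snps, h$snp)
  }
  ho <- harmonize(ref, outcome_records, palindrome_policy = palindrome_policy,
                  eaf_ambiguity_band = eaf_ambiguity_band)
  keep_snps <- intersect(keep_snps, ho$snp)
  dropped <- setdiff(union_snps, keep_snps)
  if (length(keep_snps) < 2)
    stop("fewer than 2 SNPs survive multivariable harmonization", call. = FALSE)

  out <- data.frame(snp = keep_snps, stringsAsFactors = FALSE)
  ri <- match(keep_snps, ref$snp)
  out[[paste0("beta_x.", names(exposures)[1])]] <- ref$beta[ri]
  out[[paste0("se_x.", names(exposures)[1])]] <- ref$se[ri]
  for (k in 2:K) {
    h <- aligned[[names(exposures)[k]]]
    hi <- match(keep_snps, h$snp)
    out[[paste0("beta_x.", names(exposures)[k])]] <- h$beta_out[hi]
    out[[paste0("se_x.", names(exposures)[k])]] <- h$se_out[hi]
  }
  oi <- match(keep_snps, ho$snp)
  out$beta_out <- ho$beta_out[oi]
  out$se_out <- ho$se_out[oi]
  rownames(out) <- NULL
  structure(out, exposure_names = names(exposures), dropped = dropped,
            class = c("mvmr_set", "data.frame"))
}

#' Construct an mvmr_set from aligned effect matrices
#'
#' Convenience constructor for simulations and tests: exposure effects are
#' assumed already expressed per a common allele.
#'
#' @param beta_x Numeric J x K matrix of SNP-exposure effects.
#' @param se_x Numeric J x K matrix of their standard errors.
#' @param beta_out,se_out Outcome effects and standard errors (length J).
#' @param exposure_names Optional exposure labels (length K).
#' @param snp Optional SNP identifiers.
#' @return An `"mvmr_set"` data frame.
#' @export
mvmr_set <- function(beta_x, se_x, beta_out, se_out,
                     exposure_names = colnames(beta_x), snp = NULL) {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  J <- nrow(beta_x); K <- ncol(beta_x)
  if (K < 2) stop("multivariable MR needs at least 2 exposures", call. = FALSE)
  stopifnot(all(dim(se_x) == c(J, K)), length(beta_out) == J,
            length(se_out) == J)
  .assert_numeric(se_out, "se_out", positive = TRUE)
  if (is.null(exposure_names)) exposure_names <- sprintf("X%d", seq_len(K))
  if (is.null(snp)) snp <- sprintf("snp_%d", seq_len(J))
  out <- data.frame(snp = snp, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    out[[paste0("beta_x.", exposure_names[k])]] <- beta_x[, k]
    out[[paste0("se_x.", exposure_names[k])]] <- se_x[, k]
  }
  out$beta_out <- beta_out
  out$se_out <- se_out
  structure(out, exposure_names = exposure_names, dropped = character(0),
            class = c("mvmr_set", "data.frame"))
}

.mvmr_matrices <- function(set) {
  en <- attr(set, "exposure_names")
  X <- as.matrix(set[paste0("beta_x.", en)])
  S <- as.matrix(set[paste0("se_x.", en)])
  colnames(X) <- colnames(S) <- en
  list(X = X, S = S, y = set$beta_out, sy = set$se_out, names = en)
}

#' Inverse-variance weighted multivariable MR
#'
#' Zero-intercept weighted regression of the SNP-outcome effects on the K
#' exposures' SNP effects, weights `1/se_out^2`. The coefficient on each
#' exposure is its direct effect on the outcome, holding the other
#' exposures fixed. Standard errors are inflated by
#' `sqrt(max(1, Q/(J-K)))` (multiplicative random effects); p-values use a
#' normal reference. Conditional instrument strength per exposure uses the
#' Sanderson-Windmeijer form: regress that exposure's SNP effects on the
#' other exposures' with weights `1/se_xk^2` and divide the residual
#' Q-statistic by `J - K + 1`; values below 10 flag a conditionally weak
#' instrument.
#'
#' Nearly collinear exposure columns (weighted correlation above
#' `collinearity_limit`) make direct effects unidentifiable and are
#' refused unless `force = TRUE`.
#'
#' @param set An `"mvmr_set"` data frame.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param collinearity_limit Absolute pairwise weighted correlation above
#'   which fitting is refused.
#' @param force Fit despite a collinearity warning.
#' @return An object of class `"mvmr_fit"`: list with `estimates` (one row
#'   per exposure: `exposure`, `b`, `se`, `pval`, `conditional_F`),
#'   `heterogeneity` (Q, df, p, I2), `nsnp`, `set`.
#' @export
mvmr_fit <- function(set, effects_model = c("multiplicative_random", "fixed"),
                     collinearity_limit = 0.95, force = FALSE) {
  effects_model <- match.arg(effects_model)
  m <- .mvmr_matrices(set)
  J <- nrow(m$X); K <- ncol(m$X)
  if (J <= K)
    stop("need more SNPs than exposures (J > K)", call. = FALSE)

  w <- 1 / m$sy^2
  Xw <- m$X * sqrt(w)
  if (qr(Xw)$rank < K)
    stop("rank-deficient design: exposure effects are collinear", call. = FALSE)
  # uncentered weighted cosine similarity: the fit is through the origin,
  # so identifiability hinges on the uncentered Gram matrix
  G <- crossprod(Xw)
  cc <- G / tcrossprod(sqrt(diag(G)))
  worst <- max(abs(cc[upper.tri(cc)]))
  if (worst > collinearity_limit && !force) {
    pair <- which(abs(cc) == worst & upper.tri(cc), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("exposures '%s' and '%s' are nearly collinear ",
                        "(weighted r = %.3f); direct effects are not ",
                        "identifiable -- use force = TRUE to fit anyway"),
                 m$names[pair[1]], m$names[pair[2]], worst), call. = FALSE)
  }

  XtWX <- G
  theta <- solve(XtWX, crossprod(m$X * w, m$y))[, 1]
  resid <- m$y - m$X %*% theta
  Q <- sum(w * resid^2)
  df <- J - K
  scale2 <- if (effects_model == "multiplicative_random") max(1, Q / df) else 1
  se <- sqrt(diag(solve(XtWX)) * scale2)
  pval <- .p_from_z(theta / se)

  cond_f <- vapply(seq_len(K), function(k) {
    dk <- 1 / m$S[, k]^2
    Xo <- m$X[, -k, drop = FALSE]
    delta <- solve(crossprod(Xo * sqrt(dk)), crossprod(Xo * dk, m$X[, k]))[, 1]
    Qk <- sum(dk * (m$X[, k] - Xo %*% delta)^2)
    Qk / (J - K + 1)
  }, numeric(1))
  if (any(cond_f < 10))
    warning(sprintf("conditionally weak instrument (F < 10) for: %s",
                    paste(m$names[cond_f < 10], collapse = ", ")), call. = FALSE)

  estimates <- data.frame(exposure = m$names, b = theta, se = se, pval = pval,
                          conditional_F = cond_f, stringsAsFactors = FALSE,
                          row.names = NULL)
  structure(list(estimates = estimates,
                 heterogeneity = data.frame(Q = Q, Q_df = df,
                                            Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
                                            I2 = i_squared(Q, df)),
                 nsnp = J, set = set, effects_model = effects_model,
                 call = match.call()),
            class = "mvmr_fit")
}

#' Heterogeneity of a multivariable MR fit about given direct effects
#'
#' `Q = sum w_j (beta_out_j - sum_k theta_k beta_xkj)^2` with weights
#' `1/se_out^2`, `df = J - K`, I-squared as in the univariable case.
#'
#' @param set An `"mvmr_set"` data frame.
#' @param theta Direct-effect vector (length K, exposure order of the set).
#' @return A `"heterogeneity"` list: `Q`, `df`, `pval`, `I2`.
#' @export
mvmr_q <- function(set, theta) {
  m <- .mvmr_matrices(set)
  stopifnot(length(theta) == ncol(m$X))
  w <- 1 / m$sy^2
  Q <- sum(w * (m$y - m$X %*% theta)^2)
  df <- nrow(m$X) - ncol(m$X)
  structure(list(Q = Q, df = as.integer(df),
                 pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 I2 = i_squared(Q, df)),
            class = "heterogeneity")
}

#' @export
print.mvmr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Multivariable MR fit (%d SNPs, %d exposures)\n",
              x$nsnp, nrow(x$estimates)))
  est <- x$estimates
  print(data.frame(exposure = est$exposure, b = round(est$b, digits),
                   se = round(est$se, digits), p = signif(est$pval, digits),
                   `F(cond)` = round(est$conditional_F, digits),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mvmr_fit <- function(object, ...) {
  print(object)
  h <- object$heterogeneity
  cat(sprintf("\nCochran's Q = %.3f on %d df (p = %.3g), I2 = %.3f%%\n",
              h$Q, h$Q_df, h$Q_pval, h$I2))
  invisible(object)
}

#' @export
coef.mvmr_fit <- function(object, ...) {
  stats::setNames(object$estimates$b, object$estimates$exposure)
}

#' @export
residuals.mvmr_fit <- function(object, ...) {
  m <- .mvmr_matrices(object$set)
  stats::setNames((m$y - m$X %*% object$estimates$b)[, 1], object$set$snp)
}
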