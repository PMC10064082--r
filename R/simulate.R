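#' Simulate two-sample GWAS summary statistics for an MR study
#'
#' Generates exposure and outcome summary-statistic tables with the
#' sampling structure two-sample MR assumes: independent SNPs, per-SNP
#' standard errors `1/sqrt(2 maf (1-maf) n)` for standardized traits, and
#' outcome effects `theta * gamma_j + alpha_j` where `gamma_j` is the true
#' SNP-exposure effect and `alpha_j` an optional horizontal-pleiotropic
#' effect. Instruments are modelled post-selection: true exposure
#' z-statistics are `z0 + |N(0, z_sd)|` with a random sign (defaults
#' `z0 = 8`, `z_sd = 20`), so every SNP clears genome-wide significance
#' while effect magnitudes spread over an order of magnitude, as lead
#' signals of consortium-scale GWAS do. That spread keeps exposure
#' measurement error negligible relative to the between-SNP effect
#' variance (the NOME condition), under which MR-Egger is unbiased and
#' the residual IVW attenuation is of order `1/F`. Reported p-values equal
#' `2 * pnorm(-|beta/se|)` exactly, and the same seed reproduces the same
#' tables byte for byte.
#'
#' Pleiotropy models (`pleiotropy = list(type = ...)`):
#' \describe{
#'   \item{`"none"`}{`alpha_j = 0` (default).}
#'   \item{`"balanced"`}{`alpha_j ~ N(0, sd)`: heterogeneity, no bias.}
#'   \item{`"directional"`}{`alpha_j ~ N(mean, sd)`: biases IVW; MR-Egger's
#'     intercept estimates `mean` (InSIDE holds).}
#'   \item{`"inside_violating"`}{`alpha_j` correlated with instrument
#'     strength `|gamma_j|` (correlation `corr`), the failure mode of
#'     MR-Egger.}
#' }
#' Pleiotropic effects are defined per copy of the exposure-increasing
#' allele (the convention under which "directional" means a consistent
#' push on the outcome), so `alpha_j` inherits the sign of `gamma_j`.
#' `invalid_fraction` restricts the pleiotropic effect to a random subset
#' of `round(invalid_fraction * J)` SNPs (1 = all SNPs).
#'
#' A fraction of SNPs get palindromic (A/T or C/G) allele pairs, and a
#' fraction of outcome rows have their allele labels (and beta sign,
#' frequency) swapped, so the harmonization path is exercised end to end;
#' [harmonize()] must undo the swaps exactly.
#'
#' @param config Optional list of the parameters below (e.g. from
#'   [mr_scenario()]); entries override the defaults, and named arguments
#'   in `...` override `config`.
#' @param ... Parameters: `J` (SNP count, default 49), `theta` (true
#'   causal effect, 0.5), `n_exp` (exposure GWAS size, 151013), `n_out`
#'   (outcome GWAS size, 563946), `maf_range` (c(0.05, 0.5)), `z0` and
#'   `z_sd` (true exposure z-statistic floor and spread, 8 and 20),
#'   `pleiotropy` (list, see above), `invalid_fraction` (1),
#'   `palindromic_fraction` (0.2), `swap_fraction` (0.3).
#' @param seed Optional integer seed.
#' @return A list with elements `exposure` and `outcome` (both
#'   `summary_stats` data frames) and `truth` (per-SNP `gamma`, `alpha`,
#'   `invalid`, plus `theta`).
#' @examples
#' sim <- simulate_two_sample_gwas(mr_scenario("null"), seed = 7)
#' head(sim$exposure)
#' @export
simulate_two_sample_gwas <- function(config = list(), ..., seed = NULL) {
  p <- list(J = 49L, theta = 0.5, n_exp = 151013, n_out = 563946,
            maf_range = c(0.05, 0.5), z0 = 8, z_sd = 20,
            pleiotropy = list(type = "none"), invalid_fraction = 1,
            palindromic_fraction = 0.2, swap_fraction = 0.3)
  config <- config[!vapply(config, is.null, logical(1))]
  p[names(config)] <- config
  dots <- list(...)
  p[names(dots)] <- dots
  stopifnot(p$J >= 3, p$n_exp > 0, p$n_out > 0,
            p$invalid_fraction >= 0, p$invalid_fraction <= 1)

  .with_seed(seed, {
    J <- as.integer(p$J)
    maf <- stats::runif(J, p$maf_range[1], p$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * p$n_exp)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * p$n_out)
    z_true <- (p$z0 + abs(stats::rnorm(J, 0, p$z_sd))) *
      sample(c(-1, 1), J, replace = TRUE)
    gamma <- z_true * se_x

    pl <- p$pleiotropy
    # alpha on the exposure-increasing-allele scale
    alpha_o <- switch(pl$type,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, pl$sd),
      directional = stats::rnorm(J, pl$mean, pl$sd %||% 0),
      inside_violating = {
        rho <- pl$corr
        g <- abs(gamma)
        sdv <- pl$sd %||% stats::sd(g)
        g_std <- (g - mean(g)) / stats::sd(g)
        (pl$mean %||% 0) + sdv * (rho * g_std + sqrt(1 - rho^2) * stats::rnorm(J))
      },
      stop("unknown pleiotropy type: ", pl$type, call. = FALSE))
    invalid <- rep(FALSE, J)
    n_inv <- round(p$invalid_fraction * J)
    if (n_inv > 0) invalid[sample.int(J, n_inv)] <- TRUE
    alpha <- sign(gamma) * alpha_o * invalid

    beta_x <- stats::rnorm(J, gamma, se_x)
    beta_y <- stats::rnorm(J, p$theta * gamma + alpha, se_y)

    # allele pairs; palindromic fraction exercises strand-ambiguity handling
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    npl_pairs <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                      c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    is_pal <- stats::runif(J) < p$palindromic_fraction
    alleles <- t(vapply(is_pal, function(pp)
      if (pp) pal_pairs[[sample.int(4, 1)]] else npl_pairs[[sample.int(8, 1)]],
      character(2)))
    eaf <- ifelse(stats::runif(J) < 0.5, maf, 1 - maf)
    eaf_out <- pmin(pmax(eaf + stats::rnorm(J, 0, 0.005), 0.01), 0.99)

    snp <- sprintf("rs%06d", seq_len(J))
    exposure <- data.frame(
      snp = snp, effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta_x, se = se_x,
      pval = .p_from_z(beta_x / se_x), n = p$n_exp,
      stringsAsFactors = FALSE)

    swap <- stats::runif(J) < p$swap_fraction
    outcome <- data.frame(
      snp = snp,
      effect_allele = ifelse(swap, alleles[, 2], alleles[, 1]),
      other_allele = ifelse(swap, alleles[, 1], alleles[, 2]),
      eaf = ifelse(swap, 1 - eaf_out, eaf_out),
      beta = ifelse(swap, -beta_y, beta_y), se = se_y,
      pval = .p_from_z(beta_y / se_y), n = p$n_out,
      stringsAsFactors = FALSE)
    class(exposure) <- class(outcome) <- c("summary_stats", "data.frame")
    attr(exposure, "exposure_name") <- "simulated exposure"

    list(exposure = exposure, outcome = outcome,
         truth = list(gamma = gamma, alpha = alpha, invalid = invalid,
                      theta = p$theta, swap = swap))
  })
}

#' Named simulation scenarios
#'
#' Preset configurations for [simulate_two_sample_gwas()]:
#' \describe{
#'   \item{`"fi_hb_like"`}{49-SNP instrument at fasting-insulin /
#'     hemoglobin GWAS scale (n = 151,013 exposure; 563,946 outcome),
#'     causal effect 0.54, no pleiotropy.}
#'   \item{`"weak_instrument"`}{true exposure z-statistics around 2,
#'     giving a mean F-statistic around 5 (below the conventional 10).}
#'   \item{`"median_robust"`}{40% of SNPs invalid with directional
#'     pleiotropy (mean 0.02): the weighted median's home turf.}
#'   \item{`"null"`}{no causal effect (theta = 0).}
#' }
#'
#' @param name Scenario name.
#' @return A config list for [simulate_two_sample_gwas()].
#' @export
mr_scenario <- function(name) {
  presets <- list(
    fi_hb_like = list(J = 49L, theta = 0.54, n_exp = 151013, n_out = 563946),
    weak_instrument = list(J = 49L, theta = 0.5, z0 = 0.5, z_sd = 1.5),
    median_robust = list(J = 49L, theta = 0.5, invalid_fraction = 0.4,
                         pleiotropy = list(type = "directional",
                                           mean = 0.05, sd = 0.01)),
    null = list(J = 49L, theta = 0)
  )
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  presets[[name]]
}

#' Simulate a patient-level cohort for the glycation-gap analysis
#'
#' Generates a post-filter outpatient cohort with two glycemic strata.
#' Within each stratum, fasting glucose and triglyceride are log-normal
#' (calibrated to the observed stratum medians and interquartile ranges),
#' the triglyceride-glucose index follows from them, the glycation gap is
#' `intercept_s + slope_s * TGI + noise`, measured HbA1c is the fixed
#' prediction equation `pred_coef[1] + pred_coef[2] * fg` plus the gap,
#' and hemoglobin is `hb_intercept + hb_slope * TGI + noise` clipped to a
#' physiologic range. Records violating the post-filter invariants
#' (stratum fasting-glucose bound, HbA1c below 6.5%) are redrawn. The
#' generating stratum is kept in the `stratum` column, and the generator's
#' own `tgi` and `gap` columns are included so downstream regressions can
#' target the planted truth.
#'
#' @param n Cohort size.
#' @param frac_pre Fraction assigned to the pre-T2D stratum.
#' @param gap_slope_pre,gap_slope_normo Gap-vs-TGI slopes planted per
#'   stratum (defaults -0.087 and +0.023).
#' @param gap_intercept_pre,gap_intercept_normo Planted intercepts
#'   (defaults 1.77 and 0.14).
#' @param hb_slope Hemoglobin-vs-TGI slope (default 1.88).
#' @param hb_intercept Hemoglobin intercept, g/L.
#' @param noise_sd_gap_pre,noise_sd_gap_normo,noise_sd_hb Residual SDs.
#' @param pred_coef (intercept, slope) of the HbA1c prediction equation.
#' @param seed Optional integer seed.
#' @return A data frame with columns `age`, `sex`, `fg`, `tg`, `hdl`,
#'   `hba1c`, `hb`, `tgi`, `gap`, `stratum`.
#' @examples
#' cohort <- simulate_cohort(n = 1000, seed = 3)
#' table(cohort$stratum)
#' @export
simulate_cohort <- function(n = 7600, frac_pre = 0.144,
                            gap_slope_pre = -0.087, gap_slope_normo = 0.023,
                            gap_intercept_pre = 1.77, gap_intercept_normo = 0.14,
                            hb_slope = 1.88, hb_intercept = 129,
                            noise_sd_gap_pre = 0.16, noise_sd_gap_normo = 0.30,
                            noise_sd_hb = 13,
                            pred_coef = c(4.163, 0.172), seed = NULL) {
  stopifnot(n >= 100, frac_pre > 0, frac_pre < 1)
  .with_seed(seed, {
    pre <- stats::runif(n) < frac_pre
    # per-stratum log-normal parameters matched to observed medians/IQRs
    par <- list(
      normo = list(fg = c(log(5.10), 0.117), tg = c(log(1.16), 0.505),
                   hdl = c(log(1.29), 0.284), age = c(49.5, 11),
                   fg_max = 6.0, p_female = 0.48,
                   slope = gap_slope_normo, inter = gap_intercept_normo,
                   noise = noise_sd_gap_normo),
      pre = list(fg = c(log(5.70), 0.130), tg = c(log(1.33), 0.491),
                 hdl = c(log(1.19), 0.258), age = c(55, 9),
                 fg_max = 7.0, p_female = 0.51,
                 slope = gap_slope_pre, inter = gap_intercept_pre,
                 noise = noise_sd_gap_pre)
    )
    draw_stratum <- function(m, pp) {
      out <- NULL
      need <- m
      for (iter in seq_len(100)) {
        fg <- stats::rlnorm(need, pp$fg[1], pp$fg[2])
        tg <- stats::rlnorm(need, pp$tg[1], pp$tg[2])
        tg_i <- tgi(tg, fg)
        gap <- pp$inter + pp$slope * tg_i + stats::rnorm(need, 0, pp$noise)
        hba1c <- pred_coef[1] + pred_coef[2] * fg + gap
        ok <- fg < pp$fg_max & hba1c < 6.5
        chunk <- data.frame(fg = fg, tg = tg, tgi = tg_i, gap = gap,
                            hba1c = hba1c)[ok, , drop = FALSE]
        out <- rbind(out, chunk)
        need <- m - nrow(out)
        if (need <= 0) break
      }
      out <- out[seq_len(m), , drop = FALSE]
      out$hdl <- stats::rlnorm(m, pp$hdl[1], pp$hdl[2])
      out$age <- round(pmin(pmax(stats::rnorm(m, pp$age[1], pp$age[2]), 18), 65))
      out$sex <- ifelse(stats::runif(m) < pp$p_female, "female", "male")
      out$hb <- pmin(pmax(hb_intercept + hb_slope * out$tgi +
                            stats::rnorm(m, 0, noise_sd_hb), 105), 190)
      out
    }
    d_normo <- draw_stratum(sum(!pre), par$normo)
    d_pre <- draw_stratum(sum(pre), par$pre)
    d_normo$stratum <- "normoglycemia"
    d_pre$stratum <- "preT2D"
    out <- rbind(d_normo, d_pre)
    out <- out[sample.int(nrow(out)), ] # shuffle strata together
    rownames(out) <- NULL
    out[c("age", "sex", "fg", "tg", "hdl", "hba1c", "hb", "tgi", "gap",
          "stratum")]
  })
}
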