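# Shared fixtures, built in code.

# Minimal summary-stats data frame with sensible defaults.
make_stats <- function(snp, beta, se, effect_allele = "A", other_allele = "G",
                       eaf = 0.3, pval = NULL, n = 1e5) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  structure(data.frame(snp = snp, effect_allele = effect_allele,
                       other_allele = other_allele, eaf = eaf,
                       beta = beta, se = se, pval = pval, n = n,
                       stringsAsFactors = FALSE),
            class = c("summary_stats", "data.frame"))
}

# The hand-computable 3-SNP set: beta_x all 1, beta_y (0.5, 0.7, 0.6),
# se_out 0.1 -> IVW slope 0.6, fixed se sqrt(1/300), Q = 2.
hand_set <- function() {
  harmonized_set(beta_exp = c(1, 1, 1), se_exp = c(0.02, 0.02, 0.02),
                 beta_out = c(0.5, 0.7, 0.6), se_out = c(0.1, 0.1, 0.1))
}

# Write a small delimited file and return its path.
write_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
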