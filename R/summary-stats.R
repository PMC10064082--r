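#' Read GWAS summary statistics from a delimited text file
#'
#' Reads one trait's per-SNP association statistics (effect sizes are per
#' copy of the effect allele, on the trait-SD or log-odds scale) into a
#' canonical data frame. The delimiter is sniffed from the header line
#' (tab if present, otherwise comma).
#'
#' Rows whose beta or standard error is missing or non-numeric are dropped;
#' the number dropped (with reasons) is recorded in the `"rejections"`
#' attribute of the result. Allele codes are upper-cased. When a SNP
#' identifier occurs more than once, the row with the smallest p-value is
#' kept and the rest are rejected.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to column names in the file. Defaults follow common GWAS exports
#'   (`SNP`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`). `eaf` and `n` are
#'   optional; the rest are required.
#' @return A data frame of class `"summary_stats"` with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @examples
#' f <- system.file("extdata", "example_exposure.tsv", package = "mrgap")
#' head(read_summary_stats(f))
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  defaults <- c(snp = "SNP", effect_allele = "EA", other_allele = "OA",
                eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)

  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols))
    stop("required column(s) not found in ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)

  get_col <- function(key, numeric = FALSE) {
    col <- map[[key]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[col]]
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }

  out <- data.frame(
    snp = get_col("snp"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = get_col("eaf", numeric = TRUE),
    beta = get_col("beta", numeric = TRUE),
    se = get_col("se", numeric = TRUE),
    pval = get_col("pval", numeric = TRUE),
    n = get_col("n", numeric = TRUE),
    stringsAsFactors = FALSE
  )

  rejections <- character(0)
  bad <- is.na(out$beta) | is.na(out$se)
  if (any(bad))
    rejections <- c(rejections,
                    sprintf("%s: missing or non-numeric beta/se", out$snp[bad]))
  nonpos <- !bad & out$se <= 0
  if (any(nonpos))
    rejections <- c(rejections, sprintf("%s: non-positive se", out$snp[nonpos]))
  out <- out[!(bad | nonpos), , drop = FALSE]

  dup <- duplicated_lowest_p(out)
  if (any(dup)) {
    rejections <- c(rejections,
                    sprintf("%s: duplicate id, higher p dropped", out$snp[dup]))
    out <- out[!dup, , drop = FALSE]
  }

  rownames(out) <- NULL
  structure(out, rejections = rejections,
            class = c("summary_stats", "data.frame"))
}

# Flag duplicated snp ids, keeping the row with the lowest p-value
# (first occurrence wins ties).
duplicated_lowest_p <- function(records) {
  ord <- order(records$pval, seq_len(nrow(records)))
  dup_in_ord <- duplicated(records$snp[ord])
  flag <- logical(nrow(records))
  flag[ord] <- dup_in_ord
  flag
}

#' Select a genetic instrument at a p-value threshold
#'
#' Retains the SNPs robustly associated with the exposure, i.e. those with
#' `pval < p_threshold` (strict inequality; the conventional genome-wide
#' significance threshold 5e-8 by default). Input order is preserved.
#'
#' @param records A `summary_stats` data frame for the exposure trait.
#' @param p_threshold Selection threshold on the two-sided p-value.
#' @param exposure_name Label carried on the returned instrument.
#' @return A data frame of class `"mr_instrument"` with attributes
#'   `exposure_name` and `p_threshold`.
#' @export
select_instrument <- function(records, p_threshold = 5e-8,
                              exposure_name = "exposure") {
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  keep <- !is.na(records$pval) & records$pval < p_threshold
  if (!any(keep))
    stop(sprintf("no SNPs pass the selection threshold p < %g", p_threshold),
         call. = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(as.data.frame(out), exposure_name = exposure_name,
            p_threshold = p_threshold,
            class = c("mr_instrument", "data.frame"))
}

#' Substitute LD proxies for instrument SNPs missing from the outcome GWAS
#'
#' Instrument SNPs absent from the outcome summary statistics are replaced
#' by their highest-r-squared proxy with `r2 > r2_min` that is present in
#' the outcome records; SNPs with no qualifying proxy are dropped. A
#' substituted row takes the proxy's identifier and allele labels (so that
#' harmonization matches the outcome file directly) while keeping the
#' original SNP's exposure effect; the original identifier is recorded in
#' the `proxy_for` column and `proxy_used` is set. This assumes the proxy
#' is reported phased to the same trait-increasing allele, which r-squared
#' alone cannot verify; supply signed LD information upstream if that
#' assumption is unsafe.
#'
#' @param instrument An `mr_instrument` data frame.
#' @param outcome_records Summary statistics for the outcome trait.
#' @param ld_table Data frame with columns `snp`, `proxy`, `r2`.
#' @param r2_min Minimum r-squared for an acceptable proxy (exclusive).
#' @return The instrument with columns `proxy_used` (logical) and
#'   `proxy_for` (original id or `NA`); dropped SNPs are listed in the
#'   `"dropped"` attribute.
#' @export
proxy_substitute <- function(instrument, outcome_records, ld_table,
                             r2_min = 0.8) {
  stopifnot(all(c("snp", "proxy", "r2") %in% names(ld_table)))
  out <- instrument
  out$proxy_used <- FALSE
  out$proxy_for <- NA_character_
  dropped <- character(0)
  present <- out$snp %in% outcome_records$snp
  for (i in which(!present)) {
    cand <- ld_table[ld_table$snp == out$snp[i] &
                       ld_table$r2 > r2_min &
                       ld_table$proxy %in% outcome_records$snp, , drop = FALSE]
    if (nrow(cand) == 0) {
      dropped <- c(dropped, out$snp[i])
      next
    }
    best <- cand[which.max(cand$r2), ]
    orec <- outcome_records[match(best$proxy, outcome_records$snp), ]
    out$proxy_for[i] <- out$snp[i]
    out$snp[i] <- best$proxy
    out$effect_allele[i] <- orec$effect_allele
    out$other_allele[i] <- orec$other_allele
    out$proxy_used[i] <- TRUE
  }
  if (length(dropped)) out <- out[!out$snp %in% dropped, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exposure_name = attr(instrument, "exposure_name"),
            p_threshold = attr(instrument, "p_threshold"),
            dropped = dropped,
            class = c("mr_instrument", "data.frame"))
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns per-SNP outcome effects to the exposure's effect allele so that
#' both betas are expressed per copy of the same allele. Outcome rows whose
#' alleles are swapped relative to the exposure have their beta sign flipped
#' and allele frequency complemented. Allele sets that match neither
#' directly nor swapped are irreconcilable and dropped (no strand-flip
#' guessing is attempted).
#'
#' Palindromic SNPs (A/T or C/G) carry no strand information in their
#' allele codes. Under `palindrome_policy = "drop_all"` they are removed;
#' under `"infer_by_eaf"` (the default, common two-sample MR practice) they
#' are aligned by allele-frequency concordance, and removed only when
#' either trait's frequency lies inside the ambiguity band (or is missing).
#'
#' @param exposure_records,outcome_records `summary_stats`-shaped data
#'   frames keyed by `snp`.
#' @param palindrome_policy `"infer_by_eaf"` or `"drop_all"`.
#' @param eaf_ambiguity_band Frequency band within which a palindromic SNP
#'   cannot be aligned by frequency.
#' @param exposure_name,outcome_name Labels carried on the result.
#' @return A data frame of class `"harmonized_set"` with one row per
#'   retained SNP: `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `eaf_exp`, `eaf_out`, `proxy_used`, `flipped`. Drops (with reasons)
#'   are recorded in the `"dropped"` attribute.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      palindrome_policy = c("infer_by_eaf", "drop_all"),
                      eaf_ambiguity_band = c(0.42, 0.58),
                      exposure_name = attr(exposure_records, "exposure_name"),
                      outcome_name = "outcome") {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure_records$snp, outcome_records$snp)
  if (length(shared) == 0)
    stop("no shared SNPs between exposure and outcome records", call. = FALSE)

  ex <- exposure_records[match(shared, exposure_records$snp), ]
  ou <- outcome_records[match(shared, outcome_records$snp), ]

  n <- length(shared)
  flipped <- logical(n)
  keep <- rep(TRUE, n)
  reason <- character(n)
  beta_out <- ou$beta
  eaf_out <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, n)
  eaf_exp <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, n)

  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele

  for (i in seq_len(n)) {
    if (pal[i]) {
      # allele labels cannot resolve strand for palindromes
      if (!(same[i] || swapped[i])) {
        keep[i] <- FALSE; reason[i] <- "irreconcilable alleles"; next
      }
      if (palindrome_policy == "drop_all") {
        keep[i] <- FALSE; reason[i] <- "palindromic (drop_all)"; next
      }
      in_band <- function(f) is.na(f) ||
        (f > eaf_ambiguity_band[1] & f < eaf_ambiguity_band[2])
      if (in_band(eaf_exp[i]) || in_band(eaf_out[i])) {
        keep[i] <- FALSE; reason[i] <- "palindromic, ambiguous eaf"; next
      }
      if ((eaf_exp[i] < 0.5) != (eaf_out[i] < 0.5)) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        flipped[i] <- TRUE
      }
    } else if (same[i]) {
      # already aligned
    } else if (swapped[i]) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
    } else {
      keep[i] <- FALSE; reason[i] <- "irreconcilable alleles"
    }
  }

  proxy_used <- if ("proxy_used" %in% names(ex)) ex$proxy_used else rep(FALSE, n)
  out <- data.frame(
    snp = shared, beta_exp = ex$beta, se_exp = ex$se,
    beta_out = beta_out, se_out = ou$se,
    eaf_exp = eaf_exp, eaf_out = eaf_out,
    proxy_used = proxy_used, flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL

  dropped <- if (any(!keep)) stats::setNames(reason[!keep], shared[!keep]) else character(0)
  structure(out,
            exposure_name = if (is.null(exposure_name)) "exposure" else exposure_name,
            outcome_name = outcome_name,
            palindrome_policy = palindrome_policy,
            dropped = dropped,
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where exposure
#' and outcome effects are already expressed per the same allele.
#'
#' @param beta_exp,se_exp,beta_out,se_out Numeric vectors of equal length.
#' @param snp Optional SNP identifiers.
#' @param exposure_name,outcome_name Labels.
#' @return A `"harmonized_set"` data frame.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp = NULL, exposure_name = "exposure",
                           outcome_name = "outcome") {
  .assert_numeric(beta_exp, "beta_exp")
  .assert_numeric(se_exp, "se_exp", positive = TRUE)
  .assert_numeric(beta_out, "beta_out")
  .assert_numeric(se_out, "se_out", positive = TRUE)
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J)
  if (is.null(snp)) snp <- sprintf("snp_%d", seq_len(J))
  structure(data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
                       beta_out = beta_out, se_out = se_out,
                       eaf_exp = NA_real_, eaf_out = NA_real_,
                       proxy_used = FALSE, flipped = FALSE,
                       stringsAsFactors = FALSE),
            exposure_name = exposure_name, outcome_name = outcome_name,
            palindrome_policy = "none", dropped = character(0),
            class = c("harmonized_set", "data.frame"))
}

#' Write a harmonized set to a tab-separated audit file
#'
#' @param set A `"harmonized_set"` data frame.
#' @param path Output file path.
#' @export
write_harmonized <- function(set, path) {
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
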