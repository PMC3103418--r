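#' Read a risk-SNP table
#'
#' @param path TSV with header columns `snp`, `risk_allele` and optionally
#'   `trait`, `gene`, `ancestral_allele`.
#' @return A `risk_snp_table` data.frame.
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop_gd("SNP table not found: ", path)
  as_risk_snp_table(read_tsv_gd(path))
}

#' Construct and validate a risk-SNP table
#'
#' @param df data.frame with at least `snp` and `risk_allele`.
#' @return A `risk_snp_table`.
#' @export
as_risk_snp_table <- function(df) {
  need <- c("snp", "risk_allele")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gd("SNP table is missing column(s): ", paste(miss, collapse = ", "))
  df$snp <- as.character(df$snp)
  df$risk_allele <- toupper(as.character(df$risk_allele))
  for (col in c("trait", "gene", "ancestral_allele"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$ancestral_allele <- toupper(as.character(df$ancestral_allele))
  if (anyDuplicated(df$snp))
    stop_gd("duplicate SNP id(s) in SNP table: ",
            paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
  if (!all(is_base(df$risk_allele)))
    stop_gd("risk_allele must be a single base A/C/G/T")
  df <- df[, c("snp", "risk_allele", "trait", "gene", "ancestral_allele")]
  rownames(df) <- NULL
  structure(df, class = c("risk_snp_table", "data.frame"))
}

#' Write a risk-SNP table to TSV
#' @param snps a `risk_snp_table`.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  write_tsv_gd(as.data.frame(snps), path)
}

#' Reconcile risk alleles with genotype allele pairs
#'
#' Standard GWAS-merge hygiene: a risk allele is matched to the genotyped
#' allele pair by letter; if it matches neither allele but matches the
#' reverse complement of one, it is strand-flipped with a warning. Ambiguous
#' A/T and C/G SNPs are never auto-flipped: when their risk allele does not
#' match directly they are flagged for manual resolution and dropped from
#' downstream frequency computation.
#'
#' @param ds a `geno_dataset`.
#' @param snps a `risk_snp_table`; every SNP must be present in `ds`.
#' @return data.frame with columns `snp`, `risk_is_a` (does the risk allele
#'   equal allele A, i.e. the counted allele), `flipped`, `ambiguous`.
#' @export
reconcile_risk_alleles <- function(ds, snps) {
  idx <- match(snps$snp, ds$alleles$snp)
  if (anyNA(idx))
    stop_gd("SNP(s) absent from genotype data: ",
            paste(snps$snp[is.na(idx)], collapse = ", "))
  a <- ds$alleles$allele_a[idx]
  b <- ds$alleles$allele_b[idx]
  risk <- snps$risk_allele
  ambiguous_pair <- (a == rev_comp_base(b))   # A/T or C/G SNPs

  risk_is_a <- rep(NA, length(risk))
  flipped <- rep(FALSE, length(risk))
  direct_a <- risk == a
  direct_b <- risk == b
  risk_is_a[direct_a] <- TRUE
  risk_is_a[direct_b] <- FALSE
  todo <- !direct_a & !direct_b
  rc <- rev_comp_base(risk)
  flip_a <- todo & !ambiguous_pair & rc == a
  flip_b <- todo & !ambiguous_pair & rc == b
  risk_is_a[flip_a] <- TRUE
  risk_is_a[flip_b] <- FALSE
  flipped <- flip_a | flip_b
  ambiguous <- todo & ambiguous_pair

  unresolved <- todo & !flip_a & !flip_b & !ambiguous_pair
  if (any(unresolved))
    stop_gd("risk allele matches neither genotyped allele nor a reverse ",
            "complement for: ", paste(snps$snp[unresolved], collapse = ", "))
  if (any(flipped))
    warning("strand-flipped risk allele for ", sum(flipped), " SNP(s): ",
            paste(snps$snp[flipped], collapse = ", "), call. = FALSE)
  if (any(ambiguous))
    warning(sum(ambiguous), " ambiguous A/T or C/G SNP(s) with unmatched risk ",
            "allele flagged for manual resolution: ",
            paste(snps$snp[ambiguous], collapse = ", "), call. = FALSE)

  data.frame(snp = snps$snp, risk_is_a = risk_is_a, flipped = flipped,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}
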