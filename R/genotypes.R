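#' Construct a genotype dataset
#'
#' Container for biallelic genotype calls: an integer matrix of allele-A copy
#' counts (0, 1, 2 or `NA`) with SNPs in rows and samples in columns, the two
#' alleles of each SNP, and the population panel the sample columns follow.
#'
#' @param calls integer matrix, SNPs x samples, entries in \{0, 1, 2, NA\};
#'   rownames are SNP ids, colnames are sample ids matching `panel$sample`.
#' @param allele_a,allele_b per-SNP allele bases; `calls` counts copies of
#'   `allele_a`.
#' @param panel a [pop_panel][as_pop_panel] whose samples match the columns.
#' @return A `geno_dataset` object.
#' @export
geno_dataset <- function(calls, allele_a, allele_b, panel) {
  if (!is.matrix(calls)) stop_gd("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop_gd("'calls' needs SNP rownames and sample colnames")
  if (!identical(colnames(calls), panel$sample))
    stop_gd("call matrix columns must match panel samples (same order)")
  if (anyDuplicated(rownames(calls)))
    stop_gd("duplicate SNP ids in call matrix")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop_gd("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  allele_a <- toupper(as.character(allele_a))
  allele_b <- toupper(as.character(allele_b))
  if (length(allele_a) != nrow(calls) || length(allele_b) != nrow(calls))
    stop_gd("allele vectors must have one entry per SNP")
  if (!all(is_base(allele_a)) || !all(is_base(allele_b)))
    stop_gd("alleles must be single bases A/C/G/T")
  if (any(allele_a == allele_b))
    stop_gd("monomorphic allele pair (allele_a == allele_b) at: ",
            paste(rownames(calls)[allele_a == allele_b], collapse = ", "))
  structure(list(calls = calls,
                 alleles = data.frame(snp = rownames(calls),
                                      allele_a = allele_a,
                                      allele_b = allele_b,
                                      stringsAsFactors = FALSE),
                 panel = panel),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf("geno_dataset: %d SNPs x %d samples (%d populations, %d regions)\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$panel$population)),
              length(unique(x$panel$region))))
  cat(sprintf("  overall missingness: %.4f\n", mean(is.na(x$calls))))
  invisible(x)
}

#' Per-SNP missingness fraction
#'
#' @param ds a `geno_dataset`.
#' @return Named numeric vector, fraction of missing calls per SNP.
#' @export
snp_missingness <- function(ds) {
  rowMeans(is.na(ds$calls))
}

#' Read genotypes from VCF or genotype-matrix TSV
#'
#' The TSV dialect is: tab-separated, header row of sample ids, first column
#' the SNP id, cells the count of allele A in \{0, 1, 2\} or `NA`. Optional
#' columns `allele_a`/`allele_b` carry the allele letters (defaulting to A/B
#' placeholders is not allowed when a risk-SNP table must be reconciled, so
#' simulated TSVs always carry them). VCF records must be biallelic SNPs;
#' multi-allelic or non-SNP records are skipped with a warning. Calls count
#' copies of the VCF REF allele.
#'
#' @param path path to a `.vcf` file or a genotype TSV.
#' @param panel a `pop_panel`; samples are aligned (and restricted) to it.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A `geno_dataset`.
#' @export
read_genotypes <- function(path, panel, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_gd("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path, panel) else read_genotypes_tsv(path, panel)
}

read_genotypes_tsv <- function(path, panel) {
  df <- read_tsv_gd(path)
  if (ncol(df) < 2L) stop_gd("genotype TSV needs a SNP column plus samples")
  snp_ids <- as.character(df[[1L]])
  allele_a <- if ("allele_a" %in% names(df)) toupper(df$allele_a) else rep("A", nrow(df))
  allele_b <- if ("allele_b" %in% names(df)) toupper(df$allele_b) else rep("C", nrow(df))
  keep <- setdiff(names(df)[-1L], c("allele_a", "allele_b"))
  common <- intersect(panel$sample, keep)
  if (!length(common)) stop_gd("no overlap between genotype samples and panel")
  extra <- setdiff(keep, panel$sample)
  if (length(extra))
    warning(length(extra), " genotype sample(s) absent from panel were dropped",
            call. = FALSE)
  panel_use <- subset_panel(panel, common)
  m <- as.matrix(df[, panel_use$sample, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which((!is.na(m) & m != "NA") & (is.na(num) | !(num %in% c(0, 1, 2))),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop_gd("malformed genotype cell at SNP '", snp_ids[bad[1, 1]],
            "', sample '", panel_use$sample[bad[1, 2]], "': '",
            m[bad[1, , drop = FALSE]], "'")
  }
  rownames(num) <- snp_ids
  colnames(num) <- panel_use$sample
  geno_dataset(num, allele_a, allele_b, panel_use)
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  ok <- is_base(ref) & is_base(alt) & !grepl(",", alt)
  if (any(!ok))
    warning("skipped ", sum(!ok), " multi-allelic/non-SNP VCF record(s): ",
            paste(utils::head(ids[!ok], 5), collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  calls <- parse_gt_matrix(gt)
  rownames(calls) <- ids[ok]
  common <- intersect(panel$sample, colnames(calls))
  if (!length(common)) stop_gd("no overlap between VCF samples and panel")
  panel_use <- subset_panel(panel, common)
  calls <- calls[, panel_use$sample, drop = FALSE]
  geno_dataset(calls, ref[ok], alt[ok], panel_use)
}

# GT strings ("0/1", "1|1", ".", "./.") -> count of REF allele; any missing
# allele makes the call missing
parse_gt_matrix <- function(gt) {
  u <- unique(as.vector(gt))
  conv <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    if (!all(al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "0")
  }, integer(1))
  m <- matrix(conv[match(as.vector(gt), u)], nrow(gt), ncol(gt))
  dimnames(m) <- dimnames(gt)
  m
}

subset_panel <- function(panel, samples) {
  keep <- panel[panel$sample %in% samples, , drop = FALSE]
  as_pop_panel(as.data.frame(keep), regions = attr(panel, "regions") %||% default_regions())
}

#' Write a genotype dataset as TSV
#'
#' Emits the genotype-matrix dialect accepted by [read_genotypes()]
#' (SNP id, allele columns, then one column of 0/1/2/NA per sample).
#'
#' @param ds a `geno_dataset`.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(ds, path) {
  df <- data.frame(snp = rownames(ds$calls),
                   allele_a = ds$alleles$allele_a,
                   allele_b = ds$alleles$allele_b,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ds$calls))
  write_tsv_gd(df, path)
}

#' Write a genotype dataset as plain-text VCF
#'
#' Minimal VCFv4.2 with GT-only genotypes, REF = allele A. Positions are
#' synthetic (sequential on chromosome 1) unless SNP ids carry `chr:pos`.
#'
#' @param ds a `geno_dataset`.
#' @param path output path (`.vcf`).
#' @export
write_genotypes_vcf <- function(ds, path) {
  n <- nrow(ds$calls)
  gt_of <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
  body <- vapply(seq_len(n), function(i) {
    g <- ds$calls[i, ]
    gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
    paste(c("1", i, rownames(ds$calls)[i], ds$alleles$allele_a[i],
            ds$alleles$allele_b[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=geodiffr",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(ds$calls)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
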