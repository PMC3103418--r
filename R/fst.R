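#' Weir-Cockerham variance components for every SNP
#'
#' Multi-population moment estimator of F_ST from genotype data. For each SNP
#' with r groups of sizes n_i, allele frequencies p_i and observed
#' heterozygote proportions h_i:
#'
#'   n_bar = mean n_i;  n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)
#'   p_bar = sum n_i p_i / sum n_i;  h_bar = sum n_i h_i / sum n_i
#'   s2 = sum n_i (p_i - p_bar)^2 / ((r - 1) n_bar)
#'   a = n_bar/n_c * (s2 - (p_bar(1-p_bar) - s2 (r-1)/r - h_bar/4) / (n_bar-1))
#'   b = n_bar/(n_bar-1) * (p_bar(1-p_bar) - s2 (r-1)/r - h_bar (2 n_bar-1)/(4 n_bar))
#'   c = h_bar / 2
#'   theta = a / (a + b + c)
#'
#' `a` is the among-group component, `b` among-individuals-within-group, `c`
#' within-individual. Negative estimates are reported as computed (see
#' `truncate`). SNPs monomorphic across the groups considered (a + b + c = 0)
#' get `theta = NA` and `monomorphic = TRUE`; the estimator also requires
#' mean group size > 1. Groups with zero non-missing calls at a SNP are
#' dropped for that SNP.
#'
#' @param ds a `geno_dataset`.
#' @param grouping `"population"`, `"region"`, or a factor/character vector of
#'   group labels over the samples (NA label excludes a sample).
#' @param snp_ids optional subset of SNP ids (default all).
#' @param truncate if `TRUE`, negative theta estimates are set to 0.
#' @return data.frame: snp, a, b, c, theta, n_groups_used, monomorphic.
#' @export
weir_fst_components <- function(ds, grouping = "population", snp_ids = NULL,
                                truncate = FALSE) {
  g <- resolve_grouping(ds, grouping)
  calls <- ds$calls
  if (!is.null(snp_ids)) {
    missing_ids <- setdiff(snp_ids, rownames(calls))
    if (length(missing_ids))
      stop_gd("SNP(s) absent from dataset: ", paste(missing_ids, collapse = ", "))
    calls <- calls[snp_ids, , drop = FALSE]
  }
  keep <- !is.na(g)
  calls <- calls[, keep, drop = FALSE]
  g <- factor(g[keep])
  if (nlevels(g) < 2L) stop_gd("need at least 2 groups")

  S <- nrow(calls)
  lv <- levels(g)
  nmat <- matrix(0, S, length(lv))
  pnum <- matrix(0, S, length(lv))   # allele-A counts
  hnum <- matrix(0, S, length(lv))   # heterozygote counts
  for (k in seq_along(lv)) {
    sub <- calls[, g == lv[k], drop = FALSE]
    nmat[, k] <- rowSums(!is.na(sub))
    pnum[, k] <- rowSums(sub, na.rm = TRUE)
    hnum[, k] <- rowSums(sub == 1L, na.rm = TRUE)
  }
  pmat <- pnum / (2 * nmat)
  pmat[nmat == 0] <- 0               # weight n_i = 0 removes the term anyway

  r <- rowSums(nmat > 0)
  N <- rowSums(nmat)
  nbar <- N / r
  n_c <- (N - rowSums(nmat^2) / N) / (r - 1)
  pbar <- rowSums(nmat * pmat) / N
  hbar <- rowSums(hnum) / N
  s2 <- rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar)

  inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
  a <- nbar / n_c * (s2 - inner / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- a / denom
  mono <- !is.na(denom) & abs(denom) < .Machine$double.eps * 8
  bad <- r < 2 | nbar <= 1
  theta[mono | bad] <- NA_real_
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  if (truncate) theta <- pmax(theta, 0)

  data.frame(snp = rownames(calls), a = a, b = b, c = cc, theta = theta,
             n_groups_used = r, monomorphic = mono & !bad,
             stringsAsFactors = FALSE)
}

resolve_grouping <- function(ds, grouping) {
  if (is.character(grouping) && length(grouping) == 1L) {
    switch(grouping,
           population = ds$panel$population,
           region = ds$panel$region,
           stop_gd("unknown grouping '", grouping,
                   "' (use \"population\", \"region\" or a label vector)"))
  } else {
    if (length(grouping) != ncol(ds$calls))
      stop_gd("grouping vector must have one label per sample")
    as.character(grouping)
  }
}

#' Weir-Cockerham F_ST for one SNP
#'
#' @inheritParams weir_fst_components
#' @param snp a single SNP id.
#' @return one-row data.frame as [weir_fst_components()].
#' @export
weir_fst <- function(ds, snp, grouping = "population", truncate = FALSE) {
  weir_fst_components(ds, grouping = grouping, snp_ids = snp,
                      truncate = truncate)
}

#' Global, region-pair and population-pair F_ST matrices
#'
#' For each requested SNP: the global theta across all populations, the
#' region-by-region matrix of pairwise theta (individuals of a region's
#' populations pooled), and the population-by-population pairwise matrix.
#' Cells where the SNP is monomorphic over the pair are `NA`.
#'
#' @param ds a `geno_dataset`.
#' @param snp_ids SNP ids to compute (default all SNPs in `ds`).
#' @param scopes any of `"global"`, `"region"`, `"population"`.
#' @param truncate passed to [weir_fst_components()].
#' @return list with `global` (data.frame), `region` and `population`
#'   (named lists of symmetric matrices, one per SNP, `NA` diagonal).
#' @export
fst_matrices <- function(ds, snp_ids = NULL,
                         scopes = c("global", "region", "population"),
                         truncate = FALSE) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (is.null(snp_ids)) snp_ids <- rownames(ds$calls)
  out <- list()
  if ("global" %in% scopes)
    out$global <- weir_fst_components(ds, "population", snp_ids, truncate)
  if ("region" %in% scopes)
    out$region <- pairwise_fst(ds, snp_ids, ds$panel$region, truncate)
  if ("population" %in% scopes)
    out$population <- pairwise_fst(ds, snp_ids, ds$panel$population, truncate)
  out
}

# pairwise theta over all label pairs; returns one matrix per SNP
pairwise_fst <- function(ds, snp_ids, labels, truncate = FALSE) {
  lv <- unique(labels)
  K <- length(lv)
  mats <- lapply(snp_ids, function(s)
    matrix(NA_real_, K, K, dimnames = list(lv, lv)))
  names(mats) <- snp_ids
  for (i in seq_len(K - 1)) for (j in seq((i + 1), K)) {
    lab <- ifelse(labels %in% c(lv[i], lv[j]), labels, NA)
    comp <- weir_fst_components(ds, lab, snp_ids, truncate)
    for (s in seq_along(snp_ids)) {
      mats[[s]][i, j] <- mats[[s]][j, i] <- comp$theta[s]
    }
  }
  mats
}

#' Write pairwise F_ST matrices as long TSV
#'
#' @param mats named list of matrices from [fst_matrices()].
#' @param path output TSV (columns snp, group_a, group_b, theta).
#' @param header optional `#` provenance line.
#' @export
write_fst_pairs <- function(mats, path, header = NULL) {
  rows <- lapply(names(mats), function(s) {
    m <- mats[[s]]
    ij <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(snp = s, group_a = rownames(m)[ij[, 1]],
               group_b = colnames(m)[ij[, 2]], theta = m[ij],
               stringsAsFactors = FALSE)
  })
  write_tsv_gd(do.call(rbind, rows), path, header = header)
}

#' Mean global F_ST over SNPs
#'
#' Unweighted arithmetic mean of the defined (non-`NA`) per-SNP theta values.
#'
#' @param fst data.frame from [weir_fst_components()].
#' @return single number.
#' @export
mean_global_fst <- function(fst) {
  mean(fst$theta, na.rm = TRUE)
}
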