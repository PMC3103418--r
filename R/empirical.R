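#' Folded minor-allele frequency per SNP
#'
#' Pooled allele frequency over all non-missing calls, folded to `[0, 0.5]`.
#'
#' @param ds a `geno_dataset`.
#' @param snp_ids optional subset.
#' @return named numeric vector of folded MAFs.
#' @export
folded_maf <- function(ds, snp_ids = NULL) {
  calls <- ds$calls
  if (!is.null(snp_ids)) calls <- calls[snp_ids, , drop = FALSE]
  p <- rowSums(calls, na.rm = TRUE) / (2 * rowSums(!is.na(calls)))
  pmin(p, 1 - p)
}

maf_bin_index <- function(maf, width) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop_gd("folded MAF must lie in [0, 0.5]")
  b <- ceiling(maf / width)
  b[!is.na(b) & b == 0L] <- 1L       # maf exactly 0 goes to the lowest bin
  b
}

#' Empirical F_ST null distribution from a neutral SNP panel
#'
#' Global Weir-Cockerham theta and folded MAF for every neutral SNP, binned
#' by folded MAF so that observed SNPs can be compared to frequency-matched
#' neutral SNPs. Bins partition (0, 0.5] with the given width.
#'
#' @param ds_neutral `geno_dataset` of putatively neutral SNPs, genotyped on
#'   the same individuals as the SNPs to be tested.
#' @param maf_bin_width folded-MAF bin width (default 0.05, i.e. 10 bins).
#' @return An `empirical_null`: list with `table` (snp, theta, maf, bin),
#'   `maf_bin_width`, and `percentiles` (95th and 99th of the defined thetas).
#' @export
empirical_null <- function(ds_neutral, maf_bin_width = 0.05) {
  check_scalar_number(maf_bin_width, "maf_bin_width", lower = 1e-6, upper = 0.5)
  fst <- weir_fst_components(ds_neutral, "population")
  maf <- folded_maf(ds_neutral)
  tab <- data.frame(snp = fst$snp, theta = fst$theta, maf = unname(maf),
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$theta), , drop = FALSE]
  if (!nrow(tab)) stop_gd("no neutral SNP with a defined theta")
  tab$bin <- maf_bin_index(tab$maf, maf_bin_width)
  structure(list(table = tab, maf_bin_width = maf_bin_width,
                 percentiles = stats::quantile(tab$theta, c(0.95, 0.99),
                                               names = TRUE, type = 1)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null: %d neutral SNPs, bin width %.3f; 95%%=%.4f 99%%=%.4f\n",
              nrow(x$table), x$maf_bin_width,
              x$percentiles[[1]], x$percentiles[[2]]))
  invisible(x)
}

#' Empirical p-values against the neutral null
#'
#' Rank-based upper-tail p with add-one correction,
#' `P = (1 + #\{theta_null >= theta_obs\}) / (N + 1)`, over all neutral SNPs
#' (`p_value`) and over neutral SNPs in the observed SNP's folded-MAF bin
#' (`p_cor`). `p_cor` is `NA` when the bin holds fewer than `min_bin_size`
#' neutral SNPs.
#'
#' @param theta_obs observed theta values (vector).
#' @param maf_obs folded MAFs of the observed SNPs (vector, same length).
#' @param null an [empirical_null()].
#' @param min_bin_size minimum neutral SNPs a bin must hold for `p_cor`
#'   (default 20).
#' @param alpha significance level for the flags (default 0.05).
#' @return data.frame: theta, maf, bin, p_value, p_cor, n_null, n_bin,
#'   significant (on `p_value`), significant_cor (on `p_cor`).
#' @export
empirical_pvalue <- function(theta_obs, maf_obs, null, min_bin_size = 20,
                             alpha = 0.05) {
  if (length(theta_obs) != length(maf_obs))
    stop_gd("'theta_obs' and 'maf_obs' must have equal length")
  nt <- null$table$theta
  N <- length(nt)
  bins <- maf_bin_index(maf_obs, null$maf_bin_width)
  p <- vapply(theta_obs, function(t0) {
    if (is.na(t0)) return(NA_real_)
    (1 + sum(nt >= t0)) / (N + 1)
  }, numeric(1))
  n_bin <- integer(length(theta_obs))
  p_cor <- rep(NA_real_, length(theta_obs))
  for (i in seq_along(theta_obs)) {
    nb <- nt[null$table$bin == bins[i]]
    n_bin[i] <- length(nb)
    if (!is.na(theta_obs[i]) && length(nb) >= min_bin_size)
      p_cor[i] <- (1 + sum(nb >= theta_obs[i])) / (length(nb) + 1)
  }
  data.frame(theta = theta_obs, maf = maf_obs, bin = bins,
             p_value = p, p_cor = p_cor, n_null = N, n_bin = n_bin,
             significant = !is.na(p) & p < alpha,
             significant_cor = !is.na(p_cor) & p_cor < alpha)
}

#' Frequency-matched mean-F_ST resampling comparison
#'
#' Tests whether the mean theta of a target SNP set exceeds that of random
#' frequency-matched SNP sets: each resample draws, for every target SNP, one
#' pool SNP from the same folded-MAF bin (without replacement within a
#' resample) and records the mean theta;
#' `p = (1 + #\{resample mean >= target mean\}) / (n_resample + 1)`.
#'
#' @param target data.frame with columns `theta`, `maf` (the SNP set under
#'   test).
#' @param pool data.frame with columns `theta`, `maf` (e.g. the neutral
#'   panel).
#' @param n_resample number of resamples (default 1000).
#' @param maf_bin_width folded-MAF bin width (default 0.05).
#' @param seed optional RNG seed.
#' @return list: `target_mean`, `resample_means`, `p_value`, `n_resample`.
#' @export
mean_fst_comparison <- function(target, pool, n_resample = 1000,
                                maf_bin_width = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(target$theta)
  target <- target[keep, , drop = FALSE]
  pool <- pool[!is.na(pool$theta), , drop = FALSE]
  tb <- maf_bin_index(target$maf, maf_bin_width)
  pb <- maf_bin_index(pool$maf, maf_bin_width)
  need <- table(tb)
  have <- table(factor(pb, levels = names(need)))
  short <- names(need)[as.integer(have) < as.integer(need)]
  if (length(short))
    stop_gd("pool cannot frequency-match target in MAF bin(s): ",
            paste(short, collapse = ", "))
  target_mean <- mean(target$theta)
  bin_idx <- split(seq_along(pb), pb)
  means <- vapply(seq_len(n_resample), function(b) {
    picked <- unlist(lapply(names(need), function(bn) {
      pop <- bin_idx[[bn]]
      pop[sample.int(length(pop), need[[bn]])]   # safe for length-1 bins
    }), use.names = FALSE)
    mean(pool$theta[picked])
  }, numeric(1))
  list(target_mean = target_mean, resample_means = means,
       p_value = (1 + sum(means >= target_mean)) / (n_resample + 1),
       n_resample = n_resample)
}

#' Multiple-testing adjustment
#'
#' Bonferroni or Benjamini-Hochberg adjustment via [stats::p.adjust()].
#'
#' @param p_values p-values in (0, 1].
#' @param method `"bonferroni"` or `"BH"`.
#' @param alpha significance level for the returned significant set.
#' @return list: `adjusted`, `significant` (logical), `method`.
#' @export
multiple_testing <- function(p_values, method = c("bonferroni", "BH"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (!length(p_values))
    return(list(adjusted = numeric(0), significant = logical(0), method = method))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop_gd("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p_values, method = method)
  list(adjusted = adj, significant = !is.na(adj) & adj < alpha, method = method)
}
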