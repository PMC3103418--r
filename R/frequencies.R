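#' Risk-allele frequency table
#'
#' Computes per-population risk-allele frequencies (RAF) and unweighted
#' per-region mean RAFs for every SNP in a risk-SNP table. Missing genotypes
#' are excluded from allele counts (complete case per SNP per population); a
#' population with zero non-missing calls at a SNP gets `NA` and is excluded
#' from its region mean. Ambiguous-strand SNPs flagged by
#' [reconcile_risk_alleles()] are dropped with a warning.
#'
#' @param ds a `geno_dataset`.
#' @param snps a `risk_snp_table`; every SNP must be present in `ds`.
#' @return A `freq_table`: list with matrices `raf` (SNP x population),
#'   `n_alleles` (non-missing allele counts), `region_raf` (SNP x region),
#'   plus the population-to-region map and the SNP table used.
#' @export
compute_freq_table <- function(ds, snps) {
  rec <- reconcile_risk_alleles(ds, snps)
  keep <- !rec$ambiguous
  if (!any(keep)) stop_gd("no SNPs left after dropping ambiguous-strand SNPs")
  snps_used <- snps[keep, , drop = FALSE]
  rec <- rec[keep, , drop = FALSE]

  calls <- ds$calls[snps_used$snp, , drop = FALSE]
  pops <- panel_populations(ds$panel)
  pop_of <- ds$panel$population
  count_a <- vapply(pops, function(p) {
    rowSums(calls[, pop_of == p, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(calls)))
  n_gt <- vapply(pops, function(p) {
    rowSums(!is.na(calls[, pop_of == p, drop = FALSE]))
  }, numeric(nrow(calls)))
  if (nrow(calls) == 1L) {     # vapply drops to vector-of-one rows
    count_a <- matrix(count_a, 1, dimnames = list(rownames(calls), pops))
    n_gt <- matrix(n_gt, 1, dimnames = list(rownames(calls), pops))
  }
  n_alleles <- 2 * n_gt
  raf_a <- count_a / n_alleles          # NaN where no data
  raf_a[n_alleles == 0] <- NA_real_
  raf <- raf_a
  raf[!rec$risk_is_a, ] <- 1 - raf_a[!rec$risk_is_a, , drop = FALSE]
  dimnames(raf) <- list(snps_used$snp, pops)
  dimnames(n_alleles) <- dimnames(raf)

  pop_region <- panel_pop_region(ds$panel)[pops]
  regions <- unique(unname(pop_region))
  region_raf <- vapply(regions, function(r) {
    rowMeans(raf[, pop_region == r, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(raf)))
  if (nrow(raf) == 1L)
    region_raf <- matrix(region_raf, 1, dimnames = list(rownames(raf), regions))
  region_raf[is.nan(region_raf)] <- NA_real_
  dimnames(region_raf) <- list(rownames(raf), regions)

  structure(list(raf = raf, n_alleles = n_alleles, region_raf = region_raf,
                 pop_region = pop_region, snps = snps_used),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d SNPs x %d populations (%d regions)\n",
              nrow(x$raf), ncol(x$raf), ncol(x$region_raf)))
  invisible(x)
}

#' Write / read a frequency table
#'
#' Long TSV with columns `snp`, `level` (`population` or `region`), `group`,
#' `raf`, `n_alleles` (empty at region level). Frequencies are written with 6
#' decimal places.
#'
#' @param ft a `freq_table`.
#' @param path TSV path.
#' @param header optional provenance comment written as a `#` line.
#' @export
write_freq_table <- function(ft, path, header = NULL) {
  pop_long <- data.frame(
    snp = rep(rownames(ft$raf), ncol(ft$raf)),
    level = "population",
    group = rep(colnames(ft$raf), each = nrow(ft$raf)),
    raf = as.vector(ft$raf),
    n_alleles = as.vector(ft$n_alleles))
  reg_long <- data.frame(
    snp = rep(rownames(ft$region_raf), ncol(ft$region_raf)),
    level = "region",
    group = rep(colnames(ft$region_raf), each = nrow(ft$region_raf)),
    raf = as.vector(ft$region_raf),
    n_alleles = NA_real_)
  write_tsv_gd(rbind(pop_long, reg_long), path, header = header)
}

#' @rdname write_freq_table
#' @param panel the `pop_panel` the table was computed against (restores the
#'   population-to-region map).
#' @export
read_freq_table <- function(path, panel) {
  df <- read_tsv_gd(path)
  pop <- df[df$level == "population", ]
  reg <- df[df$level == "region", ]
  snp_ids <- unique(df$snp)
  pops <- unique(pop$group)
  regions <- unique(reg$group)
  raf <- matrix(NA_real_, length(snp_ids), length(pops),
                dimnames = list(snp_ids, pops))
  n_alleles <- raf
  raf[cbind(match(pop$snp, snp_ids), match(pop$group, pops))] <- pop$raf
  n_alleles[cbind(match(pop$snp, snp_ids), match(pop$group, pops))] <- pop$n_alleles
  region_raf <- matrix(NA_real_, length(snp_ids), length(regions),
                       dimnames = list(snp_ids, regions))
  region_raf[cbind(match(reg$snp, snp_ids), match(reg$group, regions))] <- reg$raf
  structure(list(raf = raf, n_alleles = n_alleles, region_raf = region_raf,
                 pop_region = panel_pop_region(panel)[pops],
                 snps = NULL),
            class = "freq_table")
}

#' Fixed/missed alleles and maximum pairwise RAF differences
#'
#' Per SNP, the largest absolute RAF difference over all population pairs,
#' and flags for being fixed (RAF = 1) or missed (RAF = 0) in at least one
#' population. SNPs with data in fewer than two populations are excluded
#' with a warning.
#'
#' @param ft a `freq_table`.
#' @return list with `per_snp` (data.frame: snp, max_pairwise_diff, fixed_any,
#'   missed_any, n_pops_used), `n_fixed`, `n_missed`, and `excluded` SNP ids.
#' @export
summarize_raf_extremes <- function(ft) {
  if (ncol(ft$raf) < 2L) stop_gd("need at least 2 populations")
  n_used <- rowSums(!is.na(ft$raf))
  excluded <- rownames(ft$raf)[n_used < 2L]
  if (length(excluded))
    warning(length(excluded), " SNP(s) with data in <2 populations excluded",
            call. = FALSE)
  keep <- n_used >= 2L
  raf <- ft$raf[keep, , drop = FALSE]
  # max over pairs |raf_i - raf_j| equals range width
  mx <- apply(raf, 1, max, na.rm = TRUE)
  mn <- apply(raf, 1, min, na.rm = TRUE)
  per_snp <- data.frame(
    snp = rownames(raf),
    max_pairwise_diff = mx - mn,
    fixed_any = mx == 1,
    missed_any = mn == 0,
    n_pops_used = n_used[keep],
    stringsAsFactors = FALSE)
  rownames(per_snp) <- NULL
  list(per_snp = per_snp,
       n_fixed = sum(per_snp$fixed_any),
       n_missed = sum(per_snp$missed_any),
       excluded = excluded)
}

#' In-region versus out-of-region RAF contrast (delta-F)
#'
#' For a SNP and a region, `f_in` is the unweighted mean RAF over the
#' region's populations and `f_out` the unweighted mean over all other
#' populations; `delta_f = f_out - f_in`. Negative values mean the risk
#' allele is commoner inside the tested region than in the rest of the world.
#' Populations with missing RAF at the SNP are dropped from both sides.
#'
#' @param ft a `freq_table`.
#' @param snp SNP id.
#' @param region region name.
#' @return one-row data.frame: snp, region, f_in, f_out, delta_f.
#' @export
delta_f <- function(ft, snp, region) {
  if (!snp %in% rownames(ft$raf)) stop_gd("unknown SNP: ", snp)
  if (!region %in% ft$pop_region) stop_gd("unknown region: ", region)
  x <- ft$raf[snp, ]
  inside <- ft$pop_region == region
  xi <- x[inside & !is.na(x)]
  xo <- x[!inside & !is.na(x)]
  if (!length(xi)) stop_gd("region '", region, "' has no population with data at ", snp)
  if (!length(xo)) stop_gd("complement of region '", region, "' has no population with data at ", snp)
  data.frame(snp = snp, region = region,
             f_in = mean(xi), f_out = mean(xo),
             delta_f = mean(xo) - mean(xi),
             stringsAsFactors = FALSE)
}

#' All SNP-by-region delta-F values
#'
#' @param ft a `freq_table`.
#' @return data.frame: snp, region, f_in, f_out, delta_f (one row per SNP per
#'   region; rows where a side has no data carry `NA`).
#' @export
delta_f_table <- function(ft) {
  raf <- ft$raf
  regions <- colnames(ft$region_raf)
  sum_all <- rowSums(raf, na.rm = TRUE)
  cnt_all <- rowSums(!is.na(raf))
  out <- lapply(regions, function(r) {
    inside <- ft$pop_region == r
    sum_in <- rowSums(raf[, inside, drop = FALSE], na.rm = TRUE)
    cnt_in <- rowSums(!is.na(raf[, inside, drop = FALSE]))
    f_in <- ifelse(cnt_in > 0, sum_in / cnt_in, NA_real_)
    cnt_out <- cnt_all - cnt_in
    f_out <- ifelse(cnt_out > 0, (sum_all - sum_in) / cnt_out, NA_real_)
    data.frame(snp = rownames(raf), region = r, f_in = f_in, f_out = f_out,
               delta_f = f_out - f_in, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag SNPs with a large delta-F in at least one region
#'
#' @param results data.frame from [delta_f_table()] or
#'   [permutation_test_delta_f()] (needs columns `snp`, `delta_f`).
#' @param threshold magnitude above which |delta_f| counts as large (strict
#'   inequality). Default 0.3.
#' @return list with `per_snp` (snp, max_abs_delta_f, large), `n_large`,
#'   `n_snps`, `fraction`, `percent`.
#' @export
classify_large_delta <- function(results, threshold = 0.3) {
  check_scalar_number(threshold, "threshold", lower = 0)
  if (threshold <= 0) stop_gd("'threshold' must be > 0")
  ids <- unique(results$snp)
  mx <- tapply(abs(results$delta_f), factor(results$snp, levels = ids),
               function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  per_snp <- data.frame(snp = ids, max_abs_delta_f = as.numeric(mx),
                        large = !is.na(mx) & mx > threshold,
                        stringsAsFactors = FALSE)
  n_large <- sum(per_snp$large)
  list(per_snp = per_snp, n_large = n_large, n_snps = nrow(per_snp),
       fraction = n_large / nrow(per_snp),
       percent = 100 * n_large / nrow(per_snp))
}

#' Permutation test for delta-F
#'
#' Null distribution of delta-F obtained by randomly reassigning populations
#' to regions while preserving the observed region sizes; the two-sided
#' p-value uses the add-one correction
#' `p = (1 + #\{|delta_perm| >= |delta_obs|\}) / (n_perm + 1)`.
#' Populations with missing RAF at the SNP are dropped from both the observed
#' statistic and every permutation.
#'
#' @param ft a `freq_table`.
#' @param snp SNP id.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed (set once per call).
#' @return data.frame: snp, region, f_in, f_out, delta_f, p_perm, n_perm.
#' @export
permutation_test_delta_f <- function(ft, snp, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop_gd("'n_perm' must be >= 1")
  if (length(unique(ft$pop_region)) < 2L) stop_gd("need at least 2 regions")
  if (!snp %in% rownames(ft$raf)) stop_gd("unknown SNP: ", snp)
  x_all <- ft$raf[snp, ]
  ok <- !is.na(x_all)
  x <- x_all[ok]
  lab <- ft$pop_region[ok]
  regions <- unique(ft$pop_region)
  present <- intersect(regions, unique(lab))
  if (length(present) < length(regions))
    warning("region(s) without data at ", snp, " dropped: ",
            paste(setdiff(regions, present), collapse = ", "), call. = FALSE)
  if (length(present) < 2L)
    stop_gd("fewer than 2 regions with data at ", snp)
  P <- length(x)
  total <- sum(x)
  # one shared relabeling per permutation: columns are permuted raf vectors
  idx <- matrix(0L, P, n_perm)
  for (b in seq_len(n_perm)) idx[, b] <- sample.int(P)
  X <- matrix(x[idx], P, n_perm)

  rows <- lapply(present, function(r) {
    slots <- which(lab == r)
    n_in <- length(slots)
    obs_in <- mean(x[slots])
    obs_out <- (total - sum(x[slots])) / (P - n_in)
    d_obs <- obs_out - obs_in
    s_in <- if (n_in == 1L) X[slots, ] else colSums(X[slots, , drop = FALSE])
    d_perm <- (total - s_in) / (P - n_in) - s_in / n_in
    # tolerance keeps exact ties (same |delta| up to rounding) in the tail
    p <- (1 + sum(abs(d_perm) >= abs(d_obs) - 1e-12)) / (n_perm + 1)
    data.frame(snp = snp, region = r, f_in = obs_in, f_out = obs_out,
               delta_f = d_obs, p_perm = p, n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Permutation delta-F scan over all SNPs
#'
#' @param ft a `freq_table`.
#' @param n_perm permutations per SNP.
#' @param seed RNG seed (set once; SNPs consume the stream sequentially, so
#'   results are reproducible for a fixed SNP order).
#' @return data.frame as [permutation_test_delta_f()], all SNPs stacked.
#' @export
delta_f_scan <- function(ft, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(rownames(ft$raf), function(s)
    permutation_test_delta_f(ft, s, n_perm = n_perm))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
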