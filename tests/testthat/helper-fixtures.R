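# Fixture builders and independent oracles shared across the test files.

make_panel_df <- function(n_per_pop, pops, regions, lat = NULL, lon = NULL) {
  stopifnot(length(pops) == length(regions))
  if (is.null(lat)) lat <- seq(0, 10, length.out = length(pops))
  if (is.null(lon)) lon <- seq(0, 10, length.out = length(pops))
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, length(pops))
  data.frame(
    sample = sprintf("s%03d", seq_len(sum(n_per_pop))),
    population = rep(pops, times = n_per_pop),
    region = rep(regions, times = n_per_pop),
    lat = rep(lat, times = n_per_pop),
    lon = rep(lon, times = n_per_pop),
    stringsAsFactors = FALSE)
}

# genotype dataset from an explicit call matrix (rows = SNPs)
make_ds <- function(calls, panel, allele_a = NULL, allele_b = NULL) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("snp%02d", seq_len(nrow(calls)))
  colnames(calls) <- panel$sample
  if (is.null(allele_a)) allele_a <- rep("A", nrow(calls))
  if (is.null(allele_b)) allele_b <- rep("G", nrow(calls))
  geno_dataset(calls, allele_a, allele_b, as_pop_panel(panel))
}

# freq_table built directly from a RAF matrix (SNP x population)
make_ft <- function(raf, pop_region) {
  regions <- unique(unname(pop_region))
  region_raf <- vapply(regions, function(r) {
    rowMeans(raf[, pop_region == r, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(raf)))
  if (nrow(raf) == 1L)
    region_raf <- matrix(region_raf, 1, dimnames = list(rownames(raf), regions))
  dimnames(region_raf) <- list(rownames(raf), regions)
  structure(list(raf = raf, n_alleles = raf * 0 + 20,
                 region_raf = region_raf, pop_region = pop_region,
                 snps = NULL),
            class = "freq_table")
}

# Independent Weir-Cockerham oracle via the nested ANOVA sums of squares
# (populations / individuals / gametes), a different algebraic route than
# the package's direct variance-component formulas.
oracle_fst_anova <- function(calls_row, labels) {
  ok <- !is.na(calls_row)
  x <- calls_row[ok]
  lab <- labels[ok]
  groups <- split(x, lab)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  r <- length(groups)
  if (r < 2) return(NA_real_)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  pbar <- sum(unlist(groups)) / (2 * N)
  SSG <- sum(unlist(groups) == 1) * 0.5
  SSI <- sum(unlist(lapply(groups, function(g) 2 * (g / 2 - mean(g) / 2)^2)))
  SSP <- sum(vapply(seq_len(r), function(i)
    2 * n[i] * (mean(groups[[i]]) / 2 - pbar)^2, numeric(1)))
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# spherical law of cosines, an alternative great-circle formula
oracle_slc_km <- function(lat1, lon1, lat2, lon2, radius = 6371) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  radius * acos(pmin(pmax(d, -1), 1))
}

write_tiny_vcf <- function(path, ids, ref, alt, gt_rows, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(ids), function(i) {
    paste(c("1", i, ids[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
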