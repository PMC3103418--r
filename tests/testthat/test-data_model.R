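# Panel, genotype and SNP-table readers plus the RAF table.

test_that("panel TSV parses and validates membership structure", {
  df <- make_panel_df(1, c("Yoruba", "Yoruba", "French", "French"),
                      c("Africa", "Africa", "Europe", "Europe"))
  # four samples in two populations
  df$population <- c("Yoruba", "Yoruba", "French", "French")
  df$region <- c("Africa", "Africa", "Europe", "Europe")
  df$lat <- c(8, 8, 46, 46); df$lon <- c(4, 4, 2, 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- read_panel(path)
  expect_s3_class(panel, "pop_panel")
  expect_equal(length(unique(panel$population)), 2L)
  expect_equal(length(unique(panel$region)), 2L)
})

test_that("panel validation rejects bad input", {
  df <- make_panel_df(2, c("p1", "p2"), c("Africa", "Europe"))
  bad <- df; bad$region[3:4] <- "Atlantis"
  expect_error(as_pop_panel(bad), "Atlantis")
  dup <- df; dup$sample[2] <- dup$sample[1]
  expect_error(as_pop_panel(dup), "duplicate sample")
  nopop <- df; nopop$population[1] <- ""
  expect_error(as_pop_panel(nopop), "missing population")
  split_pop <- df; split_pop$region <- c("Africa", "Europe", "Africa", "Europe")
  expect_error(as_pop_panel(split_pop), "more than one region")
  one_pop <- df; one_pop$population <- "p1"; one_pop$region <- "Africa"
  expect_error(as_pop_panel(one_pop), "at least 2 populations")
})

test_that("simulated panel round-trips identically through TSV", {
  cfg <- sim_config(n_regions = 3, pops_per_region = 2, samples_per_pop = 5,
                    n_snps = 4, n_neutral_snps = 100, seed = 3)
  panel <- simulate_dataset(cfg)$dataset$panel
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path, regions = attr(panel, "regions"))
  expect_equal(as.data.frame(back), as.data.frame(panel), tolerance = 1e-9)
})

test_that("genotype TSV parses to the expected call matrix", {
  panel <- as_pop_panel(make_panel_df(2, c("p1", "p2"), c("Africa", "Europe")))
  df <- data.frame(snp = c("rs1", "rs2", "rs3"),
                   allele_a = "A", allele_b = "G",
                   s001 = c(0, 1, NA), s002 = c(2, 1, 0),
                   s003 = c(1, 2, 2), s004 = c(0, 0, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_genotypes(path, panel)
  expect_equal(dim(ds$calls), c(3L, 4L))
  expect_equal(unname(ds$calls["rs1", ]), c(0L, 2L, 1L, 0L))
  expect_equal(unname(snp_missingness(ds)), c(0, 0, 0.25))
})

test_that("malformed genotype cells are reported with context", {
  panel <- as_pop_panel(make_panel_df(1, c("p1", "p2"), c("Africa", "Europe")))
  df <- data.frame(snp = "rs1", s001 = 1, s002 = "x")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(path, panel), "rs1.*s002")
})

test_that("multi-allelic VCF records are skipped with a warning", {
  panel <- as_pop_panel(make_panel_df(2, c("p1", "p2"), c("Africa", "Europe")))
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- list(c("0/0", "0/1", "1/1", "./."),
             c("0/1", "0/1", "0/0", "1/1"),
             c("0/0", "0/2", "1/1", "2/2"),   # triallelic
             c("1/1", "1/1", "0/1", "0/0"),
             c("0/0", "0/0", "0/1", "0/1"))
  write_tiny_vcf(path, paste0("rs", 1:5), c("A", "C", "G", "T", "A"),
                 c("G", "T", "A,C", "C", "C"), gt, panel$sample)
  expect_warning(ds <- read_genotypes(path, panel), "multi-allelic")
  expect_equal(nrow(ds$calls), 4L)
  expect_false("rs3" %in% rownames(ds$calls))
  expect_equal(unname(ds$calls["rs1", ]), c(2L, 1L, 0L, NA))
})

test_that("VCF and equivalent TSV give identical call matrices", {
  panel <- as_pop_panel(make_panel_df(2, c("p1", "p2"), c("Africa", "Europe")))
  set.seed(21)
  calls <- matrix(sample(c(0:2, NA), 12, replace = TRUE), 3, 4)
  ds <- make_ds(calls, make_panel_df(2, c("p1", "p2"), c("Africa", "Europe")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_tsv(ds, tsv)
  write_genotypes_vcf(ds, vcf)
  ds_tsv <- read_genotypes(tsv, panel)
  ds_vcf <- read_genotypes(vcf, panel)
  expect_identical(ds_tsv$calls, ds_vcf$calls)
  expect_identical(ds_tsv$alleles, ds_vcf$alleles)
})

test_that("risk-allele frequencies count alleles correctly", {
  # genotypes AA, Aa, Aa, aa, aa with risk = A -> RAF 0.4
  panel <- make_panel_df(5, "p1", "Africa")
  panel <- rbind(panel, data.frame(sample = "s900", population = "p2",
                                   region = "Europe", lat = 0, lon = 0))
  ds <- make_ds(matrix(c(2, 1, 1, 0, 0, 2), 1), panel)
  snps <- as_risk_snp_table(data.frame(snp = "snp01", risk_allele = "A"))
  ft <- compute_freq_table(ds, snps)
  expect_equal(unname(ft$raf["snp01", "p1"]), 0.4)
  expect_equal(unname(ft$n_alleles["snp01", "p1"]), 10)
  # all homozygous risk -> fixed
  ds2 <- make_ds(matrix(c(2, 2, 2, 2, 2, 0), 1), panel)
  ft2 <- compute_freq_table(ds2, snps)
  expect_equal(unname(ft2$raf["snp01", "p1"]), 1.0)
  # raf counts are integers within rounding
  expect_equal(ft$raf * ft$n_alleles, round(ft$raf * ft$n_alleles))
})

test_that("region means are unweighted over member populations", {
  panel <- make_panel_df(c(5, 10, 4), c("p1", "p2", "p3"),
                         c("Africa", "Africa", "Europe"))
  # p1 raf 0.2 (n=5), p2 raf 0.4 (n=10): region mean must be 0.3 (unweighted)
  calls <- matrix(c(rep(0, 4), 2,             # p1: 2/10
                    rep(1, 8), 0, 0,          # p2: 8/20
                    rep(1, 4)), 1)            # p3: 4/8
  ds <- make_ds(calls, panel)
  snps <- as_risk_snp_table(data.frame(snp = "snp01", risk_allele = "A"))
  ft <- compute_freq_table(ds, snps)
  expect_equal(unname(ft$raf["snp01", c("p1", "p2")]), c(0.2, 0.4))
  expect_equal(unname(ft$region_raf["snp01", "Africa"]), 0.3)
  # brute-force recomputation over the panel
  brute <- mean(ft$raf["snp01", names(ft$pop_region)[ft$pop_region == "Africa"]])
  expect_identical(unname(ft$region_raf["snp01", "Africa"]), brute)
})

test_that("frequency table round-trips through TSV at 6 decimals", {
  cfg <- sim_config(n_regions = 3, pops_per_region = 2, samples_per_pop = 8,
                    n_snps = 12, n_neutral_snps = 100, seed = 9)
  sim <- simulate_dataset(cfg)
  ft <- compute_freq_table(sim$dataset, sim$snp_table)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(ft, path)
  back <- read_freq_table(path, sim$dataset$panel)
  expect_equal(back$raf, ft$raf, tolerance = 1e-6)
  expect_equal(back$region_raf, ft$region_raf, tolerance = 1e-6)
  expect_true(all(ft$raf >= 0 & ft$raf <= 1, na.rm = TRUE))
})

test_that("risk alleles are reconciled by letter with strand-flip rules", {
  panel <- make_panel_df(2, c("p1", "p2"), c("Africa", "Europe"))
  calls <- matrix(rep(1L, 12), 3)
  ds <- make_ds(calls, panel, allele_a = c("A", "A", "A"),
                allele_b = c("G", "G", "T"))
  # rs2 risk C = revcomp(G) -> flip; rs3 is A/T ambiguous with unmatched risk
  snps <- as_risk_snp_table(data.frame(
    snp = c("snp01", "snp02", "snp03"),
    risk_allele = c("G", "C", "C")))
  expect_warning(expect_warning(rec <- reconcile_risk_alleles(ds, snps),
                                "strand-flipped"), "ambiguous")
  expect_false(rec$risk_is_a[1])
  expect_false(rec$risk_is_a[2])   # C ~ G after flip
  expect_true(rec$flipped[2])
  expect_true(rec$ambiguous[3])
  # SNPs absent from the dataset error out
  bad <- as_risk_snp_table(data.frame(snp = "rs_nope", risk_allele = "C"))
  expect_error(reconcile_risk_alleles(ds, bad), "absent")
})
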