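# Weir-Cockerham F_ST, the empirical null, and the resampling comparisons.

two_pop_panel <- function(n) make_panel_df(n, c("p1", "p2"), c("Africa", "Europe"))

test_that("opposite fixation gives theta at the maximal-differentiation limit", {
  n <- 1000
  calls <- matrix(c(rep(2L, n), rep(0L, n)), 1)
  ds <- make_ds(calls, two_pop_panel(n))
  expect_lt(abs(weir_fst(ds, "snp01")$theta - 1), 1e-3)
})

test_that("identical allele and genotype composition gives near-zero theta", {
  mix <- c(rep(2L, 4), rep(1L, 12), rep(0L, 4))  # HWE mix at p = 0.5, n = 20
  calls <- matrix(c(mix, mix, mix), 1)
  ds <- make_ds(calls, make_panel_df(20, c("p1", "p2", "p3"),
                                     c("Africa", "Europe", "East_Asia")))
  res <- weir_fst(ds, "snp01")
  # s2 = 0 leaves only the small finite-sample correction in a (<= 0)
  expect_lt(abs(res$a), 0.01)
  expect_lte(res$theta, 0.05)
})

test_that("theta matches the independent ANOVA oracle on an explicit fixture", {
  # 3 populations x 10 genotypes, counts fixed in the test
  g1 <- c(2, 2, 2, 1, 1, 1, 1, 0, 0, 0)
  g2 <- c(2, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  g3 <- c(2, 2, 2, 2, 2, 1, 1, 1, 0, 0)
  calls <- matrix(as.integer(c(g1, g2, g3)), 1)
  panel <- make_panel_df(10, c("p1", "p2", "p3"),
                         c("Africa", "Europe", "East_Asia"))
  ds <- make_ds(calls, panel)
  got <- weir_fst(ds, "snp01")
  want <- oracle_fst_anova(calls[1, ], panel$population)
  expect_lt(abs(got$theta - want), 1e-12)
  expect_lt(abs(got$theta - got$a / (got$a + got$b + got$c)), 1e-15)
})

test_that("theta agrees with the oracle over random fixtures with missingness", {
  set.seed(202)
  for (i in 1:200) {
    r <- sample(2:8, 1)
    n <- sample(3:12, r, replace = TRUE)
    panel <- make_panel_df(n, paste0("p", seq_len(r)),
                           rep(default_regions(), length.out = r))
    calls <- matrix(sample(c(0:2, NA), sum(n), replace = TRUE,
                           prob = c(.3, .3, .3, .1)), 1)
    ds <- make_ds(calls, panel)
    got <- weir_fst(ds, "snp01")$theta
    want <- oracle_fst_anova(calls[1, ], panel$population)
    if (is.na(want)) expect_true(is.na(got))
    else expect_lt(abs(got - want), 1e-10)
  }
})

test_that("theta is invariant to swapping allele labels", {
  set.seed(77)
  calls <- matrix(sample(0:2, 60, replace = TRUE), 2)
  panel <- make_panel_df(c(10, 10, 10), c("p1", "p2", "p3"),
                         c("Africa", "Europe", "East_Asia"))
  ds <- make_ds(calls, panel)
  ds_flip <- make_ds(2L - calls, panel)
  expect_equal(weir_fst_components(ds)$theta,
               weir_fst_components(ds_flip)$theta, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged, not silently zeroed", {
  panel <- two_pop_panel(5)
  ds <- make_ds(matrix(rep(2L, 10), 1), panel)     # monomorphic
  res <- weir_fst(ds, "snp01")
  expect_true(is.na(res$theta))
  expect_true(res$monomorphic)
  one_group <- rep("p1", 10)
  expect_error(weir_fst_components(ds, one_group), "at least 2 groups")
})

test_that("matrix scopes have the expected shapes and are consistent", {
  cfg <- sim_config(n_regions = 7, pops_per_region = 4, samples_per_pop = 8,
                    n_snps = 2, n_neutral_snps = 100, seed = 5)
  sim <- simulate_dataset(cfg)
  m <- fst_matrices(sim$dataset)
  expect_equal(dim(m$region[[1]]), c(7L, 7L))
  expect_equal(dim(m$population[[1]]), c(28L, 28L))
  expect_true(all(is.na(diag(m$population[[1]]))))
  expect_equal(m$population[[1]], t(m$population[[1]]))
  # global theta on a 2-population dataset equals the single pairwise cell
  cfg2 <- sim_config(n_regions = 2, pops_per_region = 1, samples_per_pop = 12,
                     n_snps = 3, n_neutral_snps = 100, seed = 6)
  sim2 <- simulate_dataset(cfg2)
  m2 <- fst_matrices(sim2$dataset)
  expect_equal(m2$global$theta, vapply(m2$population, function(x) x[1, 2],
                                       numeric(1)), ignore_attr = TRUE)
})

test_that("pooling populations into a region equals merging their labels", {
  set.seed(11)
  calls <- matrix(sample(0:2, 90, replace = TRUE), 3)
  panel <- make_panel_df(10, c("p1", "p2", "p3"),
                         c("Africa", "Africa", "Europe"))
  ds <- make_ds(calls, panel)
  by_region <- weir_fst_components(ds, "region")
  merged <- ifelse(panel$population == "p3", "grp2", "grp1")
  by_merged <- weir_fst_components(ds, merged)
  expect_equal(by_region$theta, by_merged$theta, tolerance = 1e-12)
})

test_that("empirical p-values follow the add-one rank rule", {
  nul <- structure(list(
    table = data.frame(snp = paste0("n", 1:19),
                       theta = seq(0.01, 0.19, by = 0.01),
                       maf = rep(0.25, 19), bin = rep(5L, 19)),
    maf_bin_width = 0.05,
    percentiles = stats::quantile(seq(0.01, 0.19, 0.01), c(.95, .99), type = 1)),
    class = "empirical_null")
  res <- empirical_pvalue(0.155, 0.25, nul, min_bin_size = 5)
  # exhaustive rank: 4 null values (0.16..0.19) are >= 0.155
  expect_equal(res$p_value, (1 + 4) / 20)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$p_cor, 0.25)    # single occupied bin: Pcor equals P
  # extreme rank with a large null
  big <- structure(list(
    table = data.frame(snp = paste0("n", 1:2036),
                       theta = seq(0, 0.2, length.out = 2036),
                       maf = rep(0.25, 2036), bin = rep(5L, 2036)),
    maf_bin_width = 0.05, percentiles = c(`95%` = 0.19, `99%` = 0.198)),
    class = "empirical_null")
  expect_equal(empirical_pvalue(0.9, 0.25, big)$p_value, 1 / 2037)
})

test_that("empirical p is monotone in theta and significance mirrors the q95", {
  set.seed(303)
  thetas <- stats::rbeta(1999, 2, 12)
  nul <- structure(list(
    table = data.frame(snp = paste0("n", 1:1999), theta = thetas,
                       maf = stats::runif(1999, 0, 0.5)),
    maf_bin_width = 0.5, percentiles = stats::quantile(thetas, c(.95, .99))),
    class = "empirical_null")
  nul$table$bin <- 1L
  obs <- seq(0, 0.6, by = 0.01)
  res <- empirical_pvalue(obs, rep(0.2, length(obs)), nul)
  expect_true(all(diff(res$p_value) <= 0))
  # with N = 1999 and add-one, P < 0.05 iff theta beats the 99th largest
  cut95 <- sort(thetas, decreasing = TRUE)[99]
  expect_equal(res$significant, obs > cut95)
  # single bin (width 0.5): Pcor identical to P
  expect_equal(res$p_cor, res$p_value)
})

test_that("underfilled MAF bins yield an unavailable Pcor but a valid P", {
  nul <- structure(list(
    table = data.frame(snp = paste0("n", 1:30), theta = seq(0.01, 0.30, 0.01),
                       maf = rep(0.45, 30), bin = rep(10L, 30)),
    maf_bin_width = 0.05, percentiles = c(`95%` = 0.29, `99%` = 0.3)),
    class = "empirical_null")
  res <- empirical_pvalue(0.25, 0.02, nul)      # bin 1 is empty
  expect_true(is.na(res$p_cor))
  expect_false(is.na(res$p_value))
})

test_that("mean-F_ST resampling matches enumeration on a constructed pool", {
  # 3 targets in 3 distinct bins; 2 pool SNPs per bin -> 8 equally likely draws
  target <- data.frame(theta = c(0.10, 0.20, 0.30), maf = c(0.02, 0.12, 0.22))
  pool <- data.frame(theta = c(0.05, 0.07, 0.15, 0.17, 0.25, 0.27),
                     maf = c(0.02, 0.03, 0.12, 0.13, 0.22, 0.23))
  res <- mean_fst_comparison(target, pool, n_resample = 4000, seed = 9)
  # expected resample mean = mean of the three bin means
  exact_mean <- mean(c(mean(c(0.05, 0.07)), mean(c(0.15, 0.17)),
                       mean(c(0.25, 0.27))))
  expect_lt(abs(mean(res$resample_means) - exact_mean), 0.002)
  # every resample mean is one of the 8 enumerable combinations
  combos <- rowMeans(expand.grid(c(0.05, 0.07), c(0.15, 0.17), c(0.25, 0.27)))
  nearest <- apply(abs(outer(res$resample_means, combos, "-")), 1, min)
  expect_lt(max(nearest), 1e-12)
})

test_that("mean-F_ST comparison p behaves at the extremes and under reordering", {
  pool <- data.frame(theta = stats::rbeta(400, 2, 10), maf = stats::runif(400, 0, 0.5))
  target_hi <- data.frame(theta = rep(0.99, 5), maf = pool$maf[1:5])
  res <- mean_fst_comparison(target_hi, pool, n_resample = 300, seed = 2)
  expect_equal(res$p_value, 1 / 301)
  # order invariance
  target <- data.frame(theta = pool$theta[1:20], maf = pool$maf[1:20])
  p1 <- mean_fst_comparison(target, pool, n_resample = 200, seed = 4)$p_value
  p2 <- mean_fst_comparison(target[20:1, ], pool, n_resample = 200, seed = 4)$p_value
  expect_equal(p1, p2)
  # a target drawn from the pool itself is unremarkable
  expect_gt(p1, 0.01)
  # unmatched bins are reported
  target_bad <- data.frame(theta = 0.1, maf = 0.49)
  pool_lo <- data.frame(theta = rep(0.1, 50), maf = rep(0.01, 50))
  expect_error(mean_fst_comparison(target_bad, pool_lo), "bin")
})

test_that("multiple-testing adjustments follow the closed forms", {
  expect_equal(multiple_testing(0.001, "bonferroni")$adjusted, 0.001)
  expect_equal(multiple_testing(c(0.01, 0.02, 0.03), "bonferroni")$adjusted,
               c(0.03, 0.06, 0.09))
  # BH step-up, hand-walked: sorted p (0.001, 0.008, 0.039, 0.041) against
  # i/m * q -> all four significant at q = 0.05
  bh <- multiple_testing(c(0.039, 0.001, 0.041, 0.008), "BH", alpha = 0.05)
  expect_true(all(bh$significant))
  expect_equal(multiple_testing(numeric(0))$adjusted, numeric(0))
  expect_error(multiple_testing(c(0.5, 0)), "0, 1")
})
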