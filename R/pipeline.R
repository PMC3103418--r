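#' Pipeline run configuration
#'
#' Either supply input paths (`genotypes`, `panel`, `snps`,
#' `neutral_genotypes`) or a `simulate` block of [sim_config()] fields; all
#' other fields have defaults.
#'
#' @param genotypes,panel,snps,neutral_genotypes input file paths (TSV/VCF);
#'   ignored when `simulate` is given.
#' @param simulate `NULL` or a list of [sim_config()] arguments.
#' @param n_perm permutations for the delta-F test (default 10000).
#' @param n_resample resamples for the mean-F_ST comparison (default 1000).
#' @param maf_bin_width folded-MAF bin width (default 0.05).
#' @param delta_f_threshold |delta-F| threshold for the "large difference"
#'   classification (default 0.3).
#' @param alpha significance level (default 0.05).
#' @param min_bin_size minimum neutral SNPs per MAF bin for `p_cor`.
#' @param waypoints optional waypoint TSV path (default: shipped routes).
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(genotypes = NULL, panel = NULL, snps = NULL,
                       neutral_genotypes = NULL, simulate = NULL,
                       n_perm = 10000, n_resample = 1000,
                       maf_bin_width = 0.05, delta_f_threshold = 0.3,
                       alpha = 0.05, min_bin_size = 20, waypoints = NULL,
                       seed = 1L, outdir = "geodiffr_out") {
  if (is.null(simulate)) {
    for (f in c("genotypes", "panel", "snps", "neutral_genotypes")) {
      v <- get(f)
      if (is.null(v)) stop_gd("'", f, "' is required when 'simulate' is not set")
      if (!file.exists(v)) stop_gd("input file not found: ", v)
    }
  }
  if (!is.null(waypoints) && !file.exists(waypoints))
    stop_gd("waypoint file not found: ", waypoints)
  check_scalar_number(n_perm, "n_perm", 1)
  check_scalar_number(n_resample, "n_resample", 1)
  check_scalar_number(alpha, "alpha", 1e-12, 1)
  check_scalar_number(seed, "seed")
  structure(list(genotypes = genotypes, panel = panel, snps = snps,
                 neutral_genotypes = neutral_genotypes, simulate = simulate,
                 n_perm = as.integer(n_perm), n_resample = as.integer(n_resample),
                 maf_bin_width = maf_bin_width,
                 delta_f_threshold = delta_f_threshold, alpha = alpha,
                 min_bin_size = as.integer(min_bin_size),
                 waypoints = waypoints, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_gd("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full geographic-differentiation pipeline
#'
#' Stages: risk-allele frequencies -> fixed/missed and delta-F summaries ->
#' delta-F permutation test -> Weir-Cockerham F_ST at global, region-pair and
#' population-pair scales -> empirical P/Pcor against the neutral panel ->
#' frequency-matched mean-F_ST comparison -> isolation-by-distance
#' regression -> summary table of significant SNPs. Every output TSV carries
#' a `# seed=` provenance header and the run is bit-for-bit reproducible
#' under the same config. A stage failure aborts the run with a stage-tagged
#' error and removes partial outputs.
#'
#' @param config a [run_config()], or path to a YAML file.
#' @param verbose print per-stage progress (default `TRUE`).
#' @return (invisibly) a list of all stage results plus `summary`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  hdr <- paste0("seed=", config$seed)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_gd(df, p, header = hdr)
    written <<- c(written, p)
    p
  }
  say <- function(...) if (verbose) message("[geodiffr] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_gd("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # -- inputs -----------------------------------------------------------
  res <- list(config = config)
  stage("input", {
    if (!is.null(config$simulate)) {
      say("simulating dataset")
      cfg <- do.call(sim_config, c(config$simulate,
                                   if (is.null(config$simulate$seed))
                                     list(seed = config$seed)))
      sim <- simulate_dataset(cfg)
      res$dataset <- sim$dataset
      res$snp_table <- sim$snp_table
      res$truth <- sim$truth
      res$neutral <- simulate_neutral_panel(cfg, sim$dataset)$dataset
    } else {
      say("reading inputs")
      panel <- read_panel(config$panel)
      res$dataset <- read_genotypes(config$genotypes, panel)
      res$snp_table <- read_snp_table(config$snps)
      res$neutral <- read_genotypes(config$neutral_genotypes, panel)
    }
  })
  yaml::write_yaml(config_to_yamlable(config), file.path(outdir, "run_config.yaml"))

  # -- frequencies ------------------------------------------------------
  stage("frequencies", {
    say("risk-allele frequencies")
    res$freq <- compute_freq_table(res$dataset, res$snp_table)
    write_freq_table(res$freq, file.path(outdir, "freq_table.tsv"), header = hdr)
    written <- c(written, file.path(outdir, "freq_table.tsv"))
    res$extremes <- summarize_raf_extremes(res$freq)
    emit(res$extremes$per_snp, "raf_extremes.tsv")
  })

  # -- delta-F + permutation test --------------------------------------
  stage("delta_f", {
    say("delta-F permutation scan (", config$n_perm, " permutations)")
    res$delta <- delta_f_scan(res$freq, n_perm = config$n_perm,
                               seed = config$seed)
    emit(res$delta, "delta_f.tsv")
    res$large_delta <- classify_large_delta(res$delta,
                                             threshold = config$delta_f_threshold)
  })

  # -- F_ST at three scales --------------------------------------------
  stage("fst", {
    say("Weir-Cockerham F_ST (global, region pairs, population pairs)")
    ids <- rownames(res$freq$raf)
    res$fst <- fst_matrices(res$dataset, snp_ids = ids)
    emit(res$fst$global, "fst_global.tsv")
    write_fst_pairs(res$fst$region, file.path(outdir, "fst_region_pairs.tsv"),
                    header = hdr)
    write_fst_pairs(res$fst$population, file.path(outdir, "fst_population_pairs.tsv"),
                    header = hdr)
    written <- c(written, file.path(outdir, c("fst_region_pairs.tsv",
                                               "fst_population_pairs.tsv")))
  })

  # -- empirical null ---------------------------------------------------
  stage("empirical_null", {
    say("empirical null from ", nrow(res$neutral$calls), " neutral SNPs")
    res$null <- empirical_null(res$neutral, maf_bin_width = config$maf_bin_width)
    maf <- folded_maf(res$dataset, rownames(res$freq$raf))
    res$pvalues <- cbind(snp = res$fst$global$snp,
                          empirical_pvalue(res$fst$global$theta, unname(maf),
                                           res$null,
                                           min_bin_size = config$min_bin_size,
                                           alpha = config$alpha))
    emit(res$pvalues, "fst_pvalues.tsv")
  })

  # -- mean F_ST comparison --------------------------------------------
  stage("mean_fst", {
    say("frequency-matched mean-F_ST comparison")
    target <- data.frame(theta = res$pvalues$theta, maf = res$pvalues$maf)
    res$mean_fst <- mean_fst_comparison(
      target, res$null$table, n_resample = config$n_resample,
      maf_bin_width = config$maf_bin_width, seed = config$seed + 2L)
  })

  # -- geography --------------------------------------------------------
  stage("geography", {
    say("isolation-by-distance regression")
    wp <- if (is.null(config$waypoints)) default_waypoints()
          else read_waypoints(config$waypoints)
    res$distances <- population_distances(res$dataset$panel, wp)
    res$ibd <- ibd_regression(res$fst$population, res$distances)
    emit(res$ibd, "ibd_regression.tsv")
  })

  # -- summary ----------------------------------------------------------
  stage("summary", {
    adj_b <- multiple_testing(res$pvalues$p_value, "bonferroni", config$alpha)
    adj_f <- multiple_testing(res$pvalues$p_value, "BH", config$alpha)
    raf_global <- rowMeans(res$freq$raf, na.rm = TRUE)
    sig <- res$pvalues$significant & res$pvalues$significant_cor
    meta_idx <- match(res$pvalues$snp, res$snp_table$snp)
    res$significant <- data.frame(
      snp = res$pvalues$snp,
      trait = res$snp_table$trait[meta_idx],
      gene = res$snp_table$gene[meta_idx],
      raf = unname(raf_global[res$pvalues$snp]),
      global_fst = res$pvalues$theta,
      p_value = res$pvalues$p_value,
      p_cor = res$pvalues$p_cor,
      p_bonferroni = adj_b$adjusted,
      p_bh = adj_f$adjusted,
      stringsAsFactors = FALSE)[sig, , drop = FALSE]
    emit(res$significant, "significant_snps.tsv")

    pooled <- res$ibd[res$ibd$snp == "pooled", ]
    res$summary <- data.frame(
      metric = c("n_snps", "n_populations", "n_regions",
                 "n_fixed_any", "n_missed_any",
                 "n_large_delta_f", "pct_large_delta_f", "max_abs_delta_f",
                 "mean_global_fst", "mean_fst_comparison_p",
                 "n_significant_fst", "null_fst_p95", "null_fst_p99",
                 "pooled_ibd_slope", "pooled_ibd_r_squared"),
      value = c(nrow(res$freq$raf), ncol(res$freq$raf),
                ncol(res$freq$region_raf),
                res$extremes$n_fixed, res$extremes$n_missed,
                res$large_delta$n_large, res$large_delta$percent,
                max(abs(res$delta$delta_f), na.rm = TRUE),
                mean_global_fst(res$fst$global), res$mean_fst$p_value,
                nrow(res$significant),
                unname(res$null$percentiles[1]), unname(res$null$percentiles[2]),
                pooled$slope, pooled$r_squared),
      stringsAsFactors = FALSE)
    emit(res$summary, "summary.tsv")
  })

  say("done; outputs in ", outdir)
  invisible(res)
}

config_to_yamlable <- function(config) {
  out <- unclass(config)
  out[!vapply(out, is.null, logical(1))]
}
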