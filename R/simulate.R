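#' Simulation configuration
#'
#' Parameters of the hierarchical Balding-Nichols genotype simulator. The
#' shipped defaults emulate the structure of the HGDP study system: seven
#' continental regions with a few populations each, per-population sample
#' sizes in the tens, region-level drift around 0.10 and population-level
#' drift around 0.05 (so total expected differentiation
#' `f_region + f_pop - f_region * f_pop` is about 0.145), a large neutral
#' SNP panel of 2036 markers, and an optional handful of artificially
#' over-differentiated (outlier) SNPs whose region-level drift is multiplied
#' by `outlier_boost`.
#'
#' @param n_regions number of geographic regions (default 7).
#' @param pops_per_region populations per region; scalar or vector of length
#'   `n_regions`.
#' @param samples_per_pop individuals per population; scalar or one value per
#'   population.
#' @param n_snps number of target (risk) SNPs.
#' @param n_neutral_snps size of the neutral panel (default 2036).
#' @param f_region Balding-Nichols drift between the ancestral and region
#'   frequencies, in (0, 1).
#' @param f_pop drift between region and population frequencies, in (0, 1).
#' @param ancestral_freq ancestral allele-frequency distribution: either
#'   `list(dist = "uniform", min, max)` (default Uniform(0.05, 0.95)) or
#'   `list(dist = "beta", shape1, shape2)`.
#' @param n_outlier_snps number of target SNPs given boosted regional drift.
#' @param outlier_boost multiplier on `f_region` for outlier SNPs
#'   (`outlier_boost * f_region` must stay below 1).
#' @param regional_model `"hierarchical"` (regions drawn independently around
#'   the ancestral frequency; exchangeable regions) or `"serial"` (each
#'   region drifts from the previous one along the configured region order,
#'   a serial-founder chain that produces isolation by distance).
#' @param seed integer RNG seed (mandatory; the simulator is deterministic
#'   given the config).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_regions = 7, pops_per_region = 4, samples_per_pop = 20,
                       n_snps = 200, n_neutral_snps = 2036,
                       f_region = 0.10, f_pop = 0.05,
                       ancestral_freq = list(dist = "uniform", min = 0.05, max = 0.95),
                       n_outlier_snps = 0, outlier_boost = 1,
                       regional_model = c("hierarchical", "serial"),
                       seed = 1L) {
  regional_model <- match.arg(regional_model)
  check_scalar_number(n_regions, "n_regions", 1)
  check_scalar_number(n_snps, "n_snps", 1)
  check_scalar_number(n_neutral_snps, "n_neutral_snps", 1)
  check_scalar_number(f_region, "f_region")
  check_scalar_number(f_pop, "f_pop")
  check_scalar_number(outlier_boost, "outlier_boost", 0)
  check_scalar_number(seed, "seed")
  if (f_region <= 0 || f_region >= 1) stop_gd("'f_region' must be in (0, 1)")
  if (f_pop <= 0 || f_pop >= 1) stop_gd("'f_pop' must be in (0, 1)")
  if (outlier_boost * f_region >= 1)
    stop_gd("'outlier_boost' * 'f_region' must be < 1")
  if (n_outlier_snps > n_snps)
    stop_gd("'n_outlier_snps' cannot exceed 'n_snps'")
  if (length(pops_per_region) == 1L)
    pops_per_region <- rep(pops_per_region, n_regions)
  if (length(pops_per_region) != n_regions)
    stop_gd("'pops_per_region' must be scalar or length n_regions")
  if (any(pops_per_region < 1)) stop_gd("'pops_per_region' must be >= 1")
  n_pops <- sum(pops_per_region)
  if (length(samples_per_pop) == 1L)
    samples_per_pop <- rep(samples_per_pop, n_pops)
  if (length(samples_per_pop) != n_pops)
    stop_gd("'samples_per_pop' must be scalar or one value per population")
  if (any(samples_per_pop < 1)) stop_gd("'samples_per_pop' must be >= 1")
  if (!ancestral_freq$dist %in% c("uniform", "beta"))
    stop_gd("'ancestral_freq$dist' must be \"uniform\" or \"beta\"")
  structure(list(n_regions = as.integer(n_regions),
                 pops_per_region = as.integer(pops_per_region),
                 samples_per_pop = as.integer(samples_per_pop),
                 n_snps = as.integer(n_snps),
                 n_neutral_snps = as.integer(n_neutral_snps),
                 f_region = f_region, f_pop = f_pop,
                 ancestral_freq = ancestral_freq,
                 n_outlier_snps = as.integer(n_outlier_snps),
                 outlier_boost = outlier_boost,
                 regional_model = regional_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# rough continental anchor coordinates for the seven default regions,
# ordered along the classic out-of-Africa expansion chain
sim_region_centers <- function(region_names) {
  anchors <- rbind(Africa = c(2, 20), Middle_East = c(33, 44),
                   Europe = c(48, 10), Central_South_Asia = c(28, 72),
                   East_Asia = c(33, 108), Oceania = c(-6, 147),
                   America = c(-10, -60))
  out <- matrix(NA_real_, length(region_names), 2,
                dimnames = list(region_names, c("lat", "lon")))
  known <- intersect(region_names, rownames(anchors))
  out[known, ] <- anchors[known, ]
  extra <- setdiff(region_names, rownames(anchors))
  if (length(extra)) {
    out[extra, 1] <- stats::runif(length(extra), -45, 55)
    out[extra, 2] <- stats::runif(length(extra), -170, 170)
  }
  out
}

sim_panel <- function(cfg) {
  region_names <- if (cfg$n_regions <= 7L) default_regions()[seq_len(cfg$n_regions)]
                  else c(default_regions(), paste0("Region_", 8:cfg$n_regions))
  centers <- sim_region_centers(region_names)
  pop_names <- character(0); pop_region <- character(0)
  lat <- numeric(0); lon <- numeric(0)
  for (r in seq_len(cfg$n_regions)) {
    k <- cfg$pops_per_region[r]
    nm <- paste0(region_names[r], "_p", seq_len(k))
    pop_names <- c(pop_names, nm)
    pop_region <- c(pop_region, rep(region_names[r], k))
    lat <- c(lat, pmin(89, pmax(-89, centers[r, 1] + stats::runif(k, -8, 8))))
    lon <- c(lon, pmin(179, pmax(-179, centers[r, 2] + stats::runif(k, -8, 8))))
  }
  n <- cfg$samples_per_pop
  df <- data.frame(sample = sprintf("ind%05d", seq_len(sum(n))),
                   population = rep(pop_names, times = n),
                   region = rep(pop_region, times = n),
                   lat = rep(lat, times = n),
                   lon = rep(lon, times = n),
                   stringsAsFactors = FALSE)
  as_pop_panel(df, regions = region_names)
}

draw_ancestral <- function(n, spec) {
  draw <- function(k) switch(spec$dist,
    uniform = stats::runif(k, spec$min, spec$max),
    beta = stats::rbeta(k, spec$shape1, spec$shape2))
  p <- draw(n)
  bad <- p <= 0 | p >= 1            # monomorphic ancestral draws rejected
  tries <- 0L
  while (any(bad) && tries < 50L) {
    p[bad] <- draw(sum(bad))
    bad <- p <= 0 | p >= 1
    tries <- tries + 1L
  }
  if (any(bad)) stop_gd("could not draw polymorphic ancestral frequencies")
  p
}

# Balding-Nichols draw: Beta(p (1-F)/F, (1-p) (1-F)/F) around p, clamped
# away from exact fixation so downstream Beta draws stay defined
bn_draw <- function(p, F) {
  eps <- 1e-12
  q <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pmin(pmax(q, eps), 1 - eps)
}

sim_genotypes <- function(cfg, panel, n_snps, id_prefix, f_region_snp) {
  n_pops <- length(panel_populations(panel))
  pop_region_map <- panel_pop_region(panel)
  region_names <- unique(unname(pop_region_map))

  p_anc <- draw_ancestral(n_snps, cfg$ancestral_freq)
  p_region <- matrix(NA_real_, n_snps, cfg$n_regions,
                     dimnames = list(NULL, region_names))
  if (cfg$regional_model == "hierarchical") {
    for (r in seq_len(cfg$n_regions))
      p_region[, r] <- bn_draw(p_anc, f_region_snp)
  } else {
    p_region[, 1] <- bn_draw(p_anc, f_region_snp)
    for (r in seq_len(cfg$n_regions)[-1])
      p_region[, r] <- bn_draw(p_region[, r - 1], f_region_snp)
  }
  pops <- panel_populations(panel)
  p_pop <- matrix(NA_real_, n_snps, n_pops, dimnames = list(NULL, pops))
  for (k in seq_len(n_pops))
    p_pop[, k] <- bn_draw(p_region[, pop_region_map[pops[k]]],
                          rep(cfg$f_pop, n_snps))
  snp_ids <- sprintf("%s%05d", id_prefix, seq_len(n_snps))
  calls <- matrix(NA_integer_, n_snps, nrow(panel),
                  dimnames = list(snp_ids, panel$sample))
  for (k in seq_len(n_pops)) {
    cols <- which(panel$population == pops[k])
    calls[, cols] <- stats::rbinom(n_snps * length(cols), 2L, p_pop[, k])
  }
  rownames(p_region) <- snp_ids
  rownames(p_pop) <- snp_ids
  list(ds = geno_dataset(calls, rep("A", n_snps), rep("G", n_snps), panel),
       p_anc = stats::setNames(p_anc, snp_ids),
       p_region = p_region, p_pop = p_pop)
}

#' Simulate a hierarchically structured genotype dataset
#'
#' Hierarchical Balding-Nichols sampling: an ancestral frequency per SNP,
#' region frequencies drifted from it with `f_region` (boosted for outlier
#' SNPs), population frequencies drifted from their region with `f_pop`, and
#' Hardy-Weinberg genotypes `Binomial(2, p_pop)`. The risk allele is allele A
#' for every simulated SNP. Deterministic for a fixed config (seed included).
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a `geno_dataset`), `snp_table` (a
#'   `risk_snp_table`), and `truth` (ancestral/region/population frequencies,
#'   outlier flags, and the config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panel <- sim_panel(cfg)
  outlier <- rep(FALSE, cfg$n_snps)
  if (cfg$n_outlier_snps > 0)
    outlier[sample.int(cfg$n_snps, cfg$n_outlier_snps)] <- TRUE
  f_snp <- ifelse(outlier, cfg$f_region * cfg$outlier_boost, cfg$f_region)
  sim <- sim_genotypes(cfg, panel, cfg$n_snps, "snp", f_snp)
  snp_ids <- rownames(sim$ds$calls)
  snp_table <- as_risk_snp_table(data.frame(
    snp = snp_ids,
    risk_allele = "A",
    trait = "synthetic_trait",
    gene = sprintf("GENE%05d", seq_len(cfg$n_snps)),
    ancestral_allele = sample(c("A", "G"), cfg$n_snps, replace = TRUE),
    stringsAsFactors = FALSE))
  names(outlier) <- snp_ids
  list(dataset = sim$ds, snp_table = snp_table,
       truth = list(p_anc = sim$p_anc, p_region = sim$p_region,
                    p_pop = sim$p_pop, outlier = outlier, config = cfg))
}

#' Simulate a neutral SNP panel on the same individuals
#'
#' Same hierarchical model and the same population panel (so null and target
#' SNPs are measured on identical individuals), no outlier boost. Uses a
#' derived seed (`seed + 1`) so that the neutral draw is independent of, but
#' reproducibly tied to, the paired [simulate_dataset()] call.
#'
#' @param cfg a [sim_config()] with `n_neutral_snps >= 100`.
#' @param dataset optional result of `simulate_dataset(cfg)$dataset`; when
#'   omitted the panel is rebuilt deterministically from the config.
#' @return list with `dataset` (the neutral `geno_dataset`) and `truth`.
#' @export
simulate_neutral_panel <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_neutral_snps < 100L)
    stop_gd("'n_neutral_snps' must be >= 100 for a usable empirical null")
  if (is.null(dataset)) {
    set.seed(cfg$seed)
    panel <- sim_panel(cfg)
  } else {
    panel <- dataset$panel
  }
  set.seed(cfg$seed + 1L)
  sim <- sim_genotypes(cfg, panel, cfg$n_neutral_snps, "neut",
                       rep(cfg$f_region, cfg$n_neutral_snps))
  list(dataset = sim$ds,
       truth = list(p_anc = sim$p_anc, p_region = sim$p_region,
                    p_pop = sim$p_pop, config = cfg))
}
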