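Package: geodiffr
Title: Geographic Differentiation of GWAS Risk Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for geographic differentiation of disease risk
    alleles across hierarchically structured populations. Computes risk-allele
    frequencies per population and geographic region, the in-region versus
    out-of-region frequency contrast (delta-F) with a permutation null,
    Weir-Cockerham F_ST at global, regional and pairwise scales, empirical
    outlier significance against a frequency-matched neutral SNP panel,
    frequency-matched mean-F_ST resampling comparisons, and the regression of
    pairwise F_ST on waypoint-routed great-circle distance. Includes a
    Balding-Nichols simulator of hierarchically structured genotype data so the
    full pipeline is testable end to end without external genotype resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
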