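Package: tempodrift
Title: Spatiotemporal SNP Population Genomics and Temporal Outlier Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatiotemporal population-genomic analysis of diploid
    biallelic SNP genotypes: quality control (call-rate and replicate-
    concordance filters), classical summary and differentiation statistics
    (heterozygosity, Hardy-Weinberg Monte-Carlo tests, composite linkage-
    disequilibrium r2 and pruning, Weir-Cockerham FST, summed chi-square
    allele-frequency tests, Storey q-values), discriminant analysis of
    principal components (DAPC) with K-means/BIC cluster selection and
    hold-out cross-validation, and a temporal outlier test that contrasts
    per-locus temporal differentiation against a Wright-Fisher drift null
    conditioned on heterozygosity, together with temporal-method estimation
    of effective population size. Includes a synthetic-data generator that
    emulates a multi-cluster, two-era sampling design for power and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
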