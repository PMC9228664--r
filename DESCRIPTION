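Package: ratiogwas
Title: Ratio-Phenotype Metabolite GWAS with the P-Gain Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis of metabolite panels with a high
    degree of missingness using pairwise log-ratio phenotypes and the p-gain
    statistic. Provides variant quality control (minor allele frequency, call
    rate, Hardy-Weinberg exact test), LD pruning, genomic principal components
    and a genomic relationship matrix; ordinary least squares and one-component
    mixed-model association with covariates; trait-wide Bonferroni and p-gain
    significance thresholds; greedy clumping of suggestive associations into
    independent loci with nearest-gene and candidate-gene annotation; and a
    seeded synthetic cohort generator that plants pathway-style genetic effect
    archetypes (branch partition, conversion step, shared dilution) together
    with run-day batch structure and limit-of-detection missingness, so the
    whole pipeline is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
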