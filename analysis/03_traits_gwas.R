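#!/usr/bin/env Rscript
# Stage 3: sample inclusion, trait construction, association scan.
#
# Samples need >= 5 of the 9 metabolites detected. Traits are the 9 log
# abundances plus all 36 pairwise log-ratios (45 in total); each trait is
# analyzed on its own complete cases. Association is OLS of the trait on
# allele dosage with age, sex and 10 genomic PCs as covariates.

suppressPackageStartupMessages({
  library(ratiogwas)
  library(data.table)
})

dir.create("results/gwas", showWarnings = FALSE, recursive = TRUE)

genotypes <- read_vcf("results/cohort/genotypes.vcf")
filtered <- filter_variants(genotypes)
panel <- read_metabolites("results/cohort/metabolites.tsv")
covar_raw <- read_covariates("results/cohort/covariates.tsv")
pcs_df <- fread("results/qc/pcs.tsv", data.table = FALSE)
pcs <- as.matrix(pcs_df[, -1L])
rownames(pcs) <- pcs_df$sample

included <- select_samples(panel, min_detected = 5L)
cat("included samples:", length(included), "of", nrow(panel$abundances), "\n")

covar <- assemble_covariates(covar_raw, pcs)
samples <- Reduce(intersect, list(included, genotypes$sample_ids,
                                  rownames(covar)))
traits <- build_traits(panel, samples)
print(traits)

results <- run_gwas(traits, filtered, covar[samples, , drop = FALSE])
cat("association rows:", nrow(results),
    " untestable:", attr(results, "untestable"), "\n")
write_sumstats(results, "results/gwas/sumstats.tsv")
fwrite(traits$info, "results/gwas/trait_info.tsv", sep = "\t", quote = FALSE)
cat("strongest association:\n")
print(results[which.min(results$p), ])
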