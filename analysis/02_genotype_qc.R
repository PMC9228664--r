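#!/usr/bin/env Rscript
# Stage 2: variant QC, LD pruning, principal components, relationship matrix.
#
# Filters follow standard WGS association practice: drop variants with
# MAF < 5%, call rate < 90%, Hardy-Weinberg exact p < 1e-6, non-autosomal
# variants and indels (strict violations only, boundary values survive).
# The surviving set is LD-pruned at r^2 = 0.5 and used for the genomic PCs
# and the relationship matrix.

suppressPackageStartupMessages({
  library(ratiogwas)
  library(data.table)
})

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

genotypes <- read_vcf("results/cohort/genotypes.vcf")
stats <- compute_variant_stats(genotypes)
fwrite(stats, "results/qc/variant_stats.tsv", sep = "\t", quote = FALSE)

filtered <- filter_variants(genotypes)
cat("variants in:", ncol(genotypes$dosages),
    " after QC:", ncol(filtered$dosages), "\n")
cat("removed per criterion:\n")
print(attr(filtered, "removed"))

pruned_idx <- ld_prune(filtered, r2_max = 0.5)
pruned <- genotype_matrix(filtered$dosages[, pruned_idx, drop = FALSE],
                          filtered$variants[pruned_idx, , drop = FALSE])
cat("pruned independent set:", length(pruned_idx), "variants\n")
fwrite(data.frame(id = pruned$variants$id), "results/qc/pruned_set.tsv",
       sep = "\t", quote = FALSE)

pcs <- compute_pcs(pruned, k = 10L)
fwrite(data.frame(sample = rownames(pcs), pcs), "results/qc/pcs.tsv",
       sep = "\t", quote = FALSE)

grm <- compute_grm(pruned)
cat("GRM over", grm$n_variants_used, "variants; mean diagonal",
    round(mean(diag(grm$values)), 3), "\n")
fwrite(as.data.frame(grm$values), "results/qc/grm.tsv", sep = "\t",
       quote = FALSE)
writeLines(rownames(grm$values), "results/qc/grm_ids.txt")
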