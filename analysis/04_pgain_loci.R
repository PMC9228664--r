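#!/usr/bin/env Rscript
# Stage 4: p-gain classification, suggestive screen, clumping, annotation.
#
# Thresholds for T = 45 traits: genome- and trait-wide significance at
# p < 5e-8/45 = 1.1e-9 and ratio-specific significance at p-gain > 450;
# the suggestive screen keeps p < 1e-5. Suggestive hits are clumped per
# trait into independent loci (r^2 < 0.1), annotated with the nearest gene
# of the toy track, and cross-referenced against the candidate pathway
# genes planted by stage 1.

suppressPackageStartupMessages({
  library(ratiogwas)
  library(data.table)
})

dir.create("results/loci", showWarnings = FALSE, recursive = TRUE)

genotypes <- read_vcf("results/cohort/genotypes.vcf")
filtered <- filter_variants(genotypes)
genes <- read_bed_genes("results/cohort/genes.bed")
results <- fread("results/gwas/sumstats.tsv", data.table = FALSE)
trait_info <- fread("results/gwas/trait_info.tsv", data.table = FALSE)
trait_info$denominator[trait_info$denominator == ""] <- NA_character_

thresholds <- compute_thresholds(nrow(trait_info))
cat(sprintf("T = %d traits: p_bonf = %.3g, pgain_bonf = %g\n",
            thresholds$n_traits, thresholds$p_bonf, thresholds$pgain_bonf))

classified <- classify_associations(results, trait_info, thresholds)
write_pgain(classified, "results/loci/pgain.tsv")
cat("ratio associations significant on both criteria:",
    sum(classified$bonferroni_significant & classified$pgain_significant,
        na.rm = TRUE), "\n")

sugg <- results[!is.na(results$p) & results$p < thresholds$suggestive_p, ]
loci <- list()
for (tr in unique(sugg$trait)) {
  hits <- sugg[sugg$trait == tr, , drop = FALSE]
  pg <- classified[classified$trait == tr, c("variant", "pgain")]
  hits$pgain <- pg$pgain[match(hits$variant, pg$variant)]
  loci <- c(loci, clump_loci(hits, filtered, r2_independence = 0.1))
}
loci <- lapply(loci, nearest_gene, genes = genes)
loci <- candidate_crossref(loci, c("UGT_LIKE", "COMT_LIKE"))
ltab <- loci_table(loci)
fwrite(ltab, "results/loci/loci.tsv", sep = "\t", quote = FALSE)

cat(nrow(sugg), "suggestive associations at", nrow(ltab),
    "per-trait loci;", sum(ltab$candidate_gene_hit),
    "at candidate pathway genes\n")
print(ltab[ltab$candidate_gene_hit,
           c("index_variant", "trait", "p", "pgain", "nearest_genes")])
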