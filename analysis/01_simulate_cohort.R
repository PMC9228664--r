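#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 520 samples, the nine-metabolite acetaminophen panel with
# limit-of-detection missingness matching its observed detection fractions,
# run-day batch structure, and two planted pathway effects:
#   - a branch (glucuronidation vs sulfation partition) effect on the
#     canonical phase-II pair, tagged by a gene named UGT-like;
#   - a conversion (methylation product vs substrate) effect on the
#     methoxy/hydroxy sulfate pair, tagged by a gene named COMT-like.
# Variants come in 5-variant LD blocks so pruning and clumping have work to
# do. Everything is deterministic under the seed below.

suppressPackageStartupMessages(library(ratiogwas))

seed <- 1L
out_dir <- "results/cohort"

cfg <- sim_config(
  n_samples = 520L, n_variants = 60L, maf = 0.3, seed = seed,
  ld_block_size = 5L, ld_copy_prob = 0.9,
  effect_plan = list(
    planted_effect(11L, "branch",
                   c("4-acetamidophenyl glucuronide",
                     "4-acetaminophen sulfate"), 0.4),
    planted_effect(41L, "conversion",
                   c("2-methoxyacetaminophen sulfate",
                     "2-hydroxyacetaminophen sulfate"), 0.4)
  )
)
cohort <- simulate_cohort(cfg, gene_names = c("UGT_LIKE", "COMT_LIKE"))
paths <- write_cohort(cohort, out_dir)

cat("samples:", cfg$n_samples, " variants:", cfg$n_variants, "\n")
cat("detected per metabolite:\n")
print(colSums(cohort$panel$detected))
cat("files written:\n")
print(paths)
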