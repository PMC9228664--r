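#' Pipeline configuration
#'
#' All stage parameters of the ratio-GWAS pipeline with their standard
#' defaults: sample inclusion at >= 5 detected metabolites; variant QC at
#' MAF >= 0.05, call rate >= 0.90, Hardy-Weinberg exact p >= 1e-6,
#' autosomes only, indels removed; LD pruning at r^2 = 0.5 (window 50,
#' step 5) for principal components and the relationship matrix; 10 PCs as
#' covariates; OLS association engine (LMM optional); suggestive screen at
#' p < 1e-5; locus independence at r^2 < 0.1.
#'
#' Inputs are either file paths (`vcf`, `metabolites`, `covariates`,
#' `genes`) or a `simulate` list of [sim_config()] arguments, in which case
#' the cohort is generated and written under the output directory.
#'
#' @param vcf,metabolites,covariates,genes Input file paths (ignored when
#'   `simulate` is given).
#' @param simulate `NULL`, or a list of arguments for [sim_config()].
#' @param outdir Output directory.
#' @param min_detected,maf_min,call_rate_min,hwe_p_min,prune_r2,
#'   prune_window,prune_step,n_pcs,engine,suggestive_p,clump_r2 Stage
#'   parameters (see above).
#' @param candidate_genes Character vector of pathway candidate gene names.
#' @param seed Integer seed controlling simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, metabolites = NULL,
                            covariates = NULL, genes = NULL,
                            simulate = NULL, outdir = "ratiogwas_out",
                            min_detected = 5L, maf_min = 0.05,
                            call_rate_min = 0.90, hwe_p_min = 1e-6,
                            prune_r2 = 0.5, prune_window = 50L,
                            prune_step = 5L, n_pcs = 10L,
                            engine = c("ols", "lmm"),
                            suggestive_p = 1e-5, clump_r2 = 0.1,
                            candidate_genes = character(), seed = 1L) {
  engine <- match.arg(engine)
  structure(
    list(vcf = vcf, metabolites = metabolites, covariates = covariates,
         genes = genes, simulate = simulate, outdir = outdir,
         min_detected = as.integer(min_detected), maf_min = maf_min,
         call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
         prune_r2 = prune_r2, prune_window = as.integer(prune_window),
         prune_step = as.integer(prune_step), n_pcs = as.integer(n_pcs),
         engine = engine, suggestive_p = suggestive_p, clump_r2 = clump_r2,
         candidate_genes = as.character(candidate_genes),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; a `simulate`
#' mapping mirrors [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full ratio-GWAS pipeline
#'
#' Executes (optional) simulation, variant QC, trait construction,
#' association, p-gain classification, clumping and annotation, and writes
#' the result tables plus a provenance manifest under `config$outdir`:
#' `variant_stats.tsv`, `inclusion.tsv`, `sumstats.tsv`, `pgain.tsv`,
#' `loci.tsv`, a `summary.tsv` of candidate-pathway loci (locus gene,
#' trait, variant, chromosome, position, MAF, beta, p, p-gain) and
#' `manifest.yaml` (parameters, seed, package version, input checksums) —
#' the manifest alone suffices to rerun the pipeline identically. A stage
#' failure halts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`genotypes`,
#'   `stats`, `filtered`, `pcs`, `traits`, `results`, `classified`, `loci`,
#'   `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- stage("simulate", {
      sc <- do.call(sim_config, sim_args)
      simulate_cohort(sc)
    })
    in_dir <- file.path(config$outdir, "inputs")
    paths_in <- write_cohort(cohort, in_dir)
    config$vcf <- unname(paths_in["vcf"])
    config$metabolites <- unname(paths_in["metabolites"])
    config$covariates <- unname(paths_in["covariates"])
    config$genes <- unname(paths_in["genes"])
  }

  genotypes <- stage("read_vcf", read_vcf(config$vcf))
  panel <- stage("read_metabolites", read_metabolites(config$metabolites))
  covar_raw <- stage("read_covariates", read_covariates(config$covariates))
  genes <- stage("read_genes", {
    if (grepl("\\.gff3?$", config$genes, ignore.case = TRUE))
      read_gff3_genes(config$genes)
    else read_bed_genes(config$genes)
  })

  stats <- stage("variant_stats", compute_variant_stats(genotypes))
  filtered <- stage("filter_variants",
                    filter_variants(genotypes, config$maf_min,
                                    config$call_rate_min, config$hwe_p_min,
                                    stats = stats))
  pruned_idx <- stage("ld_prune",
                      ld_prune(filtered, config$prune_r2,
                               config$prune_window, config$prune_step))
  pruned <- genotype_matrix(filtered$dosages[, pruned_idx, drop = FALSE],
                            filtered$variants[pruned_idx, , drop = FALSE])
  pcs <- stage("compute_pcs", compute_pcs(pruned, config$n_pcs))
  grm <- if (config$engine == "lmm")
    stage("compute_grm", compute_grm(pruned)) else NULL

  included <- stage("select_samples",
                    select_samples(panel, config$min_detected))
  covar <- stage("assemble_covariates", assemble_covariates(covar_raw, pcs))
  samples <- Reduce(intersect, list(included, genotypes$sample_ids,
                                    rownames(covar)))
  traits <- stage("build_traits", build_traits(panel, samples))

  results <- stage("run_gwas",
                   run_gwas(traits, filtered, covar[samples, , drop = FALSE],
                            engine = config$engine, grm = grm))

  thresholds <- compute_thresholds(ncol(traits$values), config$suggestive_p)
  classified <- stage("classify",
                      classify_associations(results, traits$info, thresholds))

  # suggestive screen over all traits; clump per trait, pgain joined for ratios
  sugg <- results[!is.na(results$p) & results$p < config$suggestive_p, ,
                  drop = FALSE]
  loci <- stage("clump", {
    out <- list()
    for (tr in unique(sugg$trait)) {
      hits <- sugg[sugg$trait == tr, , drop = FALSE]
      pg <- classified[classified$trait == tr, c("variant", "pgain")]
      hits$pgain <- pg$pgain[match(hits$variant, pg$variant)]
      out <- c(out, clump_loci(hits, filtered, config$clump_r2))
    }
    out
  })
  loci <- stage("annotate", {
    loci <- lapply(loci, nearest_gene, genes = genes)
    candidate_crossref(loci, config$candidate_genes)
  })
  ltab <- loci_table(loci)

  # independent loci across traits: clump the union of index variants
  n_indep <- if (nrow(ltab) > 0L) {
    uniq <- ltab[!duplicated(ltab$index_variant), , drop = FALSE]
    length(clump_loci(data.frame(variant = uniq$index_variant,
                                 chrom = uniq$chrom, pos = uniq$pos,
                                 p = uniq$p),
                      filtered, config$clump_r2))
  } else 0L

  summary_tab <- if (nrow(ltab) > 0L) {
    cand <- ltab[!is.na(ltab$candidate_gene_hit) & ltab$candidate_gene_hit, ,
                 drop = FALSE]
    show <- if (nrow(cand) > 0L) cand else ltab
    maf <- stats$maf[match(show$index_variant, stats$id)]
    beta <- results$beta[match(paste(show$trait, show$index_variant),
                               paste(results$trait, results$variant))]
    data.frame(locus = show$nearest_genes, trait = show$trait,
               variant = show$index_variant, chrom = show$chrom,
               pos = show$pos, maf = maf, beta = beta, p = show$p,
               pgain = show$pgain, stringsAsFactors = FALSE)
  } else data.frame(locus = character(), trait = character(),
                    variant = character(), chrom = character(),
                    pos = integer(), maf = numeric(), beta = numeric(),
                    p = numeric(), pgain = numeric(),
                    stringsAsFactors = FALSE)

  paths <- c(
    variant_stats = file.path(config$outdir, "variant_stats.tsv"),
    inclusion = file.path(config$outdir, "inclusion.tsv"),
    sumstats = file.path(config$outdir, "sumstats.tsv"),
    pgain = file.path(config$outdir, "pgain.tsv"),
    loci = file.path(config$outdir, "loci.tsv"),
    summary = file.path(config$outdir, "summary.tsv"),
    manifest = file.path(config$outdir, "manifest.yaml")
  )
  data.table::fwrite(stats, paths["variant_stats"], sep = "\t", quote = FALSE)
  incl <- data.frame(sample = rownames(panel$abundances),
                     n_detected = rowSums(panel$detected),
                     included = rownames(panel$abundances) %in% samples)
  data.table::fwrite(incl, paths["inclusion"], sep = "\t", quote = FALSE)
  write_sumstats(results, paths["sumstats"])
  write_pgain(classified, paths["pgain"])
  data.table::fwrite(ltab, paths["loci"], sep = "\t", quote = FALSE)
  data.table::fwrite(summary_tab, paths["summary"], sep = "\t", quote = FALSE)

  manifest <- list(
    package = "ratiogwas",
    version = as.character(utils::packageVersion("ratiogwas")),
    parameters = config[c("min_detected", "maf_min", "call_rate_min",
                          "hwe_p_min", "prune_r2", "prune_window",
                          "prune_step", "n_pcs", "engine", "suggestive_p",
                          "clump_r2", "seed")],
    simulate = config$simulate,
    candidate_genes = config$candidate_genes,
    inputs = lapply(config[c("vcf", "metabolites", "covariates", "genes")],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    counts = list(
      samples_included = length(samples),
      variants_input = ncol(genotypes$dosages),
      variants_after_qc = ncol(filtered$dosages),
      variants_pruned_set = length(pruned_idx),
      traits = ncol(traits$values),
      untestable_pairs = attr(results, "untestable"),
      suggestive_associations = nrow(sugg),
      loci_per_trait = nrow(ltab),
      independent_loci = n_indep
    )
  )
  yaml::write_yaml(manifest, paths["manifest"])

  invisible(list(genotypes = genotypes, panel = panel, stats = stats,
                 filtered = filtered, pruned = pruned, pcs = pcs, grm = grm,
                 traits = traits, covariates = covar, results = results,
                 thresholds = thresholds, classified = classified,
                 loci = loci, loci_table = ltab, summary = summary_tab,
                 n_independent_loci = n_indep, paths = paths))
}

#' Demo configuration: a small simulated cohort, end to end
#'
#' A compact configuration whose simulated cohort carries one branch effect
#' (glucuronide vs sulfate partition, the UGT-style archetype) and one
#' conversion effect (methylation product vs substrate, the COMT-style
#' archetype), LD blocks to exercise pruning and clumping, and the panel's
#' limit-of-detection missingness. Runs in well under a minute.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param engine Association engine, `"ols"` or `"lmm"`.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(outdir = tempfile("ratiogwas_demo_"), seed = 1L,
                        engine = "ols") {
  panel <- acetaminophen_panel()
  pipeline_config(
    simulate = list(
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
    ),
    outdir = outdir, seed = seed, engine = engine,
    candidate_genes = c("EFFECT_GENE_1", "EFFECT_GENE_2")
  )
}
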