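#' Metadata for the nine-metabolite acetaminophen panel
#'
#' Descriptors of the nine acetaminophen metabolites used as the default
#' synthetic panel: compound name, CAS registry number, LC/MS mode,
#' retention index, monoisotopic mass, and the fraction of a 520-sample
#' cohort in which each metabolite is typically detected. The detection
#' fractions drive the default limit-of-detection censoring of the
#' generator, so synthetic cohorts reproduce the missingness profile of a
#' real non-targeted LC-MS drug-metabolite panel.
#'
#' @return A `data.frame` with columns `name`, `cas`, `lcms_mode`,
#'   `retention_index`, `mass`, `detection_fraction`.
#' @export
acetaminophen_panel <- function() {
  data.frame(
    name = c(
      "4-acetamidophenol",
      "4-acetamidophenyl glucuronide",
      "2-methoxyacetaminophen glucuronide",
      "2-hydroxyacetaminophen sulfate",
      "2-methoxyacetaminophen sulfate",
      "4-acetaminophen sulfate",
      "3-(N-acetyl-L-cystein-S-yl) acetaminophen",
      "3-(methylthio) acetaminophen sulfate",
      "3-(cystein-S-yl) acetaminophen"
    ),
    cas = c("103-90-2", "120595-80-4", "53446-12-1", "53446-14-3",
            "53446-13-2", "10066-90-7", "52372-86-8", "78194-51-1",
            "53446-10-9"),
    lcms_mode = c("Neg", "Neg", "Neg", "Neg", "Neg", "Neg", "Neg", "Neg",
                  "Pos Early"),
    retention_index = c(2173.7, 1400, 1633, 1674, 1949, 1792, 2094, 2265,
                        2420),
    mass = c(150.05605, 326.08814, 356.0987, 246.00778, 260.02343,
             230.01287, 311.07072, 276.00059, 271.07471),
    detection_fraction = c(497, 510, 416, 497, 405, 514, 363, 475, 363) / 520,
    stringsAsFactors = FALSE
  )
}

#' Describe a genetic effect to plant in a synthetic cohort
#'
#' A planted effect ties one simulated variant to the log-abundance model of
#' one or more metabolites with a per-allele effect `beta` on the natural-log
#' scale. Four archetypes are supported:
#' \describe{
#'   \item{`direct`}{`+beta` per alternate allele on one metabolite.}
#'   \item{`branch`}{a partition shift between two competing products of the
#'     same precursor (e.g. glucuronidation vs sulfation): `+beta` on the
#'     first target, `-beta` on the second, per allele. The induced per-allele
#'     effect on the pairwise log-ratio is `2*beta`.}
#'   \item{`conversion`}{an enzymatic conversion step: `+beta` on the product
#'     (first target), `-beta` on the substrate (second target).}
#'   \item{`dilution`}{the same `+beta` per allele on every metabolite of a
#'     sample, emulating a genotype-dependent shared factor (dose, excretion);
#'     it cancels exactly in every pairwise log-ratio.}
#' }
#'
#' @param variant_index Column index of the variant in the simulated
#'   genotype matrix.
#' @param kind One of `"direct"`, `"branch"`, `"conversion"`, `"dilution"`.
#' @param targets Character vector of metabolite names: exactly one for
#'   `direct`, exactly two for `branch`/`conversion` (signed as described
#'   above), none for `dilution` (all metabolites are affected).
#' @param beta Per-allele effect on the natural-log abundance scale.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(variant_index, kind, targets = character(), beta) {
  kind <- match.arg(kind, c("direct", "branch", "conversion", "dilution"))
  n_targets <- length(targets)
  if (kind == "direct" && n_targets != 1L)
    stop("a 'direct' effect names exactly one metabolite")
  if (kind %in% c("branch", "conversion") && n_targets != 2L)
    stop("'branch' and 'conversion' effects name exactly two metabolites")
  if (kind == "dilution" && n_targets != 0L)
    stop("a 'dilution' effect affects all metabolites; leave targets empty")
  structure(
    list(variant_index = as.integer(variant_index), kind = kind,
         targets = as.character(targets), beta = as.numeric(beta)),
    class = "planted_effect"
  )
}

#' Configuration of a synthetic genotype-metabolite cohort
#'
#' Bundles every parameter of the generator. Defaults reproduce the study
#' conditions of a 520-sample acetaminophen-metabolite cohort: nine
#' metabolites with limit-of-detection censoring tuned to their observed
#' detection fractions (363--514 of 520), run-day batch structure with
#' median-registration normalization, ages 18--76 and 59.2% female.
#'
#' @param n_samples Number of samples.
#' @param n_variants Number of simulated biallelic autosomal variants.
#' @param maf Alternate-allele frequency per variant, each in (0, 0.5];
#'   recycled to `n_variants`.
#' @param seed Integer seed; every artifact of the generator is a
#'   deterministic function of the configuration including this seed.
#' @param metabolites Data frame of metabolite descriptors with at least a
#'   `name` column (default [acetaminophen_panel()]).
#' @param lod_quantile Fraction in \[0, 1) of each metabolite censored below
#'   the detection limit; recycled across metabolites. Default
#'   `1 - detection_fraction` of the panel.
#' @param missing_mode `"lod"` for left-censoring at the per-metabolite
#'   quantile of the latent abundances (missing-not-at-random, the LC-MS
#'   non-detection mechanism) or `"mcar"` for missingness completely at
#'   random at the same rate (null-calibration experiments).
#' @param batch_count Number of run-day blocks; samples are assigned to
#'   blocks in contiguous chunks.
#' @param batch_sd Standard deviation of the per-(block, metabolite)
#'   log-normal batch factor.
#' @param noise_sd Per-metabolite residual standard deviation on the
#'   natural-log scale.
#' @param dilution_sd Standard deviation of a per-sample log-normal factor
#'   shared by all metabolites (urine-concentration-style dilution, dose and
#'   time-since-ingestion variability); cancels in every pairwise log-ratio.
#' @param mu Baseline natural-log abundance per metabolite; recycled.
#' @param effect_plan List of [planted_effect()] objects.
#' @param age_range Two-element numeric vector, uniform age range in years.
#' @param sex_fraction Fraction of samples coded `sex = 1` (female).
#' @param ld_block_size Number of consecutive variants forming an LD block;
#'   1 simulates independent variants.
#' @param ld_copy_prob Within an LD block, per-sample probability that a
#'   variant copies the genotype of the previous variant instead of being
#'   drawn fresh under Hardy-Weinberg proportions.
#' @param chrom Chromosome label of the single synthetic autosome.
#' @param positions Optional integer vector of 1-based variant positions
#'   (strictly increasing); default uniformly spaced.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 520L,
                       n_variants = 100L,
                       maf = 0.3,
                       seed = 1L,
                       metabolites = acetaminophen_panel(),
                       lod_quantile = NULL,
                       missing_mode = c("lod", "mcar"),
                       batch_count = 10L,
                       batch_sd = 0.2,
                       noise_sd = 0.5,
                       dilution_sd = 0.5,
                       mu = 0,
                       effect_plan = list(),
                       age_range = c(18, 76),
                       sex_fraction = 0.592,
                       ld_block_size = 1L,
                       ld_copy_prob = 0.9,
                       chrom = "1",
                       positions = NULL) {
  missing_mode <- match.arg(missing_mode)
  n_samples <- as.integer(n_samples)
  n_variants <- as.integer(n_variants)
  if (is.na(n_samples) || n_samples <= 0L)
    stop("n_samples must be a positive integer")
  if (is.na(n_variants) || n_variants <= 0L)
    stop("n_variants must be a positive integer")
  maf <- rep_len(as.numeric(maf), n_variants)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("all allele frequencies must lie in (0, 0.5]")
  m <- nrow(metabolites)
  if (is.null(lod_quantile)) {
    lod_quantile <- if ("detection_fraction" %in% names(metabolites))
      1 - metabolites$detection_fraction else 0
  }
  lod_quantile <- rep_len(as.numeric(lod_quantile), m)
  if (any(lod_quantile < 0) || any(lod_quantile >= 1))
    stop("lod_quantile must lie in [0, 1)")
  mu <- rep_len(as.numeric(mu), m)
  for (eff in effect_plan) {
    if (!inherits(eff, "planted_effect"))
      stop("effect_plan must be a list of planted_effect objects")
    if (eff$variant_index < 1L || eff$variant_index > n_variants)
      stop("planted effect references unknown variant index ",
           eff$variant_index)
    unknown <- setdiff(eff$targets, metabolites$name)
    if (length(unknown) > 0L)
      stop("planted effect references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != n_variants || any(diff(positions) <= 0L))
      stop("positions must be strictly increasing, one per variant")
  }
  structure(
    list(n_samples = n_samples, n_variants = n_variants, maf = maf,
         seed = as.integer(seed), metabolites = metabolites,
         lod_quantile = lod_quantile, missing_mode = missing_mode,
         batch_count = as.integer(batch_count), batch_sd = batch_sd,
         noise_sd = noise_sd, dilution_sd = dilution_sd, mu = mu,
         effect_plan = effect_plan, age_range = age_range,
         sex_fraction = sex_fraction,
         ld_block_size = as.integer(ld_block_size),
         ld_copy_prob = ld_copy_prob, chrom = chrom, positions = positions),
    class = "sim_config"
  )
}

#' Simulate genotypes under Hardy-Weinberg proportions
#'
#' Draws a samples-by-variants dosage matrix (0/1/2 copies of the alternate
#' allele), each variant at its configured allele frequency under
#' Hardy-Weinberg equilibrium, on a single synthetic autosome with strictly
#' increasing positions. When `ld_block_size > 1`, consecutive variants
#' within a block are generated by copying-with-mutation from their left
#' neighbour, inducing LD usable to exercise pruning and clumping.
#'
#' @param config A [sim_config()] object.
#' @return A [genotype_matrix()] with variant metadata.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  v <- config$n_variants
  dos <- matrix(0L, n, v)
  for (j in seq_len(v)) {
    in_block <- config$ld_block_size > 1L &&
      (j - 1L) %% config$ld_block_size != 0L
    fresh <- stats::rbinom(n, 2L, config$maf[j])
    if (in_block) {
      copy <- stats::runif(n) < config$ld_copy_prob
      dos[, j] <- ifelse(copy, dos[, j - 1L], fresh)
    } else {
      dos[, j] <- fresh
    }
  }
  pos <- if (is.null(config$positions)) seq_len(v) * 10000L else config$positions
  variants <- data.frame(
    chrom = rep(config$chrom, v), pos = pos,
    id = sprintf("var%05d", seq_len(v)),
    ref = rep("A", v), alt = rep("G", v), is_indel = rep(FALSE, v),
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(dos) <- list(sample_ids, variants$id)
  genotype_matrix(dos, variants)
}

#' Simulate a metabolite panel over simulated genotypes
#'
#' Generates latent log abundances under the additive model
#' `log m_ij = mu_j + sum of planted effects(g_i) + batch_(b(i),j) +
#' dilution_i + eps_ij` with Gaussian residuals, then (1) censors values
#' below the per-metabolite limit-of-detection quantile (missing not at
#' random; or MCAR at the same rate if configured), and (2) registers the
#' median of the detected values of each metabolite within each run-day
#' block to one, mirroring standard non-targeted LC-MS block normalization.
#'
#' The latent (pre-censoring, pre-normalization) log abundances are retained
#' in the returned object (`$latent_log`) so generative claims — e.g. that a
#' dilution term cancels exactly in any log-ratio, or that censored values
#' lie below the detection quantile — are directly testable.
#'
#' @param config A [sim_config()] object.
#' @param genotypes A [genotype_matrix()] with `config$n_samples` samples.
#' @return A `metabolite_panel`: list with `abundances` (samples x
#'   metabolites, `NA` where not detected), `detected` logical mask, `meta`
#'   descriptors, `batch` assignment, `latent_log`, and `lod` thresholds.
#' @export
simulate_metabolites <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  n <- config$n_samples
  if (nrow(genotypes$dosages) != n)
    stop("genotype and configuration sample counts differ")
  set.seed(config$seed + 1L)
  m <- nrow(config$metabolites)
  mnames <- config$metabolites$name
  batch <- rep(seq_len(config$batch_count), each = ceiling(n / config$batch_count))[seq_len(n)]

  lat <- matrix(rep(config$mu, each = n), n, m) +
    matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)
  if (config$batch_sd > 0) {
    bf <- matrix(stats::rnorm(config$batch_count * m, sd = config$batch_sd),
                 config$batch_count, m)
    lat <- lat + bf[batch, , drop = FALSE]
  }
  if (config$dilution_sd > 0)
    lat <- lat + stats::rnorm(n, sd = config$dilution_sd)

  for (eff in config$effect_plan) {
    g <- genotypes$dosages[, eff$variant_index]
    g[is.na(g)] <- 0
    switch(eff$kind,
      dilution = { lat <- lat + eff$beta * g },
      direct = {
        j <- match(eff$targets[1L], mnames)
        lat[, j] <- lat[, j] + eff$beta * g
      },
      branch = ,
      conversion = {
        j1 <- match(eff$targets[1L], mnames)
        j2 <- match(eff$targets[2L], mnames)
        lat[, j1] <- lat[, j1] + eff$beta * g
        lat[, j2] <- lat[, j2] - eff$beta * g
      })
  }

  abund <- exp(lat)
  detected <- matrix(TRUE, n, m)
  for (j in seq_len(m)) {
    q <- config$lod_quantile[j]
    if (q <= 0) next
    if (config$missing_mode == "lod") {
      detected[, j] <- abund[, j] > stats::quantile(abund[, j], q)
    } else {
      detected[, j] <- stats::runif(n) >= q
    }
  }
  # censor first, then register run-day medians of the *detected* values
  abund[!detected] <- NA_real_
  for (b in seq_len(config$batch_count)) {
    rows <- which(batch == b)
    for (j in seq_len(m)) {
      med <- stats::median(abund[rows, j], na.rm = TRUE)
      if (is.finite(med) && med > 0)
        abund[rows, j] <- abund[rows, j] / med
    }
  }
  dimnames(abund) <- list(rownames(genotypes$dosages), mnames)
  dimnames(detected) <- dimnames(abund)
  dimnames(lat) <- dimnames(abund)
  structure(
    list(abundances = abund, detected = detected, meta = config$metabolites,
         batch = batch, latent_log = lat),
    class = "metabolite_panel"
  )
}

simulate_covariates <- function(config) {
  set.seed(config$seed + 2L)
  data.frame(
    sample = sprintf("S%04d", seq_len(config$n_samples)),
    age = round(stats::runif(config$n_samples, config$age_range[1],
                             config$age_range[2])),
    sex = stats::rbinom(config$n_samples, 1L, config$sex_fraction),
    stringsAsFactors = FALSE
  )
}

simulate_genes <- function(config, genotypes, gene_names = NULL,
                           n_filler = 10L, half_width = 5000L) {
  effects <- config$effect_plan
  if (is.null(gene_names))
    gene_names <- sprintf("EFFECT_GENE_%d", seq_along(effects))
  genes <- list()
  for (i in seq_along(effects)) {
    p <- genotypes$variants$pos[effects[[i]]$variant_index]
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = config$chrom, start = max(1L, p - half_width),
      end = p + half_width, name = gene_names[i], strand = "+",
      stringsAsFactors = FALSE)
  }
  span <- max(genotypes$variants$pos)
  at <- round(seq(1, span + 2L * half_width, length.out = n_filler + 2L))[-c(1L, n_filler + 2L)]
  for (i in seq_len(n_filler)) {
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = config$chrom, start = at[i], end = at[i] + 2000L,
      name = sprintf("FILLER_%02d", i), strand = "-",
      stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, genes)
  gt <- gt[order(gt$chrom, gt$start), , drop = FALSE]
  rownames(gt) <- NULL
  gt
}

#' Simulate a complete cohort
#'
#' Runs the genotype, metabolite, covariate and toy-gene-track generators
#' under a single configuration. One gene is placed over each planted-effect
#' variant (named `EFFECT_GENE_<i>` unless `gene_names` is given) so that
#' nearest-gene annotation and candidate-gene cross-referencing can be
#' exercised end-to-end.
#'
#' @param config A [sim_config()] object.
#' @param gene_names Optional names for the genes covering planted effects.
#' @return A list of class `sim_cohort` with elements `genotypes`, `panel`,
#'   `covariates`, `genes`, `config`.
#' @export
simulate_cohort <- function(config, gene_names = NULL) {
  genotypes <- simulate_genotypes(config)
  panel <- simulate_metabolites(config, genotypes)
  covariates <- simulate_covariates(config)
  genes <- simulate_genes(config, genotypes, gene_names)
  structure(list(genotypes = genotypes, panel = panel,
                 covariates = covariates, genes = genes, config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to standard file formats
#'
#' Emits the four inputs the pipeline consumes: a VCFv4.2 with GT-only
#' genotypes, a metabolite TSV (first column the sample identifier, blank
#' fields for non-detected values — never zero), a covariate TSV
#' (`sample`, `age`, `sex` coded 0/1) and a BED gene track (0-based
#' half-open). The files round-trip losslessly through the package readers.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    metabolites = file.path(out_dir, "metabolites.tsv"),
    covariates = file.path(out_dir, "covariates.tsv"),
    genes = file.path(out_dir, "genes.bed")
  )
  write_vcf(cohort$genotypes, paths["vcf"])
  write_metabolites(cohort$panel, paths["metabolites"])
  data.table::fwrite(cohort$covariates, paths["covariates"], sep = "\t")
  write_bed(cohort$genes, paths["genes"])
  invisible(paths)
}
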