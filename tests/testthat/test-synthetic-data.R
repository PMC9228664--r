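test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_samples = 50L, n_variants = 10L, seed = 42L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
  expect_identical(c1$panel$abundances, c2$panel$abundances)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$genes, c2$genes)
})

test_that("simulated genotypes follow Hardy-Weinberg at the requested frequency", {
  cfg <- sim_config(n_samples = 5000L, n_variants = 1L, maf = 0.3, seed = 5L)
  g <- simulate_genotypes(cfg)
  f_hat <- mean(g$dosages) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_lt(abs(f_hat - 0.3), 3 * se)

  cfg5 <- sim_config(n_samples = 20000L, n_variants = 1L, maf = 0.5, seed = 6L)
  g5 <- simulate_genotypes(cfg5)
  fr <- tabulate(g5$dosages + 1L, 3L) / 20000
  expect_equal(fr, c(0.25, 0.5, 0.25), tolerance = 0.05)

  expect_true(all(diff(g$variants$pos) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0L), "positive")
  expect_error(sim_config(maf = 0.6), "allele frequencies")
  expect_error(sim_config(maf = 0), "allele frequencies")
  expect_error(sim_config(lod_quantile = 1), "lod_quantile")
  expect_error(planted_effect(1L, "branch", "only-one", 0.1), "two metabolites")
  expect_error(planted_effect(1L, "direct", c("a", "b"), 0.1), "one metabolite")
  expect_error(
    sim_config(effect_plan = list(planted_effect(1L, "direct", "nope", 0.1))),
    "unknown metabolite")
  expect_error(
    sim_config(n_variants = 2L,
               effect_plan = list(planted_effect(9L, "dilution", beta = 0.1))),
    "unknown variant")
})

test_that("effect archetypes obey the generative arithmetic on latent abundances", {
  panel2 <- data.frame(name = c("A", "B"))
  # noise-free: a branch effect of +/-beta shifts log(A/B) by exactly 2*beta
  cfg <- sim_config(n_samples = 300L, n_variants = 1L, maf = 0.4, seed = 3L,
                    metabolites = panel2, lod_quantile = 0, noise_sd = 0,
                    batch_sd = 0, dilution_sd = 0, batch_count = 1L,
                    effect_plan = list(planted_effect(1L, "branch",
                                                      c("A", "B"), 0.15)))
  coh <- simulate_cohort(cfg)
  g <- unname(coh$genotypes$dosages[, 1])
  lat <- coh$panel$latent_log
  expect_equal(unname(lat[, "A"]), 0.15 * g, tolerance = 1e-12)
  expect_equal(unname(lat[, "A"] - lat[, "B"]), 0.30 * g, tolerance = 1e-12)

  # a dilution effect cancels exactly in any log-ratio, noise and all
  cfgd <- sim_config(n_samples = 300L, n_variants = 1L, maf = 0.4, seed = 3L,
                     metabolites = panel2, lod_quantile = 0,
                     dilution_sd = 1, batch_sd = 0.3,
                     effect_plan = list(planted_effect(1L, "dilution",
                                                       beta = 0.5)))
  cfg0 <- sim_config(n_samples = 300L, n_variants = 1L, maf = 0.4, seed = 3L,
                     metabolites = panel2, lod_quantile = 0,
                     dilution_sd = 1, batch_sd = 0.3)
  ratio_d <- with(simulate_cohort(cfgd)$panel, latent_log[, 1] - latent_log[, 2])
  ratio_0 <- with(simulate_cohort(cfg0)$panel, latent_log[, 1] - latent_log[, 2])
  expect_equal(ratio_d, ratio_0, tolerance = 1e-12)
})

test_that("limit-of-detection censoring is missing-not-at-random at the set rate", {
  panel1 <- data.frame(name = "A")
  cfg <- sim_config(n_samples = 2000L, n_variants = 1L, seed = 9L,
                    metabolites = panel1, lod_quantile = 0.25)
  coh <- simulate_cohort(cfg)
  miss <- !coh$panel$detected[, 1]
  expect_equal(mean(miss), 0.25, tolerance = 0.02)
  # every censored value's latent abundance lies below the 25th percentile
  lat <- coh$panel$latent_log[, 1]
  expect_true(max(lat[miss]) <= stats::quantile(lat, 0.25) + 1e-12)
  expect_true(min(lat[!miss]) >= max(lat[miss]))
})

test_that("run-day median registration leaves each batch median at exactly 1", {
  cfg <- sim_config(n_samples = 200L, n_variants = 2L, seed = 12L,
                    batch_count = 4L, batch_sd = 0.5)
  coh <- simulate_cohort(cfg)
  ab <- coh$panel$abundances
  for (b in unique(coh$panel$batch)) {
    rows <- coh$panel$batch == b
    for (j in seq_len(ncol(ab))) {
      med <- stats::median(ab[rows, j], na.rm = TRUE)
      expect_equal(med, 1, tolerance = 1e-12)
    }
  }
})

test_that("with no effects and no shared factors, metabolites are independent log-normals", {
  cfg <- sim_config(n_samples = 4000L, n_variants = 1L, seed = 21L,
                    lod_quantile = 0, batch_sd = 0, dilution_sd = 0,
                    batch_count = 1L)
  coh <- simulate_cohort(cfg)
  lg <- log(coh$panel$abundances)
  cm <- stats::cor(lg)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.08)
  expect_gt(stats::shapiro.test(lg[1:2000, 1])$p.value, 1e-4)
})

test_that("regression on the log-ratio recovers twice the planted branch effect", {
  pair <- c("4-acetamidophenyl glucuronide", "4-acetaminophen sulfate")
  cfg <- sim_config(n_samples = 2000L, n_variants = 1L, maf = 0.3, seed = 77L,
                    lod_quantile = 0,
                    effect_plan = list(planted_effect(1L, "branch", pair, 0.15)))
  coh <- simulate_cohort(cfg)
  traits <- build_traits(coh$panel)
  y <- traits$values[, paste0(pair[1], "/", pair[2])]
  names(y) <- rownames(traits$values)
  fit <- ols_association(y, coh$genotypes$dosages[, 1])
  expect_lt(abs(fit$beta - 0.30), 3 * fit$se)
})

test_that("a written cohort round-trips losslessly through the readers", {
  cfg <- sim_config(n_samples = 40L, n_variants = 8L, seed = 4L,
                    effect_plan = list(planted_effect(
                      3L, "direct", "4-acetamidophenol", 0.2)))
  coh <- simulate_cohort(cfg)
  out <- withr::local_tempdir()
  paths <- write_cohort(coh, out)

  g2 <- read_vcf(paths["vcf"])
  expect_equal(unname(g2$dosages), unname(coh$genotypes$dosages))
  expect_identical(g2$variants$pos, coh$genotypes$variants$pos)

  p2 <- read_metabolites(paths["metabolites"])
  expect_equal(p2$detected, coh$panel$detected)
  expect_equal(p2$abundances, coh$panel$abundances, tolerance = 1e-12)

  c2 <- read_covariates(paths["covariates"])
  expect_equal(c2$age, coh$covariates$age)
  expect_equal(c2$sex, coh$covariates$sex)

  genes2 <- read_bed_genes(paths["genes"])
  expect_equal(genes2$start, coh$genes$start)
  expect_equal(genes2$end, coh$genes$end)
  expect_equal(genes2$name, coh$genes$name)

  # VCF: sorted positions, one record per variant
  lines <- readLines(paths["vcf"])
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 8L)
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2L))
  expect_true(all(diff(pos) > 0))

  # missing metabolite values are blank fields, never zero
  mlines <- readLines(paths["metabolites"])
  expect_true(any(grepl("\t\t|\t$", mlines[-1L])))
  expect_false(any(grepl("\t0(\t|$)", mlines[-1L])))
})
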