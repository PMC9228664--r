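# assemble a minimal association-result table for classification tests:
# two metabolites A, B, one ratio A/B, arbitrary variants
toy_results <- function(p_num, p_den, p_ratio, variant = "rs1") {
  data.frame(
    trait = c("A", "B", "A/B"),
    variant = variant, chrom = "1", pos = 100L,
    n_used = 400L, beta = 0.1, se = 0.02,
    p = c(p_num, p_den, p_ratio), testable = TRUE,
    stringsAsFactors = FALSE)
}
toy_info <- data.frame(trait = c("A", "B", "A/B"),
                       kind = c("single", "single", "ratio"),
                       numerator = c("A", "B", "A"),
                       denominator = c(NA, NA, "B"),
                       stringsAsFactors = FALSE)

test_that("trait-wide thresholds follow the Bonferroni arithmetic", {
  th <- compute_thresholds(45L)
  expect_equal(th$p_bonf, 5e-8 / 45)
  expect_equal(signif(th$p_bonf, 2), 1.1e-9)
  expect_equal(th$pgain_bonf, 450)
  expect_equal(th$suggestive_p, 1e-5)

  th1 <- compute_thresholds(1L)
  expect_equal(th1$p_bonf, 5e-8)
  expect_equal(th1$pgain_bonf, 10)

  th10 <- compute_thresholds(10L)
  expect_equal(th10$p_bonf, 5e-9)
  expect_equal(th10$pgain_bonf, 100)

  expect_error(compute_thresholds(0L), "positive")
  # monotone in T
  expect_lt(compute_thresholds(90L)$p_bonf, th$p_bonf)
  expect_gt(compute_thresholds(90L)$pgain_bonf, th$pgain_bonf)
})

test_that("the p-gain is the smaller component p over the ratio p", {
  expect_equal(compute_pgain(0.05, 0.05, 0.05), 1)
  expect_equal(compute_pgain(0.02, 0.5, 1e-6), 2e4)
  # symmetric in the two components
  expect_equal(compute_pgain(0.02, 0.5, 1e-6), compute_pgain(0.5, 0.02, 1e-6))
  # identity: pgain * p_ratio = min(p_num, p_den)
  set.seed(71)
  pn <- runif(50); pd <- runif(50); pr <- runif(50)
  expect_equal(compute_pgain(pn, pd, pr) * pr, pmin(pn, pd),
               tolerance = 1e-15)
  expect_error(compute_pgain(0, 0.5, 0.1), "p-values")
  expect_error(compute_pgain(0.5, -1, 0.1), "p-values")
  expect_error(compute_pgain(0.5, 0.5, 1.5), "p-values")
})

test_that("the definition inverts printed lead-association statistics consistently", {
  # a ratio association with p 3.7e-10 and p-gain 4.6e7 implies a smallest
  # component p of ~1.7e-2; re-applying the definition returns the p-gain
  implied <- 4.6e7 * 3.7e-10
  expect_equal(signif(implied, 2), 1.7e-2)
  expect_equal(signif(compute_pgain(implied, 1, 3.7e-10), 2), 4.6e7)
})

test_that("classification sets the three significance flags with strict inequalities", {
  th <- compute_thresholds(45L)

  # genome- and trait-wide significant AND ratio-significant
  cl <- classify_associations(toy_results(1.7e-2, 0.8, 3.7e-10), toy_info, th)
  expect_equal(cl$pgain, 1.7e-2 / 3.7e-10, tolerance = 1e-12)
  expect_true(cl$bonferroni_significant)
  expect_true(cl$pgain_significant)
  expect_true(cl$suggestive)

  # suggestive but below the Bonferroni bar
  cl2 <- classify_associations(toy_results(0.03, 0.9, 1.5e-6), toy_info, th)
  expect_false(cl2$bonferroni_significant)
  expect_true(cl2$suggestive)
  expect_true(cl2$pgain_significant)  # 0.03 / 1.5e-6 = 2e4 > 450

  # null association: no flags
  cl3 <- classify_associations(toy_results(0.6, 0.7, 0.5), toy_info, th)
  expect_false(any(cl3$bonferroni_significant, cl3$pgain_significant,
                   cl3$suggestive))

  # strictness at the boundary: p_ratio == p_bonf and pgain == pgain_bonf
  res_b <- toy_results(450 * th$p_bonf, 0.9, th$p_bonf)
  clb <- classify_associations(res_b, toy_info, th)
  expect_false(clb$bonferroni_significant)
  expect_false(clb$pgain_significant)
})

test_that("classification joins per variant, flags incomplete rows, and is pure", {
  th <- compute_thresholds(45L)
  res <- rbind(toy_results(0.02, 0.5, 1e-6, "rs1"),
               toy_results(0.9, 0.8, 0.7, "rs2"))
  cl <- classify_associations(res, toy_info, th)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$pgain[cl$variant == "rs1"], 2e4)

  # missing component result -> undefined p-gain, row flagged
  res_m <- res[res$trait != "B" | res$variant != "rs2", ]
  clm <- classify_associations(res_m, toy_info, th)
  expect_true(clm$incomplete[clm$variant == "rs2"])
  expect_true(is.na(clm$pgain[clm$variant == "rs2"]))

  # pure function: identical inputs give identical output
  expect_identical(cl, classify_associations(res, toy_info, th))
})

test_that("p-gain is invariant under swapping numerator and denominator", {
  th <- compute_thresholds(45L)
  res <- toy_results(0.04, 0.2, 1e-5)
  info_sw <- toy_info
  info_sw$numerator[3] <- "B"
  info_sw$denominator[3] <- "A"
  cl <- classify_associations(res, toy_info, th)
  cl_sw <- classify_associations(res, info_sw, th)
  expect_equal(cl$pgain, cl_sw$pgain)
})

test_that("null calibration is seeded, bounded and consistent with the OLS engine", {
  cal <- pgain_null_calibration(n_replicates = 400L, n = 120L, seed = 72L)
  cal2 <- pgain_null_calibration(n_replicates = 400L, n = 120L, seed = 72L)
  expect_identical(cal$pgain, cal2$pgain)
  expect_identical(cal$exceedance, cal2$exceedance)
  expect_lte(cal$ci_lower, cal$exceedance)
  expect_gte(cal$ci_upper, cal$exceedance)

  # an infinite critical value is never exceeded
  expect_equal(pgain_null_calibration(n_replicates = 200L, n = 50L,
                                      critical = Inf, seed = 73L)$exceedance, 0)

  # the closed-form regression p-values match ols_association: rebuild the
  # first replicate under the same RNG stream
  seed <- 74L
  n <- 80L; r <- 5L
  set.seed(seed)
  g <- matrix(rbinom(n * r, 2L, 0.3), n, r)
  a <- matrix(rnorm(n * r, sd = 1), n, r)
  b <- matrix(rnorm(n * r, sd = 1), n, r)
  cal3 <- pgain_null_calibration(n_replicates = r, n = n, maf = 0.3,
                                 noise_sd = 1, seed = seed)
  ids <- sprintf("S%02d", seq_len(n))
  manual <- vapply(seq_len(r), function(j) {
    gv <- g[, j]; names(gv) <- ids
    pa <- ols_association(setNames(a[, j], ids), gv)$p
    pb <- ols_association(setNames(b[, j], ids), gv)$p
    pr <- ols_association(setNames(a[, j] - b[, j], ids), gv)$p
    min(pa, pb) / pr
  }, numeric(1))
  expect_equal(cal3$pgain, manual, tolerance = 1e-9)
})

test_that("ratios rescue a genetic signal masked by shared dilution variation", {
  # direct effect on one metabolite plus a large random shared dilution
  # factor: single-trait tests are swamped, the ratio test is not, so the
  # p-gain is large while the component p-values stay null-like
  panel2 <- data.frame(name = c("A", "B"))
  pg <- c(); psingle <- c()
  for (r in 1:20) {
    cfg <- sim_config(n_samples = 500L, n_variants = 1L, maf = 0.3,
                      seed = 7000L + r, metabolites = panel2,
                      lod_quantile = 0, noise_sd = 0.2, batch_sd = 0,
                      dilution_sd = 2,
                      effect_plan = list(planted_effect(1L, "direct", "A", 0.2)))
    coh <- simulate_cohort(cfg)
    tr <- build_traits(coh$panel)
    res <- run_gwas(tr, coh$genotypes)
    cl <- classify_associations(res, tr$info, compute_thresholds(3L))
    pg <- c(pg, cl$pgain)
    psingle <- c(psingle, min(cl$p_num, cl$p_den))
  }
  expect_gt(median(pg), 100)
  expect_gt(median(psingle), 0.001)
})
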