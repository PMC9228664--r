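test_that("Hardy-Weinberg exact test matches the enumeration oracle and its symmetries", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:50) {
    cnt <- as.integer(sample(0:30, 3, replace = TRUE))
    if (sum(cnt) == 0L) next
    p <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    expect_gt(p, 0)
    expect_lte(p, 1)
    # allele relabeling swaps the homozygote classes
    expect_equal(p, hwe_exact_test(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
    expect_equal(p, hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("variant statistics use non-missing genotypes only", {
  dos <- rbind(c(0, 2, 0, NA),
               c(1, 2, 0, NA),
               c(2, 2, 0, NA),
               c(0, 2, NA, NA),
               c(1, 2, 1, NA))
  g <- make_geno(dos)
  st <- compute_variant_stats(g)
  expect_equal(st$maf[1], min(4 / 10, 6 / 10))   # alt freq 4/10
  expect_equal(st$call_rate, c(1, 1, 0.8, 0))
  expect_equal(st$maf[2], 0)                      # monomorphic alt
  expect_equal(st$hwe_p[2], 1)
  expect_false(st$defined[4])
  expect_true(is.na(st$maf[4]))
})

test_that("variant filtering applies strict-violation rules and boundary values survive", {
  # construct 6 variants straddling each threshold; hand-applied rules:
  # v1 clean keep; v2 maf<0.05 drop; v3 maf exactly 0.05 keep;
  # v4 call rate 0.85 drop; v5 HWE ~0 drop; v6 indel drop
  n <- 200L
  set.seed(8)
  clean <- rbinom(n, 2, 0.3)
  rare <- c(rep(1L, 8L), rep(0L, n - 8L))            # maf 0.02
  boundary <- c(rep(1L, 20L), rep(0L, n - 20L))      # maf exactly 0.05
  lowcall <- clean; lowcall[1:30] <- NA              # call rate 0.85
  hwe_bad <- rep(1L, n)                              # all het, HWE p ~ 0
  indel <- rbinom(n, 2, 0.3)
  g <- make_geno(cbind(clean, rare, boundary, lowcall, hwe_bad, indel),
                 is_indel = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  f <- filter_variants(g)
  expect_identical(f$variants$id, c("v001", "v003"))
  removed <- attr(f, "removed")
  expect_equal(unname(removed["maf"]), 1)
  expect_equal(unname(removed["call_rate"]), 1)
  expect_equal(unname(removed["hwe"]), 1)
  expect_equal(unname(removed["indel"]), 1)

  # zero thresholds: identity filter
  f0 <- filter_variants(g, maf_min = 0, call_rate_min = 0, hwe_p_min = 0,
                        autosomes_only = FALSE, drop_indels = FALSE)
  expect_identical(f0$variants$id, g$variants$id)

  # idempotence
  f2 <- filter_variants(f)
  expect_identical(f2$variants$id, f$variants$id)

  # non-autosomal variants are dropped
  gx <- make_geno(cbind(clean, clean), chrom = c("1", "X"))
  expect_identical(filter_variants(gx)$variants$chrom, "1")
})

test_that("LD r2 is the squared pairwise-complete Pearson correlation", {
  dos <- cbind(a = c(0, 1, 2, 0, 1, 2, 1, 0),
               b = c(2, 1, 0, 2, 1, 0, 1, 2),
               c = c(0, 0, 1, 2, 1, 0, 2, 2),
               d = c(1, 1, 1, 1, 1, 1, 1, 1))
  g <- make_geno(dos)
  expect_equal(ld_r2(g, 1, 1), 1)
  expect_equal(ld_r2(g, 1, 2), 1)   # mirrored vector, correlation -1
  expect_equal(ld_r2(g, 1, 3), stats::cor(dos[, 1], dos[, 3])^2)
  expect_equal(ld_r2(g, 1, 3), ld_r2(g, 3, 1))
  expect_true(is.na(ld_r2(g, 1, 4))) # zero variance -> undefined
  # pairwise-complete subset
  dos2 <- dos
  dos2[1:2, 3] <- NA
  g2 <- make_geno(dos2)
  expect_equal(ld_r2(g2, 1, 3),
               stats::cor(dos2[3:8, 1], dos2[3:8, 3])^2)
})

test_that("greedy LD pruning removes the later variant of linked pairs", {
  set.seed(15)
  base <- rbinom(100, 2, 0.4)
  g <- make_geno(cbind(base, base, rbinom(100, 2, 0.4)))
  kept <- ld_prune(g, r2_max = 0.5)
  expect_identical(kept, c(1L, 3L))

  # all pairwise r2 below threshold: identity
  indep <- sapply(1:6, function(i) rbinom(200, 2, 0.3))
  gi <- make_geno(indep)
  expect_identical(ld_prune(gi, r2_max = 0.999), seq_len(6L))

  # constructed 10-variant block equals the exhaustive greedy oracle
  cfg <- sim_config(n_samples = 300L, n_variants = 10L, maf = 0.3,
                    seed = 19L, ld_block_size = 5L, ld_copy_prob = 0.85)
  gb <- simulate_genotypes(cfg)
  expect_identical(ld_prune(gb, r2_max = 0.5, window = 10L, step = 1L),
                   prune_oracle(gb, 0.5))
})

test_that("principal components separate structured populations and are orthogonal", {
  set.seed(23)
  n <- 60L; v <- 150L
  f1 <- runif(v, 0.1, 0.5)
  shift <- pmin(0.95, pmax(0.05, f1 + sample(c(-1, 1), v, TRUE) * 0.3))
  pop <- rep(c(1L, 2L), each = n / 2)
  dos <- sapply(seq_len(v), function(j)
    rbinom(n, 2, ifelse(pop == 1L, f1[j], shift[j])))
  g <- make_geno(dos)
  sc <- compute_pcs(g, k = 4L)
  expect_equal(dim(sc), c(n, 4L))
  # orthogonality
  cp <- crossprod(sc)
  off <- cp[upper.tri(cp)]
  expect_lt(max(abs(off)) / max(diag(cp)), 1e-8)
  # PC1 separates the two populations
  expect_gt(abs(mean(sc[pop == 1L, 1]) - mean(sc[pop == 2L, 1])),
            2 * (sd(sc[pop == 1L, 1]) + sd(sc[pop == 2L, 1])))

  # identical samples get identical scores
  dos2 <- dos
  dos2[2, ] <- dos2[1, ]
  sc2 <- compute_pcs(make_geno(dos2), k = 3L)
  expect_equal(sc2[1, ], sc2[2, ], tolerance = 1e-10)

  # excessive k is truncated with a warning
  small <- make_geno(dos[1:5, 1:20])
  expect_warning(sck <- compute_pcs(small, k = 10L), "rank")
  expect_lte(ncol(sck), 5L)
})

test_that("the relationship matrix matches the standardized-dosage formula", {
  # 3 samples x 2 variants, hand-evaluated formula oracle
  dos <- rbind(c(0, 2), c(1, 1), c(2, 0))
  g <- make_geno(dos)
  p <- colMeans(dos) / 2
  w <- sweep(sweep(dos, 2, 2 * p, `-`), 2, sqrt(2 * p * (1 - p)), `/`)
  expected <- tcrossprod(w) / 2
  grm <- compute_grm(g)
  expect_equal(unname(grm$values), expected, tolerance = 1e-12)
  expect_equal(grm$n_variants_used, 2L)
  expect_true(isSymmetric(grm$values))

  # monomorphic variants are excluded
  g2 <- make_geno(cbind(dos, c(0, 0, 0)))
  expect_equal(compute_grm(g2)$n_variants_used, 2L)

  # duplicated samples: off-diagonal entry approximately the diagonal
  set.seed(41)
  dup <- sapply(1:400, function(j) rbinom(20, 2, runif(1, 0.1, 0.5)))
  dup <- rbind(dup, dup[1, ])
  gd <- compute_grm(make_geno(dup))$values
  expect_equal(gd[1, 21], gd[1, 1], tolerance = 1e-12)
})

test_that("GRM diagonal centres at 1 for an unstructured cohort", {
  set.seed(55)
  cfg <- sim_config(n_samples = 500L, n_variants = 5000L,
                    maf = runif(5000, 0.05, 0.5), seed = 55L)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  dvals <- diag(grm$values)
  se <- sd(dvals) / sqrt(length(dvals))
  expect_lt(abs(mean(dvals) - 1), 3 * se + 0.01)
})
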