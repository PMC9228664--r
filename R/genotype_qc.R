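#' Hardy-Weinberg exact test p-value from genotype counts
#'
#' Exact conditional test of Hardy-Weinberg proportions: conditioning on the
#' observed allele counts, the p-value is the sum of the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Probabilities are built with the standard two-sided
#' recurrence over heterozygote counts (no mid-p correction). Monomorphic
#' variants return 1 by convention.
#'
#' @param n_aa Count of reference homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of alternate homozygotes.
#' @return Exact p-value in (0, 1]; invariant under swapping `n_aa`/`n_bb`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n_aa <- as.integer(n_aa); n_ab <- as.integer(n_ab); n_bb <- as.integer(n_bb)
  if (min(n_aa, n_ab, n_bb) < 0L) stop("genotype counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  n_rare <- 2L * min(n_aa, n_bb) + n_ab
  if (n_rare == 0L) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  # downward recurrence: P(h-2)/P(h) = h*(h-1) / (4*(n_hom_r+1)*(n_hom_c+1))
  if (mid_i > 1L) for (i in (mid_i - 1L):1L) {
    h <- hets[i + 1L]
    hom_r <- (n_rare - h) / 2
    hom_c <- (2 * n - n_rare - h) / 2
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  # upward recurrence: P(h+2)/P(h) = 4*hom_r*hom_c / ((h+2)*(h+1))
  if (mid_i < length(hets)) for (i in (mid_i + 1L):length(hets)) {
    h <- hets[i - 1L]
    hom_r <- (n_rare - h) / 2
    hom_c <- (2 * n - n_rare - h) / 2
    probs[i] <- probs[i - 1L] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

#' Per-variant quality-control statistics
#'
#' Computes, per variant and on non-missing genotypes only: the minor allele
#' frequency `min(f, 1 - f)` with `f` the alternate-allele frequency among
#' called genotypes, the call rate (called / total samples), and the exact
#' Hardy-Weinberg p-value ([hwe_exact_test()]). All-missing variants get
#' `NA` statistics and are flagged undefined.
#'
#' @param g A [genotype_matrix()].
#' @return Data frame: `id`, `chrom`, `pos`, `is_indel`, `maf`, `call_rate`,
#'   `hwe_p`, `defined`.
#' @export
compute_variant_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  n <- nrow(dos)
  called <- colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  f <- ifelse(called > 0L, alt / (2 * called), NA_real_)
  maf <- pmin(f, 1 - f)
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  data.frame(
    id = g$variants$id, chrom = g$variants$chrom, pos = g$variants$pos,
    is_indel = g$variants$is_indel,
    maf = maf, call_rate = called / n, hwe_p = hwe,
    defined = called > 0L,
    stringsAsFactors = FALSE
  )
}

#' Filter variants on MAF, call rate, Hardy-Weinberg and chromosome
#'
#' Removes strict violations only, so boundary values survive: a variant is
#' dropped when `maf < maf_min`, `call_rate < call_rate_min`,
#' `hwe_p < hwe_p_min`, when it lies on a non-autosome (if
#' `autosomes_only`), when it is an indel (if `drop_indels`), or when its
#' statistics are undefined (all calls missing). The counts removed per
#' criterion are attached as the `"removed"` attribute.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min,call_rate_min,hwe_p_min QC thresholds (defaults 0.05,
#'   0.90, 1e-6).
#' @param autosomes_only Drop variants whose chromosome is not 1..22.
#' @param drop_indels Drop indels (required before LD pruning).
#' @param stats Optional precomputed [compute_variant_stats()] output.
#' @return The filtered [genotype_matrix()]; empty results are permitted
#'   with a warning.
#' @export
filter_variants <- function(g, maf_min = 0.05, call_rate_min = 0.90,
                            hwe_p_min = 1e-6, autosomes_only = TRUE,
                            drop_indels = TRUE, stats = NULL) {
  if (is.null(stats)) stats <- compute_variant_stats(g)
  undefined <- !stats$defined
  low_maf <- !undefined & stats$maf < maf_min
  low_cr <- !undefined & stats$call_rate < call_rate_min
  low_hwe <- !undefined & stats$hwe_p < hwe_p_min
  non_auto <- if (autosomes_only)
    !(stats$chrom %in% as.character(1:22)) else rep(FALSE, nrow(stats))
  indel <- if (drop_indels) stats$is_indel else rep(FALSE, nrow(stats))
  drop <- undefined | low_maf | low_cr | low_hwe | non_auto | indel
  keep <- which(!drop)
  if (length(keep) == 0L)
    warning("no variants pass the QC filters")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE])
  attr(out, "removed") <- c(
    undefined = sum(undefined), maf = sum(low_maf), call_rate = sum(low_cr),
    hwe = sum(low_hwe), non_autosomal = sum(non_auto), indel = sum(indel)
  )
  out
}

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' Computed over pairwise-complete samples. Pairs where either dosage vector
#' has zero variance are undefined and reported as `NA` (treated as not
#' linked by [ld_prune()] and [clump_loci()]).
#'
#' @param g A [genotype_matrix()].
#' @param i,j Variant indices or ids.
#' @return Squared correlation in \[0, 1\], or `NA` if undefined.
#' @export
ld_r2 <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$variants$id)
  if (is.character(j)) j <- match(j, g$variants$id)
  x <- g$dosages[, i]
  y <- g$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` consecutive variants, pairs with
#' `r^2 > r2_max` are resolved by removing the later-positioned variant;
#' the window then advances by `step` variants. The result is a set in
#' which no retained pair within any window exceeds `r2_max`. Deterministic.
#'
#' @param g A filtered [genotype_matrix()].
#' @param r2_max LD threshold (default 0.5).
#' @param window,step Window size and step in variant counts (defaults
#'   50 / 5).
#' @return Integer indices (into `g`) of the retained variants.
#' @export
ld_prune <- function(g, r2_max = 0.5, window = 50L, step = 5L) {
  v <- ncol(g$dosages)
  keep <- rep(TRUE, v)
  if (v < 2L) return(which(keep))
  start <- 1L
  repeat {
    end <- min(start + window - 1L, v)
    idx <- start:end
    for (a in idx) {
      if (!keep[a]) next
      for (b in idx[idx > a]) {
        if (!keep[b]) next
        r2 <- ld_r2(g, a, b)
        if (!is.na(r2) && r2 > r2_max) keep[b] <- FALSE
      }
    }
    if (end >= v) break
    start <- start + step
  }
  which(keep)
}

#' Top genomic principal components
#'
#' Missing dosages are mean-imputed per variant, columns are standardized
#' (zero mean, unit variance; zero-variance variants are dropped), and the
#' top `k` principal components of the standardized matrix are returned.
#' The sign of each component is fixed by making its largest-magnitude
#' variant loading positive.
#'
#' @param g A pruned, filtered [genotype_matrix()].
#' @param k Number of components (default 10); silently truncated with a
#'   warning if it exceeds the matrix rank.
#' @return Samples x k matrix of scores (columns `PC1..PCk`).
#' @export
compute_pcs <- function(g, k = 10L) {
  dos <- g$dosages
  for (j in seq_len(ncol(dos))) {
    miss <- is.na(dos[, j])
    if (any(miss)) dos[miss, j] <- mean(dos[, j], na.rm = TRUE)
  }
  sds <- apply(dos, 2L, stats::sd)
  keepv <- sds > 0
  z <- scale(dos[, keepv, drop = FALSE])
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  kmax <- sum(pr$sdev > 1e-8)
  if (k > kmax) {
    warning("k = ", k, " exceeds rank; returning ", kmax, " components")
    k <- kmax
  }
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- pr$x[, seq_len(k), drop = FALSE] %*% diag(flip, k, k)
  dimnames(scores) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  scores
}

#' Genomic relationship matrix
#'
#' GCTA-style estimator: entry (j, k) averages, over variants called in both
#' samples, `(x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))` with `p_i`
#' the sample alternate-allele frequency of variant i. Missing dosages are
#' handled by per-pair averaging over jointly called variants; monomorphic
#' variants are excluded from the sum.
#'
#' @param g A pruned, filtered [genotype_matrix()].
#' @return A list of class `relationship_matrix`: `values` (samples x
#'   samples, symmetric) and `n_variants_used`.
#' @export
compute_grm <- function(g) {
  dos <- g$dosages
  called <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * called)
  poly <- is.finite(p) & p > 0 & p < 1
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(dos, 2L, 2 * p, `-`)
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(w)
  w[!obs] <- 0
  counts <- tcrossprod(obs * 1)
  values <- tcrossprod(w) / counts
  values[counts == 0L] <- NA_real_
  dimnames(values) <- list(g$sample_ids, g$sample_ids)
  structure(list(values = values, n_variants_used = ncol(dos)),
            class = "relationship_matrix")
}
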