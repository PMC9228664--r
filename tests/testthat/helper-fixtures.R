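# shared fixture builders and independent oracles

# genotype_matrix from a plain dosage matrix, all on one autosome
make_geno <- function(dos, chrom = "1", pos = NULL, is_indel = NULL) {
  v <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(v) * 1000L
  if (is.null(is_indel)) is_indel <- rep(FALSE, v)
  genotype_matrix(dos, data.frame(
    chrom = rep_len(chrom, v), pos = pos, id = sprintf("v%03d", seq_len(v)),
    ref = "A", alt = "G", is_indel = is_indel, stringsAsFactors = FALSE))
}

# metabolite_panel from an abundance matrix (NA = not detected)
make_panel <- function(ab) {
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("S%04d", seq_len(nrow(ab)))
  if (is.null(colnames(ab))) colnames(ab) <- LETTERS[seq_len(ncol(ab))]
  structure(list(abundances = ab, detected = !is.na(ab),
                 meta = data.frame(name = colnames(ab)),
                 batch = NULL, latent_log = NULL),
            class = "metabolite_panel")
}

# independent HWE oracle: full enumeration with closed-form log-factorial
# conditional probabilities (no recurrence)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  na <- 2L * n_aa + n_ab
  if (na == 0L || na == 2L * n) return(1)
  hets <- seq(na %% 2L, min(na, 2L * n - na), by = 2L)
  lp <- vapply(hets, function(h) {
    hom_a <- (na - h) / 2
    hom_b <- (2 * n - na - h) / 2
    lfactorial(n) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b) +
      h * log(2) + lfactorial(na) + lfactorial(2L * n - na) -
      lfactorial(2L * n)
  }, numeric(1))
  probs <- exp(lp)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# exhaustive greedy LD-pruning oracle over the full variant set (single
# window covering everything): literal restatement of the removal rule
prune_oracle <- function(g, r2_max) {
  v <- ncol(g$dosages)
  keep <- rep(TRUE, v)
  for (a in seq_len(v)) {
    if (!keep[a]) next
    for (b in seq_len(v)) {
      if (b <= a || !keep[b]) next
      r2 <- suppressWarnings(stats::cor(g$dosages[, a], g$dosages[, b],
                                        use = "pairwise.complete.obs")^2)
      if (!is.na(r2) && r2 > r2_max) keep[b] <- FALSE
    }
  }
  which(keep)
}

# brute-force nearest-gene oracle: scan every interval
nearest_oracle <- function(pos, chrom, genes) {
  on_chr <- genes[genes$chrom == chrom, , drop = FALSE]
  d <- vapply(seq_len(nrow(on_chr)), function(i) {
    if (pos >= on_chr$start[i] && pos <= on_chr$end[i]) return(0)
    min(abs(pos - on_chr$start[i]), abs(pos - on_chr$end[i]))
  }, numeric(1))
  list(names = on_chr$name[d == min(d)], dist = min(d))
}

# exhaustive greedy clumping oracle
clump_oracle <- function(hits, genotypes, r2_thresh) {
  hits <- hits[order(hits$p, hits$chrom, hits$pos), , drop = FALSE]
  vidx <- match(hits$variant, genotypes$variants$id)
  left <- seq_len(nrow(hits))
  loci <- list()
  while (length(left) > 0L) {
    lead <- left[1L]
    grab <- lead
    for (o in left[-1L]) {
      if (hits$chrom[o] != hits$chrom[lead]) next
      r2 <- suppressWarnings(
        stats::cor(genotypes$dosages[, vidx[lead]],
                   genotypes$dosages[, vidx[o]],
                   use = "pairwise.complete.obs")^2)
      if (!is.na(r2) && r2 >= r2_thresh) grab <- c(grab, o)
    }
    loci[[length(loci) + 1L]] <- hits$variant[grab]
    left <- setdiff(left, grab)
  }
  loci
}
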