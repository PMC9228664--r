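#' Per-variant ordinary least squares association
#'
#' Regresses a (log-scale) trait on additive allele dosage plus covariates
#' and an intercept, over complete cases of (trait, covariates, genotype);
#' missing dosages drop the sample, never imputed. The effect is per
#' alternate allele on the trait scale; the two-sided p-value comes from the
#' t distribution on the residual degrees of freedom, floored at the
#' smallest positive representable number. Variants that are monomorphic
#' within the analysis subset are flagged untestable (`NA` statistics).
#'
#' @param trait Named numeric vector (names = sample ids), `NA` where the
#'   trait is undefined.
#' @param dosage Named numeric dosage vector (0/1/2, `NA` missing).
#' @param covariates Numeric matrix with sample-id rownames, or `NULL`.
#' @return One-row data frame: `n_used`, `beta`, `se`, `p`, `testable`.
#' @export
ols_association <- function(trait, dosage, covariates = NULL) {
  ids <- names(trait)
  if (is.null(ids)) stop("trait must be a named vector of sample ids")
  g <- dosage[ids]
  C <- if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE]
  ok <- is.finite(trait) & is.finite(g)
  if (!is.null(C)) ok <- ok & rowSums(!is.finite(C)) == 0L
  y <- trait[ok]; gg <- g[ok]
  X <- if (is.null(C)) cbind(intercept = 1, dosage = gg)
       else cbind(intercept = 1, C[ok, , drop = FALSE], dosage = gg)
  .ols_fit(y, X)
}

.ols_fit <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  gg <- X[, p]
  if (n < p + 2L || stats::var(gg) == 0)
    return(data.frame(n_used = n, beta = NA_real_, se = NA_real_,
                      p = NA_real_, testable = FALSE))
  qr_x <- qr(X)
  if (qr_x$rank < p)
    return(data.frame(n_used = n, beta = NA_real_, se = NA_real_,
                      p = NA_real_, testable = FALSE))
  coef <- qr.coef(qr_x, y)
  res <- y - X %*% coef
  df <- n - p
  s2 <- sum(res^2) / df
  xtx_inv_pp <- chol2inv(qr.R(qr_x))[p, p]
  se <- sqrt(s2 * xtx_inv_pp)
  beta <- coef[p]
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval <- max(pval, .Machine$double.xmin)
  data.frame(n_used = n, beta = beta, se = se, p = pval, testable = TRUE)
}

#' REML variance components for a one-component mixed model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 A)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, profiling the
#' likelihood over the variance ratio `delta = sigma_g^2 / sigma_e^2` on the
#' eigenbasis of `A` (the standard efficient scheme for a single dense
#' relationship matrix). `sigma_g^2` may hit the zero boundary, in which
#' case the model collapses to OLS.
#'
#' @param y Response vector (complete cases only).
#' @param X Fixed-effect design matrix (with intercept).
#' @param A Relationship matrix restricted to the same samples.
#' @return List: `sigma_g2`, `sigma_e2`, `delta`, plus the eigenbasis
#'   (`U`, `d`) and rotated data (`yt`, `Xt`) for reuse in per-variant
#'   generalized least squares.
#' @export
reml_variance_components <- function(y, X, A) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(A) == n, ncol(A) == n)
  ed <- eigen(A, symmetric = TRUE)
  U <- ed$vectors
  d <- pmax(ed$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  reml_nll <- function(log_delta) {
    delta <- exp(log_delta)
    winv <- delta * d + 1
    w <- 1 / winv
    xtwx <- crossprod(Xt, Xt * w)
    b <- solve(xtwx, crossprod(Xt, yt * w))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * log(s2) + sum(log(winv)) +
             determinant(xtwx, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(reml_nll, interval = c(-12, 12))
  # compare against the OLS boundary (delta -> 0)
  delta <- if (reml_nll(-30) <= opt$objective) 0 else exp(opt$minimum)
  w <- 1 / (delta * d + 1)
  xtwx <- crossprod(Xt, Xt * w)
  b <- solve(xtwx, crossprod(Xt, yt * w))
  r <- yt - Xt %*% b
  s2 <- sum(w * r^2) / (n - p)
  list(sigma_g2 = delta * s2, sigma_e2 = s2, delta = delta,
       U = U, d = d, yt = yt, Xt = Xt)
}

#' Per-variant mixed-model association (MLMA scheme)
#'
#' Variance components are estimated once per trait under the covariate-only
#' null model ([reml_variance_components()]); each variant is then tested by
#' generalized least squares under the fitted covariance — the standard
#' mixed-linear-model association scheme. With `A = I` the procedure reduces
#' exactly to [ols_association()]. P-values use the t distribution on the
#' residual degrees of freedom, the same convention as the OLS engine. If
#' the REML fit fails, the function falls back to OLS and flags the result.
#'
#' @inheritParams ols_association
#' @param grm A `relationship_matrix` from [compute_grm()] covering the
#'   analysis samples.
#' @param vc Optional precomputed [reml_variance_components()] fit for this
#'   trait's complete-case set (must match exactly); computed if `NULL`.
#' @return One-row data frame: `n_used`, `beta`, `se`, `p`, `testable`,
#'   `sigma_g2`, `sigma_e2`, `reml_ok`.
#' @export
lmm_association <- function(trait, dosage, covariates = NULL, grm, vc = NULL) {
  ids <- names(trait)
  g <- dosage[ids]
  C <- if (is.null(covariates)) NULL else covariates[ids, , drop = FALSE]
  ok <- is.finite(trait) & is.finite(g)
  if (!is.null(C)) ok <- ok & rowSums(!is.finite(C)) == 0L
  use <- ids[ok]
  y <- trait[ok]; gg <- g[ok]
  X0 <- if (is.null(C)) cbind(intercept = rep(1, sum(ok)))
        else cbind(intercept = 1, C[ok, , drop = FALSE])
  if (stats::var(gg) == 0 || length(y) < ncol(X0) + 3L)
    return(data.frame(n_used = length(y), beta = NA_real_, se = NA_real_,
                      p = NA_real_, testable = FALSE, sigma_g2 = NA_real_,
                      sigma_e2 = NA_real_, reml_ok = NA))
  if (is.null(vc)) {
    A <- grm$values[use, use, drop = FALSE]
    vc <- tryCatch(reml_variance_components(y, X0, A), error = function(e) NULL)
  }
  if (is.null(vc)) {
    out <- .ols_fit(y, cbind(X0, dosage = gg))
    out$sigma_g2 <- NA_real_; out$sigma_e2 <- NA_real_; out$reml_ok <- FALSE
    warning("REML did not converge; fell back to OLS")
    return(out)
  }
  gt <- crossprod(vc$U, gg)
  w <- 1 / (vc$delta * vc$d + 1)
  Xt <- cbind(vc$Xt, dosage = gt)
  fit <- .wls_fit(vc$yt, Xt, w)
  cbind(fit, data.frame(sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                        reml_ok = TRUE))
}

.wls_fit <- function(y, X, w) {
  n <- length(y)
  p <- ncol(X)
  sw <- sqrt(w)
  fit <- .ols_fit(y * sw, X * sw)
  fit$n_used <- n
  fit
}

#' Run the full trait-by-variant association scan
#'
#' One result per testable (trait, variant) pair, complete-case per pair.
#' Untestable pairs (monomorphic in subset, insufficient samples) are
#' retained with `NA` statistics and counted in the `"untestable"`
#' attribute; errors never abort the scan. With `engine = "lmm"` the
#' variance components are estimated once per trait and reused across
#' variants.
#'
#' @param traits A `trait_matrix` from [build_traits()].
#' @param genotypes A [genotype_matrix()] (typically QC-filtered).
#' @param covariates Covariate matrix from [assemble_covariates()], or
#'   `NULL`.
#' @param engine `"ols"` (default) or `"lmm"`.
#' @param grm `relationship_matrix`, required for `engine = "lmm"`.
#' @return A `data.frame` with one row per (trait, variant): `trait`,
#'   `variant`, `chrom`, `pos`, `n_used`, `beta`, `se`, `p`, `testable`.
#' @export
run_gwas <- function(traits, genotypes, covariates = NULL,
                     engine = c("ols", "lmm"), grm = NULL) {
  engine <- match.arg(engine)
  if (engine == "lmm" && is.null(grm))
    stop("engine = 'lmm' requires a relationship matrix")
  tv <- traits$values
  ids <- rownames(tv)
  out <- vector("list", ncol(tv))
  for (t in seq_len(ncol(tv))) {
    trait <- tv[, t]
    names(trait) <- ids
    vc <- NULL
    vc_ok <- rep(FALSE, length(ids))
    if (engine == "lmm") {
      # variance components once per trait on its covariate-complete cases;
      # reused for variants fully called on that case set
      ok <- is.finite(trait)
      if (!is.null(covariates)) {
        C <- covariates[ids, , drop = FALSE]
        ok <- ok & rowSums(!is.finite(C)) == 0L
      }
      use <- ids[ok]
      X0 <- if (is.null(covariates)) cbind(intercept = rep(1, sum(ok)))
            else cbind(intercept = 1, covariates[use, , drop = FALSE])
      vc <- tryCatch(
        reml_variance_components(trait[use], X0,
                                 grm$values[use, use, drop = FALSE]),
        error = function(e) NULL)
      vc_ok <- ok
    }
    rows <- vector("list", ncol(genotypes$dosages))
    for (v in seq_len(ncol(genotypes$dosages))) {
      dosage <- genotypes$dosages[, v]
      reuse <- engine == "lmm" && !is.null(vc) &&
        !anyNA(dosage[vc_ok])
      res <- tryCatch(
        if (engine == "ols")
          ols_association(trait, dosage, covariates)
        else
          lmm_association(trait, dosage, covariates, grm,
                          vc = if (reuse) vc else NULL)[, 1:5],
        error = function(e)
          data.frame(n_used = 0L, beta = NA_real_, se = NA_real_,
                     p = NA_real_, testable = FALSE))
      rows[[v]] <- res
    }
    block <- do.call(rbind, rows)
    block$trait <- colnames(tv)[t]
    block$variant <- genotypes$variants$id
    block$chrom <- genotypes$variants$chrom
    block$pos <- genotypes$variants$pos
    out[[t]] <- block
  }
  res <- do.call(rbind, out)
  res <- res[, c("trait", "variant", "chrom", "pos", "n_used",
                 "beta", "se", "p", "testable")]
  res <- res[order(res$trait, res$chrom, res$pos), ]
  rownames(res) <- NULL
  attr(res, "untestable") <- sum(!res$testable)
  res
}

#' Write association results as a summary-statistics TSV
#'
#' Fixed column set (`trait`, `variant`, `chrom`, `pos`, `n_used`, `beta`,
#' `se`, `p`, `testable`), one header line, p-values in scientific
#' notation.
#'
#' @param results Data frame from [run_gwas()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(results, path) {
  out <- results
  out$p <- formatC(out$p, format = "e", digits = 6)
  out$p[out$p == " NA" | is.na(results$p)] <- "NA"
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
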