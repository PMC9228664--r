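#' Select samples by detected-metabolite count
#'
#' Keeps samples in which at least `min_detected` of the panel's metabolites
#' were detected. With a nine-metabolite panel and the default of 5, this is
#' the inclusion rule of a high-missingness drug-metabolite cohort: enough
#' of the pathway present to form informative ratios.
#'
#' @param panel A `metabolite_panel`.
#' @param min_detected Minimum number of detected metabolites (default 5).
#' @return Character vector of retained sample identifiers.
#' @export
select_samples <- function(panel, min_detected = 5L) {
  n_det <- rowSums(panel$detected)
  rownames(panel$abundances)[n_det >= min_detected]
}

#' Build single-metabolite and pairwise log-ratio traits
#'
#' For M metabolites, emits M single traits (natural log abundance) and
#' M(M-1)/2 ratio traits (log numerator minus log denominator), i.e.
#' `M + M(M-1)/2` traits in total — 45 for the nine-metabolite panel. Ratio
#' orientation is canonical: the metabolite earlier in the panel's column
#' order is the numerator (association p-values are orientation-invariant;
#' inverting a ratio only negates the trait). A single trait is defined for
#' a sample iff the metabolite was detected; a ratio trait iff both
#' components were. No imputation: analysis is complete-case per trait.
#'
#' @param panel A `metabolite_panel`.
#' @param samples Optional sample subset (e.g. from [select_samples()]).
#' @return A list of class `trait_matrix`: `values` (samples x traits, `NA`
#'   where undefined) and `info` (per-trait `trait`, `kind`, `numerator`,
#'   `denominator`).
#' @export
build_traits <- function(panel, samples = NULL) {
  ab <- panel$abundances
  if (!is.null(samples)) ab <- ab[samples, , drop = FALSE]
  if (any(!is.na(ab) & ab <= 0))
    stop("metabolite abundances must be positive where present")
  m <- ncol(ab)
  mnames <- colnames(ab)
  logs <- log(ab)
  n_ratio <- m * (m - 1L) / 2L
  values <- matrix(NA_real_, nrow(ab), m + n_ratio)
  info <- data.frame(trait = character(m + n_ratio), kind = "",
                     numerator = "", denominator = NA_character_,
                     stringsAsFactors = FALSE)
  values[, seq_len(m)] <- logs
  info$trait[seq_len(m)] <- mnames
  info$kind[seq_len(m)] <- "single"
  info$numerator[seq_len(m)] <- mnames
  t <- m
  if (m >= 2L) for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
    t <- t + 1L
    values[, t] <- logs[, i] - logs[, j]
    info$trait[t] <- paste0(mnames[i], "/", mnames[j])
    info$kind[t] <- "ratio"
    info$numerator[t] <- mnames[i]
    info$denominator[t] <- mnames[j]
  }
  dimnames(values) <- list(rownames(ab), info$trait)
  structure(list(values = values, info = info), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "traits (", sum(x$info$kind == "single"), "single,",
      sum(x$info$kind == "ratio"), "ratio )\n")
  invisible(x)
}

#' Assemble the covariate matrix for association testing
#'
#' Joins age and sex with the first k genomic principal components by
#' sample identifier. Samples missing from either source, or with any
#' missing covariate value, are dropped with a warning — the association
#' model requires complete covariates.
#'
#' @param covariates Data frame with `sample`, `age`, `sex`.
#' @param pcs Samples x k score matrix from [compute_pcs()] (rownames are
#'   sample ids); `NULL` for no genetic covariates.
#' @return Numeric matrix (samples x (2 + k)), rownames sample ids.
#' @export
assemble_covariates <- function(covariates, pcs = NULL) {
  base <- covariates[, c("age", "sex"), drop = FALSE]
  rownames(base) <- covariates$sample
  if (!is.null(pcs)) {
    common <- intersect(covariates$sample, rownames(pcs))
    dropped <- setdiff(covariates$sample, common)
    if (length(dropped) > 0L)
      warning(length(dropped), " sample(s) absent from the genotype-derived ",
              "principal components were dropped: ",
              paste(utils::head(dropped, 5L), collapse = ", "))
    out <- cbind(as.matrix(base[common, , drop = FALSE]),
                 pcs[common, , drop = FALSE])
  } else {
    out <- as.matrix(base)
  }
  incomplete <- rowSums(!is.finite(out)) > 0L
  if (any(incomplete)) {
    warning(sum(incomplete), " sample(s) with missing covariates dropped")
    out <- out[!incomplete, , drop = FALSE]
  }
  out
}
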