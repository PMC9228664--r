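#' Construct a genotype matrix container
#'
#' The central genotype container: a samples-by-variants dosage matrix with
#' values in \{0, 1, 2, NA\} (copies of the alternate allele) plus per-variant
#' metadata. Positions are 1-based as in VCF; variant ids must be unique and
#' the sample order is stable across every object derived from it.
#'
#' @param dosages Integer/numeric matrix, samples in rows, variants in
#'   columns; `NA` for missing calls.
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `is_indel`, one row per column of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns and variant rows differ")
  need <- c("chrom", "pos", "id", "ref", "alt", "is_indel")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique")
  bad <- dosages[!is.na(dosages) & !(dosages %in% c(0, 1, 2))]
  if (length(bad) > 0L)
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  colnames(dosages) <- variants$id
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = rownames(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat("metabolite_panel:", nrow(x$abundances), "samples x",
      ncol(x$abundances), "metabolites;",
      sum(!x$detected), "values below detection\n")
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.2, GT field) into a [genotype_matrix()]. Only biallelic
#' records are kept — multi-allelic records are skipped with a warning.
#' Half-calls (e.g. `./1`) and missing genotypes become `NA`; phased and
#' unphased separators are treated alike. Indel status is derived from the
#' REF/ALT allele lengths.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = variants, columns = samples; parse allele counts
  alleles1 <- substr(gt, 1L, 1L)
  alleles2 <- substr(gt, 3L, 3L)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt))
  ok <- alleles1 %in% c("0", "1") & alleles2 %in% c("0", "1")
  dos[ok] <- (alleles1 == "1")[ok] + (alleles2 == "1")[ok]
  dos <- t(dos)
  rownames(dos) <- colnames(gt)
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM[blank], ":", fix$POS[blank])
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
    ref = fix$REF, alt = fix$ALT,
    is_indel = nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCFv4.2 with a GT-only FORMAT, one record per variant,
#' positions in ascending order within each chromosome.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  ord <- order(g$variants$chrom, g$variants$pos)
  v <- g$variants[ord, , drop = FALSE]
  dos <- g$dosages[, ord, drop = FALSE]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=ratiogwas",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", g$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    calls <- gt_code[as.character(dos[, i])]
    calls[is.na(calls)] <- "./."
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
            "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a metabolite abundance table
#'
#' TSV with the sample identifier in the first column and one column per
#' metabolite. Empty fields mean "not detected" and become `NA` with
#' `detected = FALSE`; zeros are rejected because relative abundances are
#' strictly positive when present.
#'
#' @param path Path to the TSV.
#' @param meta Optional metabolite descriptor data frame (matched by name).
#' @return A `metabolite_panel`.
#' @export
read_metabolites <- function(path, meta = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "", data.table = FALSE)
  samples <- as.character(dt[[1L]])
  ab <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- samples
  if (any(!is.na(ab) & ab <= 0))
    stop("metabolite abundances must be positive where present")
  if (is.null(meta))
    meta <- data.frame(name = colnames(ab), stringsAsFactors = FALSE)
  structure(list(abundances = ab, detected = !is.na(ab), meta = meta,
                 batch = NULL, latent_log = NULL),
            class = "metabolite_panel")
}

#' Write a metabolite panel as TSV
#'
#' First column `sample`, then one column per metabolite; non-detected
#' values are written as empty fields (never zero).
#'
#' @param panel A `metabolite_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metabolites <- function(panel, path) {
  df <- data.frame(sample = rownames(panel$abundances),
                   panel$abundances, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' TSV with columns `sample`, `age`, `sex` (0/1).
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample", "age", "sex")
  if (!all(need %in% names(dt)))
    stop("covariate table must have columns: ", paste(need, collapse = ", "))
  dt$sample <- as.character(dt$sample)
  dt
}

#' Read a gene track from BED
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' internal 1-based inclusive convention (`start_1 = start + 1`,
#' `end_1 = end`), matching VCF coordinates.
#'
#' @param path Path to a BED file (>= 4 columns: chrom, start, end, name).
#' @return A data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `name`, `strand`, sorted by chromosome and start.
#' @export
read_bed_genes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) < 4L)
    stop("BED gene track needs at least 4 columns (chrom,start,end,name)")
  out <- data.frame(
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]) + 1L,
    end = as.integer(dt[[3L]]),
    name = as.character(dt[[4L]]),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "*",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene features from GFF3
#'
#' Keeps `gene` features only; coordinates in GFF3 are already 1-based
#' inclusive. The gene name is taken from the `Name=` attribute, falling
#' back to `ID=`.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame like [read_bed_genes()].
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9L && p[3L] == "gene",
                 logical(1))
  parts <- parts[keep]
  if (length(parts) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  out <- do.call(rbind, lapply(parts, function(p) {
    nm <- attr_field(p[9L], "Name")
    if (is.na(nm)) nm <- attr_field(p[9L], "ID")
    data.frame(chrom = p[1L], start = as.integer(p[4L]),
               end = as.integer(p[5L]), name = nm, strand = p[7L],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_bed <- function(genes, path) {
  # internal 1-based inclusive -> BED 0-based half-open
  df <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$name,
                   0L, genes$strand)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
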