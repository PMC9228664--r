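#' Clump suggestive associations into independent loci
#'
#' Greedy clumping per trait: repeatedly take the unassigned variant with
#' the smallest p-value as the index of a new locus (ties broken by
#' chromosome then position), absorb every unassigned variant on the same
#' chromosome whose LD with the index reaches `r2 >= r2_independence`, and
#' repeat until every suggestive variant is assigned. Index variants of
#' distinct loci therefore have pairwise `r^2` below the independence
#' threshold, and the loci partition the suggestive variants.
#'
#' @param hits Data frame of suggestive associations (one trait): columns
#'   `variant`, `chrom`, `pos`, `p` (and optionally `pgain`).
#' @param genotypes [genotype_matrix()] used for LD; must contain every hit.
#' @param r2_independence Independence threshold (default 0.1): variants
#'   with `r^2 >= r2_independence` to an index are absorbed into its locus.
#' @return List of `locus` objects: `index_variant`, `chrom`, `pos`, `p`,
#'   `pgain` (if supplied), `members` (character vector incl. the index).
#' @export
clump_loci <- function(hits, genotypes, r2_independence = 0.1) {
  if (nrow(hits) == 0L) return(list())
  ord <- order(hits$p, hits$chrom, hits$pos)
  hits <- hits[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(hits))
  vidx <- match(hits$variant, genotypes$variants$id)
  if (anyNA(vidx)) stop("hits contain variants absent from the genotypes")
  loci <- list()
  while (!all(assigned)) {
    lead <- which(!assigned)[1L]
    members <- lead
    for (other in which(!assigned)) {
      if (other == lead) next
      if (hits$chrom[other] != hits$chrom[lead]) next
      r2 <- ld_r2(genotypes, vidx[lead], vidx[other])
      if (!is.na(r2) && r2 >= r2_independence) members <- c(members, other)
    }
    assigned[members] <- TRUE
    loci[[length(loci) + 1L]] <- structure(
      list(index_variant = hits$variant[lead], chrom = hits$chrom[lead],
           pos = hits$pos[lead], p = hits$p[lead],
           pgain = if ("pgain" %in% names(hits)) hits$pgain[lead] else NA_real_,
           trait = if ("trait" %in% names(hits)) hits$trait[lead] else NA_character_,
           members = hits$variant[members]),
      class = "locus")
  }
  loci
}

#' Annotate a locus with its nearest gene(s)
#'
#' Distance from the index variant to a gene is 0 if the variant lies
#' inside the gene interval (1-based inclusive internal convention),
#' otherwise the distance to the nearest interval edge, strand-agnostic.
#' The gene(s) minimizing this distance on the variant's chromosome are
#' reported; on an exact tie all tied genes are returned. The signed
#' distance is negative when the variant lies upstream (left) of the gene
#' start and positive when downstream of its end.
#'
#' @param locus A `locus` from [clump_loci()], or any list with
#'   `index_variant`, `chrom`, `pos`.
#' @param genes Gene track data frame from [read_bed_genes()] /
#'   [read_gff3_genes()] (1-based inclusive coordinates).
#' @return The locus with `nearest_genes` (character vector) and
#'   `gene_distance` (signed bp, 0 inside) added; unannotated with a
#'   warning if the chromosome is absent from the track.
#' @export
nearest_gene <- function(locus, genes) {
  on_chr <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  if (nrow(on_chr) == 0L) {
    warning("no genes on chromosome ", locus$chrom, "; locus unannotated")
    locus$nearest_genes <- character()
    locus$gene_distance <- NA_real_
    return(locus)
  }
  p <- locus$pos
  dist <- ifelse(p >= on_chr$start & p <= on_chr$end, 0,
                 pmin(abs(p - on_chr$start), abs(p - on_chr$end)))
  dmin <- min(dist)
  hit <- which(dist == dmin)
  signed <- if (dmin == 0) 0 else {
    g1 <- hit[1L]
    if (p < on_chr$start[g1]) -dmin else dmin
  }
  locus$nearest_genes <- on_chr$name[hit]
  locus$gene_distance <- signed
  locus
}

#' Flag loci whose nearest gene is a pathway candidate
#'
#' Case-insensitive exact name matching of each locus's nearest gene(s)
#' against a supplied candidate list (e.g. the genes of a drug's metabolic
#' pathway). An empty candidate list flags nothing.
#'
#' @param loci List of annotated loci (after [nearest_gene()]).
#' @param candidate_genes Character vector of gene names.
#' @return The loci, each with a logical `candidate_gene_hit` added.
#' @export
candidate_crossref <- function(loci, candidate_genes) {
  cand <- toupper(trimws(candidate_genes))
  lapply(loci, function(l) {
    l$candidate_gene_hit <- length(cand) > 0L &&
      any(toupper(l$nearest_genes) %in% cand)
    l
  })
}

#' Tabulate annotated loci
#'
#' @param loci List of loci (annotated or not).
#' @return Data frame, one row per locus: `index_variant`, `chrom`, `pos`,
#'   `trait`, `p`, `pgain`, `n_members`, `members`, `nearest_genes`,
#'   `gene_distance`, `candidate_gene_hit`.
#' @export
loci_table <- function(loci) {
  if (length(loci) == 0L)
    return(data.frame(index_variant = character(), chrom = character(),
                      pos = integer(), trait = character(), p = numeric(),
                      pgain = numeric(), n_members = integer(),
                      members = character(), nearest_genes = character(),
                      gene_distance = numeric(),
                      candidate_gene_hit = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(loci, function(l) data.frame(
    index_variant = l$index_variant, chrom = l$chrom, pos = l$pos,
    trait = if (is.null(l$trait)) NA_character_ else l$trait,
    p = l$p, pgain = l$pgain, n_members = length(l$members),
    members = paste(l$members, collapse = ","),
    nearest_genes = if (is.null(l$nearest_genes)) NA_character_
                    else paste(l$nearest_genes, collapse = ","),
    gene_distance = if (is.null(l$gene_distance)) NA_real_
                    else l$gene_distance,
    candidate_gene_hit = if (is.null(l$candidate_gene_hit)) NA
                         else l$candidate_gene_hit,
    stringsAsFactors = FALSE)))
}
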