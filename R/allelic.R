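# Assignment of per-SNP pileup base counts to the maternal and paternal
# alleles of a hybrid sample, and aggregation to gene-level totals.

#' Assign base counts to parental alleles
#'
#' For each SNP, splits the sample's base counts into reads supporting the
#' maternal allele, the paternal allele, and "other" bases (matching
#' neither parental allele; typically sequencing error).  The cross
#' orientation declares which parent line is the mother of this sample:
#' with `maternal_line = "A"` the maternal base is `allele_a`, with `"B"`
#' it is `allele_b`.
#'
#' @param base_counts Data.frame from [read_base_counts()] (one sample).
#' @param snps SNP table from [read_snp_table()].
#' @param maternal_line `"A"` or `"B"`.
#' @return A data.frame with one row per SNP present in `base_counts`:
#'   `chrom`, `pos`, `maternal_reads`, `paternal_reads`, `other_reads`.
#'   Counts conserve the pileup total:
#'   maternal + paternal + other equals the summed base counts at the site.
#' @export
assign_alleles <- function(base_counts, snps, maternal_line = c("A", "B")) {
  maternal_line <- match.arg(maternal_line)
  if (!all(snps$allele_a %in% BASES) || !all(snps$allele_b %in% BASES)) {
    stop("SNP alleles must be one of A/C/G/T")
  }
  key_bc <- paste(base_counts$chrom, base_counts$pos)
  key_snp <- paste(snps$chrom, snps$pos)
  idx <- match(key_bc, key_snp)
  keep <- !is.na(idx)
  bc <- base_counts[keep, , drop = FALSE]
  sn <- snps[idx[keep], , drop = FALSE]
  cm <- as.matrix(bc[, paste0("count_", BASES)])
  total <- rowSums(cm)
  mat_allele <- if (maternal_line == "A") sn$allele_a else sn$allele_b
  pat_allele <- if (maternal_line == "A") sn$allele_b else sn$allele_a
  n <- nrow(bc)
  maternal <- cm[cbind(seq_len(n), match(mat_allele, BASES))]
  paternal <- cm[cbind(seq_len(n), match(pat_allele, BASES))]
  out <- data.frame(chrom = bc$chrom, pos = bc$pos,
                    maternal_reads = as.numeric(maternal),
                    paternal_reads = as.numeric(paternal),
                    other_reads = as.numeric(total - maternal - paternal),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sum allelic counts over the SNPs of each gene
#'
#' A SNP belongs to a gene iff its position lies within the gene's
#' `[start, end]` span (same chromosome).  SNPs overlapping more than one
#' gene (overlapping annotations) contribute to each, with a warning.
#' SNPs whose "other" fraction exceeds `max_other_frac` are treated as
#' unreliable (e.g. mismapping) and excluded from the gene sums.
#'
#' @param allelic_counts Data.frame from [assign_alleles()].
#' @param genes Gene models from [read_gene_models()].
#' @param max_other_frac Maximum tolerated fraction of non-parental bases
#'   at a SNP before it is excluded (default 0.2).
#' @return A data.frame with one row per gene (in `genes` order):
#'   `gene_id`, `M` (maternal total), `P` (paternal total), `n_snps`
#'   (number of SNPs contributing at least one assignable read).
#' @export
summarize_genes <- function(allelic_counts, genes, max_other_frac = 0.2) {
  ac <- allelic_counts
  total <- ac$maternal_reads + ac$paternal_reads + ac$other_reads
  reliable <- total == 0 | (ac$other_reads / pmax(total, 1)) <= max_other_frac
  ac <- ac[reliable, , drop = FALSE]
  M <- numeric(nrow(genes))
  P <- numeric(nrow(genes))
  n_snps <- integer(nrow(genes))
  if (nrow(ac) > 0 && nrow(genes) > 0) {
    snp_gr <- GenomicRanges::GRanges(ac$chrom,
                                     IRanges::IRanges(ac$pos, ac$pos))
    gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(genes$start,
                                                       genes$end))
    hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (anyDuplicated(qh)) {
      warning(sum(duplicated(qh)),
              " SNP(s) overlap multiple genes; counted in each")
    }
    if (length(qh) > 0) {
      informative <- (ac$maternal_reads + ac$paternal_reads)[qh] > 0
      agg <- rowsum(cbind(ac$maternal_reads[qh], ac$paternal_reads[qh],
                          as.numeric(informative)), sh)
      gi <- as.integer(rownames(agg))
      M[gi] <- agg[, 1]
      P[gi] <- agg[, 2]
      n_snps[gi] <- as.integer(agg[, 3])
    }
  }
  data.frame(gene_id = genes$gene_id, M = M, P = P, n_snps = n_snps,
             stringsAsFactors = FALSE)
}

#' Analyzability filter for reciprocal-cross gene summaries
#'
#' A gene is allelically analyzable when at least `min_reads` reads could
#' be assigned to a parental allele (M + P) in *each* direction of the
#' reciprocal cross.  Genes missing from either direction are
#' non-analyzable.
#'
#' @param summary_fwd,summary_rev Gene summaries from [summarize_genes()]
#'   for the forward and reciprocal samples.
#' @param min_reads Minimum assignable reads per direction (default 10,
#'   boundary inclusive).
#' @return A named logical vector over the union of gene ids.
#' @export
is_analyzable <- function(summary_fwd, summary_rev, min_reads = 10) {
  ids <- union(summary_fwd$gene_id, summary_rev$gene_id)
  ok_dir <- function(s) {
    v <- stats::setNames(rep(FALSE, length(ids)), ids)
    i <- match(s$gene_id, ids)
    v[i] <- (s$M + s$P) >= min_reads
    v
  }
  ok_dir(summary_fwd) & ok_dir(summary_rev)
}
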