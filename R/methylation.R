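# Bulk weighted methylation levels and gene-anchored metaprofiles.

#' Bulk weighted methylation level
#'
#' Weighted methylation: sum of methylated read counts divided by the sum
#' of total (methylated + unmethylated) counts over all sites of the
#' requested context covered by at least `min_depth` reads.
#'
#' @param cytosines Data.frame from [read_cytosine_report()].
#' @param context One of CG/CHG/CHH.
#' @param min_depth Minimum reads per site (default 5).
#' @return A fraction in `[0, 1]`, or NA if no site qualifies.
#' @export
bulk_level <- function(cytosines, context = c("CG", "CHG", "CHH"),
                       min_depth = 5) {
  context <- match.arg(context)
  x <- cytosines[cytosines$context == context, , drop = FALSE]
  depth <- x$meth + x$unmeth
  x <- x[depth >= min_depth, , drop = FALSE]
  if (nrow(x) == 0) return(NA_real_)
  sum(x$meth) / sum(x$meth + x$unmeth)
}

#' Gene-anchored methylation metaprofile
#'
#' Average methylation over a set of genes across fixed-width upstream
#' bins, length-scaled gene-body bins and fixed-width downstream bins
#' (default 2 kb flanks in 100-bp bins, 40 body bins).  Within each bin
#' of each gene the level is the weighted methylation over qualifying
#' sites; bins are then averaged across genes ignoring genes with no
#' covered site in that bin (`mode = "per_gene"`, the default), or read
#' counts are pooled across genes before the ratio (`mode = "pooled"`).
#' Minus-strand genes are flipped so bins always run 5' to 3'.
#'
#' @param cytosines Cytosine report data.frame.
#' @param genes Gene models.
#' @param gene_set Character vector of gene ids to profile (must be
#'   non-empty and present in `genes`).
#' @param context One of CG/CHG/CHH.
#' @param n_body_bins Number of scaled gene-body bins (default 40).
#' @param flank Flank width in bp (default 2000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param min_depth Minimum reads for a site to contribute (default 5).
#' @param mode Averaging mode, `"per_gene"` or `"pooled"`.
#' @return Data.frame with one row per bin: `bin` (1-based index across
#'   the profile), `region` (upstream/body/downstream), `level`
#'   (NA where no gene had coverage), `n_genes` (genes contributing).
#' @export
metaprofile <- function(cytosines, genes, gene_set,
                        context = c("CG", "CHG", "CHH"),
                        n_body_bins = 40, flank = 2000, flank_bin = 100,
                        min_depth = 5, mode = c("per_gene", "pooled")) {
  context <- match.arg(context)
  mode <- match.arg(mode)
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  g <- genes[genes$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(g) == 0) stop("no gene in gene_set matches the gene models")
  n_flank_bins <- as.integer(flank / flank_bin)
  n_bins <- 2L * n_flank_bins + n_body_bins
  region <- rep(c("upstream", "body", "downstream"),
                c(n_flank_bins, n_body_bins, n_flank_bins))

  x <- cytosines[cytosines$context == context, , drop = FALSE]
  x <- x[(x$meth + x$unmeth) >= min_depth, , drop = FALSE]
  meth_sum <- matrix(0, nrow(g), n_bins)
  total_sum <- matrix(0, nrow(g), n_bins)
  if (nrow(x) > 0) {
    site_gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
    reg_gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(pmax(g$start - flank, 1), g$end + flank))
    hits <- GenomicRanges::findOverlaps(site_gr, reg_gr,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh) > 0) {
      pos <- x$pos[qh]
      gs <- g$start[sh]
      ge <- g$end[sh]
      minus <- g$strand[sh] == "-"
      # reflect minus-strand genes so all run 5' -> 3'
      pos[minus] <- gs[minus] + ge[minus] - pos[minus]
      bin <- integer(length(qh))
      up <- pos < gs
      down <- pos > ge
      body <- !up & !down
      bin[up] <- pmax(n_flank_bins - floor((gs[up] - pos[up] - 1) /
                                             flank_bin), 1L)
      rel <- (pos[body] - gs[body]) / (ge[body] - gs[body] + 1)
      bin[body] <- n_flank_bins + pmin(floor(rel * n_body_bins) + 1L,
                                       n_body_bins)
      bin[down] <- n_flank_bins + n_body_bins +
        pmin(floor((pos[down] - ge[down] - 1) / flank_bin) + 1L,
             n_flank_bins)
      keep <- bin >= 1 & bin <= n_bins
      lin <- (bin[keep] - 1L) * nrow(g) + sh[keep]  # matrix linear index
      mm <- x$meth[qh][keep]
      tt <- (x$meth + x$unmeth)[qh][keep]
      agg <- rowsum(cbind(mm, tt), lin)
      lidx <- as.integer(rownames(agg))
      meth_sum[lidx] <- agg[, 1]
      total_sum[lidx] <- agg[, 2]
    }
  }
  covered <- total_sum > 0
  if (mode == "per_gene") {
    lev <- meth_sum / ifelse(covered, total_sum, NA)
    level <- colMeans(lev, na.rm = TRUE)
    level[colSums(covered) == 0] <- NA_real_
  } else {
    cs <- colSums(total_sum)
    level <- ifelse(cs > 0, colSums(meth_sum) / cs, NA_real_)
  }
  data.frame(bin = seq_len(n_bins), region = region, level = level,
             n_genes = colSums(covered))
}
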