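# Detection of genomic clusters of imprinted transcripts and spacing
# statistics.  A cluster is a maximal chain of imprinted transcripts in
# which consecutive members are at most max_span apart and every
# allelically analyzed gene lying between members is itself imprinted
# (non-analyzed genes, lacking informative SNPs or reads, do not break
# chains).

# Per-gene status vector aligned to a gene table (missing call = non_analyzed)
status_by_gene <- function(calls, genes) {
  st <- rep("non_analyzed", nrow(genes))
  i <- match(genes$gene_id, calls$gene_id)
  st[!is.na(i)] <- calls$status[i[!is.na(i)]]
  st
}

#' Find clusters of imprinted transcripts
#'
#' Scans each chromosome (genes sorted by start) and chains imprinted
#' transcripts — any stringency, coding or noncoding, either parental
#' direction — whenever (a) consecutive imprinted members are separated
#' by at most `max_span` (start-to-start) and (b) no allelically analyzed
#' non-imprinted (biallelic) gene lies between them.  Chains of at least
#' two members are reported.  With `rule = "span"` the chain's total
#' start-to-start span is additionally capped at `max_span`.
#'
#' @param calls Imprinting calls from [call_imprinting()].
#' @param genes Gene models sorted by (chrom, start); unsorted input is
#'   an error.
#' @param max_span Maximum separation in bp (default 1 Mb).
#' @param rule `"chain"` (default; pairwise gap rule) or `"span"`.
#' @return Data.frame with one row per cluster: `chrom`, `start`, `end`
#'   (span of member gene bodies), `n_members`, `n_maternal`,
#'   `n_paternal`, `members` (comma-separated gene ids in genomic order).
#' @export
find_clusters <- function(calls, genes, max_span = 1e6,
                          rule = c("chain", "span")) {
  rule <- match.arg(rule)
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  if (!identical(ord, seq_len(nrow(genes)))) {
    stop("genes must be sorted by (chrom, start)")
  }
  st <- status_by_gene(calls, genes)
  imprinted <- st %in% imprinted_statuses("any")
  blocking <- st == "biallelic"
  res <- list()
  close_chain <- function(chain_idx) {
    if (length(chain_idx) < 2) return(NULL)
    m <- genes[chain_idx, , drop = FALSE]
    s <- st[chain_idx]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
               n_members = nrow(m),
               n_maternal = sum(s %in% imprinted_statuses("any", "maternal")),
               n_paternal = sum(s %in% imprinted_statuses("any", "paternal")),
               members = paste(m$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    chain <- integer(0)
    blocked <- FALSE
    for (i in idx) {
      if (imprinted[i]) {
        extend <- length(chain) > 0 && !blocked &&
          (genes$start[i] - genes$start[chain[length(chain)]]) <= max_span
        if (extend && rule == "span") {
          extend <- (genes$start[i] - genes$start[chain[1]]) <= max_span
        }
        if (extend) {
          chain <- c(chain, i)
        } else {
          res[[length(res) + 1L]] <- close_chain(chain)
          chain <- i
        }
        blocked <- FALSE
      } else if (blocking[i]) {
        blocked <- TRUE
      }
    }
    res[[length(res) + 1L]] <- close_chain(chain)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_members = integer(),
                      n_maternal = integer(), n_paternal = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spacing of imprinted transcripts along the genome
#'
#' Start-to-start distances between consecutive imprinted transcripts
#' within each chromosome; chromosomes with fewer than two imprinted
#' transcripts contribute no distances.
#'
#' @param calls Imprinting calls.
#' @param genes Gene models.
#' @return A list with `mean_distance` (NA if no pair exists) and
#'   `distances` (numeric vector over all consecutive pairs).
#' @export
spacing_stats <- function(calls, genes) {
  st <- status_by_gene(calls, genes)
  g <- genes[st %in% imprinted_statuses("any"), , drop = FALSE]
  dists <- unlist(lapply(split(g$start, g$chrom), function(s) {
    if (length(s) < 2) return(numeric(0))
    diff(sort(s))
  }), use.names = FALSE)
  list(mean_distance = if (length(dists)) mean(dists) else NA_real_,
       distances = dists)
}

#' Cluster size distribution
#'
#' Fraction of clusters containing each number of imprinted transcripts,
#' plus the total membership and its maternal/paternal breakdown.
#'
#' @param clusters Data.frame from [find_clusters()].
#' @return A list with `distribution` (data.frame `size`, `n_clusters`,
#'   `percent`), `total_members`, `n_maternal`, `n_paternal`.  Empty
#'   input yields an empty distribution.
#' @export
cluster_size_distribution <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(list(distribution = data.frame(size = integer(),
                                          n_clusters = integer(),
                                          percent = numeric()),
                total_members = 0L, n_maternal = 0L, n_paternal = 0L))
  }
  tab <- table(clusters$n_members)
  dist <- data.frame(size = as.integer(names(tab)),
                     n_clusters = as.integer(tab),
                     percent = 100 * as.integer(tab) / nrow(clusters))
  list(distribution = dist,
       total_members = sum(clusters$n_members),
       n_maternal = sum(clusters$n_maternal),
       n_paternal = sum(clusters$n_paternal))
}
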