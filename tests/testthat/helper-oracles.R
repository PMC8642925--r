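# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# chi-square(1) survival function through the normal distribution:
# if Z ~ N(0,1) then Z^2 ~ chi-square(1), so P(X > x) = 2 * P(Z > sqrt(x)).
chisq1_sf_oracle <- function(x) 2 * pnorm(sqrt(x), lower.tail = FALSE)

# Benjamini-Hochberg by the defining formula: q_i = min_{j : p_j >= p_i}
# of p_j * m / rank_j, computed by explicit enumeration.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins, summing multinomial-free hypergeometric probabilities
# computed from factorials.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lp <- function(x) {
    # P(table with top-left = x) under fixed margins
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(xs, lp, numeric(1))
  min(1, sum(probs[probs <= lp(a) * (1 + 1e-7)]))
}

# Maximal-valid-subset cluster oracle: enumerate every contiguous window
# of the (chrom, start)-sorted gene list, keep windows that are valid
# clusters, and retain the maximal ones.  status is aligned to genes.
cluster_oracle <- function(genes, status, max_span = 1e6) {
  imp_set <- c("MEG", "PEG", "MNC", "PNC", "low_MEG", "low_PEG")
  out <- list()
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    st <- status[idx]
    starts <- genes$start[idx]
    n <- length(idx)
    valid <- list()
    for (i in seq_len(n)) {
      for (j in i:n) {
        win <- i:j
        imp <- win[st[win] %in% imp_set]
        if (length(imp) < 2) next
        if (!(st[i] %in% imp_set) || !(st[j] %in% imp_set)) next
        if (any(st[win] == "biallelic")) next
        if (any(diff(starts[imp]) > max_span)) next
        valid[[length(valid) + 1L]] <- genes$gene_id[idx[imp]]
      }
    }
    # keep maximal member sets only
    keep <- vapply(seq_along(valid), function(k) {
      !any(vapply(seq_along(valid), function(l) {
        l != k && all(valid[[k]] %in% valid[[l]]) &&
          length(valid[[l]]) > length(valid[[k]])
      }, logical(1)))
    }, logical(1))
    out <- c(out, unique(valid[keep]))
  }
  unique(out)
}

# All-pairs interval intersection oracle for gene +/- flank vs DMRs.
overlap_oracle <- function(genes, dmrs, flank = 2000) {
  vapply(seq_len(nrow(genes)), function(i) {
    gs <- max(genes$start[i] - flank, 1)
    ge <- genes$end[i] + flank
    any(dmrs$chrom == genes$chrom[i] &
          dmrs$start <= ge & dmrs$end >= gs)
  }, logical(1))
}

# Tiny gene-model builder: equally spaced single-chromosome genes.
make_genes <- function(starts, width = 1000, chrom = "chr1", strand = "+",
                       biotype = "coding", ids = NULL) {
  n <- length(starts)
  data.frame(
    gene_id = if (is.null(ids)) sprintf("g%02d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n), start = starts, end = starts + width - 1,
    strand = rep_len(strand, n), biotype = rep_len(biotype, n),
    stringsAsFactors = FALSE)
}

# Minimal imprinting-call table with given statuses for make_genes() genes.
make_calls <- function(genes, status) {
  data.frame(gene_id = genes$gene_id, status = status,
             stringsAsFactors = FALSE)
}

# Cytosine-report builder.
make_cytosines <- function(pos, meth, unmeth, context = "CG",
                           chrom = "chr1", strand = "+") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             strand = rep_len(strand, length(pos)),
             meth = rep_len(meth, length(pos)),
             unmeth = rep_len(unmeth, length(pos)),
             context = rep_len(context, length(pos)),
             stringsAsFactors = FALSE)
}

# Random genome of n genes with mixed statuses for cluster equivalence.
random_cluster_genome <- function(n = 50, chrom_len = 5e6) {
  starts <- sort(sample.int(chrom_len, n))
  genes <- make_genes(starts, width = 500)
  status <- sample(c("MEG", "PEG", "low_MEG", "low_PEG", "biallelic",
                     "non_analyzed"), n, replace = TRUE,
                   prob = c(0.1, 0.15, 0.05, 0.05, 0.25, 0.4))
  list(genes = genes, calls = make_calls(genes, status), status = status)
}
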