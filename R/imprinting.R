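# The core imprinting statistic: Pearson chi-square of gene-level
# maternal/paternal read totals against the triploid-endosperm 2m:1p
# dosage null, BH correction, and two-tier MEG/PEG classification.

# Status vocabulary ---------------------------------------------------------

#' Imprinting status labels
#'
#' Returns the status labels counted as imprinted at a given stringency
#' and parental direction.  High-stringency labels are MEG/PEG (coding)
#' and MNC/PNC (noncoding); low-stringency-only calls are low_MEG/low_PEG
#' regardless of biotype.
#'
#' @param stringency `"any"` (default), `"low"` (all imprinted calls,
#'   since high-stringency calls also satisfy the low-stringency rule) or
#'   `"high"`.
#' @param direction `"both"` (default), `"maternal"` or `"paternal"`.
#' @return Character vector of status labels.
#' @export
imprinted_statuses <- function(stringency = c("any", "low", "high"),
                               direction = c("both", "maternal", "paternal")) {
  stringency <- match.arg(stringency)
  direction <- match.arg(direction)
  mat_high <- c("MEG", "MNC")
  pat_high <- c("PEG", "PNC")
  mat <- switch(stringency, high = mat_high, c(mat_high, "low_MEG"))
  pat <- switch(stringency, high = pat_high, c(pat_high, "low_PEG"))
  switch(direction, maternal = mat, paternal = pat, both = c(mat, pat))
}

# Core test -----------------------------------------------------------------

#' Chi-square test of allele counts against the 2m:1p endosperm null
#'
#' Pearson chi-square (1 df, no continuity correction) of the observed
#' (maternal, paternal) read counts against expected proportions given by
#' the endosperm genome dosage (default 2 maternal : 1 paternal, i.e.
#' expected counts (2n/3, n/3) for n = M + P).  Two-tailed by
#' construction.  Genes with an expected cell count below 5 are flagged
#' (`small_expected`) but still tested.
#'
#' @param maternal,paternal Non-negative counts (vectors recycle).
#' @param dosage Length-2 maternal:paternal genome dosage, default
#'   `c(2, 1)`.
#' @return A data.frame with `statistic`, `p_value`, `small_expected`.
#' @export
chi2_two_to_one <- function(maternal, paternal, dosage = c(2, 1)) {
  n <- maternal + paternal
  if (length(n) == 0) {
    return(data.frame(statistic = numeric(), p_value = numeric(),
                      small_expected = logical()))
  }
  if (any(n == 0)) {
    stop("chi2_two_to_one requires maternal + paternal > 0; ",
         "pre-filter non-analyzable genes")
  }
  pm <- dosage[1] / sum(dosage)
  e_m <- n * pm
  e_p <- n * (1 - pm)
  stat <- (maternal - e_m)^2 / e_m + (paternal - e_p)^2 / e_p
  data.frame(statistic = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             small_expected = pmin(e_m, e_p) < 5)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of p-values.  NAs are
#' preserved and excluded from the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_q <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' High-stringency allelic-fraction thresholds
#'
#' The high-stringency rule requires the favorable allele to exceed the
#' non-favorable allele by a fold factor beyond the dosage expectation.
#' With dosage 2m:1p and fold 5 this gives a maternal-fraction threshold
#' of 2*5/(2*5 + 1) = 10/11 for MEGs and a paternal-fraction threshold of
#' 5*1/(2 + 5*1) = 5/7 for PEGs.  The thresholds are computed from `fold`
#' and `dosage`, not hard-coded.
#'
#' @param fold Fold excess of the favorable allele (default 5).
#' @param dosage Maternal:paternal genome dosage (default `c(2, 1)`).
#' @return Named numeric vector `meg_maternal`, `peg_paternal`.
#' @export
stringency_thresholds <- function(fold = 5, dosage = c(2, 1)) {
  c(meg_maternal = fold * dosage[1] / (fold * dosage[1] + dosage[2]),
    peg_paternal = fold * dosage[2] / (dosage[1] + fold * dosage[2]))
}

#' Classify genes as imprinted from reciprocal-cross evidence
#'
#' Low-stringency imprinting requires a significant deviation from the
#' dosage null in both cross directions (q below `q_threshold`) with a
#' consistent parental direction (maternal fraction above the null
#' fraction 2/3 in both directions for maternal calls, below in both for
#' paternal).  Genes significant in opposite directions across the two
#' crosses reflect genotype rather than parent-of-origin effects and are
#' labelled biallelic.  High-stringency calls additionally require the
#' allelic fraction to exceed the [stringency_thresholds()] strictly in
#' both directions; they are labelled MEG/PEG for coding genes and
#' MNC/PNC for noncoding ones.
#'
#' @param maternal_fraction_fwd,maternal_fraction_rev M/(M+P) per
#'   direction.
#' @param q_fwd,q_rev BH-adjusted chi-square q-values per direction.
#' @param biotype `"coding"` or `"noncoding"` per gene (recycled).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @param fold,dosage Passed to [stringency_thresholds()].
#' @return Character vector of statuses: MEG/PEG/MNC/PNC, low_MEG,
#'   low_PEG, or biallelic.
#' @export
classify_imprinting <- function(maternal_fraction_fwd, maternal_fraction_rev,
                                q_fwd, q_rev, biotype = "coding",
                                q_threshold = 0.05, fold = 5,
                                dosage = c(2, 1)) {
  n <- length(maternal_fraction_fwd)
  biotype <- rep_len(biotype, n)
  th <- stringency_thresholds(fold, dosage)
  null_frac <- dosage[1] / sum(dosage)
  sig <- q_fwd < q_threshold & q_rev < q_threshold
  mat_low <- sig & maternal_fraction_fwd > null_frac &
    maternal_fraction_rev > null_frac
  pat_low <- sig & maternal_fraction_fwd < null_frac &
    maternal_fraction_rev < null_frac
  mat_high <- mat_low & maternal_fraction_fwd > th[["meg_maternal"]] &
    maternal_fraction_rev > th[["meg_maternal"]]
  pat_high <- pat_low & (1 - maternal_fraction_fwd) > th[["peg_paternal"]] &
    (1 - maternal_fraction_rev) > th[["peg_paternal"]]
  status <- rep("biallelic", n)
  status[mat_low] <- "low_MEG"
  status[pat_low] <- "low_PEG"
  status[mat_high] <- ifelse(biotype[mat_high] == "noncoding", "MNC", "MEG")
  status[pat_high] <- ifelse(biotype[pat_high] == "noncoding", "PNC", "PEG")
  status
}

#' Call imprinted genes for one reciprocal cross pair
#'
#' Full gene-level imprinting analysis: applies the analyzability filter
#' (at least `min_reads` assignable reads in each direction, plus an
#' optional expressed-gene filter), tests each analyzable gene against
#' the 2m:1p null in both directions, adjusts p-values by
#' Benjamini-Hochberg within the family of analyzable genes per
#' direction, and classifies.
#'
#' @param summary_fwd,summary_rev Gene summaries from [summarize_genes()]
#'   for the two directions of one reciprocal cross.
#' @param genes Gene models (supplies the biotype); genes absent from the
#'   table default to coding.
#' @param q_threshold,fold,dosage See [classify_imprinting()].
#' @param min_reads See [is_analyzable()].
#' @param expressed_genes Optional character vector of gene ids passing
#'   an upstream expression filter (e.g. FPKM >= 1); genes outside it are
#'   non-analyzed.
#' @return A data.frame with one row per gene: `gene_id`, `status`
#'   (including `non_analyzed`), counts per direction, maternal
#'   fractions, chi-square statistics, p- and q-values.
#' @export
call_imprinting <- function(summary_fwd, summary_rev, genes = NULL,
                            q_threshold = 0.05, fold = 5, dosage = c(2, 1),
                            min_reads = 10, expressed_genes = NULL) {
  ids <- union(summary_fwd$gene_id, summary_rev$gene_id)
  pick <- function(s, col) {
    v <- stats::setNames(rep(0, length(ids)), ids)
    v[s$gene_id] <- s[[col]]
    v
  }
  out <- data.frame(gene_id = ids,
                    M_fwd = pick(summary_fwd, "M"),
                    P_fwd = pick(summary_fwd, "P"),
                    M_rev = pick(summary_rev, "M"),
                    P_rev = pick(summary_rev, "P"),
                    n_snps_fwd = pick(summary_fwd, "n_snps"),
                    n_snps_rev = pick(summary_rev, "n_snps"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  analyzable <- (out$M_fwd + out$P_fwd) >= min_reads &
    (out$M_rev + out$P_rev) >= min_reads
  if (!is.null(expressed_genes)) {
    analyzable <- analyzable & out$gene_id %in% expressed_genes
  }
  biotype <- rep("coding", nrow(out))
  if (!is.null(genes)) {
    i <- match(out$gene_id, genes$gene_id)
    biotype[!is.na(i)] <- genes$biotype[i[!is.na(i)]]
  }
  out$maternal_fraction_fwd <- out$M_fwd / pmax(out$M_fwd + out$P_fwd, 1)
  out$maternal_fraction_rev <- out$M_rev / pmax(out$M_rev + out$P_rev, 1)
  out$chi2_fwd <- out$chi2_rev <- NA_real_
  out$p_fwd <- out$p_rev <- NA_real_
  out$q_fwd <- out$q_rev <- NA_real_
  if (any(analyzable)) {
    tf <- chi2_two_to_one(out$M_fwd[analyzable], out$P_fwd[analyzable],
                          dosage)
    tr <- chi2_two_to_one(out$M_rev[analyzable], out$P_rev[analyzable],
                          dosage)
    out$chi2_fwd[analyzable] <- tf$statistic
    out$chi2_rev[analyzable] <- tr$statistic
    out$p_fwd[analyzable] <- tf$p_value
    out$p_rev[analyzable] <- tr$p_value
    out$q_fwd[analyzable] <- adjust_q(tf$p_value)
    out$q_rev[analyzable] <- adjust_q(tr$p_value)
  }
  out$status <- "non_analyzed"
  out$status[analyzable] <- classify_imprinting(
    out$maternal_fraction_fwd[analyzable],
    out$maternal_fraction_rev[analyzable],
    out$q_fwd[analyzable], out$q_rev[analyzable],
    biotype[analyzable], q_threshold = q_threshold,
    fold = fold, dosage = dosage)
  out$maternal_fraction_fwd[!analyzable] <- NA_real_
  out$maternal_fraction_rev[!analyzable] <- NA_real_
  cols <- c("gene_id", "status", "M_fwd", "P_fwd", "M_rev", "P_rev",
            "n_snps_fwd", "n_snps_rev", "maternal_fraction_fwd",
            "maternal_fraction_rev", "chi2_fwd", "chi2_rev",
            "p_fwd", "p_rev", "q_fwd", "q_rev")
  out[, cols]
}

#' Seed-coat marker contamination report
#'
#' Maternal seed-coat contamination inflates apparent maternal expression.
#' Given an FPKM table and ids of seed-coat-specific marker genes, reports
#' each marker's endosperm FPKM and whether it falls below the
#' contamination bound (markers expressed in clean endosperm should not
#' exceed it).
#'
#' @param fpkm Data.frame with a `gene_id` column and tissue columns.
#' @param marker_ids Character vector of seed-coat marker gene ids.
#' @param endosperm_col Name of the endosperm column.
#' @param max_fpkm Contamination bound (default 0.5).
#' @return Data.frame `gene_id`, `fpkm`, `clean` (NA fpkm for markers
#'   absent from the table).
#' @export
check_contamination_markers <- function(fpkm, marker_ids,
                                        endosperm_col = "endosperm",
                                        max_fpkm = 0.5) {
  if (!endosperm_col %in% names(fpkm)) {
    stop("no '", endosperm_col, "' column in fpkm table")
  }
  i <- match(marker_ids, fpkm$gene_id)
  v <- fpkm[[endosperm_col]][i]
  data.frame(gene_id = marker_ids, fpkm = v, clean = v < max_fpkm,
             stringsAsFactors = FALSE)
}
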