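# Downstream syntheses: imprinted-gene/DMR association, conservation of
# imprinting across species, and endosperm tissue-specificity subgroups.

#' Flag genes overlapping DMRs (gene body plus flanks)
#'
#' A gene is flagged for a DMR direction when its body extended by
#' `flank` bp on each side intersects a DMR of that direction (strict
#' flank: a DMR starting `flank + 1` bp away does not overlap).  When
#' `analyzed` spans are supplied (see [analyzed_regions()]), genes whose
#' extended span touches no analyzed methylated region are marked
#' unassessable and excluded from association counts.
#'
#' @param calls Imprinting calls.
#' @param genes Gene models.
#' @param dmrs DMRs from [call_dmrs()].
#' @param flank Flank width in bp (default 2000).
#' @param analyzed Optional data.frame of analyzed spans (`chrom`,
#'   `start`, `end`); NULL marks every gene assessable.
#' @return Data.frame per gene: `gene_id`, `status`, `assessable`,
#'   `endosperm_hypo`, `embryo_hypo` (logical overlap flags).
#' @export
gene_dmr_overlap <- function(calls, genes, dmrs, flank = 2000,
                             analyzed = NULL) {
  ext <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank, 1), genes$end + flank))
  flag <- function(intervals) {
    if (is.null(intervals) || nrow(intervals) == 0) {
      return(rep(FALSE, nrow(genes)))
    }
    gr <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
    IRanges::overlapsAny(ext, gr)
  }
  assessable <- if (is.null(analyzed)) rep(TRUE, nrow(genes)) else
    flag(analyzed)
  data.frame(
    gene_id = genes$gene_id,
    status = status_by_gene(calls, genes),
    assessable = assessable,
    endosperm_hypo = flag(dmrs[dmrs$direction == "endosperm_hypo", ,
                               drop = FALSE]),
    embryo_hypo = flag(dmrs[dmrs$direction == "embryo_hypo", ,
                            drop = FALSE]),
    stringsAsFactors = FALSE)
}

#' Fisher association between imprinting and DMR occurrence
#'
#' Two-sided Fisher exact test on the 2x2 table of
#' {imprinted, non-imprinted} x {has a DMR of the given direction within
#' gene +/- flank, lacks one}, over assessable analyzable genes.  The
#' positive DMR class defaults to endosperm-hypomethylated /
#' embryo-hypermethylated regions, the direction imprinting associates
#' with.
#'
#' @param overlap Data.frame from [gene_dmr_overlap()].
#' @param direction DMR direction column used as the positive class.
#' @param stringency Which calls count as imprinted (see
#'   [imprinted_statuses()]).
#' @return A list: `table` (2x2 matrix, rows imprinted/non-imprinted,
#'   cols with/without DMR), `odds_ratio` (conditional MLE; NA when a
#'   column margin is empty), `p_value`.
#' @export
association_test <- function(overlap,
                             direction = c("endosperm_hypo", "embryo_hypo"),
                             stringency = "any") {
  direction <- match.arg(direction)
  x <- overlap[overlap$assessable & overlap$status != "non_analyzed", ,
               drop = FALSE]
  imp <- x$status %in% imprinted_statuses(stringency)
  has <- x[[direction]]
  if (!any(imp) || all(imp)) {
    stop("degenerate margin: need at least one imprinted and one ",
         "non-imprinted assessable gene")
  }
  tab <- matrix(c(sum(imp & has), sum(imp & !has),
                  sum(!imp & has), sum(!imp & !has)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("imprinted", "non_imprinted"),
                                c("dmr", "no_dmr")))
  if (any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value)
}

#' Conservation of imprinting direction across species
#'
#' Given a homolog table mapping imprinted genes of other species to
#' local gene ids (homolog search performed upstream), computes per
#' species and foreign status the number of homologs that are allelically
#' analyzable here, how many are direction-concordant at low stringency
#' (any maternal call for a foreign MEG, any paternal call for a foreign
#' PEG), and how many are concordant at high stringency.
#'
#' @param homologs Data.frame with columns `species`,
#'   `foreign_gene_id`, `foreign_status` (MEG/PEG), `gene_id`.
#' @param calls Imprinting calls; homolog rows whose `gene_id` is absent
#'   or non-analyzed count as non-analyzable.
#' @return Data.frame per (species, foreign_status): `n_analyzable`,
#'   `n_concordant`, `pct_concordant`, `n_high_concordant`,
#'   `pct_high_concordant`.
#' @export
conservation_ratios <- function(homologs, calls) {
  st <- stats::setNames(calls$status, calls$gene_id)
  local <- st[homologs$gene_id]
  local[is.na(local)] <- "non_analyzed"
  analyzable <- local != "non_analyzed"
  dir_for <- function(foreign) {
    ifelse(foreign == "MEG", "maternal", "paternal")
  }
  conc <- mapply(function(s, d) s %in% imprinted_statuses("any", d),
                 local, dir_for(homologs$foreign_status))
  conc_high <- mapply(function(s, d) s %in% imprinted_statuses("high", d),
                      local, dir_for(homologs$foreign_status))
  uq <- unique(homologs[, c("species", "foreign_status")])
  out <- do.call(rbind, lapply(seq_len(nrow(uq)), function(i) {
    sel <- homologs$species == uq$species[i] &
      homologs$foreign_status == uq$foreign_status[i]
    n_an <- sum(analyzable[sel])
    n_c <- sum(conc[sel] & analyzable[sel])
    n_h <- sum(conc_high[sel] & analyzable[sel])
    data.frame(species = uq$species[i],
               foreign_status = uq$foreign_status[i],
               n_analyzable = n_an, n_concordant = n_c,
               pct_concordant = if (n_an > 0) 100 * n_c / n_an else NA_real_,
               n_high_concordant = n_h,
               pct_high_concordant = if (n_an > 0) 100 * n_h / n_an else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Endosperm specificity of imprinted genes
#'
#' Labels each imprinted gene with expression data as endosperm-specific
#' (endosperm FPKM at least `min_fpkm` and at least `endo_ratio` times
#' the maximum over all other tissues) or constitutive.  The labels
#' partition the imprinted genes found in the FPKM table.
#'
#' @param fpkm Data.frame with a `gene_id` column, an endosperm column
#'   and at least one other tissue column.
#' @param calls Imprinting calls.
#' @param endo_ratio Fold-excess over the best other tissue (default 4).
#' @param min_fpkm Minimum endosperm FPKM (default 1).
#' @param endosperm_col Name of the endosperm column.
#' @param stringency Which calls count as imprinted.
#' @return Data.frame `gene_id`, `status`, `label`
#'   (`endosperm_specific` / `constitutive`).
#' @export
tissue_specificity <- function(fpkm, calls, endo_ratio = 4, min_fpkm = 1,
                               endosperm_col = "endosperm",
                               stringency = "any") {
  if (!endosperm_col %in% names(fpkm)) {
    stop("no '", endosperm_col, "' column in fpkm table")
  }
  tissue_cols <- setdiff(names(fpkm), c("gene_id", endosperm_col))
  if (length(tissue_cols) == 0) stop("need at least one non-endosperm tissue")
  imp <- calls[calls$status %in% imprinted_statuses(stringency), ,
               drop = FALSE]
  x <- fpkm[fpkm$gene_id %in% imp$gene_id, , drop = FALSE]
  endo <- x[[endosperm_col]]
  other_max <- do.call(pmax, c(x[tissue_cols], list(0)))
  specific <- endo >= min_fpkm & endo >= endo_ratio * other_max
  data.frame(gene_id = x$gene_id,
             status = imp$status[match(x$gene_id, imp$gene_id)],
             label = ifelse(specific, "endosperm_specific", "constitutive"),
             stringsAsFactors = FALSE)
}
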