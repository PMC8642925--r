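# Sliding-window embryo/endosperm DMR detection: 200-bp windows stepped
# by 20 bp, pooled counts per tissue, two-sided Fisher exact test,
# BH correction across all tested windows of a context, then filtering
# (q < fdr AND |level difference| > min_diff) and merging of same-direction
# windows within merge_gap.

# Vectorized two-sided Fisher exact p for 2x2 tables (a,b;c,d), rows =
# tissues, cols = meth/unmeth.  Sums hypergeometric point probabilities
# not exceeding that of the observed table (with a relative tolerance for
# ties, as in stats::fisher.test).
fisher_p2 <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]
    m2 <- c[i] + d[i]
    k <- a[i] + c[i]
    if (m1 + m2 == 0) {
      out[i] <- NA_real_
      next
    }
    xs <- max(0, k - m2):min(k, m1)
    probs <- stats::dhyper(xs, m1, m2, k)
    p_obs <- stats::dhyper(a[i], m1, m2, k)
    out[i] <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  out
}

#' Fisher test of one methylation window
#'
#' Two-sided Fisher exact test on the 2x2 table of pooled methylated /
#' unmethylated counts in embryo versus endosperm, and the methylation
#' level difference (endosperm minus embryo).
#'
#' @param embryo_meth,embryo_unmeth Pooled embryo counts.
#' @param endosperm_meth,endosperm_unmeth Pooled endosperm counts.
#'   All arguments vectorize.
#' @return Data.frame with `p_value` and `level_diff`.  Windows where a
#'   tissue has zero total reads get NA (callers skip them; an
#'   uninformative window is not evidence of equality).
#' @export
window_test <- function(embryo_meth, embryo_unmeth,
                        endosperm_meth, endosperm_unmeth) {
  emb_tot <- embryo_meth + embryo_unmeth
  endo_tot <- endosperm_meth + endosperm_unmeth
  p <- fisher_p2(embryo_meth, embryo_unmeth,
                 endosperm_meth, endosperm_unmeth)
  p[emb_tot == 0 | endo_tot == 0] <- NA_real_
  diff <- ifelse(emb_tot > 0 & endo_tot > 0,
                 endosperm_meth / endo_tot - embryo_meth / emb_tot,
                 NA_real_)
  data.frame(p_value = p, level_diff = diff)
}

# Pool per-site counts of one tissue into tiled windows via cumulative
# sums.  pos must be sorted.  Returns meth/total/site sums per window.
pool_windows <- function(pos, meth, total, win_start, win_end) {
  o <- order(pos)
  pos <- pos[o]
  cm <- cumsum(meth[o])
  ct <- cumsum(total[o])
  cn <- cumsum(as.numeric(total[o] > 0))
  lo <- findInterval(win_start - 1, pos)
  hi <- findInterval(win_end, pos)
  at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
  list(meth = at(cm, hi) - at(cm, lo),
       total = at(ct, hi) - at(ct, lo),
       sites = at(cn, hi) - at(cn, lo))
}

# Tile and test windows for one context; internal engine behind
# call_dmrs().  Returns all tested windows with counts, p, q, diff.
test_windows <- function(embryo, endosperm, context = "CG",
                         window = 200, step = 20, phase = NULL) {
  emb <- embryo[embryo$context == context, , drop = FALSE]
  endo <- endosperm[endosperm$context == context, , drop = FALSE]
  chroms <- union(emb$chrom, endo$chrom)
  res <- list()
  for (chr in chroms) {
    e1 <- emb[emb$chrom == chr, , drop = FALSE]
    e2 <- endo[endo$chrom == chr, , drop = FALSE]
    cov1 <- e1[(e1$meth + e1$unmeth) > 0, , drop = FALSE]
    cov2 <- e2[(e2$meth + e2$unmeth) > 0, , drop = FALSE]
    if (nrow(cov1) == 0 || nrow(cov2) == 0) next
    first <- if (is.null(phase)) min(cov1$pos, cov2$pos) else phase
    last <- max(cov1$pos, cov2$pos)
    ws <- seq(first, last, by = step)
    we <- ws + window - 1
    p1 <- pool_windows(e1$pos, e1$meth, e1$meth + e1$unmeth, ws, we)
    p2 <- pool_windows(e2$pos, e2$meth, e2$meth + e2$unmeth, ws, we)
    keep <- p1$sites >= 1 & p2$sites >= 1
    if (!any(keep)) next
    res[[chr]] <- data.frame(
      chrom = chr, start = ws[keep], end = we[keep], context = context,
      embryo_meth = p1$meth[keep],
      embryo_unmeth = p1$total[keep] - p1$meth[keep],
      endosperm_meth = p2$meth[keep],
      endosperm_unmeth = p2$total[keep] - p2$meth[keep],
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), context = character(),
                      embryo_meth = numeric(), embryo_unmeth = numeric(),
                      endosperm_meth = numeric(),
                      endosperm_unmeth = numeric(), p_value = numeric(),
                      q_value = numeric(), level_diff = numeric(),
                      stringsAsFactors = FALSE))
  }
  w <- do.call(rbind, res)
  rownames(w) <- NULL
  wt <- window_test(w$embryo_meth, w$embryo_unmeth,
                    w$endosperm_meth, w$endosperm_unmeth)
  w$p_value <- wt$p_value
  w$level_diff <- wt$level_diff
  w <- w[!is.na(w$p_value), , drop = FALSE]
  w$q_value <- adjust_q(w$p_value)
  rownames(w) <- NULL
  w
}

# Merge significant same-direction windows within merge_gap (gap counted
# as bases strictly between intervals).
merge_windows <- function(sig, merge_gap = 200) {
  cols <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), context = character(),
                     direction = character(), n_windows = integer(),
                     min_q = numeric(), mean_diff = numeric(),
                     stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(cols)
  sig$direction <- ifelse(sig$level_diff < 0, "endosperm_hypo",
                          "embryo_hypo")
  out <- list()
  for (grp in split(sig, paste(sig$chrom, sig$direction))) {
    grp <- grp[order(grp$start), , drop = FALSE]
    cur_start <- grp$start[1]
    cur_end <- grp$end[1]
    members <- 1L
    qs <- grp$q_value[1]
    ds <- grp$level_diff[1]
    flush <- function() {
      data.frame(chrom = grp$chrom[1], start = cur_start, end = cur_end,
                 context = grp$context[1], direction = grp$direction[1],
                 n_windows = members, min_q = min(qs),
                 mean_diff = mean(ds), stringsAsFactors = FALSE)
    }
    if (nrow(grp) > 1) {
      for (i in 2:nrow(grp)) {
        if (grp$start[i] - cur_end - 1 <= merge_gap) {
          cur_end <- max(cur_end, grp$end[i])
          members <- members + 1L
          qs <- c(qs, grp$q_value[i])
          ds <- c(ds, grp$level_diff[i])
        } else {
          out[[length(out) + 1L]] <- flush()
          cur_start <- grp$start[i]
          cur_end <- grp$end[i]
          members <- 1L
          qs <- grp$q_value[i]
          ds <- grp$level_diff[i]
        }
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions between embryo and endosperm
#'
#' Tiles 200-bp windows every 20 bp (from each chromosome's first covered
#' cytosine unless `phase` fixes the origin), pools per-site counts per
#' tissue, tests each window with a two-sided Fisher exact test, adjusts
#' p-values by Benjamini-Hochberg across all tested windows of the
#' context, keeps windows with `q_value < fdr` AND
#' `|level_diff| > min_diff`, and merges same-direction significant
#' windows separated by at most `merge_gap` bases.  Windows lacking a
#' covered cytosine in either tissue are skipped, never counted as
#' evidence of no difference.  The direction label is `endosperm_hypo`
#' when endosperm is the less methylated tissue, else `embryo_hypo`;
#' opposite directions are never merged together.
#'
#' @param embryo,endosperm Cytosine reports
#'   (see [read_cytosine_report()]) on the same reference.
#' @param context Methylation context (default CG).
#' @param fdr BH q-value cutoff (default 0.01).
#' @param min_diff Minimum absolute methylation-level difference,
#'   in fractional units (default 0.30, strict inequality).
#' @param window,step Window size and slide step in bp (defaults 200/20).
#' @param merge_gap Maximum gap merged into one DMR (default 200 bp,
#'   inclusive).
#' @param phase Optional fixed tiling origin (1-based position).
#' @return Data.frame of DMRs: `chrom`, `start`, `end`, `context`,
#'   `direction`, `n_windows`, `min_q`, `mean_diff`.  The tested windows
#'   (with counts, p, q, diff) are attached as attribute `"windows"`.
#' @export
call_dmrs <- function(embryo, endosperm, context = c("CG", "CHG", "CHH"),
                      fdr = 0.01, min_diff = 0.30, window = 200,
                      step = 20, merge_gap = 200, phase = NULL) {
  context <- match.arg(context)
  w <- test_windows(embryo, endosperm, context, window, step, phase)
  sig <- w[w$q_value < fdr & abs(w$level_diff) > min_diff, , drop = FALSE]
  dmrs <- merge_windows(sig, merge_gap)
  attr(dmrs, "windows") <- w
  dmrs
}

#' Spans of analyzed methylated regions
#'
#' Merges the tested windows attached to a [call_dmrs()] result into
#' maximal covered spans: the regions where both tissues had covered
#' cytosines and a Fisher test was actually performed.  Used to decide
#' which genes are assessable in the imprinting/DMR association.
#'
#' @param dmrs Result of [call_dmrs()] (with its `"windows"` attribute).
#' @return Data.frame `chrom`, `start`, `end`.
#' @export
analyzed_regions <- function(dmrs) {
  w <- attr(dmrs, "windows")
  if (is.null(w) || nrow(w) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
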