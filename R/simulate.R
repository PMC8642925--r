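# Synthetic reciprocal-cross allele counts and embryo/endosperm
# methylomes with planted ground truth, emulating the study inputs:
# hybrid endosperm RNA-seq counts at parent-distinguishing SNPs with a
# 2m:1p biallelic baseline and planted MEGs/PEGs at extreme allelic
# fractions, and bisulfite cytosine reports with planted
# CG-hypomethylated-in-endosperm regions.

#' Simulate reciprocal-cross allele-specific expression data
#'
#' Lays out gene models on `n_chrom` chromosomes, assigns each gene a
#' true class (MEG / PEG / biallelic, with a noncoding biotype drawn
#' independently), places 1-8 parent-distinguishing SNPs per gene, and
#' draws per-SNP per-sample read counts: total depth negative-binomial,
#' a small fraction of reads miscalled to a non-parental base, and the
#' assignable remainder binomial with maternal probability 2/3 for
#' biallelic genes (the endosperm dosage expectation) or the configured
#' extreme for imprinted genes.  Reciprocal samples swap the parental
#' roles of the two lines while the parent-of-origin fractions stay
#' fixed, as true imprinting demands.  Both cross pairs share the same
#' parental SNP table (as if the same line pair were re-crossed).
#'
#' @param n_genes Number of genes (default 1000).
#' @param frac_meg,frac_peg Fractions of planted MEGs / PEGs (defaults
#'   0.05 / 0.10; must sum to at most 1).
#' @param frac_noncoding Fraction of genes flagged noncoding (default
#'   0.02), independent of imprinting class.
#' @param depth_mean,depth_dispersion Negative-binomial depth per SNP
#'   per sample: mean 100, dispersion 0.3 (size = 1/dispersion).
#' @param meg_maternal_fraction,peg_maternal_fraction True maternal
#'   fraction of assignable reads for planted MEGs / PEGs (defaults
#'   0.95 / 0.10, beyond the 10/11 and 1 - 5/7 high-stringency bounds).
#' @param error_rate Fraction of reads miscalled to a non-parental base
#'   (default 0.01).
#' @param snps_per_gene Integer vector sampled uniformly for the number
#'   of SNPs per gene (default `1:8`).
#' @param n_pairs Number of reciprocal cross pairs (default 2, giving
#'   four hybrid samples).
#' @param n_chrom Number of chromosomes (default 5).
#' @param seed Optional RNG seed; identical config + seed reproduces
#'   identical tables.
#' @return A list of class `ase_simulation`: `genes` (gene models),
#'   `snps` (SNP table), `counts` (named list of per-sample base-count
#'   data.frames), `samples` (sample sheet: `sample_id`, `pair`,
#'   `direction`, `maternal_line`), `truth` (per-gene `gene_id`, `class`,
#'   `biotype`, `maternal_fraction`), `params`.
#' @export
simulate_ase <- function(n_genes = 1000, frac_meg = 0.05, frac_peg = 0.10,
                         frac_noncoding = 0.02, depth_mean = 100,
                         depth_dispersion = 0.3,
                         meg_maternal_fraction = 0.95,
                         peg_maternal_fraction = 0.10,
                         error_rate = 0.01, snps_per_gene = 1:8,
                         n_pairs = 2, n_chrom = 5, seed = NULL) {
  if (frac_meg < 0 || frac_peg < 0 || frac_meg + frac_peg > 1) {
    stop("frac_meg and frac_peg must be non-negative and sum to at most 1")
  }
  if (!is.null(seed)) set.seed(seed)
  # gene layout: round-robin over chromosomes, cumulative spacing
  chrom <- sprintf("chr%d", rep_len(seq_len(n_chrom), n_genes))
  width <- sample(1000:3000, n_genes, replace = TRUE)
  gap <- sample(2000:20000, n_genes, replace = TRUE)
  start <- integer(n_genes)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(gap[i]) + c(0, cumsum(width[i])[-length(i)])
  }
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                      chrom = chrom, start = start,
                      end = start + width - 1L,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      biotype = ifelse(runif(n_genes) < frac_noncoding,
                                       "noncoding", "coding"),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  n_meg <- round(n_genes * frac_meg)
  n_peg <- round(n_genes * frac_peg)
  class <- sample(rep(c("MEG", "PEG", "biallelic"),
                      c(n_meg, n_peg, n_genes - n_meg - n_peg)))
  mat_frac <- c(MEG = meg_maternal_fraction, PEG = peg_maternal_fraction,
                biallelic = 2 / 3)[class]
  truth <- data.frame(gene_id = genes$gene_id, class = class,
                      biotype = genes$biotype,
                      maternal_fraction = as.numeric(mat_frac),
                      stringsAsFactors = FALSE)

  # SNPs: 1-8 per gene, distinct parental alleles, genotyping depth > 3
  k <- sample(snps_per_gene, n_genes, replace = TRUE)
  gidx <- rep(seq_len(n_genes), k)
  pos <- genes$start[gidx] +
    floor(runif(length(gidx)) * (genes$end - genes$start + 1)[gidx])
  allele_a <- sample(BASES, length(gidx), replace = TRUE)
  shift <- sample(1:3, length(gidx), replace = TRUE)
  allele_b <- BASES[((match(allele_a, BASES) - 1 + shift) %% 4) + 1]
  snps <- data.frame(chrom = genes$chrom[gidx], pos = as.integer(pos),
                     allele_a = allele_a, allele_b = allele_b,
                     depth = sample(10:60, length(gidx), replace = TRUE),
                     stringsAsFactors = FALSE)
  # avoid duplicate positions within a chromosome
  dup <- duplicated(paste(snps$chrom, snps$pos))
  snps <- snps[!dup, , drop = FALSE]
  gidx <- gidx[!dup]
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  gidx <- gidx[ord]
  rownames(snps) <- NULL

  samples <- do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    data.frame(sample_id = paste0(c("SY", "YS"), p),
               pair = p, direction = c("forward", "reciprocal"),
               maternal_line = c("A", "B"), stringsAsFactors = FALSE)
  }))
  f_true <- truth$maternal_fraction[gidx]
  counts <- lapply(seq_len(nrow(samples)), function(si) {
    n_snp <- nrow(snps)
    depth <- stats::rnbinom(n_snp, size = 1 / depth_dispersion,
                            mu = depth_mean)
    other <- stats::rbinom(n_snp, depth, error_rate)
    maternal <- stats::rbinom(n_snp, depth - other, f_true)
    paternal <- depth - other - maternal
    mat_allele <- if (samples$maternal_line[si] == "A") snps$allele_a else
      snps$allele_b
    pat_allele <- if (samples$maternal_line[si] == "A") snps$allele_b else
      snps$allele_a
    # route "other" reads to a base that is neither parental allele
    shift2 <- sample(1:3, n_snp, replace = TRUE)
    oth_allele <- BASES[((match(mat_allele, BASES) - 1 + shift2) %% 4) + 1]
    clash <- oth_allele == pat_allele
    oth_allele[clash] <- BASES[((match(oth_allele[clash], BASES) - 1 + 1)
                                %% 4) + 1]
    oth_allele[oth_allele == mat_allele] <-
      BASES[((match(mat_allele[oth_allele == mat_allele], BASES) + 1)
             %% 4) + 1]
    cm <- matrix(0, n_snp, 4, dimnames = list(NULL, BASES))
    cm[cbind(seq_len(n_snp), match(mat_allele, BASES))] <- maternal
    cm[cbind(seq_len(n_snp), match(pat_allele, BASES))] <- paternal
    cm[cbind(seq_len(n_snp), match(oth_allele, BASES))] <-
      cm[cbind(seq_len(n_snp), match(oth_allele, BASES))] + other
    data.frame(chrom = snps$chrom, pos = snps$pos,
               count_A = cm[, "A"], count_C = cm[, "C"],
               count_G = cm[, "G"], count_T = cm[, "T"],
               stringsAsFactors = FALSE)
  })
  names(counts) <- samples$sample_id
  structure(list(genes = genes, snps = snps, counts = counts,
                 samples = samples, truth = truth,
                 params = list(n_genes = n_genes, frac_meg = frac_meg,
                               frac_peg = frac_peg,
                               frac_noncoding = frac_noncoding,
                               depth_mean = depth_mean,
                               depth_dispersion = depth_dispersion,
                               meg_maternal_fraction = meg_maternal_fraction,
                               peg_maternal_fraction = peg_maternal_fraction,
                               error_rate = error_rate, n_pairs = n_pairs,
                               n_chrom = n_chrom, seed = seed)),
            class = "ase_simulation")
}

#' Simulate embryo and endosperm methylomes with planted hypo-DMRs
#'
#' Places cytosines of each context along one chromosome at the given
#' density, draws a per-site true methylation level from a beta
#' distribution around the context baseline (the same latent level for
#' both tissues, so the null holds outside planted regions), then draws
#' per-tissue counts binomially at Poisson-distributed depth.  Inside
#' planted regions the endosperm level is lowered by `delta`
#' (CG-hypomethylation in endosperm, the direction associated with
#' imprinting).  Regions can be placed over the 5' ends of supplied
#' genes (e.g. planted PEGs) or uniformly.
#'
#' @param chrom_length Chromosome length in bp (default 200 kb).
#' @param chrom Chromosome name.
#' @param site_density Named per-bp cytosine densities (defaults CG
#'   0.05, CHG 0.04, CHH 0.10).
#' @param baseline Named context baselines; defaults CG 0.84, CHG 0.68,
#'   CHH 0.05 (embryo bulk levels of the tissue pair being emulated).
#' @param precision Beta precision of per-site latent levels (default
#'   30).
#' @param depth Mean per-site read depth, Poisson (default 10).
#' @param n_regions Number of planted endosperm-hypo regions (default
#'   5); ignored when `regions` or `link_genes` is given.
#' @param region_length Planted region length in bp (default 600).
#' @param delta Endosperm level drop inside planted regions (default
#'   0.5; must exceed the DMR `min_diff` of 0.30 to be recoverable).
#' @param regions Optional explicit data.frame (`chrom`, `start`, `end`)
#'   of planted regions.
#' @param link_genes Optional gene-model data.frame; one region is
#'   planted over the 5' end of each of these genes.
#' @param contexts Contexts to simulate (default CG only).
#' @param seed Optional RNG seed.
#' @return A list of class `methylome_simulation`: `embryo`,
#'   `endosperm` (cytosine report data.frames), `regions` (planted
#'   truth), `params`.
#' @export
simulate_methylome <- function(chrom_length = 200000, chrom = "chr1",
                               site_density = c(CG = 0.05, CHG = 0.04,
                                                CHH = 0.10),
                               baseline = c(CG = 0.84, CHG = 0.68,
                                            CHH = 0.05),
                               precision = 30, depth = 10, n_regions = 5,
                               region_length = 600, delta = 0.5,
                               regions = NULL, link_genes = NULL,
                               contexts = "CG", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(regions)) {
    if (!is.null(link_genes) && nrow(link_genes) > 0) {
      regions <- data.frame(
        chrom = link_genes$chrom,
        start = ifelse(link_genes$strand == "-",
                       pmax(link_genes$end - region_length + 1, 1),
                       link_genes$start),
        stringsAsFactors = FALSE)
      regions$end <- regions$start + region_length - 1
    } else if (n_regions > 0) {
      # non-overlapping uniform placement with a safety margin
      slots <- floor(chrom_length / (3 * region_length))
      if (n_regions > slots) stop("too many regions for chrom_length")
      at <- sort(sample(seq_len(slots), n_regions)) * 3 * region_length -
        2 * region_length
      regions <- data.frame(chrom = chrom, start = at,
                            end = at + region_length - 1,
                            stringsAsFactors = FALSE)
    } else {
      regions <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), stringsAsFactors = FALSE)
    }
  }
  if (nrow(regions) > 0 &&
      any(regions$start < 1 | regions$end > chrom_length)) {
    stop("planted regions must lie within the chromosome")
  }
  mk <- function(ctx) {
    n <- stats::rpois(1, chrom_length * site_density[[ctx]])
    pos <- sort(sample.int(chrom_length, min(n, chrom_length)))
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    b <- baseline[[ctx]]
    lev <- stats::rbeta(length(pos), b * precision, (1 - b) * precision)
    in_region <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(regions))) {
      in_region <- in_region | (pos >= regions$start[i] &
                                  pos <= regions$end[i])
    }
    lev_endo <- lev
    lev_endo[in_region] <- pmax(lev[in_region] - delta, 0.02)
    d1 <- stats::rpois(length(pos), depth)
    d2 <- stats::rpois(length(pos), depth)
    m1 <- stats::rbinom(length(pos), d1, lev)
    m2 <- stats::rbinom(length(pos), d2, lev_endo)
    list(embryo = data.frame(chrom = chrom, pos = pos, strand = strand,
                             meth = m1, unmeth = d1 - m1, context = ctx,
                             stringsAsFactors = FALSE),
         endosperm = data.frame(chrom = chrom, pos = pos, strand = strand,
                                meth = m2, unmeth = d2 - m2, context = ctx,
                                stringsAsFactors = FALSE))
  }
  parts <- lapply(contexts, mk)
  bind <- function(which) {
    x <- do.call(rbind, lapply(parts, `[[`, which))
    x <- x[order(x$chrom, x$pos), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  if (nrow(regions) > 0) regions$direction <- "endosperm_hypo"
  structure(list(embryo = bind("embryo"), endosperm = bind("endosperm"),
                 regions = regions,
                 params = list(chrom_length = chrom_length,
                               site_density = site_density,
                               baseline = baseline, precision = precision,
                               depth = depth, region_length = region_length,
                               delta = delta, contexts = contexts,
                               seed = seed)),
            class = "methylome_simulation")
}

#' Write a simulated data set to a directory
#'
#' Serializes an [simulate_ase()] and/or [simulate_methylome()] result as
#' the plain-text formats the readers consume: SNP table, per-sample
#' base-count TSVs, gene models (GFF3), sample sheet, truth tables and
#' cytosine reports.
#'
#' @param ase `ase_simulation` object or NULL.
#' @param methylome `methylome_simulation` object or NULL.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(ase = NULL, methylome = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(ase)) {
    write_result_tsv(ase$snps, file.path(dir, "snps.tsv"))
    write_gene_models(ase$genes, file.path(dir, "genes.gff3"))
    write_result_tsv(ase$samples, file.path(dir, "samples.tsv"))
    write_result_tsv(ase$truth, file.path(dir, "ase_truth.tsv"))
    for (s in names(ase$counts)) {
      write_result_tsv(ase$counts[[s]],
                       file.path(dir, paste0("counts_", s, ".tsv")))
    }
  }
  if (!is.null(methylome)) {
    write_cytosine_report(methylome$embryo,
                          file.path(dir, "embryo.cytosine.tsv"))
    write_cytosine_report(methylome$endosperm,
                          file.path(dir, "endosperm.cytosine.tsv"))
    write_result_tsv(methylome$regions, file.path(dir, "dmr_truth.tsv"))
  }
  invisible(dir)
}
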