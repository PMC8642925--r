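# Imprinting/DMR association, conservation ratios, tissue specificity.

test_that("gene-DMR overlap respects the strict 2-kb flank", {
  genes <- make_genes(10000, width = 2000)
  calls <- make_calls(genes, "PEG")
  # DMR 500 bp beyond the gene end still inside the +2 kb window
  dmr_in <- data.frame(chrom = "chr1", start = 12500, end = 12700,
                       direction = "endosperm_hypo")
  expect_true(gene_dmr_overlap(calls, genes, dmr_in)$endosperm_hypo)
  # DMR starting 2001 bp upstream of the gene: no overlap
  dmr_out <- data.frame(chrom = "chr1", start = 7000, end = 7999,
                        direction = "endosperm_hypo")
  ov <- gene_dmr_overlap(calls, genes, dmr_out)
  expect_false(ov$endosperm_hypo)
  # boundary: a DMR ending exactly at start - 2000 does overlap
  dmr_edge <- data.frame(chrom = "chr1", start = 7500, end = 8000,
                         direction = "embryo_hypo")
  expect_true(gene_dmr_overlap(calls, genes, dmr_edge)$embryo_hypo)
})

test_that("overlap flags agree with the all-pairs oracle", {
  set.seed(23)
  genes <- make_genes(sort(sample.int(5e5, 100)), width = 1500)
  calls <- make_calls(genes, sample(c("PEG", "biallelic"), 100, TRUE))
  dmrs <- data.frame(chrom = "chr1",
                     start = sort(sample.int(5e5, 60)),
                     direction = sample(c("endosperm_hypo", "embryo_hypo"),
                                        60, TRUE))
  dmrs$end <- dmrs$start + sample(100:2000, 60, TRUE)
  ov <- gene_dmr_overlap(calls, genes, dmrs)
  for (dir in c("endosperm_hypo", "embryo_hypo")) {
    expect_equal(ov[[dir]],
                 overlap_oracle(genes, dmrs[dmrs$direction == dir, ]))
  }
})

test_that("genes outside analyzed methylated regions are unassessable", {
  genes <- make_genes(c(10000, 100000), width = 1000)
  calls <- make_calls(genes, c("PEG", "PEG"))
  analyzed <- data.frame(chrom = "chr1", start = 9000, end = 14000)
  ov <- gene_dmr_overlap(calls, genes, dmrs = analyzed[0, ],
                         analyzed = analyzed)
  expect_equal(ov$assessable, c(TRUE, FALSE))
})

test_that("association test builds the 2x2 table and matches the oracle", {
  ov <- data.frame(
    gene_id = sprintf("g%03d", 1:110),
    status = rep(c("MEG", "biallelic"), c(10, 100)),
    assessable = TRUE,
    endosperm_hypo = rep(c(TRUE, FALSE, TRUE, FALSE), c(2, 8, 5, 95)),
    embryo_hypo = FALSE)
  at <- association_test(ov)
  expect_equal(unname(at$table[1, ]), c(2, 8))   # 2 of 10 imprinted
  expect_equal(unname(at$table[2, ]), c(5, 95))
  expect_equal(at$p_value, fisher_enum_oracle(2, 8, 5, 95),
               tolerance = 1e-9)

  # large unbalanced table against the enumeration oracle
  ov2 <- data.frame(
    gene_id = seq_len(223 + 9000 + 167 + 100),
    status = rep(c("PEG", "biallelic"), c(223, 9267)),
    assessable = TRUE,
    endosperm_hypo = rep(c(TRUE, FALSE, TRUE, FALSE),
                         c(56, 167, 100, 9167)),
    embryo_hypo = FALSE)
  at2 <- association_test(ov2)
  expect_equal(at2$p_value, fisher_enum_oracle(56, 167, 100, 9167),
               tolerance = 1e-9)
  expect_gt(at2$odds_ratio, 1)

  # zero overlap everywhere: OR undefined, p = 1
  ov3 <- ov
  ov3$endosperm_hypo <- FALSE
  at3 <- association_test(ov3)
  expect_true(is.na(at3$odds_ratio))
  expect_equal(at3$p_value, 1)

  # degenerate margin: all genes imprinted
  ov4 <- ov
  ov4$status <- "MEG"
  expect_error(association_test(ov4), "degenerate")
})

test_that("conservation ratios count direction-concordant homologs", {
  calls <- data.frame(
    gene_id = sprintf("s%03d", 1:300),
    status = rep(c("MEG", "low_MEG", "PEG", "biallelic", "non_analyzed"),
                 c(20, 11, 14, 155, 100)))
  hom <- data.frame(
    species = "A. thaliana",
    foreign_gene_id = sprintf("AT%03d", 1:191),
    foreign_status = "MEG",
    gene_id = sprintf("s%03d", 1:191))
  # analyzable: ids s001-s191 minus the last 0 non-analyzed in range?
  # statuses: 1-20 MEG, 21-31 low_MEG, 32-45 PEG, 46-191 biallelic
  cr <- conservation_ratios(hom, calls)
  expect_equal(cr$n_analyzable, 191)
  expect_equal(cr$n_concordant, 31)               # MEG + low_MEG
  expect_equal(cr$pct_concordant, 100 * 31 / 191) # 16.2%
  expect_equal(cr$n_high_concordant, 20)

  # homolog ids absent from the calls count as non-analyzable
  hom2 <- rbind(hom, data.frame(species = "A. thaliana",
                                foreign_gene_id = "ATxxx",
                                foreign_status = "MEG",
                                gene_id = "missing"))
  expect_equal(conservation_ratios(hom2, calls)$n_analyzable, 191)

  # duplicating every row leaves percentages unchanged
  cr2 <- conservation_ratios(rbind(hom, hom), calls)
  expect_equal(cr2$pct_concordant, cr$pct_concordant)
  expect_equal(cr2$n_analyzable, 2 * cr$n_analyzable)
})

test_that("tissue specificity partitions imprinted genes by the 4x rule", {
  calls <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      status = c("MEG", "PEG", "biallelic", "MEG"))
  fpkm <- data.frame(gene_id = c("g1", "g2", "g3"),
                     endosperm = c(40, 40, 100),
                     leaf = c(2, 39, 1), root = c(5, 1, 1))
  ts <- tissue_specificity(fpkm, calls)
  expect_equal(ts$label[ts$gene_id == "g1"], "endosperm_specific")
  expect_equal(ts$label[ts$gene_id == "g2"], "constitutive")
  expect_false("g3" %in% ts$gene_id)   # not imprinted
  expect_false("g4" %in% ts$gene_id)   # no expression data
  expect_equal(nrow(ts), 2)            # labels partition imprinted genes

  # low endosperm expression cannot be endosperm-specific
  fpkm2 <- data.frame(gene_id = "g1", endosperm = 0.5, leaf = 0.01)
  expect_equal(tissue_specificity(fpkm2, calls)$label, "constitutive")
  expect_error(tissue_specificity(data.frame(gene_id = "g1", leaf = 1),
                                  calls), "endosperm")
})
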