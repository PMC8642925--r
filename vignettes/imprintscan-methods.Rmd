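---
title: "Calling imprinted genes and associated methylation differences in hybrid endosperm"
author: "imprintscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling imprinted genes and associated methylation differences in hybrid endosperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The biological problem and the model

Endosperm, the nutritive seed tissue of flowering plants, is triploid: it
inherits two genome copies from the mother and one from the father.  A gene
expressed from both parental alleles in proportion to gene dosage therefore
shows a 2:1 maternal:paternal ratio among RNA-seq reads that can be assigned
to a parent at parent-distinguishing SNPs.  Genomic imprinting — parent-of-
origin-dependent silencing — shows up as a departure from this 2m:1p null
that is *reproduced in both directions of a reciprocal cross*.  The
reciprocal design is essential: a genotype (cis-regulatory) effect follows
the allele, not the parent, and flips direction between the two crosses,
whereas true imprinting keeps the same parental direction in both.

For each gene the assignable reads are summed over its SNPs into maternal
and paternal totals $(M, P)$ per cross direction.  The test statistic is the
Pearson chi-square with one degree of freedom against expected counts
$(2n/3,\; n/3)$, $n = M + P$:

$$X^2 = \frac{(M - 2n/3)^2}{2n/3} + \frac{(P - n/3)^2}{n/3}
      = \tfrac{9}{2}\, n \left(\tfrac{M}{n} - \tfrac{2}{3}\right)^2 .$$

No continuity correction is applied; the test is two-tailed by construction.
P-values are converted to q-values by Benjamini–Hochberg within the family
of all analyzable genes of one cross pair and one direction.  Storey's
q-value estimator would also fit the description "P-values were converted
to Q-values"; BH was chosen as the more conservative and assumption-free
of the two.

Classification is two-tiered:

* **Low stringency** (`low_MEG` / `low_PEG`): q < 0.05 in *both* directions
  with a consistent parental direction — maternal fraction $M/n$ above the
  null fraction 2/3 in both directions (maternal) or below in both
  (paternal).  Genes significant in opposite directions are labelled
  biallelic, since that pattern indicates a genotype effect.
* **High stringency** (`MEG` / `PEG`, or `MNC` / `PNC` for noncoding
  transcripts): additionally, the favorable allele must exceed the
  unfavorable one at least five-fold beyond dosage in both directions.
  With dosage 2:1 and fold $f = 5$ the thresholds are
  $2f/(2f+1) = 10/11$ on the maternal fraction for MEGs and
  $f/(2+f) = 5/7$ on the paternal fraction for PEGs.  Both are strict
  inequalities and both are *computed* from `fold` and `dosage`
  (`stringency_thresholds()`), so the fold factor is tunable.

A gene is **analyzable** only if at least 10 parentally assignable reads
are available in *each* direction.  We read "at least 10 reads that could
be assigned to a particular allele" as $M + P \ge 10$ per direction, not 10
per allele — the per-allele reading would make every near-monoallelic
(i.e. imprinted) gene non-analyzable, which would contradict the design.
Reads matching neither parental allele ("other" bases, mostly sequencing
error) are excluded from $M$ and $P$; a SNP whose other-fraction exceeds
20% (configurable) is treated as unreliable (e.g. mismapping or a wrong
genotype call) and dropped from the gene sums.

A note on symmetry: because the null is asymmetric, swapping $M$ and $P$
does *not* leave the statistic unchanged.  The exact symmetry of the
procedure is a consistent relabelling of the parents — swapping the counts
*and* mirroring the dosage to 1:2 maps every MEG call to a PEG call — and
that is the invariance the test suite checks.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `min_depth` (SNP table) | 4 reads | `read_snp_table()` | genotyping depth > 3 per SNP |
| `min_reads` | 10 reads | `call_imprinting()` | assignable reads per direction |
| `q_threshold` | 0.05 | `call_imprinting()` | BH q cutoff, both directions |
| `fold` | 5 | `call_imprinting()` | high-stringency fold excess |
| `dosage` | 2:1 | throughout | endosperm genome dosage |
| `max_other_frac` | 0.2 | `summarize_genes()` | SNP reliability bound |
| `max_span` | 1 Mb | `find_clusters()` | cluster chaining distance |
| `min_depth` (methylation) | 5 reads | `bulk_level()`, `metaprofile()` | per-cytosine coverage |
| `window`, `step` | 200 / 20 bp | `call_dmrs()` | sliding-window geometry |
| `fdr`, `min_diff` | 0.01 / 0.30 | `call_dmrs()` | window significance and effect size |
| `merge_gap` | 200 bp | `call_dmrs()` | DMR merging distance |
| `flank` | 2000 bp | `gene_dmr_overlap()` | gene context for DMR overlap |

## Cluster detection

Imprinted transcripts (any stringency, either direction, coding or
noncoding) are chained along each chromosome: consecutive members may be at
most 1 Mb apart (start-to-start) and no allelically analyzable *biallelic*
gene may lie between members — non-analyzed genes, which simply lack
informative SNPs or reads, do not break a chain.  Chains of two or more
members are clusters.  "Within a region of 1 Mb" is implemented as this
pairwise chaining rule rather than a cap on the total chain span; the
strict-total-span variant is available with `rule = "span"`.  Distances in
`spacing_stats()` are start-to-start, since no gene anchor is canonical.
Clusters mixing maternal and paternal members are permitted.  Correctness
is checked against an exhaustive maximal-window enumeration oracle on
random small genomes.

## Methylation levels, metaprofiles and DMRs

All methylation levels are *weighted*: summed methylated reads over summed
total reads, never an unweighted mean of per-site fractions.  Bulk levels
use sites with at least 5 reads.  Gene metaprofiles use 2-kb flanks in
100-bp bins and 40 length-scaled body bins (binning is not dictated by the
underlying method description; these defaults are configurable), average
per gene first and then across genes (pooled-count mode by flag), and flip
minus-strand genes so profiles run 5′→3′.

DMRs between embryo and endosperm are called per context on 200-bp windows
stepped every 20 bp.  Windows tile from the first covered cytosine of each
chromosome (the tiling phase is configurable; no canonical origin exists).
Each window pools counts per tissue and is tested with a two-sided Fisher
exact test — implemented as a vectorized hypergeometric enumeration and
cross-checked against `stats::fisher.test` in the test suite.  Windows
lacking a covered cytosine in either tissue are skipped, not scored as
p = 1: absence of data is not evidence of equality.  BH correction runs
across all tested windows of the context; significant windows need
q < 0.01 *and* an absolute level difference above 0.30 — read as 30
percentage points, absolute, not a relative change.  Same-direction
significant windows separated by at most 200 bp (bases strictly between;
"within 200 bp" read inclusively) merge into one DMR; opposite directions
never merge.  The direction label is `endosperm_hypo` when endosperm is
the less methylated tissue — the direction that associates with
imprinting — and `embryo_hypo` otherwise.

## Downstream syntheses

`gene_dmr_overlap()` extends each gene body by 2 kb on both sides (strict
flank) and flags intersection per DMR direction; genes whose extended span
touches no *analyzed* methylated region (no tested window) are
unassessable and excluded from the association table.
`association_test()` is a two-sided Fisher exact test of
{imprinted, non-imprinted} × {has endosperm-hypo DMR, lacks one}.
`conservation_ratios()` counts homologs of foreign imprinted genes that
are analyzable here and direction-concordant, at low and high stringency
separately.  `tissue_specificity()` labels an imprinted gene
endosperm-specific when its endosperm FPKM is at least 1 and at least four
times the best other tissue; this 4×/FPKM ≥ 1 rule is this package's own
operational definition (no canonical criterion exists) and both constants
are arguments.  `check_contamination_markers()` reports whether seed-coat
marker genes stay below 0.5 FPKM in endosperm, the standard check that
maternal seed-coat tissue did not contaminate the dissection.

## What the synthetic data emulate — and what they do not

`simulate_ase()` reproduces the *statistical* structure of the study
inputs: negative-binomial sequencing depth per SNP (mean 100, dispersion
0.3 — chosen to produce a realistic heavy lower tail that stresses
low-count chi-square behavior), binomial allele sampling at maternal
fraction 2/3 for biallelic genes, 0.95 for planted MEGs and 0.10 for
planted PEGs (both beyond the high-stringency bounds in expectation, so
recovery is well-posed), 1–8 SNPs per gene, a 1% base-error rate routed to
non-parental bases, 2% noncoding genes to exercise MNC/PNC labelling, and
two reciprocal cross pairs (which share one SNP table — a simplification;
real line pairs have distinct SNP sets).  `simulate_methylome()` draws a
latent per-site level from a beta distribution around the context baseline
(CG 0.84, CHG 0.68, CHH 0.05 — endosperm/embryo bulk levels typical of
this tissue pair), shared between tissues so the no-DMR null holds
exactly, then binomial counts at Poisson depth; planted regions lower the
endosperm CG level by 0.5.

The generators do **not** model read-level alignment or mapping bias,
allele-specific methylation, maternal-tissue contamination, biological
replicates, overdispersion beyond the latent beta level, linked SNP
haplotypes, or bisulfite conversion failure.  Passing recovery tests
therefore demonstrates that the *statistical pipeline* is correct and
calibrated under its own model assumptions — not that those assumptions
hold in any particular real data set.

## Numerical choices and degenerate inputs

* `chi2_two_to_one()` refuses $n = 0$ (callers must pre-filter);
  expected-cell counts below 5 are flagged but tested.
* Fisher p-values sum point probabilities `<= p_obs * (1 + 1e-7)`, the
  same tie tolerance as `stats::fisher.test`.
* Empty p-value vectors adjust to empty; an all-zero 2×2 column margin
  yields p = 1 with an undefined odds ratio; a missing imprinted or
  non-imprinted margin is an error.
* Coordinates are 1-based inclusive everywhere in memory; only BED output
  converts to 0-based half-open.  Chromosome names match as exact strings.
* Ties in gene ordering are broken by `gene_id`; `find_clusters()`
  requires sorted input rather than silently re-sorting.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on generated
data: 1,000 genes at depth 100 for imprinting recovery; 10,000 null genes
for type-I calibration; a 200-kb chromosome at CG density 0.05 and depth
10 with eight planted 600-bp regions (and a matched region-free null) for
DMR recovery; one full simulated chromosome (~200 genes) with
endosperm-hypo regions planted at planted-PEG 5′ ends for the
imprinting/DMR association; 200 random 50-gene genomes for cluster-oracle
equivalence.
These sizes give stable Monte-Carlo estimates while keeping a full run in
well under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ase(n_genes = 1000, frac_meg = 0.05, frac_peg = 0.10,
                    depth_mean = 100, n_pairs = 1, seed = 109)
summ_f <- summarize_genes(assign_alleles(sim$counts$SY1, sim$snps, "A"),
                          sim$genes)
summ_r <- summarize_genes(assign_alleles(sim$counts$YS1, sim$snps, "B"),
                          sim$genes)
calls <- call_imprinting(summ_f, summ_r, sim$genes)
table(calls$status)
clusters <- find_clusters(calls, sim$genes)
```

## Known limitations

Gene-level pooling of SNP counts ignores per-SNP heterogeneity (a per-SNP
chi-square is available as a diagnostic through `assign_alleles()` +
`chi2_two_to_one()` but does not gate calls, because the classification
thresholds are defined on gene totals).  The binomial count model has no
overdispersion term, so q-values on real data with extra-binomial noise
will be anti-conservative; a beta-binomial extension would be the natural
next step.  DMR calling pools tissues without replicates and therefore
tests a fixed-effects null.  The cluster rule depends on annotation
completeness: unannotated analyzable genes cannot break chains.
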