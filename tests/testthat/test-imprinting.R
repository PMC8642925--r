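# The 2m:1p chi-square test, BH adjustment, and MEG/PEG classification.

test_that("chi-square against 2:1 matches hand arithmetic and the sf oracle", {
  r <- chi2_two_to_one(20, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # (100, 0): ((100 - 200/3)^2)/(200/3) + ((0 - 100/3)^2)/(100/3) = 50
  r <- chi2_two_to_one(100, 0)
  expect_equal(r$statistic, 50)
  expect_equal(r$p_value, chisq1_sf_oracle(50), tolerance = 1e-12)
  expect_lt(abs(r$p_value - 1.54e-12) / 1.54e-12, 0.01)

  # (10, 20): (10 - 20)^2/20 + (20 - 10)^2/10 = 15
  expect_equal(chi2_two_to_one(10, 20)$statistic, 15)

  expect_error(chi2_two_to_one(0, 0), "pre-filter")
})

test_that("chi-square p-values agree with stats::chisq.test on random counts", {
  set.seed(42)
  M <- rbinom(50, 300, 2 / 3) + 1
  P <- 301 - M
  r <- chi2_two_to_one(M, P)
  ref <- vapply(seq_along(M), function(i) {
    suppressWarnings(
      stats::chisq.test(c(M[i], P[i]), p = c(2, 1) / 3)$p.value)
  }, numeric(1))
  expect_equal(r$p_value, ref, tolerance = 1e-10)
})

test_that("BH adjustment matches the enumeration oracle", {
  expect_equal(adjust_q(0.01), 0.01)                    # m = 1 identity
  expect_equal(adjust_q(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_q(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_q(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(40)
  expect_equal(adjust_q(p), bh_oracle(p))
  expect_error(adjust_q(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stringency thresholds derive from the fold factor and dosage", {
  th <- stringency_thresholds()
  expect_equal(th[["meg_maternal"]], 10 / 11)
  expect_equal(th[["peg_paternal"]], 5 / 7)
  th3 <- stringency_thresholds(fold = 3)
  expect_equal(th3[["meg_maternal"]], 6 / 7)
  expect_equal(th3[["peg_paternal"]], 3 / 5)
})

test_that("classification follows the low/high stringency rules", {
  # strong maternal bias in both directions, coding -> MEG
  f_fwd <- 200 / 204
  f_rev <- 180 / 185
  expect_gt(f_fwd, 10 / 11)
  expect_equal(classify_imprinting(f_fwd, f_rev, 1e-6, 1e-6, "coding"),
               "MEG")
  # exact 2:1 in both directions -> biallelic
  expect_equal(classify_imprinting(2 / 3, 2 / 3, 1, 1, "coding"),
               "biallelic")
  # fraction exactly 10/11 is NOT high stringency (strict inequality)
  expect_equal(classify_imprinting(10 / 11, 0.95, 1e-9, 1e-9, "coding"),
               "low_MEG")
  # noncoding paternal high-stringency call -> PNC
  expect_equal(classify_imprinting(0.05, 0.10, 1e-9, 1e-9, "noncoding"),
               "PNC")
  # significant but opposite parental directions -> biallelic
  expect_equal(classify_imprinting(0.95, 0.05, 1e-9, 1e-9, "coding"),
               "biallelic")
})

test_that("relabelling the parents maps MEG calls to PEG calls exactly", {
  # The 2m:1p null is asymmetric, so swapping counts alone changes the
  # chi-square statistic; the exact symmetry is a consistent relabelling:
  # swap M and P in both directions AND mirror the dosage to 1m:2p.
  set.seed(7)
  n <- 200
  M_f <- rbinom(n, 120, runif(n)) + 1
  P_f <- 121 - M_f
  M_r <- rbinom(n, 90, runif(n)) + 1
  P_r <- 91 - M_r
  mk <- function(M1, P1, M2, P2, dosage) {
    s1 <- data.frame(gene_id = sprintf("g%03d", 1:n), M = M1, P = P1,
                     n_snps = 1L)
    s2 <- data.frame(gene_id = sprintf("g%03d", 1:n), M = M2, P = P2,
                     n_snps = 1L)
    call_imprinting(s1, s2, dosage = dosage)
  }
  a <- mk(M_f, P_f, M_r, P_r, c(2, 1))
  b <- mk(P_f, M_f, P_r, M_r, c(1, 2))
  swap <- c(MEG = "PEG", PEG = "MEG", MNC = "PNC", PNC = "MNC",
            low_MEG = "low_PEG", low_PEG = "low_MEG",
            biallelic = "biallelic", non_analyzed = "non_analyzed")
  expect_equal(unname(swap[a$status]), b$status)
  # high-stringency calls are a subset of low-stringency evidence
  high <- a$status %in% imprinted_statuses("high")
  expect_true(all(a$q_fwd[high] < 0.05 & a$q_rev[high] < 0.05))
})

test_that("call_imprinting applies analyzability and expression filters", {
  s_fwd <- data.frame(gene_id = c("g1", "g2"), M = c(100, 5), P = c(2, 1),
                      n_snps = 1L)
  s_rev <- data.frame(gene_id = c("g1", "g2"), M = c(90, 6), P = c(3, 2),
                      n_snps = 1L)
  calls <- call_imprinting(s_fwd, s_rev)
  expect_equal(calls$status[calls$gene_id == "g2"], "non_analyzed")
  expect_equal(calls$status[calls$gene_id == "g1"], "MEG")
  # expression filter knocks out g1 too
  calls2 <- call_imprinting(s_fwd, s_rev, expressed_genes = character(0))
  expect_true(all(calls2$status == "non_analyzed"))
})

test_that("seed-coat marker report flags contamination", {
  fpkm <- data.frame(gene_id = c("per36", "mum4"), endosperm = c(0.1, 2),
                     leaf = c(5, 8))
  rep <- check_contamination_markers(fpkm, c("per36", "mum4", "absent"))
  expect_equal(rep$clean, c(TRUE, FALSE, NA))
})
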