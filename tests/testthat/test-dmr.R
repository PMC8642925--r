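# Sliding-window Fisher DMR detection and merging.

test_that("window test matches hand cases and the enumeration oracle", {
  r <- window_test(50, 50, 50, 50)
  expect_equal(r$p_value, 1)
  expect_equal(r$level_diff, 0)

  r <- window_test(90, 10, 40, 60)
  expect_equal(r$level_diff, -0.5)
  expect_equal(r$p_value, fisher_enum_oracle(90, 10, 40, 60),
               tolerance = 1e-12)

  # margins (2,2,2,2): three tables, two-sided p = 1/3
  expect_equal(window_test(2, 0, 0, 2)$p_value, 1 / 3)

  expect_true(is.na(window_test(0, 0, 3, 2)$p_value))  # uncovered tissue
})

test_that("two-sided Fisher p equals stats::fisher.test on random tables", {
  set.seed(13)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) next
    mine <- window_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("DMR filter needs both q < fdr and |diff| > 0.30", {
  # two well-separated constant blocks; one strongly different, one with
  # a large-sample 25% difference (significant but under the level cutoff)
  pos1 <- seq(1000, 1990, by = 10)
  pos2 <- seq(50000, 50990, by = 10)
  emb <- rbind(make_cytosines(pos1, 18, 2), make_cytosines(pos2, 18, 2))
  endo <- rbind(make_cytosines(pos1, 2, 18),
                make_cytosines(pos2, 13, 7))  # 0.90 -> 0.65: diff 0.25
  dmrs <- call_dmrs(emb, endo)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "endosperm_hypo")
  expect_lt(dmrs$start, 2000)
  w <- attr(dmrs, "windows")
  blk2 <- w[w$start > 40000, ]
  expect_true(any(blk2$q_value < 0.01))          # significant ...
  expect_true(all(abs(blk2$level_diff) < 0.30))  # ... but under the cutoff
})

test_that("significant windows separated by exactly the merge gap merge", {
  sig <- data.frame(chrom = "chr1", start = c(1000, 1400),
                    end = c(1199, 1599), context = "CG",
                    q_value = c(1e-5, 2e-5), level_diff = c(-0.5, -0.6))
  m <- imprintscan:::merge_windows(sig, merge_gap = 200)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1000)
  expect_equal(m$end, 1599)
  expect_equal(m$n_windows, 2L)
  expect_equal(m$min_q, 1e-5)

  # one base further apart: no merge
  sig2 <- sig
  sig2$start[2] <- 1401
  sig2$end[2] <- 1600
  expect_equal(nrow(imprintscan:::merge_windows(sig2, 200)), 2)
})

test_that("merging is order-independent and never joins opposite directions", {
  sig <- data.frame(chrom = "chr1", start = c(3000, 1000, 1100),
                    end = c(3199, 1199, 1299), context = "CG",
                    q_value = c(1e-4, 1e-6, 1e-5),
                    level_diff = c(0.45, -0.5, -0.4))
  a <- imprintscan:::merge_windows(sig)
  b <- imprintscan:::merge_windows(sig[c(3, 1, 2), ])
  expect_equal(a, b)
  expect_equal(nrow(a), 2)
  expect_setequal(a$direction, c("endosperm_hypo", "embryo_hypo"))

  # adjacent but opposite-direction windows stay separate
  sig3 <- data.frame(chrom = "chr1", start = c(1000, 1100),
                     end = c(1199, 1299), context = "CG",
                     q_value = c(1e-6, 1e-6), level_diff = c(-0.5, 0.5))
  expect_equal(nrow(imprintscan:::merge_windows(sig3)), 2)

  # merging an already-merged result is a no-op on spans
  remerged <- imprintscan:::merge_windows(
    transform(a, q_value = min_q, level_diff = mean_diff))
  expect_equal(remerged[, c("chrom", "start", "end", "direction")],
               a[, c("chrom", "start", "end", "direction")])
})

test_that("a planted hypomethylated region is recovered as one DMR", {
  sim <- simulate_methylome(chrom_length = 50000, n_regions = 1,
                            region_length = 1000, delta = 0.7, seed = 17)
  dmrs <- call_dmrs(sim$embryo, sim$endosperm)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "endosperm_hypo")
  reg <- sim$regions
  ov <- min(dmrs$end, reg$end) - max(dmrs$start, reg$start) + 1
  expect_gt(ov / (reg$end - reg$start + 1), 0.8)
})

test_that("no DMRs are called on a matched null methylome", {
  sim <- simulate_methylome(chrom_length = 50000, n_regions = 0, seed = 19)
  dmrs <- call_dmrs(sim$embryo, sim$endosperm)
  expect_equal(nrow(dmrs), 0)
})
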