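test_that("Wilcoxon differential activity matches exact micro-examples", {
  B <- rbind(lv1 = c(4, 5, 6, 1, 2, 3),
             lv2 = c(1, 1, 1, 1, 1, 1))
  karyotype <- c("T21", "T21", "T21", "D21", "D21", "D21")
  tab <- test_differential_activity(B, karyotype)
  expect_equal(tab$pvalue[1], 0.1)           # most extreme arrangement, doubled
  expect_equal(tab$pvalue[2], 1)             # no rank separation
  expect_equal(tab$effect[1], 3)
  expect_equal(tab$direction[1], "up")
  expect_error(test_differential_activity(B, c("T21", rep("D21", 5))),
               ">= 2 samples")
})

test_that("Wilcoxon p-values are invariant under strictly monotone transforms", {
  set.seed(7)
  B <- matrix(rnorm(5 * 40), 5)
  karyotype <- rep(c("T21", "D21"), c(25, 15))
  p1 <- test_differential_activity(B, karyotype)$pvalue
  p2 <- test_differential_activity(exp(B), karyotype)$pvalue
  p3 <- test_differential_activity(B^3, karyotype)$pvalue
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("BH adjustment validates input and equals the step-up reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("SGM flags follow the FDR and effect gates", {
  tab <- data.frame(lv = 1:3, fdr = c(0.01, 0.01, 0.2),
                    effect = c(0.5, 0.1, 0.9),
                    direction = c("up", "up", "down"))
  out <- select_sgm(tab)
  expect_equal(out$is_sgm, c(TRUE, TRUE, FALSE))
  expect_equal(out$is_top_sgm, c(TRUE, FALSE, FALSE))
  expect_equal(unname(attr(out, "counts")["up"]), 2L)
})

test_that("planted karyotype shifts are detected and nulls are controlled", {
  # reference conditions (1.0 SD shift, 300 vs 100 samples), on the true
  # activities: every planted module must be flagged in every seed, and
  # flagged nulls must stay within what BH at FDR 0.05 concedes (51 null
  # modules across seeds; at most 2 flags, under 5%)
  null_flags <- 0
  for (s in 21:23) {
    d <- generate_dataset(simulation_config(seed = s))
    tab <- test_differential_activity(d$truth$B_true, d$truth$karyotype)
    expect_true(all(tab$is_sgm[1:3]))
    expect_true(all(tab$effect[1:3] > 0.25))
    null_flags <- null_flags + sum(tab$is_sgm[4:20])
  }
  expect_lte(null_flags, 2)
})

test_that("the chr21 representation test builds the declared table and
           matches the enumeration oracle", {
  # loadings constructed so module groups pick known genes: 40 genes,
  # 2 modules; membership_frac 0.1 -> top 4 genes per module
  Z <- matrix(0, 40, 2, dimnames = list(sprintf("g%02d", 1:40), NULL))
  Z[1:4, 1] <- 5                             # SGM members
  Z[5:8, 2] <- 5                             # non-SGM members
  chrom <- rep("1", 40)
  chrom[c(1, 2, 3, 5)] <- "21"               # 3 chr21 in SGM, 1 in non-SGM
  res <- chr21_representation_test(Z, c(TRUE, FALSE), chrom,
                                   membership_frac = 0.1)
  expect_equal(unname(res$table), matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$pvalue, 34 / 70, tolerance = 1e-12)
  expect_equal(res$pvalue, fisher_two_sided_enum(res$table),
               tolerance = 1e-12)
  expect_error(chr21_representation_test(Z, c(TRUE, TRUE), chrom),
               "degenerate")
})

test_that("two-sided Fisher agrees with hypergeometric enumeration on
           random tables", {
  set.seed(5)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_two_sided_enum(tab),
                 tolerance = 1e-9)
  }
  # zero-margin degenerate table
  expect_equal(stats::fisher.test(matrix(c(0, 10, 0, 10), 2))$p.value, 1)
})
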