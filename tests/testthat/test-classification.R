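test_that("ROC AUC matches hand counts and the pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.4), c(1, 1, 0, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(19)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(roc_auc(scores, labels), auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("negating scores reflects the AUC exactly", {
  set.seed(29)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.3)
  labels[1:2] <- c(1, 0)
  expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels),
               tolerance = 1e-12)
})

test_that("average precision matches hand counts and the sweep oracle", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  expect_equal(average_precision(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_error(average_precision(1:3, c(0, 0, 0)), "case")

  set.seed(37)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    labels <- c(1, rbinom(n - 1, 1, 0.4))
    expect_equal(average_precision(scores, labels), ap_sweep(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("classification metrics are invariant under increasing transforms", {
  set.seed(43)
  scores <- rnorm(80)
  labels <- c(1, 0, rbinom(78, 1, 0.3))
  for (f in list(function(x) 2 * x + 5, exp, function(x) x^3)) {
    expect_equal(roc_auc(f(scores), labels), roc_auc(scores, labels))
    expect_equal(average_precision(f(scores), labels),
                 average_precision(scores, labels))
    expect_equal(balanced_maps(f(scores), labels, seed = 1),
                 balanced_maps(scores, labels, seed = 1),
                 ignore_attr = TRUE)
  }
})

test_that("balanced mAPS: determinism, balanced degeneracy and stability", {
  set.seed(47)
  scores <- rnorm(60)
  labels <- rep(c(1, 0), 30)
  # equal class sizes: every draw uses all controls, so mAPS equals the
  # plain average precision with zero Monte-Carlo spread
  bm <- balanced_maps(scores, labels, seed = 5)
  expect_equal(unname(bm["maps"]), average_precision(scores, labels))
  expect_equal(unname(bm["maps_sd"]), 0)

  scores2 <- rnorm(800)
  labels2 <- rep(c(1, 0, 0, 0), 200)
  expect_identical(balanced_maps(scores2, labels2, seed = 9),
                   balanced_maps(scores2, labels2, seed = 9))
  maps10 <- vapply(1:10, function(s)
    balanced_maps(scores2, labels2, seed = s)[["maps"]], numeric(1))
  expect_lt(max(abs(maps10 - mean(maps10))), 0.02)

  # fewer controls than cases: all controls used, with a note
  bm2 <- balanced_maps(rnorm(30), rep(c(1, 1, 0), 10), seed = 1)
  expect_match(attr(bm2, "note"), "fewer controls")
})

test_that("module evaluation flags the planted comorbidity and skips
           underpowered pairs", {
  cfg <- small_config(seed = 33)
  d <- generate_dataset(cfg)
  res <- evaluate_modules(d$truth$B_true, d$metadata, seed = 2)
  planted <- res[res$lv == 2 & res$comorbidity == "comorbidity_1", ]
  expect_true(planted$passes)
  expect_gt(planted$auc, 0.65)
  nulls <- res[res$comorbidity == "null_comorbidity_1", ]
  expect_true(all(!nulls$passes))

  # a comorbidity with fewer than min_cases cases is skipped
  md <- d$metadata
  md$rare <- ifelse(md$karyotype == "T21", 0L, NA_integer_)
  md$rare[which(md$karyotype == "T21")[1:3]] <- 1L
  res2 <- evaluate_modules(d$truth$B_true, md, comorbidities = "rare",
                           seed = 2)
  expect_equal(nrow(res2), 0L)
  expect_length(attr(res2, "skipped"), 5)
})

test_that("top-quartile enrichment matches the most-extreme table and the
           enumeration oracle, and is calibrated under the null", {
  scores <- c(16:13, 12:1) + 0.0
  labels <- c(rep(1, 4), rep(0, 12))
  q <- quartile_enrichment(scores, labels)
  expect_equal(unname(q$table), matrix(c(4, 0, 0, 12), 2, byrow = TRUE))
  expect_equal(q$pvalue, 1 / choose(16, 4), tolerance = 1e-12)
  expect_error(quartile_enrichment(rep(1, 10), rep(c(0, 1), 5)), "identical")

  set.seed(53)
  for (i in 1:50) {
    n <- sample(12:60, 1)
    sc <- rnorm(n)
    lb <- c(1, 0, rbinom(n - 2, 1, 0.3))
    qq <- quartile_enrichment(sc, lb)
    a <- qq$table[1, 1]
    expect_equal(qq$pvalue,
                 hyper_tail_enum(a, sum(qq$table[1, ]), n, sum(qq$table[, 1])),
                 tolerance = 1e-12)
  }

  ps <- replicate(200, quartile_enrichment(rnorm(60),
                                           c(1, 0, rbinom(58, 1, 0.3)))$pvalue)
  # discrete one-sided p-values: stochastically no smaller than uniform
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif",
                                            alternative = "greater")$p.value),
            0.01)
})
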