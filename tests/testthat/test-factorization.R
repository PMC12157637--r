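test_that("row z-scoring centers and scales, with the constant-row convention", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_warning(zn <- zscore_rows(m), "constant")
  expect_equal(unname(zn["a", ]), c(-1, 0, 1))
  expect_equal(unname(zn["b", ]), c(0, 0, 0))
  expect_equal(attr(zn, "constant_rows"), "b")

  set.seed(1)
  X <- matrix(rnorm(200), 10, 20)
  Xn <- zscore_rows(X)
  expect_lt(max(abs(rowMeans(Xn))), 1e-12)
  expect_lt(max(abs(apply(Xn, 1, stats::sd) - 1)), 1e-12)
  expect_error(zscore_rows(matrix(1, 3, 1)), "2 samples")
})

test_that("parallel analysis recovers a planted rank and stays near zero on noise", {
  set.seed(9)
  Xp <- matrix(rnorm(500 * 3), 500) %*% matrix(rnorm(3 * 100), 3) +
    matrix(rnorm(500 * 100, sd = 0.01), 500)
  Xp <- zscore_rows(Xp)
  expect_identical(estimate_num_components(Xp, seed = 2), 3L)
  expect_identical(estimate_num_components(Xp, seed = 2),
                   estimate_num_components(Xp, seed = 2))

  ks <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xnull <- zscore_rows(matrix(rnorm(200 * 60), 200))
    estimate_num_components(Xnull, n_permutations = 10, seed = s)
  }, integer(1))
  expect_true(all(ks <= 1))
  expect_error(estimate_num_components(Xp, n_permutations = 0), "n_permutations")
})

test_that("the solver satisfies its contracts on synthetic data", {
  d <- small_dataset()
  Xn <- suppressWarnings(zscore_rows(d$expression))
  C <- gene_sets_to_matrix(d$gene_sets, rownames(Xn))
  m <- plier_fit(Xn, C, k = 5)

  # objective never increases across full block updates
  tr <- m$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  # constraints
  expect_gte(min(m$U), 0)
  expect_gte(min(m$Z_raw), 0)
  # standardization contract on non-constant columns/rows
  live <- apply(m$Z, 2, function(x) any(x != 0))
  expect_lt(max(abs(colMeans(m$Z[, live]))), 1e-8)
  expect_lt(max(abs(apply(m$Z[, live], 2, stats::var) - 1)), 1e-6)
  expect_lt(max(abs(rowMeans(m$B))), 1e-8)
  expect_lt(max(abs(apply(m$B, 1, stats::var) - 1)), 1e-6)

  expect_error(plier_fit(Xn, C[rev(seq_len(nrow(C))), ], k = 5), "identifiers")
  expect_error(plier_fit(Xn, C, k = 500), "k must be")
})

test_that("noise-free rank-k input is reconstructed nearly exactly", {
  cfg <- small_config(noise_sd_expression = 0)
  d <- generate_dataset(cfg)
  Xn <- suppressWarnings(zscore_rows(d$expression))
  C <- gene_sets_to_matrix(d$gene_sets, rownames(Xn))
  m <- plier_fit(Xn, C, k = 5, tol = 1e-6, max_iter = 500)
  expect_lt(norm(Xn - m$Z_raw %*% m$B_raw, "F") / norm(Xn, "F"), 0.05)
})

test_that("planted modules are recovered at moderate noise", {
  d <- small_dataset()   # noise_sd_expression = 0.3
  Xn <- suppressWarnings(zscore_rows(d$expression))
  C <- gene_sets_to_matrix(d$gene_sets, rownames(Xn))
  m <- plier_fit(Xn, C, k = 5)
  sdv <- apply(d$expression, 1, stats::sd)
  expect_gte(greedy_match_cor(m$Z_raw, d$truth$Z_true / sdv), 0.8)
})

test_that("alignment AUC matches hand-counted and degenerate cases", {
  # every held-out member above every non-member
  r <- modlink:::rank_auc_test(c(5, 6, 7), c(1, 2, 3, 4))
  expect_equal(r$auc, 1)
  # members {0.9, 0.3} vs non-members {0.8, 0.4}: 2 of 4 pairs concordant
  r2 <- modlink:::rank_auc_test(c(0.9, 0.3), c(0.8, 0.4))
  expect_equal(r2$auc, 0.5)
})

test_that("alignment AUC is centred at 1/2 when loadings ignore membership", {
  set.seed(4)
  aucs <- replicate(100, {
    modlink:::rank_auc_test(rnorm(10), rnorm(90))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("held-out prior members score their aligned LV highly", {
  d <- small_dataset()
  Xn <- suppressWarnings(zscore_rows(d$expression))
  C <- gene_sets_to_matrix(d$gene_sets, rownames(Xn))
  masked <- mask_prior(C, 0.25, seed = 42)
  expect_identical(masked$holdout,
                   mask_prior(C, 0.25, seed = 42)$holdout)
  # held-out members are zeroed in the masked prior
  for (s in names(masked$holdout)) {
    expect_true(all(masked$C_masked[masked$holdout[[s]], s] == 0))
  }
  m <- plier_fit(Xn, masked$C_masked, k = 5)
  al <- pathway_alignment(m, C, masked$holdout)
  expect_true(all(al$auc >= 0 & al$auc <= 1))
  expect_true(all(al$fdr >= al$pvalue - 1e-12))
  # the generator aligns prior set j with module j; the factorization should
  # recover at least half of those alignments with high held-out AUC
  good <- al[al$auc > 0.6 & al$fdr < 0.05, ]
  expect_gte(nrow(good), 2)
})
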