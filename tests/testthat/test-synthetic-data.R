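test_that("prior matrix respects set sizes and is deterministic", {
  cfg <- simulation_config(n_genes = 100, n_samples_t21 = 10,
                           n_samples_d21 = 10, k_true = 4, n_pathways = 5,
                           pathway_size_range = c(10, 10), frac_aligned = 0.75,
                           sgm_indices = 1L, trait_plants = list(),
                           comorbidity_plants = list(), seed = 3)
  C <- generate_prior_matrix(cfg)
  expect_equal(unname(colSums(C)), rep(10, 5))
  expect_identical(C, generate_prior_matrix(cfg))

  cfg2 <- simulation_config(n_genes = 2000, k_true = 20, n_pathways = 50,
                            pathway_size_range = c(20, 60), seed = 11)
  C2 <- generate_prior_matrix(cfg2)
  sizes <- colSums(C2)
  expect_true(all(sizes >= 20 & sizes <= 60))
  expect_equal(dim(C2), c(2000L, 50L))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 50, pathway_size_range = c(10, 60)),
               "exceed")
  expect_error(simulation_config(corr_rho = 1), "corr_rho")
  expect_error(simulation_config(sgm_indices = 25L), "sgm_indices")
  expect_error(simulation_config(k_true = 20, frac_aligned = 1,
                                 n_pathways = 10), "n_pathways")
  expect_error(simulation_config(trait_plants = list(
    list(trait_id = "t", module = 99L, effect = 1))), "trait")
})

test_that("datasets are deterministic and internally consistent", {
  d <- small_dataset()
  d2 <- generate_dataset(small_config())
  expect_identical(d$expression, d2$expression)
  expect_identical(d$twas, d2$twas)
  expect_identical(d$metadata, d2$metadata)

  expect_true(all(d$truth$Z_true >= 0))
  expect_equal(dim(d$truth$Z_true), c(300L, 5L))
  expect_equal(dim(d$truth$B_true), c(5L, 90L))
  expect_equal(rownames(d$truth$C_true), rownames(d$expression))
  expect_true(all(d$twas$pvalue > 0 & d$twas$pvalue <= 1))
  # comorbidity status exists only for T21 samples
  expect_true(all(is.na(d$metadata$comorbidity_1[d$metadata$karyotype == "D21"])))
  expect_false(anyNA(d$metadata$comorbidity_1[d$metadata$karyotype == "T21"]))
})

test_that("zero-noise datasets satisfy the low-rank identity", {
  cfg <- small_config(noise_sd_expression = 0, noise_sd_loadings = 0)
  d <- generate_dataset(cfg)
  expect_lt(max(abs(d$expression - d$truth$Z_true %*% d$truth$B_true)), 1e-10)
})

test_that("the true correlation matrix is SPD with unit diagonal and the
           noise attains the planted within-block correlation", {
  d <- small_dataset()
  S <- sigma_true_matrix(d$truth)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_gt(min(eigen(S[1:50, 1:50], symmetric = TRUE,
                      only.values = TRUE)$values), 0)

  # empirical check at 2,000 samples
  cfg <- simulation_config(n_genes = 80, n_samples_t21 = 1500,
                           n_samples_d21 = 500, k_true = 3, n_pathways = 3,
                           pathway_size_range = c(10, 12), sgm_indices = 1L,
                           trait_plants = list(), comorbidity_plants = list(),
                           noise_sd_expression = 1, seed = 5)
  d2 <- generate_dataset(cfg)
  noise <- d2$expression - d2$truth$Z_true %*% d2$truth$B_true
  cc <- stats::cor(t(noise))
  blk <- cc[1:10, 1:10][upper.tri(diag(10))]
  expect_lt(abs(mean(blk) - cfg$corr_rho), 0.05)
})

test_that("planted comorbidity risk increases across activity quartiles", {
  cfg <- small_config(seed = 8)
  d <- generate_dataset(cfg)
  t21 <- d$truth$karyotype == "T21"
  act <- d$truth$B_true[2, t21]
  lab <- d$metadata$comorbidity_1[d$metadata$karyotype == "T21"]
  q <- cut(act, stats::quantile(act, 0:4 / 4), include.lowest = TRUE,
           labels = FALSE)
  rate <- tapply(lab, q, mean)
  expect_true(all(diff(rate) >= 0))
})

test_that("null karyotype effect yields uniform Wilcoxon p-values", {
  # calibration property reused by the differential stage: with sgm_effect 0
  # the per-module p-values are uniform, so the sub-0.05 fraction stays
  # within the binomial 99% band
  ps <- unlist(lapply(1:10, function(s) {
    cfg <- simulation_config(n_genes = 50, n_samples_t21 = 60,
                             n_samples_d21 = 30, k_true = 10, n_pathways = 8,
                             pathway_size_range = c(5, 10), sgm_effect = 0,
                             trait_plants = list(), comorbidity_plants = list(),
                             seed = 100 + s)
    d <- generate_dataset(cfg)
    test_differential_activity(d$truth$B_true, d$truth$karyotype)$pvalue
  }))
  frac <- mean(ps < 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(frac - 0.05), band + 1e-12)
})

test_that("written datasets round-trip through the pipeline readers", {
  cfg <- small_config()
  d <- generate_dataset(cfg)
  dir <- tempfile("bundle_")
  write_dataset(d, dir, cfg)
  X <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(X, d$expression, tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "priors.gmt"))
  expect_equal(lapply(sets, sort), lapply(d$gene_sets, sort),
               ignore_attr = TRUE)
  S <- read_matrix_tsv(file.path(dir, "sigma_true.tsv"))
  expect_equal(S, sigma_true_matrix(d$truth), tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "truth", "manifest.json"))
  expect_equal(unlist(manifest$planted_sgm), c(1L, 2L))
  unlink(dir, recursive = TRUE)
})
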