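test_that("p-value to score transform matches normal quantiles and is
           monotone decreasing", {
  expect_equal(pvalues_to_scores(1), 0)
  expect_equal(pvalues_to_scores(0.05), 1.959964, tolerance = 1e-6)
  p <- sort(runif(50, 1e-6, 1))
  y <- pvalues_to_scores(p)
  expect_true(all(diff(y) < 0))
  expect_error(pvalues_to_scores(c(0.5, 0)), "\\(0, 1\\]")
  expect_true(is.finite(pvalues_to_scores(1e-320)))
})

test_that("indicator vectors have the declared support and tie-breaks", {
  set.seed(2)
  Z <- matrix(rnorm(2000), 2000, 1,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  s <- build_indicator(Z, 1, 0.01)
  expect_equal(sum(s), 20)
  expect_true(all(s %in% c(0L, 1L)))
  expect_setequal(names(s)[s == 1], rownames(Z)[order(-abs(Z[, 1]))[1:20]])

  Z0 <- matrix(0, 100, 1, dimnames = list(sprintf("g%03d", 1:100), NULL))
  expect_warning(s0 <- build_indicator(Z0, 1, 0.05), "degenerate")
  expect_equal(names(s0)[s0 == 1], sprintf("g%03d", 1:5))
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  y <- c(1, 2, 3, 4)
  s <- c(0, 0, 1, 1)
  fit <- gls_fit(y, s)
  expect_equal(fit$beta, 2.0, tolerance = 1e-10)   # difference of group means

  set.seed(17)
  for (i in 1:25) {
    g <- sample(30:80, 1)
    y <- rnorm(g)
    s <- integer(g)
    s[sample(g, 8)] <- 1L
    ref <- ols_reference(y, s)
    a <- gls_fit(y, s)
    b <- gls_fit(y, s, Sigma = diag(g))
    expect_equal(a$beta, ref$beta, tolerance = 1e-8)
    expect_equal(a$se, ref$se, tolerance = 1e-8)
    expect_equal(a$pvalue_one_sided, ref$pvalue, tolerance = 1e-8)
    expect_equal(b$beta, ref$beta, tolerance = 1e-8)
    expect_equal(b$pvalue_one_sided, ref$pvalue, tolerance = 1e-8)
  }
  expect_error(gls_fit(rnorm(10), rep(1, 10)), "degenerate")
})

test_that("the whitened fit agrees with the closed-form GLS estimator", {
  set.seed(23)
  S <- block_sigma(60, 6, 0.4)
  sh <- shrink_sigma(S)
  Sinv <- solve(sh$Sigma)
  for (i in 1:20) {
    y <- block_mvn(60, 6, 0.4)
    s <- integer(60)
    s[sample(60, 10)] <- 1L
    fit <- gls_fit(y, s, chol_sigma = sh$chol)
    # independent route: normal equations with an explicit inverse
    D <- cbind(1, s)
    bread <- solve(t(D) %*% Sinv %*% D)
    beta <- bread %*% t(D) %*% Sinv %*% y
    r <- y - D %*% beta
    sigma2 <- as.numeric(t(r) %*% Sinv %*% r) / (60 - 2)
    expect_equal(fit$beta, beta[2], tolerance = 1e-8)
    expect_equal(fit$se, sqrt(sigma2 * bread[2, 2]), tolerance = 1e-8)
  }
})

test_that("sigma shrinkage yields a positive-definite matrix", {
  # rank-deficient correlation from fewer samples than genes
  set.seed(3)
  X <- matrix(rnorm(30 * 80), 80, 30)
  S <- stats::cor(t(X))
  sh <- shrink_sigma(S)
  expect_gt(min(eigen(sh$Sigma, symmetric = TRUE, only.values = TRUE)$values),
            1e-8)
  expect_equal(sh$tau, 0.05)
  expect_error(shrink_sigma(matrix(1, 2, 3)), "square")
})

test_that("associate_all recovers the planted trait pair and drops
           underpowered traits", {
  d <- small_dataset()
  Z <- d$truth$Z_true
  S <- sigma_true_matrix(d$truth)
  res <- associate_all(Z, d$twas, S, modules = 1:5)
  hit <- res[res$lv == 1 & res$trait == "trait_1", ]
  expect_true(hit$significant)
  expect_gt(hit$beta, 0.5)

  # single-pair grid: fdr equals the raw p-value
  single <- associate_all(Z, d$twas[d$twas$trait_id == "trait_1", ], S,
                          modules = 1L)
  expect_equal(single$fdr, single$pvalue)

  # a trait covering too few genes is skipped with a record
  sparse <- d$twas[d$twas$trait_id == "trait_1", ][1:50, ]
  sparse$trait_id <- "sparse_trait"
  res2 <- associate_all(Z, rbind(d$twas, sparse), S, modules = 1L)
  expect_true("sparse_trait" %in% attr(res2, "skipped_traits"))
  expect_false("sparse_trait" %in% res2$trait)
})

test_that("permuting TWAS gene labels destroys the planted associations", {
  # full-size conditions (2,000 genes, 20-gene indicators) on the true
  # loadings: after permutation no (module, trait) pair should be flagged,
  # in at least 4 of 5 seeds
  S <- NULL
  set.seed(41)
  hits <- vapply(1:5, function(s) {
    d <- generate_dataset(simulation_config(seed = 200 + s))
    if (is.null(S)) S <<- sigma_true_matrix(d$truth)
    tw <- d$twas
    tw$gene_id <- ave(tw$gene_id, tw$trait_id, FUN = sample)
    res <- associate_all(d$truth$Z_true, tw, S, modules = 1:3)
    sum(res$significant)
  }, numeric(1))
  expect_gte(sum(hits == 0), 4)
})
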