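# Shared fixtures and independent reference implementations used as oracles.
# The references are deliberately naive (enumeration, double loops, direct
# formulas) and independent of the package's code paths.

# small, fast simulation configuration for unit tests
small_config <- function(seed = 1L, ...) {
  simulation_config(n_genes = 300, n_samples_t21 = 60, n_samples_d21 = 30,
                    k_true = 5, n_pathways = 7, pathway_size_range = c(10, 16),
                    sgm_indices = 1:2,
                    trait_plants = list(
                      list(trait_id = "trait_1", module = 1L, effect = 1.5)),
                    n_null_traits = 2,
                    comorbidity_plants = list(
                      list(comorbidity_id = "comorbidity_1", module = 2L,
                           intercept = -3, slope = 3)),
                    n_null_comorbidities = 1,
                    seed = seed, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(small_config())
    cache
  }
})

# greedy one-to-one matching of recovered to true loading columns by
# maximal absolute correlation; returns the mean matched |correlation|
greedy_match_cor <- function(Z_hat, Z_true) {
  cm <- abs(stats::cor(Z_hat, Z_true))
  cm[is.na(cm)] <- 0
  vals <- numeric(min(dim(cm)))
  for (i in seq_along(vals)) {
    w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    vals[i] <- cm[w[1], w[2]]
    cm[w[1], ] <- -1
    cm[, w[2]] <- -1
  }
  mean(vals)
}

# reference Benjamini-Hochberg step-up, direct formula
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# reference ROC AUC: O(n^2) loop over all case-control pairs
auc_pairwise <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# reference average precision: exhaustive threshold sweep over distinct
# score values
ap_sweep <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# reference hypergeometric upper tail P(X >= k) by direct summation of
# choose() terms
hyper_tail_enum <- function(k, set_size, universe_size, query_size) {
  kk <- k:min(set_size, query_size)
  sum(choose(set_size, kk) *
        choose(universe_size - set_size, query_size - kk)) /
    choose(universe_size, query_size)
}

# reference two-sided Fisher exact p: enumerate the hypergeometric support
# and sum probabilities of tables at least as extreme (prob <= observed)
fisher_two_sided_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# reference OLS one-sided p for the indicator coefficient, via lm()
ols_reference <- function(y, s) {
  fit <- summary(stats::lm(y ~ s))
  est <- fit$coefficients["s", ]
  p_two <- est["Pr(>|t|)"]
  p_one <- if (est["Estimate"] >= 0) p_two / 2 else 1 - p_two / 2
  list(beta = unname(est["Estimate"]), se = unname(est["Std. Error"]),
       pvalue = unname(p_one))
}

# draw y ~ N(0, Sigma) for the block compound-symmetric Sigma without
# forming Sigma (shared + idiosyncratic construction)
block_mvn <- function(n_genes, block_size, rho) {
  blocks <- ceiling(n_genes / block_size)
  shared <- rep(stats::rnorm(blocks), each = block_size)[seq_len(n_genes)]
  sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n_genes)
}

block_sigma <- function(n_genes, block_size, rho) {
  b <- ceiling(seq_len(n_genes) / block_size)
  S <- rho * outer(b, b, "==")
  diag(S) <- 1
  S
}
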