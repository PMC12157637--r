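# Study-level procedures over the pipeline: factorization recovery across
# seeds, GLS calibration versus OLS under a block-correlated null, and
# planted-truth recovery / global-null behavior of the end-to-end pipeline.
# The analysis drivers, the test suite and the acceptance script all call
# these, so the measured quantities are produced by one code path.

#' Greedy one-to-one matching of recovered to true loading columns
#'
#' Matches columns of `Z_hat` to columns of `Z_true` greedily by maximal
#' absolute Pearson correlation and returns the matching and its mean.
#'
#' @param Z_hat recovered loadings (gene x k).
#' @param Z_true true loadings on the same gene order (gene x k_true).
#' @return list: `pairs` (data.frame lv, module, cor) and `mean_cor`.
#' @export
match_modules <- function(Z_hat, Z_true) {
  cm <- abs(suppressWarnings(stats::cor(Z_hat, Z_true)))
  cm[is.na(cm)] <- 0
  n <- min(dim(cm))
  pairs <- data.frame(lv = integer(n), module = integer(n), cor = numeric(n))
  for (i in seq_len(n)) {
    w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pairs$lv[i] <- w[1]
    pairs$module[i] <- w[2]
    pairs$cor[i] <- cm[w[1], w[2]]
    cm[w[1], ] <- -1
    cm[, w[2]] <- -1
  }
  list(pairs = pairs, mean_cor = mean(pairs$cor))
}

#' Factorization recovery study across seeds
#'
#' For each seed, generates a dataset under the reference conditions,
#' fits the factorization with `k = k_true` and automatic penalties, and
#' measures the mean greedy-matched absolute correlation between recovered
#' and planted loadings (compared on the normalized-expression scale, i.e.
#' the true loadings are divided by the per-gene expression SD).
#'
#' @param seeds integer vector of dataset seeds.
#' @param config_fn function(seed) returning a `sim_config`; defaults to
#'   [simulation_config()] at the reference conditions.
#' @return data.frame: seed, mean_cor, n_iter, converged, monotone
#'   (objective trace non-increasing).
#' @export
recovery_study <- function(seeds = 1:5, config_fn = NULL) {
  config_fn <- config_fn %||% function(s) simulation_config(seed = s)
  rows <- lapply(seeds, function(s) {
    cfg <- config_fn(s)
    d <- generate_dataset(cfg)
    Xn <- suppressWarnings(zscore_rows(d$expression))
    C <- gene_sets_to_matrix(d$gene_sets, rownames(Xn))
    m <- plier_fit(Xn, C, k = cfg$k_true, seed = s)
    sdv <- apply(d$expression, 1, stats::sd)
    tr <- m$objective_trace
    data.frame(
      seed = s,
      mean_cor = match_modules(m$Z_raw, d$truth$Z_true / sdv)$mean_cor,
      n_iter = m$n_iter, converged = m$converged,
      monotone = all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1))
    )
  })
  do.call(rbind, rows)
}

#' GLS versus OLS calibration under a block-correlated null
#'
#' Simulates null gene scores `y ~ N(0, Sigma)` with block
#' compound-symmetric `Sigma`, regresses them on a fixed indicator covering
#' whole correlation blocks (the adversarial layout for a method that
#' ignores the covariance), and measures the one-sided rejection rate at
#' `alpha` for the GLS fit with the (shrunk) true `Sigma` and for OLS on
#' the same replicates.
#'
#' @param n_replicates number of simulated score vectors.
#' @param n_genes,block_size,rho covariance geometry.
#' @param indicator_blocks number of whole blocks covered by the indicator
#'   (`indicator_blocks * block_size` flagged genes).
#' @param alpha nominal one-sided level.
#' @param seed integer seed.
#' @return list: `gls_rejection`, `ols_rejection`, `n_replicates`.
#' @export
gls_calibration_study <- function(n_replicates = 1000, n_genes = 2000,
                                  block_size = 10, rho = 0.3,
                                  indicator_blocks = 2, alpha = 0.05,
                                  seed = 1L) {
  block_of <- ceiling(seq_len(n_genes) / block_size)
  Sigma <- rho * outer(block_of, block_of, "==")
  diag(Sigma) <- 1
  sh <- shrink_sigma(Sigma)
  s_l <- as.integer(block_of <= indicator_blocks)
  local_seed(seed, {
    p <- vapply(seq_len(n_replicates), function(i) {
      shared <- rep(stats::rnorm(max(block_of)), each = block_size)[seq_len(n_genes)]
      y <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n_genes)
      c(gls = gls_fit(y, s_l, chol_sigma = sh$chol)$pvalue_one_sided,
        ols = gls_fit(y, s_l)$pvalue_one_sided)
    }, c(gls = 0, ols = 0))
    list(gls_rejection = mean(p["gls", ] < alpha),
         ols_rejection = mean(p["ols", ] < alpha),
         n_replicates = n_replicates)
  })
}

#' Planted-truth recovery of the end-to-end pipeline
#'
#' For each seed, generates a dataset at the reference conditions (3
#' karyotype-shifted modules, 2 enriched traits, 1 comorbidity), writes it
#' to disk, runs the full pipeline from files, matches recovered latent
#' variables to planted modules by loading correlation, and records which
#' planted items the default thresholds flag and how many null items were
#' flagged alongside.
#'
#' @param seeds integer vector of dataset seeds.
#' @param config_fn function(seed) returning a `sim_config`.
#' @param k number of latent variables for the pipeline; defaults to the
#'   planted dimension of the reference conditions (`"auto"` runs parallel
#'   analysis instead).
#' @param work_dir directory for dataset bundles and run outputs; a
#'   temporary directory by default.
#' @return data.frame, one row per seed: sgm_found (planted shifts flagged),
#'   sgm_fp, trait_found, trait_fp, comorbidity_found, comorbidity_fp,
#'   clean (all planted found, zero false positives).
#' @export
planted_recovery_study <- function(seeds = 1:5, config_fn = NULL,
                                   k = 20, work_dir = NULL) {
  config_fn <- config_fn %||% function(s) simulation_config(seed = s)
  work_dir <- work_dir %||% tempfile("planted_study_")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  sigma_path <- NULL
  rows <- lapply(seeds, function(s) {
    cfg <- config_fn(s)
    d <- generate_dataset(cfg)
    bundle <- file.path(work_dir, paste0("seed_", s))
    write_dataset(d, bundle, cfg, write_sigma = is.null(sigma_path))
    if (is.null(sigma_path)) {
      sigma_path <<- file.path(bundle, "sigma_true.tsv")
    }
    pc <- pipeline_config(input_dir = bundle, sigma = sigma_path,
                          output_dir = file.path(bundle, "out"),
                          k = k, seed = s)
    run_pipeline(pc)
    out <- file.path(bundle, "out")
    Z <- read_matrix_tsv(file.path(out, "model_Z_raw.tsv"))
    sdv <- apply(d$expression, 1, stats::sd)
    mm <- match_modules(Z, d$truth$Z_true / sdv)$pairs
    lv_of <- stats::setNames(mm$lv, mm$module)

    tab <- read_table_tsv(file.path(out, "module_table.tsv"))
    assoc <- read_table_tsv(file.path(out, "associations.tsv"))
    cls <- read_table_tsv(file.path(out, "classification.tsv"))

    planted_lvs <- lv_of[as.character(d$truth$planted_sgm)]
    sgm_lvs <- tab$lv[tab$is_sgm]
    trait_pairs <- vapply(d$truth$planted_trait_pairs, function(tp) {
      paste(lv_of[as.character(tp$module)], tp$trait_id)
    }, "")
    sig_pairs <- paste(assoc$lv, assoc$trait)[assoc$significant]
    com_pairs <- vapply(d$truth$planted_comorbidity_pairs, function(cp) {
      paste(lv_of[as.character(cp$module)], cp$comorbidity_id)
    }, "")
    pass_pairs <- paste(cls$lv, cls$comorbidity)[cls$passes]

    row <- data.frame(
      seed = s,
      sgm_found = sum(planted_lvs %in% sgm_lvs),
      sgm_planted = length(planted_lvs),
      sgm_fp = length(setdiff(sgm_lvs, planted_lvs)),
      trait_found = sum(trait_pairs %in% sig_pairs),
      trait_planted = length(trait_pairs),
      trait_fp = length(setdiff(sig_pairs, trait_pairs)),
      comorbidity_found = sum(com_pairs %in% pass_pairs),
      comorbidity_planted = length(com_pairs),
      comorbidity_fp = length(setdiff(pass_pairs, com_pairs))
    )
    row$clean <- row$sgm_found == row$sgm_planted &
      row$trait_found == row$trait_planted &
      row$comorbidity_found == row$comorbidity_planted &
      row$sgm_fp + row$trait_fp + row$comorbidity_fp == 0
    unlink(file.path(bundle, "expression.tsv"))
    row
  })
  do.call(rbind, rows)
}

#' Global-null behavior of the end-to-end pipeline
#'
#' Runs the pipeline on zero-effect datasets (no karyotype shifts, no trait
#' enrichments, no comorbidity dependence) and records the sizes of the
#' SGM, association and passing-classifier lists, which should all be empty
#' at the default thresholds.
#'
#' @param seeds integer vector of dataset seeds.
#' @param k number of latent variables for the pipeline.
#' @param work_dir directory for bundles and outputs.
#' @return data.frame per seed: n_sgm, n_assoc, n_passing, empty.
#' @export
null_pipeline_study <- function(seeds = 1:5, k = 20, work_dir = NULL) {
  work_dir <- work_dir %||% tempfile("null_study_")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  sigma_path <- NULL
  rows <- lapply(seeds, function(s) {
    cfg <- simulation_config(sgm_indices = integer(0), sgm_effect = 0,
                             trait_plants = list(), n_null_traits = 5,
                             comorbidity_plants = list(),
                             n_null_comorbidities = 3, seed = s)
    d <- generate_dataset(cfg)
    bundle <- file.path(work_dir, paste0("null_seed_", s))
    write_dataset(d, bundle, cfg, write_sigma = is.null(sigma_path))
    if (is.null(sigma_path)) {
      sigma_path <<- file.path(bundle, "sigma_true.tsv")
    }
    pc <- pipeline_config(input_dir = bundle, sigma = sigma_path,
                          output_dir = file.path(bundle, "out"),
                          k = k, seed = s)
    run_pipeline(pc)
    out <- file.path(bundle, "out")
    tab <- read_table_tsv(file.path(out, "module_table.tsv"))
    assoc <- read_table_tsv(file.path(out, "associations.tsv"))
    cls <- read_table_tsv(file.path(out, "classification.tsv"))
    row <- data.frame(seed = s, n_sgm = sum(tab$is_sgm),
                      n_assoc = sum(assoc$significant),
                      n_passing = sum(cls$passes))
    row$empty <- row$n_sgm + row$n_assoc + row$n_passing == 0
    unlink(file.path(bundle, "expression.tsv"))
    row
  })
  do.call(rbind, rows)
}
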