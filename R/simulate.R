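# Synthetic-data module: generates expression, metadata, TWAS, annotation and
# prior gene sets with planted ground truth (modules, karyotype shifts, trait
# enrichments, comorbidity dependence) so every downstream stage has a
# parameter-recovery test at desk scale.

#' Configuration for the synthetic-data generator
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests and analyses: 2,000 genes, 300 trisomic (T21) and 100
#' euploid (D21) samples, 20 planted modules of which 3 carry a 1.0-SD
#' karyotype shift in activity, two traits enriched (effect 1.5 on the probit
#' score scale) in the top-loading genes of two shifted modules, and one
#' comorbidity whose labels depend logistically (slope 3) on a third shifted
#' module's activity. Trait and comorbidity plants sit on karyotype-shifted
#' modules because the downstream workflow, like the study design it mirrors,
#' only carries karyotype-specific modules forward to those stages.
#'
#' @param n_genes number of genes.
#' @param n_samples_t21,n_samples_d21 samples per karyotype group.
#' @param k_true number of planted modules.
#' @param n_pathways number of prior gene sets written to the GMT; must be at
#'   least `round(frac_aligned * k_true)` (the aligned sets); the remainder
#'   are decoy sets with random membership.
#' @param pathway_size_range integer pair (min, max) of gene-set sizes.
#' @param frac_aligned fraction of planted modules whose gene support is
#'   present as a prior set in the GMT; the remaining modules have hidden
#'   supports that no supplied prior set describes.
#' @param sgm_indices indices (1-based, within `1:k_true`) of modules whose
#'   T21 activities are shifted.
#' @param sgm_effect karyotype shift added to T21 activities, in activity
#'   standard deviations.
#' @param noise_sd_expression SD of the additive expression noise; the noise
#'   is drawn with the block compound-symmetric gene-gene correlation
#'   `Sigma_true` so the GLS stage has a matched covariance to estimate.
#' @param noise_sd_loadings SD of the loading noise added to the support
#'   part of `Z_true` before truncation at zero. The truncated noise gives
#'   every gene a small nonnegative background loading; large values make
#'   all loading columns overlap and blur module identity (and, for
#'   karyotype-shifted modules, spread the shift as a dense positive signal
#'   across the whole transcriptome); the default keeps the background at a
#'   few percent of each module's squared loading mass so that module
#'   membership, and hence the null/non-null labeling of modules, is
#'   well defined.
#' @param trait_plants list of `list(trait_id=, module=, effect=)`: traits
#'   whose association magnitudes are inflated by `effect` for the planted
#'   module's top-1 percent loading genes.
#' @param n_null_traits number of additional traits with no planted signal.
#' @param corr_block_size,corr_rho size and within-block correlation of the
#'   compound-symmetric noise blocks (`corr_rho` in `[0, 1)`).
#' @param comorbidity_plants list of `list(comorbidity_id=, module=,
#'   intercept=, slope=)`: comorbidity labels for T21 samples drawn
#'   `Bernoulli(plogis(intercept + slope * activity))`.
#' @param n_null_comorbidities number of additional comorbidities with labels
#'   independent of every module (slope 0, intercept -1).
#' @param frac_chr21 fraction of genes annotated to chromosome "21".
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical datasets.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_samples_t21 = 300,
                              n_samples_d21 = 100,
                              k_true = 20,
                              n_pathways = 25,
                              pathway_size_range = c(15, 25),
                              frac_aligned = 0.8,
                              sgm_indices = c(1L, 2L, 3L),
                              sgm_effect = 1.0,
                              noise_sd_expression = 0.3,
                              noise_sd_loadings = 0.02,
                              trait_plants = list(
                                list(trait_id = "trait_1", module = 1L, effect = 1.5),
                                list(trait_id = "trait_2", module = 2L, effect = 1.5)
                              ),
                              n_null_traits = 3,
                              corr_block_size = 10,
                              corr_rho = 0.3,
                              comorbidity_plants = list(
                                list(comorbidity_id = "comorbidity_1", module = 3L,
                                     intercept = -3, slope = 3)
                              ),
                              n_null_comorbidities = 2,
                              frac_chr21 = 0.02,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_samples_t21 = n_samples_t21,
    n_samples_d21 = n_samples_d21, k_true = k_true,
    n_pathways = n_pathways, pathway_size_range = pathway_size_range,
    frac_aligned = frac_aligned, sgm_indices = as.integer(sgm_indices),
    sgm_effect = sgm_effect,
    noise_sd_expression = noise_sd_expression,
    noise_sd_loadings = noise_sd_loadings,
    trait_plants = trait_plants, n_null_traits = n_null_traits,
    corr_block_size = corr_block_size, corr_rho = corr_rho,
    comorbidity_plants = comorbidity_plants,
    n_null_comorbidities = n_null_comorbidities,
    frac_chr21 = frac_chr21, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @return the configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    for (f in c("n_genes", "n_samples_t21", "n_samples_d21", "k_true",
                "n_pathways", "corr_block_size")) {
      if (!is_count(cfg[[f]])) abort_input("invalid configuration: ", f,
                                           " must be a positive integer")
    }
    if (length(pathway_size_range) != 2 ||
        pathway_size_range[1] > pathway_size_range[2] ||
        pathway_size_range[1] < 1) {
      abort_input("invalid configuration: pathway_size_range must be an ",
                  "increasing positive pair")
    }
    if (pathway_size_range[2] > n_genes) {
      abort_input("invalid configuration: pathway sizes exceed the gene universe")
    }
    if (frac_aligned < 0 || frac_aligned > 1) {
      abort_input("invalid configuration: frac_aligned must be in [0, 1]")
    }
    if (n_pathways < round(frac_aligned * k_true)) {
      abort_input("invalid configuration: n_pathways smaller than the number ",
                  "of aligned modules")
    }
    if (length(sgm_indices) && (any(sgm_indices < 1) || any(sgm_indices > k_true))) {
      abort_input("invalid configuration: sgm_indices outside 1..k_true")
    }
    for (tp in trait_plants) {
      if (tp$module < 1 || tp$module > k_true) {
        abort_input("invalid configuration: planted trait module outside 1..k_true")
      }
    }
    for (cp in comorbidity_plants) {
      if (cp$module < 1 || cp$module > k_true) {
        abort_input("invalid configuration: planted comorbidity module outside 1..k_true")
      }
    }
    if (corr_rho < 0 || corr_rho >= 1) {
      abort_input("invalid configuration: corr_rho must be in [0, 1)")
    }
    if (noise_sd_expression < 0 || noise_sd_loadings < 0) {
      abort_input("invalid configuration: noise SDs must be nonnegative")
    }
    if (frac_chr21 < 0 || frac_chr21 > 1) {
      abort_input("invalid configuration: frac_chr21 must be in [0, 1]")
    }
  })
  invisible(cfg)
}

#' Generate the prior gene-set membership matrix
#'
#' Draws `n_pathways` gene sets with sizes uniform in `pathway_size_range`
#' and members sampled without replacement from the gene universe, and
#' returns the binary gene-by-set membership matrix C. Deterministic given
#' the configuration seed.
#'
#' @param cfg a `sim_config`.
#' @return binary matrix, `n_genes` x `n_pathways`, with gene and set names.
#' @export
generate_prior_matrix <- function(cfg) {
  validate_config(cfg)
  local_seed(derive_seed(cfg$seed, 1L), {
    genes <- gene_ids(cfg$n_genes)
    C <- matrix(0, cfg$n_genes, cfg$n_pathways,
                dimnames = list(genes, sprintf("pathway_%02d", seq_len(cfg$n_pathways))))
    size_choices <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                     replace = TRUE)]
    for (p in seq_len(cfg$n_pathways)) {
      C[sample.int(cfg$n_genes, sizes[p]), p] <- 1
    }
    C
  })
}

gene_ids <- function(n) sprintf("gene_%05d", seq_len(n))

#' Generate a synthetic dataset with planted ground truth
#'
#' Builds a low-rank expression matrix `X = Z_true %*% B_true + noise`, where
#' each module's loading column is a gene support (a prior set from the GMT
#' for aligned modules, a hidden random set otherwise) plus truncated
#' Gaussian background (`Z_true = max(0, support + loading noise)`), activities
#' are standard normal with a karyotype shift added to T21 samples for the
#' designated modules, the expression noise carries a block
#' compound-symmetric gene-gene correlation, TWAS p-values are two-sided
#' normal tails with inflated magnitudes for planted (trait, module) pairs,
#' and comorbidity labels for T21 samples follow a logistic model on one
#' module's activity.
#'
#' @param cfg a `sim_config`.
#' @return a list with elements `expression` (gene x sample matrix),
#'   `metadata` (data.frame: sample_id, karyotype, one column per
#'   comorbidity; comorbidity status is `NA` for D21 samples), `twas`
#'   (data.frame: gene_id, trait_id, pvalue), `annotation` (data.frame:
#'   gene_id, chromosome), `gene_sets` (named list, GMT-ready) and `truth`
#'   (class `sim_truth`: Z_true, B_true, C_true, karyotype, planted_sgm,
#'   planted_trait_pairs, planted_comorbidity_pairs, sigma_blocks).
#' @export
generate_dataset <- function(cfg) {
  validate_config(cfg)
  C <- generate_prior_matrix(cfg)
  genes <- rownames(C)
  n <- cfg$n_samples_t21 + cfg$n_samples_d21
  samples <- sprintf("sample_%04d", seq_len(n))
  karyotype <- c(rep("T21", cfg$n_samples_t21), rep("D21", cfg$n_samples_d21))

  local_seed(derive_seed(cfg$seed, 2L), {
    n_aligned <- round(cfg$frac_aligned * cfg$k_true)
    # Every planted module has a gene support; the first n_aligned use a
    # prior set from the GMT (so prior knowledge covers them), the rest get
    # hidden supports of comparable size that no prior set describes.
    U <- matrix(0, cfg$n_pathways, cfg$k_true,
                dimnames = list(colnames(C), sprintf("module_%02d", seq_len(cfg$k_true))))
    for (j in seq_len(n_aligned)) U[j, j] <- 1
    S <- C %*% U
    if (cfg$k_true > n_aligned) {
      size_choices <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
      for (j in seq(n_aligned + 1, cfg$k_true)) {
        sz <- size_choices[sample.int(length(size_choices), 1)]
        S[sample.int(cfg$n_genes, sz), j] <- 1
      }
    }
    Z <- S + matrix(stats::rnorm(cfg$n_genes * cfg$k_true,
                                 sd = cfg$noise_sd_loadings),
                    cfg$n_genes, cfg$k_true)
    Z <- pmax(Z, 0)
    dimnames(Z) <- list(genes, colnames(U))

    B <- matrix(stats::rnorm(cfg$k_true * n), cfg$k_true, n,
                dimnames = list(colnames(U), samples))
    if (length(cfg$sgm_indices)) {
      B[cfg$sgm_indices, karyotype == "T21"] <-
        B[cfg$sgm_indices, karyotype == "T21"] + cfg$sgm_effect
    }

    X <- Z %*% B +
      cfg$noise_sd_expression * block_correlated_noise(cfg$n_genes, n,
                                                       cfg$corr_block_size,
                                                       cfg$corr_rho)
    dimnames(X) <- list(genes, samples)

    # gene annotation: a fixed fraction on chromosome 21, rest spread over
    # the other autosomes and X
    chrom <- sample(c(as.character(c(1:20, 22)), "X"), cfg$n_genes, replace = TRUE)
    n21 <- round(cfg$frac_chr21 * cfg$n_genes)
    if (n21 > 0) chrom[sample.int(cfg$n_genes, n21)] <- "21"
    annotation <- data.frame(gene_id = genes, chromosome = chrom,
                             stringsAsFactors = FALSE)

    twas <- generate_twas(cfg, Z, genes)
    metadata <- generate_metadata(cfg, B, karyotype, samples)

    truth <- structure(list(
      Z_true = Z, B_true = B, C_true = C, karyotype = karyotype,
      planted_sgm = cfg$sgm_indices,
      planted_trait_pairs = lapply(cfg$trait_plants, function(tp)
        list(trait_id = tp$trait_id, module = tp$module)),
      planted_comorbidity_pairs = lapply(cfg$comorbidity_plants, function(cp)
        list(comorbidity_id = cp$comorbidity_id, module = cp$module)),
      sigma_blocks = list(block_size = cfg$corr_block_size, rho = cfg$corr_rho)
    ), class = "sim_truth")

    sets <- apply(C, 2, function(col) rownames(C)[col > 0], simplify = FALSE)

    list(expression = X, metadata = metadata, twas = twas,
         annotation = annotation, gene_sets = sets, truth = truth)
  })
}

# Gaussian noise with block compound-symmetric correlation: within each block
# of `block_size` consecutive genes, every pair correlates at `rho`.
block_correlated_noise <- function(n_genes, n_samples, block_size, rho) {
  shared <- matrix(stats::rnorm(ceiling(n_genes / block_size) * n_samples),
                   ncol = n_samples)
  block_of <- ceiling(seq_len(n_genes) / block_size)
  sqrt(rho) * shared[block_of, , drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
}

#' Materialize the true gene-gene correlation matrix
#'
#' @param truth a `sim_truth`.
#' @return dense correlation matrix (symmetric positive definite, unit
#'   diagonal) of the expression noise.
#' @export
sigma_true_matrix <- function(truth) {
  n_genes <- nrow(truth$Z_true)
  bs <- truth$sigma_blocks$block_size
  rho <- truth$sigma_blocks$rho
  block_of <- ceiling(seq_len(n_genes) / bs)
  S <- rho * outer(block_of, block_of, "==")
  diag(S) <- 1
  dimnames(S) <- list(rownames(truth$Z_true), rownames(truth$Z_true))
  S
}

# TWAS table: per (gene, trait), a two-sided normal-tail p-value from a
# z-score drawn with the gene-gene correlation Sigma_true (standard-normal
# marginals), whose magnitude is inflated by `effect` for the top-1% loading
# genes of the planted module. Correlated scores are what motivate the GLS
# stage's covariance model.
generate_twas <- function(cfg, Z, genes) {
  trait_ids <- c(vapply(cfg$trait_plants, `[[`, "", "trait_id"),
                 if (cfg$n_null_traits > 0)
                   sprintf("null_trait_%d", seq_len(cfg$n_null_traits)))
  planted <- stats::setNames(
    lapply(cfg$trait_plants, function(tp) tp),
    vapply(cfg$trait_plants, `[[`, "", "trait_id"))
  rows <- lapply(trait_ids, function(tid) {
    z <- block_correlated_noise(cfg$n_genes, 1, cfg$corr_block_size,
                                cfg$corr_rho)[, 1]
    mag <- abs(z)
    tp <- planted[[tid]]
    if (!is.null(tp)) {
      idx <- top_gene_indices(Z[, tp$module], genes, 0.01)
      mag[idx] <- mag[idx] + tp$effect
    }
    data.frame(gene_id = genes, trait_id = tid,
               pvalue = 2 * stats::pnorm(-mag), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

generate_metadata <- function(cfg, B, karyotype, samples) {
  md <- data.frame(sample_id = samples, karyotype = karyotype,
                   stringsAsFactors = FALSE)
  t21 <- karyotype == "T21"
  plants <- cfg$comorbidity_plants
  if (cfg$n_null_comorbidities > 0) {
    plants <- c(plants, lapply(seq_len(cfg$n_null_comorbidities), function(i) {
      list(comorbidity_id = sprintf("null_comorbidity_%d", i),
           module = 1L, intercept = -1, slope = 0)
    }))
  }
  for (cp in plants) {
    pr <- stats::plogis(cp$intercept + cp$slope * B[cp$module, t21])
    lab <- rep(NA_integer_, length(karyotype))
    lab[t21] <- stats::rbinom(sum(t21), 1, pr)
    md[[cp$comorbidity_id]] <- lab
  }
  md
}

# Indices of the ceiling(frac * g) genes with largest values, ties at the
# boundary broken by lexicographic gene ID (shared with the ORA/GLS stages).
top_gene_indices <- function(values, ids, frac) {
  n_top <- ceiling(frac * length(values))
  ord <- order(-abs(values), ids)
  ord[seq_len(n_top)]
}

#' Write a synthetic dataset to a directory
#'
#' Writes the pipeline inputs (expression TSV, metadata TSV, TWAS TSV,
#' gene-annotation TSV, prior sets GMT, and optionally the true gene-gene
#' correlation matrix as `sigma_true.tsv`) and the ground truth (Z/B/C as
#' TSV matrices plus a JSON manifest) under `dir`.
#'
#' @param data result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param cfg the `sim_config` used (echoed into the manifest).
#' @param write_sigma whether to materialize and write `sigma_true.tsv`
#'   (dense, so sizable for large gene counts).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, cfg = NULL, write_sigma = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- table_comment(if (is.null(cfg)) NA else cfg$seed)
  write_matrix_tsv(data$expression, file.path(dir, "expression.tsv"),
                   id_col = "gene_id", comment = cm)
  write_table_tsv(data$metadata, file.path(dir, "metadata.tsv"), comment = cm)
  write_table_tsv(data$twas, file.path(dir, "twas.tsv"), comment = cm)
  write_table_tsv(data$annotation, file.path(dir, "gene_annotation.tsv"),
                  comment = cm)
  write_gmt(data$gene_sets, file.path(dir, "priors.gmt"))
  if (write_sigma) {
    write_matrix_tsv(sigma_true_matrix(data$truth),
                     file.path(dir, "sigma_true.tsv"),
                     id_col = "gene_id", comment = cm)
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_matrix_tsv(data$truth$Z_true, file.path(tdir, "Z_true.tsv"),
                   id_col = "gene_id", comment = cm)
  write_matrix_tsv(data$truth$B_true, file.path(tdir, "B_true.tsv"),
                   id_col = "module", comment = cm)
  write_matrix_tsv(data$truth$C_true, file.path(tdir, "C_true.tsv"),
                   id_col = "gene_id", comment = cm)
  manifest <- list(
    planted_sgm = data$truth$planted_sgm,
    planted_trait_pairs = data$truth$planted_trait_pairs,
    planted_comorbidity_pairs = data$truth$planted_comorbidity_pairs,
    sigma_blocks = data$truth$sigma_blocks,
    config = if (!is.null(cfg)) unclass(cfg)
  )
  jsonlite::write_json(manifest, file.path(tdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
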