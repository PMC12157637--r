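# End-to-end orchestration: a single configuration drives normalization,
# component estimation, prior-guided factorization, alignment scoring,
# karyotype-specific module inference, over-representation annotation,
# GLS trait association and comorbidity classification, with TSV/GMT/JSON
# I/O and a machine-readable run report. Trait association and comorbidity
# classification are run on the karyotype-specific modules only, mirroring
# the study design the workflow implements.

#' Build a pipeline configuration
#'
#' Defaults follow the workflow's standard thresholds: SGM FDR 0.05 with
#' absolute-effect gate 0.25, ORA on the top 5 percent of module genes at
#' FDR 0.05, GLS on the top 1 percent indicator at FDR 0.1, classification
#' thresholds AUC and mAPS 0.65 with 50 subsampling iterations.
#'
#' @param input_dir directory holding `expression.tsv`, `metadata.tsv`,
#'   `twas.tsv`, `gene_annotation.tsv`, `priors.gmt` (as written by
#'   [write_dataset()]); individual paths can be overridden.
#' @param output_dir directory for stage outputs and the run report.
#' @param expression,metadata,twas,annotation,gmt optional explicit paths.
#' @param sigma optional path to a gene-gene correlation TSV; by default the
#'   correlation is computed from the normalized expression matrix.
#' @param k number of latent variables, or `"auto"` for permutation-based
#'   parallel analysis.
#' @param frac target fraction of pathway-active LVs in the factorization.
#' @param holdout_frac prior-set member fraction held out for alignment.
#' @param n_permutations,pa_quantile parallel-analysis settings.
#' @param ora_frac,gls_top_frac,membership_frac top-loading fractions for
#'   annotation, association and the chr21 test.
#' @param sgm_fdr,sgm_effect_threshold,ora_fdr,assoc_fdr FDR and effect
#'   thresholds.
#' @param auc_threshold,maps_threshold,iterations,min_cases classification
#'   settings.
#' @param max_iter,tol solver settings.
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = tempfile("modlink_run_"),
                            expression = NULL, metadata = NULL, twas = NULL,
                            annotation = NULL, gmt = NULL, sigma = NULL,
                            k = "auto", frac = 0.7, holdout_frac = 0.2,
                            n_permutations = 20, pa_quantile = 0.95,
                            ora_frac = 0.05, gls_top_frac = 0.01,
                            membership_frac = 0.05,
                            sgm_fdr = 0.05, sgm_effect_threshold = 0.25,
                            ora_fdr = 0.05, assoc_fdr = 0.1,
                            auc_threshold = 0.65, maps_threshold = 0.65,
                            iterations = 50, min_cases = 5,
                            max_iter = 350, tol = 5e-3, seed = 1L) {
  pick <- function(x, name) x %||%
    (if (!is.null(input_dir)) file.path(input_dir, name))
  cfg <- list(
    expression = pick(expression, "expression.tsv"),
    metadata = pick(metadata, "metadata.tsv"),
    twas = pick(twas, "twas.tsv"),
    annotation = pick(annotation, "gene_annotation.tsv"),
    gmt = pick(gmt, "priors.gmt"),
    sigma = sigma, output_dir = output_dir,
    k = k, frac = frac, holdout_frac = holdout_frac,
    n_permutations = n_permutations, pa_quantile = pa_quantile,
    ora_frac = ora_frac, gls_top_frac = gls_top_frac,
    membership_frac = membership_frac,
    sgm_fdr = sgm_fdr, sgm_effect_threshold = sgm_effect_threshold,
    ora_fdr = ora_fdr, assoc_fdr = assoc_fdr,
    auc_threshold = auc_threshold, maps_threshold = maps_threshold,
    iterations = iterations, min_cases = min_cases,
    max_iter = max_iter, tol = tol, seed = as.integer(seed)
  )
  for (thr in c("sgm_fdr", "ora_fdr", "assoc_fdr", "auc_threshold",
                "maps_threshold", "frac", "holdout_frac", "ora_frac",
                "gls_top_frac", "membership_frac")) {
    if (cfg[[thr]] <= 0 || cfg[[thr]] > 1) {
      abort_input("invalid configuration: ", thr, " must be in (0, 1]")
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) abort_input("unknown configuration keys: ",
                                 paste(extra, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Read and harmonize the pipeline inputs
#'
#' Loads the five inputs and harmonizes identifiers: expression genes define
#' the factorization universe; gene-set members and TWAS rows outside it are
#' dropped; genes without a chromosome annotation are retained for
#' factorization but excluded from the chr21 test; metadata and expression
#' samples are intersected. Duplicate gene or sample identifiers, or an
#' empty sample intersection, are fatal.
#'
#' @param config a `pipeline_config`.
#' @return list: expression (matrix), metadata, twas, annotation,
#'   gene_sets, C (prior matrix), harmonization (counts of dropped items).
#' @export
read_inputs <- function(config) {
  X <- read_matrix_tsv(config$expression)
  metadata <- read_table_tsv(config$metadata)
  twas <- read_table_tsv(config$twas)
  annotation <- read_table_tsv(config$annotation)
  sets <- read_gmt(config$gmt)

  if (anyDuplicated(rownames(X))) abort_input("duplicate gene identifiers")
  if (anyDuplicated(colnames(X))) abort_input("duplicate sample identifiers")
  if (anyDuplicated(metadata$sample_id)) {
    abort_input("duplicate sample identifiers in metadata")
  }
  samples <- intersect(colnames(X), metadata$sample_id)
  if (length(samples) == 0) {
    abort_input("empty intersection of sample identifiers")
  }
  genes <- rownames(X)
  C <- gene_sets_to_matrix(sets, genes)
  twas_known <- twas[twas$gene_id %in% genes, ]
  annotated <- intersect(genes, annotation$gene_id)

  list(
    expression = X[, samples, drop = FALSE],
    metadata = metadata[match(samples, metadata$sample_id), ],
    twas = twas_known,
    annotation = annotation[match(annotated, annotation$gene_id), ],
    gene_sets = sets,
    C = C,
    harmonization = list(
      n_genes = length(genes),
      n_samples = length(samples),
      samples_dropped_expression = ncol(X) - length(samples),
      samples_dropped_metadata = nrow(metadata) - length(samples),
      genes_without_annotation = length(genes) - length(annotated),
      twas_rows_dropped = nrow(twas) - nrow(twas_known),
      gmt_members_dropped = sum(attr(C, "dropped"))
    )
  )
}

#' Run the pipeline end-to-end
#'
#' Executes normalize, estimate-k (if `k = "auto"`), fit, align,
#' differential, ORA, GLS association and classification in order, writing
#' every stage's table under `config$output_dir` and returning (and
#' writing) a run report. Stages can be restricted via `stages`; a skipped
#' stage's outputs are read back from a previous run in the same output
#' directory. The run is fully deterministic given the master seed.
#'
#' @param config a `pipeline_config`.
#' @param stages character vector among `c("fit", "differential", "ora",
#'   "gls", "classify")`; normalization and alignment travel with `"fit"`.
#' @return the run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("fit", "differential", "ora", "gls",
                                    "classify")) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  cm <- table_comment(config$seed)
  report <- list(
    package = "modlink",
    version = as.character(utils::packageVersion("modlink")),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(unlist(
      config[c("expression", "metadata", "twas", "annotation", "gmt")]))),
    stages = list()
  )
  completed <- character(0)
  on_fail <- function(stage, e) {
    report$stages_completed <- completed
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  inputs <- tryCatch(read_inputs(config), error = function(e)
    on_fail("read_inputs", e))
  report$harmonization <- inputs$harmonization
  completed <- c(completed, "read_inputs")

  Xn <- suppressWarnings(zscore_rows(inputs$expression))

  # --- fit (+ alignment) ------------------------------------------------
  if ("fit" %in% stages) {
    model <- tryCatch({
      k <- config$k
      if (identical(k, "auto")) {
        k <- estimate_num_components(Xn, config$n_permutations,
                                     config$pa_quantile,
                                     seed = derive_seed(config$seed, 10L))
        if (k < 1) abort_input("parallel analysis found no components")
      }
      masked <- mask_prior(inputs$C, config$holdout_frac,
                           seed = derive_seed(config$seed, 11L))
      model <- plier_fit(Xn, masked$C_masked, k = k, frac = config$frac,
                         max_iter = config$max_iter, tol = config$tol,
                         seed = derive_seed(config$seed, 12L))
      alignment <- pathway_alignment(model, inputs$C, masked$holdout)
      write_matrix_tsv(model$Z, out("model_Z.tsv"), "gene_id", cm)
      write_matrix_tsv(model$B, out("model_B.tsv"), "lv", cm)
      write_matrix_tsv(model$Z_raw, out("model_Z_raw.tsv"), "gene_id", cm)
      write_matrix_tsv(model$U, out("model_U.tsv"), "gene_set", cm)
      write_table_tsv(alignment, out("alignment.tsv"), cm)
      jsonlite::write_json(
        list(k = model$k, penalties = model$penalties, frac = model$frac,
             converged = model$converged, n_iter = model$n_iter,
             final_objective = utils::tail(model$objective_trace, 1),
             nonneg_note = paste("Z constrained nonnegative before",
                                 "standardization; component count by",
                                 "permutation-based parallel analysis")),
        out("model_manifest.json"), auto_unbox = TRUE, digits = NA)
      report$stages$fit <- list(k = model$k, converged = model$converged,
                                n_iter = model$n_iter,
                                n_aligned_lvs = sum(colSums(model$U > 0) > 0),
                                alignment_rows = nrow(alignment))
      model
    }, error = function(e) on_fail("fit", e))
    completed <- c(completed, "fit")
  } else {
    model <- list(Z = read_matrix_tsv(out("model_Z.tsv")),
                  B = read_matrix_tsv(out("model_B.tsv")),
                  Z_raw = read_matrix_tsv(out("model_Z_raw.tsv")),
                  U = read_matrix_tsv(out("model_U.tsv")))
    model$k <- ncol(model$Z)
  }

  # --- differential activity + chr21 test -------------------------------
  if ("differential" %in% stages) {
    module_table <- tryCatch({
      tab <- test_differential_activity(model$B, inputs$metadata$karyotype,
                                        config$sgm_fdr,
                                        config$sgm_effect_threshold)
      cols <- c("lv", "statistic", "pvalue", "fdr", "effect", "direction",
                "is_sgm", "is_top_sgm")
      write_table_tsv(tab[, cols], out("module_table.tsv"), cm)
      ann_genes <- intersect(rownames(model$Z), inputs$annotation$gene_id)
      chr21 <- NULL
      if (any(tab$is_sgm) && !all(tab$is_sgm) && length(ann_genes) > 0) {
        chrom <- inputs$annotation$chromosome[
          match(ann_genes, inputs$annotation$gene_id)]
        chr21 <- chr21_representation_test(
          model$Z[ann_genes, , drop = FALSE], tab$is_sgm, chrom,
          config$membership_frac)
        jsonlite::write_json(
          list(table = chr21$table, odds_ratio = chr21$odds_ratio,
               pvalue = chr21$pvalue, sidedness = chr21$sidedness),
          out("chr21_test.json"), auto_unbox = TRUE, digits = NA,
          matrix = "rowmajor")
      }
      report$stages$differential <- list(
        n_lvs = nrow(tab), n_sgm = sum(tab$is_sgm),
        n_top_sgm = sum(tab$is_top_sgm),
        counts = as.list(attr(tab, "counts")),
        chr21_pvalue = if (!is.null(chr21)) chr21$pvalue)
      tab
    }, error = function(e) on_fail("differential", e))
    completed <- c(completed, "differential")
  } else if (any(c("gls", "classify") %in% stages)) {
    module_table <- read_table_tsv(out("module_table.tsv"))
  } else {
    module_table <- NULL
  }
  sgm_lvs <- module_table$lv[module_table$is_sgm]

  # --- over-representation annotation -----------------------------------
  if ("ora" %in% stages) {
    tryCatch({
      ora <- annotate_modules(model$Z, inputs$gene_sets,
                              universe = rownames(model$Z),
                              frac = config$ora_frac,
                              fdr_threshold = config$ora_fdr)
      write_table_tsv(ora, out("ora.tsv"), cm)
      report$stages$ora <- list(n_pairs = nrow(ora),
                                n_significant = sum(ora$significant),
                                skipped_sets = attr(ora, "skipped"))
    }, error = function(e) on_fail("ora", e))
    completed <- c(completed, "ora")
  }

  # --- GLS trait association (SGM modules only) -------------------------
  if ("gls" %in% stages) {
    tryCatch({
      Sigma <- if (!is.null(config$sigma)) read_matrix_tsv(config$sigma) else
        expression_correlation(Xn)
      assoc <- associate_all(model$Z, inputs$twas, Sigma,
                             top_frac = config$gls_top_frac,
                             fdr_threshold = config$assoc_fdr,
                             modules = sgm_lvs)
      write_table_tsv(assoc, out("associations.tsv"), cm)
      report$stages$gls <- list(
        n_pairs = nrow(assoc), n_significant = sum(assoc$significant),
        n_modules_linked = length(unique(assoc$lv[assoc$significant])),
        skipped_traits = attr(assoc, "skipped_traits"),
        score_transform = "qnorm(1 - p/2)")
      assoc
    }, error = function(e) on_fail("gls", e))
    completed <- c(completed, "gls")
  }

  # --- comorbidity classification (SGM modules only) --------------------
  if ("classify" %in% stages) {
    tryCatch({
      metrics <- evaluate_modules(model$B, inputs$metadata,
                                  modules = sgm_lvs,
                                  auc_threshold = config$auc_threshold,
                                  maps_threshold = config$maps_threshold,
                                  iterations = config$iterations,
                                  seed = derive_seed(config$seed, 20L),
                                  min_cases = config$min_cases,
                                  min_controls = config$min_cases)
      write_table_tsv(metrics, out("classification.tsv"), cm)
      quart <- quartile_tests(model$B, inputs$metadata, metrics)
      write_table_tsv(quart, out("quartile_tests.tsv"), cm)
      report$stages$classify <- list(
        n_pairs = nrow(metrics), n_passing = sum(metrics$passes),
        passing = if (any(metrics$passes))
          metrics[metrics$passes, c("lv", "comorbidity")])
    }, error = function(e) on_fail("classify", e))
    completed <- c(completed, "classify")
  }

  report$stages_completed <- completed
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(report)
}

# gene-gene correlation from the row-normalized expression matrix
expression_correlation <- function(Xn) {
  S <- tcrossprod(Xn) / (ncol(Xn) - 1)
  d <- sqrt(diag(S))
  d[d == 0] <- 1
  S <- S / outer(d, d)
  diag(S) <- 1
  S
}

# one-sided top-quartile enrichment for every pair that passed both
# classification thresholds
quartile_tests <- function(B, metadata, metrics) {
  rows <- list()
  md <- metadata[match(colnames(B), metadata$sample_id), ]
  t21 <- which(md$karyotype == "T21")
  pass <- metrics[metrics$passes, , drop = FALSE]
  for (i in seq_len(nrow(pass))) {
    status <- md[[pass$comorbidity[i]]][t21]
    ok <- !is.na(status)
    qt <- quartile_enrichment(B[pass$lv[i], t21][ok], status[ok])
    rows[[length(rows) + 1]] <- data.frame(
      lv = pass$lv[i], comorbidity = pass$comorbidity[i],
      odds_ratio = qt$odds_ratio, pvalue = qt$pvalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(lv = integer(0), comorbidity = character(0),
               odds_ratio = numeric(0), pvalue = numeric(0),
               stringsAsFactors = FALSE)
}
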