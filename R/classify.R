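# Module-based comorbidity classification among T21 samples: ROC AUC,
# average precision, balanced mean average precision over negative-class
# subsamples, threshold-based pass flags, and top-quartile enrichment.

#' ROC AUC by the Mann-Whitney normalization
#'
#' The probability that a uniformly chosen case outscores a uniformly chosen
#' control, ties counting one half.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort_input("undefined metric: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision over the ranked score sequence
#'
#' The step-sum `sum_k (R_k - R_{k-1}) * P_k` over thresholds descending
#' through the distinct score values (tied scores enter at one threshold),
#' where `P_k` and `R_k` are precision and recall after the k-th threshold.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @return average precision in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort_input("undefined metric: at least one case required")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thresholds)
  tp_at <- cumsum(vapply(seq_along(thresholds), function(t)
    sum(labels[grp == t]), numeric(1)))
  n_at <- cumsum(vapply(seq_along(thresholds), function(t)
    sum(grp == t), numeric(1)))
  precision <- tp_at / n_at
  recall <- tp_at / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Balanced mean average precision over negative-class subsamples
#'
#' Repeatedly subsamples the controls (without replacement) to match the
#' number of cases, computes average precision on cases plus subsample, and
#' returns the mean and Monte-Carlo SD over `iterations` draws. If there are
#' fewer controls than cases all controls are used every iteration (recorded
#' in the `"note"` attribute).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @param iterations number of subsample draws.
#' @param seed integer seed.
#' @return named numeric vector `c(maps, maps_sd)` with attributes.
#' @export
balanced_maps <- function(scores, labels, iterations = 50, seed = 1L) {
  labels <- as.integer(labels)
  cases <- which(labels == 1)
  controls <- which(labels == 0)
  if (length(cases) == 0) abort_input("undefined metric: at least one case required")
  note <- NULL
  if (length(controls) < length(cases)) {
    note <- "fewer controls than cases: all controls used every iteration"
  }
  aps <- local_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      sub <- if (length(controls) <= length(cases)) controls else
        sample(controls, length(cases))
      idx <- c(cases, sub)
      average_precision(scores[idx], labels[idx])
    }, numeric(1))
  })
  out <- c(maps = mean(aps), maps_sd = stats::sd(aps))
  if (!is.null(note)) attr(out, "note") <- note
  out
}

#' Evaluate modules as comorbidity classifiers
#'
#' For every (LV, comorbidity) pair among T21 samples with at least
#' `min_cases` cases and `min_controls` controls (samples with missing
#' status excluded pairwise), computes ROC AUC, average precision and the
#' balanced mean average precision, and flags pairs passing both thresholds.
#' Each pair draws its subsamples from an independent stream derived from
#' the master seed. Under-powered pairs are skipped (listed in the
#' `"skipped"` attribute).
#'
#' @param B LV x sample activity matrix.
#' @param metadata data.frame with `sample_id`, `karyotype` and one 0/1/NA
#'   column per comorbidity, aligned by `sample_id` with the columns of B.
#' @param comorbidities character vector of metadata columns to evaluate;
#'   default: all columns other than `sample_id` and `karyotype`.
#' @param modules integer vector of LV indices to evaluate; default all.
#' @param auc_threshold,maps_threshold pass thresholds.
#' @param iterations subsample draws per pair.
#' @param seed master seed.
#' @param min_cases,min_controls minimum class sizes per pair.
#' @return data.frame: lv, comorbidity, n_cases, n_controls, auc, aps, maps,
#'   maps_sd, passes.
#' @export
evaluate_modules <- function(B, metadata, comorbidities = NULL,
                             modules = NULL, auc_threshold = 0.65,
                             maps_threshold = 0.65, iterations = 50,
                             seed = 1L, min_cases = 5, min_controls = 5) {
  comorbidities <- comorbidities %||%
    setdiff(colnames(metadata), c("sample_id", "karyotype"))
  modules <- modules %||% seq_len(nrow(B))
  md <- metadata[match(colnames(B), metadata$sample_id), ]
  t21 <- which(md$karyotype == "T21")
  rows <- list()
  skipped <- character(0)
  stream <- 0L
  for (cm in comorbidities) {
    status <- md[[cm]][t21]
    ok <- !is.na(status)
    for (j in modules) {
      stream <- stream + 1L
      labels <- as.integer(status[ok])
      scores <- B[j, t21][ok]
      n_cases <- sum(labels == 1)
      n_controls <- sum(labels == 0)
      if (n_cases < min_cases || n_controls < min_controls) {
        skipped <- c(skipped, sprintf("LV%d:%s", j, cm))
        next
      }
      auc <- roc_auc(scores, labels)
      aps <- average_precision(scores, labels)
      bm <- balanced_maps(scores, labels, iterations,
                          seed = derive_seed(seed, stream))
      rows[[length(rows) + 1]] <- data.frame(
        lv = j, comorbidity = cm, n_cases = n_cases,
        n_controls = n_controls, auc = auc, aps = aps,
        maps = bm[["maps"]], maps_sd = bm[["maps_sd"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lv = integer(0), comorbidity = character(0),
               n_cases = integer(0), n_controls = integer(0),
               auc = numeric(0), aps = numeric(0), maps = numeric(0),
               maps_sd = numeric(0), stringsAsFactors = FALSE)
  out$passes <- out$auc > auc_threshold & out$maps > maps_threshold
  attr(out, "skipped") <- skipped
  out
}

#' Top-quartile enrichment of cases
#'
#' Dichotomizes samples at the empirical `quantile_level` quantile of the
#' scores (at or above versus below) and tests overrepresentation of cases
#' in the upper group with a one-sided ("greater") Fisher exact test.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = case).
#' @param quantile_level quantile defining the upper group.
#' @return list of class `fisher_result`: table, odds_ratio, pvalue,
#'   sidedness.
#' @export
quartile_enrichment <- function(scores, labels, quantile_level = 0.75) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort_input("undefined metric: both classes required")
  }
  if (length(unique(scores)) < 2) {
    abort_input("degenerate table: all scores identical")
  }
  thr <- stats::quantile(scores, quantile_level, names = FALSE)
  high <- scores >= thr
  tab <- matrix(c(sum(high & labels == 1), sum(high & labels == 0),
                  sum(!high & labels == 1), sum(!high & labels == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("top", "rest"), c("case", "control")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 pvalue = ft$p.value, sidedness = "greater"),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher exact test (", x$sidedness, ")\n", sep = "")
  print(x$table)
  cat("odds ratio:", signif(x$odds_ratio, 4), " p-value:",
      signif(x$pvalue, 4), "\n")
  invisible(x)
}
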