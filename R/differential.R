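# Karyotype-specific gene modules: per-LV Wilcoxon rank-sum tests on
# activities, Benjamini-Hochberg correction, SGM flagging, and the
# chromosome-21 representation test.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the step-up procedure
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Two-sided Wilcoxon rank-sum p-value: exact when both groups have <= 25
# samples and the data are tie-free, normal approximation with continuity
# and tie correction otherwise.
wilcoxon_two_sided <- function(x, y) {
  exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- res$p.value
  # a single massive tie group has zero rank variance; no separation
  if (is.na(p)) p <- 1
  list(statistic = unname(res$statistic), pvalue = p)
}

#' Test modules for differential activity between karyotype groups
#'
#' Compares T21 versus D21 activities of every latent variable with a
#' two-sided Wilcoxon rank-sum test, adjusts across LVs by
#' Benjamini-Hochberg, and reports the effect as the difference of group
#' means (T21 - D21) of the standardized activities. The activity matrix is
#' standardized and signed, so a fold-change ratio is ill-defined; the
#' mean-difference effect carries the conventional magnitude threshold
#' instead (see [select_sgm()]), a convention recorded in the
#' `"effect_definition"` attribute.
#'
#' @param B latent-variable x sample activity matrix.
#' @param karyotype character vector, `"T21"`/`"D21"`, aligned with the
#'   columns of B.
#' @param fdr_threshold,effect_threshold thresholds passed to [select_sgm()].
#' @return data.frame (one row per LV): lv, statistic, pvalue, fdr, effect,
#'   direction, is_sgm, is_top_sgm.
#' @export
test_differential_activity <- function(B, karyotype,
                                       fdr_threshold = 0.05,
                                       effect_threshold = 0.25) {
  if (length(karyotype) != ncol(B)) {
    abort_input("karyotype labels must align with the columns of B")
  }
  t21 <- karyotype == "T21"
  d21 <- karyotype == "D21"
  if (sum(t21) < 2 || sum(d21) < 2) {
    abort_input("both karyotype groups need >= 2 samples")
  }
  res <- lapply(seq_len(nrow(B)), function(j) {
    w <- wilcoxon_two_sided(B[j, t21], B[j, d21])
    data.frame(lv = j, statistic = w$statistic, pvalue = w$pvalue,
               effect = mean(B[j, t21]) - mean(B[j, d21]))
  })
  tab <- do.call(rbind, res)
  if (!is.null(rownames(B))) tab$lv_name <- rownames(B)
  tab$fdr <- benjamini_hochberg(tab$pvalue)
  tab$direction <- ifelse(tab$effect >= 0, "up", "down")
  tab <- select_sgm(tab, fdr_threshold, effect_threshold)
  attr(tab, "effect_definition") <-
    "difference of group means (T21 - D21) of standardized activities"
  tab
}

#' Flag karyotype-specific gene modules
#'
#' Sets `is_sgm` (FDR below threshold) and `is_top_sgm` (additionally
#' `|effect|` above threshold) flags; up/down counts are attached as the
#' `"counts"` attribute.
#'
#' @param table module table with `fdr` and `effect` columns.
#' @param fdr_threshold FDR gate for `is_sgm`.
#' @param effect_threshold absolute-effect gate for `is_top_sgm`.
#' @return the table with flag columns set.
#' @export
select_sgm <- function(table, fdr_threshold = 0.05, effect_threshold = 0.25) {
  table$is_sgm <- table$fdr < fdr_threshold
  table$is_top_sgm <- table$is_sgm & abs(table$effect) > effect_threshold
  attr(table, "counts") <- c(
    up = sum(table$is_sgm & table$direction == "up"),
    down = sum(table$is_sgm & table$direction == "down")
  )
  table
}

#' Chromosome-21 representation test
#'
#' Tests whether chromosome-21 genes are differently represented among the
#' member genes of karyotype-specific modules versus the other modules. A
#' gene is a member of a module group if it lies in the top
#' `membership_frac` by absolute loading of any module in that group; genes
#' qualifying for both groups are counted with the SGM group, genes in
#' neither are excluded. The 2x2 table (chr21 / other) x (SGM member /
#' non-SGM member) is tested two-sided by Fisher's exact test.
#'
#' @param Z gene x LV loading matrix.
#' @param sgm_flags logical vector over LVs (which modules are SGMs).
#' @param gene_chromosomes character vector of chromosome labels aligned
#'   with the rows of Z (chromosome 21 spelled `"21"`).
#' @param membership_frac top fraction by absolute loading defining module
#'   membership.
#' @return list of class `fisher_result`: table, odds_ratio, pvalue,
#'   sidedness.
#' @export
chr21_representation_test <- function(Z, sgm_flags, gene_chromosomes,
                                      membership_frac = 0.05) {
  if (length(gene_chromosomes) != nrow(Z)) {
    abort_input("chromosome annotation must cover all genes in Z")
  }
  if (!any(sgm_flags) || all(sgm_flags)) {
    abort_input("degenerate table: both module groups must be non-empty")
  }
  genes <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  member_of_group <- function(lvs) {
    idx <- unique(unlist(lapply(lvs, function(j)
      top_gene_indices(Z[, j], genes, membership_frac))))
    genes[idx]
  }
  sgm_members <- member_of_group(which(sgm_flags))
  other_members <- setdiff(member_of_group(which(!sgm_flags)), sgm_members)
  if (length(sgm_members) == 0 || length(other_members) == 0) {
    abort_input("degenerate table: a module gene group is empty")
  }
  is21 <- stats::setNames(gene_chromosomes == "21", genes)
  tab <- matrix(c(sum(is21[sgm_members]), sum(is21[other_members]),
                  sum(!is21[sgm_members]), sum(!is21[other_members])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("chr21", "other"), c("sgm", "non_sgm")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 pvalue = ft$p.value, sidedness = "two-sided"),
            class = "fisher_result")
}
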