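# Over-representation analysis of module genes against external gene-set
# collections: hypergeometric upper-tail test of the overlap between each
# module's top-loading genes and each reference set, within a gene universe.

#' Top-loading genes of a latent variable
#'
#' Returns the `ceiling(frac * g)` genes with the largest absolute loading in
#' the LV; boundary ties are broken by lexicographic gene ID so the result
#' is deterministic.
#'
#' @param Z gene x LV loading matrix with gene rownames.
#' @param lv LV index.
#' @param frac top fraction, in (0, 1].
#' @return character vector of gene IDs.
#' @export
top_genes <- function(Z, lv, frac = 0.05) {
  if (frac <= 0 || frac > 1) abort_input("frac must be in (0, 1]")
  genes <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  genes[top_gene_indices(Z[, lv], genes, frac)]
}

#' Hypergeometric over-representation test
#'
#' Tests whether `query` overlaps `gene_set` more than expected by chance
#' within `universe`: the one-sided upper tail `P(X >= overlap)` for
#' hypergeometric X. The gene set is intersected with the universe before
#' testing.
#'
#' @param query character vector, a subset of `universe`.
#' @param gene_set character vector of reference-set gene IDs.
#' @param universe character vector: all testable genes.
#' @return one-row data.frame: overlap_count, query_size, set_size,
#'   universe_size, fold_enrichment, pvalue.
#' @export
ora_test <- function(query, gene_set, universe) {
  if (length(universe) == 0) abort_input("empty universe")
  if (length(setdiff(query, universe))) {
    abort_input("query genes must be a subset of the universe")
  }
  set_in <- intersect(gene_set, universe)
  overlap <- length(intersect(query, set_in))
  m <- length(set_in)
  n_u <- length(universe)
  q <- length(query)
  p <- stats::phyper(overlap - 1, m, n_u - m, q, lower.tail = FALSE)
  fe <- if (q > 0 && m > 0) (overlap / q) / (m / n_u) else NA_real_
  data.frame(overlap_count = overlap, query_size = q, set_size = m,
             universe_size = n_u, fold_enrichment = fe, pvalue = p)
}

#' Annotate all modules by over-representation analysis
#'
#' Runs [ora_test()] on the top `frac` genes of every LV against every gene
#' set, with Benjamini-Hochberg adjustment across all (LV, set) pairs of the
#' run. Gene sets with no genes in the universe are skipped (recorded in the
#' `"skipped"` attribute).
#'
#' @param Z gene x LV loading matrix.
#' @param gene_sets named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param universe character vector of testable genes; defaults to the rows
#'   of Z.
#' @param frac top-loading fraction defining each module's query set.
#' @param fdr_threshold rows with `fdr` below this are flagged `significant`.
#' @return data.frame: lv, gene_set, overlap_count, query_size, set_size,
#'   universe_size, fold_enrichment, pvalue, fdr, significant.
#' @export
annotate_modules <- function(Z, gene_sets, universe = rownames(Z),
                             frac = 0.05, fdr_threshold = 0.05) {
  if (length(gene_sets) == 0) abort_input("gene_sets must be nonempty")
  skipped <- names(gene_sets)[vapply(gene_sets, function(s)
    length(intersect(s, universe)) == 0, TRUE)]
  keep <- setdiff(names(gene_sets), skipped)
  rows <- list()
  for (j in seq_len(ncol(Z))) {
    query <- intersect(top_genes(Z, j, frac), universe)
    for (s in keep) {
      row <- ora_test(query, gene_sets[[s]], universe)
      rows[[length(rows) + 1]] <- cbind(data.frame(lv = j, gene_set = s,
                                                   stringsAsFactors = FALSE),
                                        row)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$pvalue)
  out$significant <- out$fdr < fdr_threshold
  attr(out, "skipped") <- skipped
  out
}
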