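# Readers and writers for the workflow's plain-text interchange formats:
# TSV matrices with row identifiers in the first column, GMT gene-set
# collections, and TSV tables. All writers prepend a comment line with the
# package version and the run seed; all readers skip '#' comment lines.

#' Read a numeric matrix from TSV
#'
#' Expects row identifiers in the first column and column identifiers in the
#' header. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_input("matrix TSV needs an ID column plus data: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) abort_input("duplicate row identifiers in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a numeric matrix to TSV
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @param id_col name for the identifier column.
#' @param comment optional comment line (written with a leading `#`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path file path.
#' @param comment optional comment line (written with a leading `#`).
#' @export
write_table_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

table_comment <- function(seed = NA) {
  sprintf("modlink %s seed=%s",
          as.character(utils::packageVersion("modlink")), as.character(seed))
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member gene IDs.
#'
#' @param path file path.
#' @return named list of character vectors of gene IDs; set descriptions are
#'   kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) abort_input("GMT lines need name, description and >=1 gene: ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) abort_input("duplicate gene-set names in ", path)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors of gene IDs.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||% rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a gene-set list to a binary membership matrix
#'
#' Builds the prior matrix C (gene x gene set) over a given gene universe;
#' set members outside the universe are dropped (counts reported via the
#' `"dropped"` attribute).
#'
#' @param sets named list of character vectors of gene IDs.
#' @param genes character vector: the gene universe, in the row order of the
#'   expression matrix.
#' @return binary matrix, genes x sets.
#' @export
gene_sets_to_matrix <- function(sets, genes) {
  if (anyDuplicated(genes)) abort_input("duplicate gene identifiers")
  C <- matrix(0, nrow = length(genes), ncol = length(sets),
              dimnames = list(genes, names(sets)))
  dropped <- integer(length(sets))
  for (i in seq_along(sets)) {
    keep <- intersect(sets[[i]], genes)
    dropped[i] <- length(sets[[i]]) - length(keep)
    C[keep, i] <- 1
  }
  attr(C, "dropped") <- stats::setNames(dropped, names(sets))
  C
}
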