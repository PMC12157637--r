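# Module-trait association: generalized least squares regression of
# probit-transformed TWAS p-values on a top-loading gene indicator, with
# residual covariance given by a (shrunk) gene-gene correlation matrix.

#' Transform association p-values to normal-scale scores
#'
#' Maps each p-value to the magnitude of the two-sided standard-normal
#' quantile, `y = qnorm(1 - p/2)`, a monotone-decreasing transform that puts
#' association strength on the scale of an absolute z-score. Values below
#' 1e-300 are clipped before transforming.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return nonnegative scores.
#' @export
pvalues_to_scores <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    abort_input("p-values must lie in (0, 1]")
  }
  stats::qnorm(pmax(pvalues, 1e-300) / 2, lower.tail = FALSE)
}

#' Top-loading indicator vector for a latent variable
#'
#' Binary vector flagging the `ceiling(top_frac * g)` genes with largest
#' absolute loading in the LV, ties broken by lexicographic gene ID. If the
#' loadings are all zero the indicator falls back to the lexicographically
#' first genes with a warning.
#'
#' @param Z gene x LV loading matrix.
#' @param lv LV index.
#' @param top_frac top fraction, in (0, 1).
#' @return named 0/1 integer vector over the genes of Z.
#' @export
build_indicator <- function(Z, lv, top_frac = 0.01) {
  if (top_frac <= 0 || top_frac >= 1) abort_input("top_frac must be in (0, 1)")
  genes <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  if (all(Z[, lv] == 0)) {
    warning("degenerate loadings: all zero; indicator assigned by gene ID",
            call. = FALSE)
  }
  idx <- top_gene_indices(Z[, lv], genes, top_frac)
  s <- stats::setNames(integer(length(genes)), genes)
  s[idx] <- 1L
  s
}

#' Shrink a correlation matrix towards the identity
#'
#' Returns `(1 - tau) * Sigma + tau * I`, doubling `tau` (up to 0.5) until
#' the Cholesky factorization succeeds, which guarantees positive
#' definiteness for downstream whitening.
#'
#' @param Sigma symmetric correlation matrix with unit diagonal.
#' @param tau initial shrinkage weight.
#' @return list: `Sigma` (shrunk matrix), `tau` (weight used), `chol` (upper
#'   triangular Cholesky factor).
#' @export
shrink_sigma <- function(Sigma, tau = 0.05) {
  if (nrow(Sigma) != ncol(Sigma)) abort_input("Sigma must be square")
  repeat {
    S <- (1 - tau) * Sigma
    diag(S) <- (1 - tau) * diag(Sigma) + tau
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (!is.null(ch)) return(list(Sigma = S, tau = tau, chol = ch))
    if (tau >= 0.5) abort_input("Sigma not positive definite after shrinkage")
    tau <- min(2 * tau, 0.5)
  }
}

#' Generalized least squares enrichment fit
#'
#' Fits `y = b0 + b1 * s_l (+ covariates)` by GLS with residual covariance
#' `Sigma`: the data are whitened by the Cholesky factor of `Sigma` and the
#' coefficient on `s_l` is tested one-sided (enrichment = positive
#' coefficient) against the t distribution with `g - rank(D)` degrees of
#' freedom. With `Sigma = NULL` (or the identity) the fit reduces exactly to
#' ordinary least squares.
#'
#' @param y numeric score vector over genes.
#' @param s_l binary indicator vector over the same genes.
#' @param covariates optional numeric matrix of gene-level covariates.
#' @param Sigma gene-gene covariance/correlation matrix, or `NULL` for the
#'   identity.
#' @param chol_sigma optional precomputed upper-triangular Cholesky factor
#'   of (shrunk) `Sigma`; overrides `Sigma`.
#' @return one-row data.frame: beta, se, df, tvalue, pvalue_one_sided,
#'   n_genes_used.
#' @export
gls_fit <- function(y, s_l, covariates = NULL, Sigma = NULL,
                    chol_sigma = NULL) {
  g <- length(y)
  if (length(s_l) != g) abort_input("y and s_l must align on the same genes")
  if (length(unique(s_l)) < 2) {
    abort_input("degenerate design: indicator is constant")
  }
  D <- cbind(intercept = 1, s = as.numeric(s_l))
  if (!is.null(covariates)) D <- cbind(D, covariates)
  if (!is.null(chol_sigma)) {
    R <- chol_sigma
  } else if (!is.null(Sigma)) {
    R <- shrink_sigma(Sigma)$chol
  } else {
    R <- NULL
  }
  if (!is.null(R)) {
    yw <- backsolve(R, y, transpose = TRUE)
    Dw <- backsolve(R, D, transpose = TRUE)
  } else {
    yw <- y
    Dw <- D
  }
  qr_d <- qr(Dw)
  if (qr_d$rank < ncol(Dw)) abort_input("degenerate design: rank deficient")
  beta <- qr.coef(qr_d, yw)
  res <- yw - Dw %*% beta
  df <- g - qr_d$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_d))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta[2] / se[2]    # the s_l coefficient (column 2 of the design)
  data.frame(beta = beta[2], se = se[2], df = df, tvalue = tval,
             pvalue_one_sided = stats::pt(tval, df, lower.tail = FALSE),
             n_genes_used = g)
}

#' Associate all modules with all traits
#'
#' Builds the top-loading indicator of every requested module, transforms
#' each trait's TWAS p-values to probit scores, and runs [gls_fit()] on
#' every (module, trait) pair, with Benjamini-Hochberg adjustment across the
#' full grid. Traits covering fewer than `min_coverage` of the model genes
#' or fewer than 100 genes are skipped; genes without a score are dropped
#' pairwise (both recorded in attributes).
#'
#' @param Z gene x LV loading matrix.
#' @param twas data.frame with columns gene_id, trait_id, pvalue.
#' @param Sigma gene-gene correlation matrix over the rows of Z (e.g. from
#'   the normalized expression), or `NULL` for the identity.
#' @param top_frac indicator fraction.
#' @param fdr_threshold rows with `fdr` below this are flagged `significant`.
#' @param modules integer vector of LV indices to test; default all.
#' @param min_coverage minimum fraction of model genes a trait must cover.
#' @return data.frame: lv, trait, beta, se, pvalue, fdr, n_genes_used,
#'   significant.
#' @export
associate_all <- function(Z, twas, Sigma = NULL, top_frac = 0.01,
                          fdr_threshold = 0.1, modules = NULL,
                          min_coverage = 0.9) {
  genes <- rownames(Z)
  modules <- modules %||% seq_len(ncol(Z))
  if (length(modules) == 0) {
    return(empty_assoc_table())
  }
  traits <- unique(twas$trait_id)
  shr <- if (!is.null(Sigma)) shrink_sigma(Sigma) else NULL
  indicators <- lapply(modules, function(j) build_indicator(Z, j, top_frac))
  names(indicators) <- as.character(modules)

  skipped <- character(0)
  dropped <- list()
  chol_cache <- list()
  rows <- list()
  for (tr in traits) {
    tt <- twas[twas$trait_id == tr, ]
    tt <- tt[!duplicated(tt$gene_id), ]
    scored <- intersect(genes, tt$gene_id)
    if (length(scored) < max(100, min_coverage * length(genes))) {
      skipped <- c(skipped, tr)
      next
    }
    dropped[[tr]] <- length(genes) - length(scored)
    y <- pvalues_to_scores(tt$pvalue[match(scored, tt$gene_id)])
    key <- paste0("g", length(scored), "_",
                  substr(paste(scored[c(1, length(scored))], collapse = ""), 1, 40))
    R <- NULL
    if (!is.null(shr)) {
      if (length(scored) == length(genes)) {
        R <- shr$chol
      } else {
        if (is.null(chol_cache[[key]])) {
          chol_cache[[key]] <- chol(shr$Sigma[scored, scored])
        }
        R <- chol_cache[[key]]
      }
    }
    for (j in modules) {
      s_l <- indicators[[as.character(j)]][scored]
      if (length(unique(s_l)) < 2) next
      fit <- gls_fit(y, s_l, chol_sigma = R)
      rows[[length(rows) + 1]] <- data.frame(
        lv = j, trait = tr, beta = fit$beta, se = fit$se,
        pvalue = fit$pvalue_one_sided, n_genes_used = fit$n_genes_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_assoc_table()
  out$fdr <- benjamini_hochberg(out$pvalue)
  out$significant <- out$fdr < fdr_threshold
  attr(out, "skipped_traits") <- skipped
  attr(out, "dropped_genes") <- dropped
  out
}

empty_assoc_table <- function() {
  data.frame(lv = integer(0), trait = character(0), beta = numeric(0),
             se = numeric(0), pvalue = numeric(0),
             n_genes_used = integer(0), stringsAsFactors = FALSE)
}
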