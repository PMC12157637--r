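# Pathway-guided matrix factorization: per-gene normalization, permutation
# based component-number estimation, a penalized block-coordinate solver for
#   || Xn - Z B ||_F^2 + lambda1 || Z - C U ||_F^2
#     + lambda2 || B ||_F^2 + lambda3 || U ||_1,   U >= 0, Z >= 0,
# post-hoc standardization of Z columns / B rows, and cross-validated
# pathway-alignment scoring on held-out prior-set members.
#
# Block order is U, Z, B within each cycle: U first, so that the prior term
# pulls Z toward C %*% U from the first update instead of toward zero.

#' Z-score normalize expression rows
#'
#' Centers and scales every gene row to mean 0 and unit sample standard
#' deviation (n - 1 denominator). Constant rows cannot be scaled; they are
#' set to all-zero, flagged with a warning, and listed in the
#' `"constant_rows"` attribute.
#'
#' @param X gene x sample numeric matrix with at least 2 columns.
#' @return normalized matrix of the same shape.
#' @export
zscore_rows <- function(X) {
  if (!is.matrix(X) || ncol(X) < 2) {
    abort_input("zscore_rows needs a matrix with >= 2 samples")
  }
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  Xn <- (X - mu) / sdv
  if (any(const)) {
    Xn[const, ] <- 0
    warning(sum(const), " constant gene row(s) set to zero", call. = FALSE)
  }
  attr(Xn, "constant_rows") <- rownames(X)[const] %||% which(const)
  Xn
}

#' Estimate the number of latent components by parallel analysis
#'
#' Compares the singular values of `Xn` with those of row-wise independently
#' permuted copies: the returned k is the number of leading singular values
#' exceeding the chosen quantile of the corresponding permuted singular
#' values (counting stops at the first that does not exceed its threshold).
#'
#' @param Xn row-normalized gene x sample matrix.
#' @param n_permutations number of permuted copies (>= 1).
#' @param quantile_level quantile of the permuted singular values used as the
#'   per-index threshold.
#' @param seed integer seed for the permutations.
#' @return integer k >= 0.
#' @export
estimate_num_components <- function(Xn, n_permutations = 20,
                                    quantile_level = 0.95, seed = 1L) {
  if (!is_count(n_permutations)) {
    abort_input("invalid configuration: n_permutations must be >= 1")
  }
  d <- svd(Xn, nu = 0, nv = 0)$d
  perm_d <- local_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      P <- t(apply(Xn, 1, sample))
      svd(P, nu = 0, nv = 0)$d
    }, numeric(length(d)))
  })
  thresh <- apply(perm_d, 1, stats::quantile, probs = quantile_level,
                  names = FALSE)
  exceeds <- d > thresh
  if (!exceeds[1]) return(0L)
  if (all(exceeds)) return(length(d))
  as.integer(which(!exceeds)[1] - 1L)
}

#' Fit the pathway-guided factorization
#'
#' Approximately minimizes the penalized objective by block coordinate
#' minimization: B by ridge least squares (closed form), Z by cyclic column
#' updates with nonnegativity (each column update is an exact minimizer), and
#' U column-wise by coordinate descent with soft-thresholding and
#' nonnegativity. Every block update is an exact minimizer of its
#' subproblem, so the objective trace is non-increasing.
#'
#' When `penalties` is `NULL` the penalties are set from the spectrum of
#' `Xn`: `lambda2 = d[k+1]`, the first singular value beyond the model rank
#' (a ridge at the noise floor that vanishes for noise-free rank-k input),
#' `lambda1 = lambda2 / 2`, and `lambda3` is tuned by bisection over at
#' most 10 warm-started refits so that the fraction of latent variables
#' with at least one nonzero pathway coefficient is closest to `frac`.
#'
#' @param Xn row-normalized gene x sample matrix.
#' @param C binary gene x gene-set prior matrix; rows must match `Xn` exactly.
#' @param k number of latent variables.
#' @param frac target fraction of latent variables with at least one nonzero
#'   pathway coefficient (used only when `lambda3` is tuned).
#' @param penalties optional list with any of `lambda1`, `lambda2`,
#'   `lambda3`; missing entries are set automatically.
#' @param max_iter maximum number of full block-update cycles.
#' @param tol convergence tolerance on the relative Frobenius change of B.
#' @param seed integer seed (the solver itself is deterministic; kept for
#'   interface uniformity).
#' @return an object of class `factor_model`: standardized `Z` (gene x k) and
#'   `B` (k x sample), pre-standardization `Z_raw`/`B_raw`, nonnegative `U`
#'   (gene set x k), `k`, `penalties`, `frac`, `objective_trace`,
#'   `converged`, `n_iter`.
#' @export
plier_fit <- function(Xn, C, k, frac = 0.7, penalties = NULL,
                      max_iter = 350, tol = 1e-3, seed = 1L) {
  if (!identical(rownames(Xn), rownames(C))) {
    abort_input("gene identifiers of the expression matrix and prior matrix ",
                "must match and be ordered identically")
  }
  if (!is_count(k) || k > min(dim(Xn))) {
    abort_input("invalid configuration: k must be in 1..min(genes, samples)")
  }
  if (frac <= 0 || frac > 1) abort_input("frac must be in (0, 1]")

  sv <- svd(Xn, nu = k, nv = k)
  # deterministic sign convention: largest-|entry| coordinate positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  Z0 <- pmax(sv$u[, seq_len(k), drop = FALSE], 0)
  B0 <- diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])

  lambda2 <- penalties$lambda2 %||%
    (if (length(sv$d) > k) sv$d[k + 1] else 0)
  lambda1 <- penalties$lambda1 %||% max(lambda2 / 2, 1e-4)
  lambda3 <- penalties$lambda3

  if (is.null(lambda3)) {
    tuned <- tune_lambda3(Xn, C, Z0, B0, lambda1, lambda2, frac,
                          max_iter = max_iter, tol = tol)
    lambda3 <- tuned$lambda3
    state <- plier_solve(Xn, C, tuned$Z, tuned$B, lambda1, lambda2, lambda3,
                         max_iter = max_iter, tol = tol, U0 = tuned$U)
  } else {
    state <- plier_solve(Xn, C, Z0, B0, lambda1, lambda2, lambda3,
                         max_iter = max_iter, tol = tol)
  }

  lv_names <- sprintf("LV%d", seq_len(k))
  dimnames(state$Z) <- list(rownames(Xn), lv_names)
  dimnames(state$B) <- list(lv_names, colnames(Xn))
  dimnames(state$U) <- list(colnames(C), lv_names)

  model <- list(
    Z = standardize_columns(state$Z),
    B = t(standardize_columns(t(state$B))),
    Z_raw = state$Z, B_raw = state$B, U = state$U, k = as.integer(k),
    penalties = list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
    frac = frac, objective_trace = state$trace,
    converged = state$converged, n_iter = state$n_iter
  )
  class(model) <- "factor_model"
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Pathway-guided factor model\n",
      "  genes: ", nrow(x$Z), ", samples: ", ncol(x$B), ", k: ", x$k, "\n",
      "  penalties: lambda1=", signif(x$penalties$lambda1, 3),
      " lambda2=", signif(x$penalties$lambda2, 3),
      " lambda3=", signif(x$penalties$lambda3, 3), "\n",
      "  iterations: ", x$n_iter, " (converged: ", x$converged, ")\n",
      "  LVs with nonzero pathway coefficients: ",
      sum(colSums(x$U > 0) > 0), "/", x$k, "\n", sep = "")
  invisible(x)
}

# One full solver run from given starting values. Returns raw Z, B, U, the
# per-cycle objective trace and convergence diagnostics.
plier_solve <- function(X, C, Z, B, lambda1, lambda2, lambda3,
                        max_iter, tol, U0 = NULL) {
  k <- ncol(Z)
  p <- ncol(C)
  U <- U0 %||% matrix(0, p, k)
  G <- crossprod(C)            # p x p
  diagG <- diag(G)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # U: per-column nonnegative lasso on ||Z_j - C u_j||^2, coordinate descent
    U <- update_U(Z, C, U, G, diagG, lambda1, lambda3)

    # Z: cyclic exact column updates with nonnegativity
    CU <- C %*% U
    R <- X - Z %*% B
    for (j in seq_len(k)) {
      bj <- B[j, ]
      denom <- sum(bj^2) + lambda1
      zj_old <- Z[, j]
      num <- R %*% bj + zj_old * sum(bj^2) + lambda1 * CU[, j]
      zj <- pmax(as.vector(num) / denom, 0)
      R <- R + outer(zj_old - zj, bj)
      Z[, j] <- zj
    }

    # B: ridge least squares given Z
    B_new <- solve(crossprod(Z) + diag(lambda2, k), crossprod(Z, X))
    rel <- norm(B_new - B, "F") / max(norm(B, "F"), .Machine$double.eps)
    B <- B_new

    trace <- c(trace, plier_objective(X, C, Z, B, U, lambda1, lambda2, lambda3))
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(Z = Z, B = B, U = U, trace = trace, converged = converged, n_iter = it)
}

update_U <- function(Z, C, U, G, diagG, lambda1, lambda3, sweeps = 30,
                     eps = 1e-10) {
  thr <- lambda3 / (2 * lambda1)
  H <- crossprod(C, Z)         # p x k
  p <- nrow(U)
  for (j in seq_len(ncol(U))) {
    u <- U[, j]
    h <- H[, j]
    for (s in seq_len(sweeps)) {
      delta <- 0
      for (q in seq_len(p)) {
        if (diagG[q] == 0) next
        g <- h[q] - sum(G[q, ] * u) + diagG[q] * u[q]
        u_new <- max(0, (g - thr) / diagG[q])
        if (u_new != u[q]) {
          delta <- delta + abs(u_new - u[q])
          u[q] <- u_new
        }
      }
      if (delta < eps) break
    }
    U[, j] <- u
  }
  U
}

plier_objective <- function(X, C, Z, B, U, lambda1, lambda2, lambda3) {
  sum((X - Z %*% B)^2) + lambda1 * sum((Z - C %*% U)^2) +
    lambda2 * sum(B^2) + lambda3 * sum(U)
}

# Bisection on lambda3 against the target fraction of LVs with >= 1 nonzero
# pathway coefficient. An initial short run at lambda3 = 0 sets the scale of
# the search interval (the soft-threshold level at which U would vanish for
# the fitted Z); subsequent refits are warm-started and capped at a reduced
# iteration budget. The best state seeds the final full-length fit.
tune_lambda3 <- function(X, C, Z0, B0, lambda1, lambda2, frac,
                         max_iter, tol, n_refits = 10) {
  short_iter <- min(max_iter, 40)
  active_frac <- function(U) mean(colSums(U > 0) > 0)
  run <- function(l3, Z, B, U) {
    plier_solve(X, C, Z, B, lambda1, lambda2, l3,
                max_iter = short_iter, tol = tol, U0 = U)
  }
  st <- run(0, Z0, B0, NULL)
  best <- list(lambda3 = 0, state = st)
  best_gap <- abs(active_frac(st$U) - frac)
  # level above which every U entry soft-thresholds to zero for this Z
  hi <- 2 * lambda1 * max(abs(crossprod(C, st$Z)))
  lo <- 0
  for (i in seq_len(n_refits - 1)) {
    cur <- (lo + hi) / 2
    st <- run(cur, st$Z, st$B, st$U)
    gap <- abs(active_frac(st$U) - frac)
    if (gap < best_gap ||
        (gap == best_gap && cur < best$lambda3)) {
      best <- list(lambda3 = cur, state = st)
      best_gap <- gap
    }
    if (active_frac(st$U) > frac) lo <- cur else hi <- cur
  }
  list(lambda3 = best$lambda3, Z = best$state$Z, B = best$state$B,
       U = best$state$U)
}

# Column-wise standardization to mean 0, unit sample variance; constant
# columns are left at all-zero.
standardize_columns <- function(M) {
  mu <- colMeans(M)
  sdv <- sqrt(colSums((t(t(M) - mu))^2) / (nrow(M) - 1))
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  S <- t((t(M) - mu) / sdv)
  S[, const] <- 0
  dimnames(S) <- dimnames(M)
  S
}

#' Mask a fraction of each prior set's members for alignment scoring
#'
#' Holds out `holdout_frac` of every gene set's members (at least one gene
#' per set with >= 2 members) by zeroing their entries in C; the held-out
#' genes are scored by [pathway_alignment()] after fitting on the masked
#' prior, which prevents circular alignment statistics.
#'
#' @param C binary gene x gene-set matrix.
#' @param holdout_frac fraction of members to hold out, in (0, 1).
#' @param seed integer seed.
#' @return list with `C_masked` and `holdout` (named list of held-out gene
#'   IDs per set).
#' @export
mask_prior <- function(C, holdout_frac = 0.2, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 1) {
    abort_input("holdout_frac must be in (0, 1)")
  }
  local_seed(seed, {
    holdout <- list()
    Cm <- C
    for (s in colnames(C)) {
      members <- rownames(C)[C[, s] > 0]
      if (length(members) < 2) next
      n_out <- max(1L, round(holdout_frac * length(members)))
      out <- sample(members, n_out)
      Cm[out, s] <- 0
      holdout[[s]] <- out
    }
    list(C_masked = Cm, holdout = holdout)
  })
}

#' Score pathway alignment on held-out prior-set members
#'
#' For every (latent variable, gene set) pair with a nonzero pathway
#' coefficient, computes the Mann-Whitney AUC of the LV's pre-standardization
#' loadings for held-out member genes versus all non-member genes, with a
#' one-sided normal-approximation p-value (tie-corrected) and
#' Benjamini-Hochberg FDR across all scored pairs. Pairs with fewer than 2
#' held-out members are skipped (recorded in the `"skipped"` attribute).
#'
#' @param model a `factor_model` fitted on the masked prior.
#' @param C the full (unmasked) binary prior matrix.
#' @param holdout named list of held-out gene IDs per set, from
#'   [mask_prior()].
#' @return data.frame: lv, gene_set, n_holdout, auc, pvalue, fdr.
#' @export
pathway_alignment <- function(model, C, holdout) {
  Z <- model$Z_raw
  rows <- list()
  skipped <- character(0)
  for (j in seq_len(model$k)) {
    active <- colnames(C)[model$U[, j] > 0]
    for (s in active) {
      held <- intersect(holdout[[s]] %||% character(0), rownames(Z))
      if (length(held) < 2) {
        skipped <- c(skipped, sprintf("LV%d:%s", j, s))
        next
      }
      nonmembers <- rownames(Z)[C[, s] == 0]
      res <- rank_auc_test(Z[held, j], Z[nonmembers, j])
      rows[[length(rows) + 1]] <- data.frame(
        lv = j, gene_set = s, n_holdout = length(held),
        auc = res$auc, pvalue = res$pvalue, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lv = integer(0), gene_set = character(0),
               n_holdout = integer(0), auc = numeric(0), pvalue = numeric(0))
  out$fdr <- benjamini_hochberg(out$pvalue)
  attr(out, "skipped") <- skipped
  out
}

# Mann-Whitney AUC (ties count 0.5) of x versus y with the one-sided
# normal-approximation p-value, tie-corrected.
rank_auc_test <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- W / (n1 * n2)
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (W - n1 * n2 / 2) / sqrt(max(sigma2, .Machine$double.eps))
  list(auc = auc, pvalue = stats::pnorm(z, lower.tail = FALSE))
}
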