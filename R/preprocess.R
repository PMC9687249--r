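## Methylation preprocessing: reference-based cell-type deconvolution by
## constrained least squares, correction of beta-values for composition,
## and methylation principal-component covariates from an uncorrelated CpG
## subset.

## Solve min ||b - R f||^2 subject to f >= 0, sum(f) = 1 by enumerating
## support sets (exact for the small number of cell types used in
## reference-based deconvolution). `rtr` = t(R) %*% R, `rtb` = t(R) %*% b.
simplex_ls <- function(rtr, rtb, k) {
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^k - 1L)) {
    s <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    m <- length(s)
    ## Equality-constrained LS on the support via the KKT system.
    kkt <- rbind(cbind(2 * rtr[s, s, drop = FALSE], rep(1, m)),
                 c(rep(1, m), 0))
    rhs <- c(2 * rtb[s], 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    f_s <- sol[seq_len(m)]
    if (any(f_s < -1e-9)) next
    f <- numeric(k)
    f[s] <- pmax(f_s, 0)
    f <- f / sum(f)
    obj <- as.numeric(t(f) %*% rtr %*% f - 2 * sum(f * rtb))
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- f
    }
  }
  best
}

#' Estimate cell-type fractions by constrained least squares
#'
#' Reference-based deconvolution: for every sample, solves
#' `min || beta_s - R f ||^2` subject to `f >= 0`, `sum(f) = 1` over the
#' CpGs shared between the beta matrix and the reference. The solution is
#' exact (support enumeration), which is feasible for the small cell-type
#' panels used in methylation references.
#'
#' @param beta CpGs x samples matrix with CpG row names.
#' @param ref CpGs x cell-types reference matrix of mean beta-values.
#' @param min_shared minimum number of shared CpGs required (default 50).
#' @return samples x cell-types matrix of fractions.
#' @export
estimate_cell_fractions <- function(beta, ref, min_shared = 50L) {
  ref <- as.matrix(ref)
  shared <- intersect(rownames(beta), rownames(ref))
  if (length(shared) < min_shared)
    stopf("only %d CpGs shared between beta matrix and reference (need >= %d)",
          length(shared), min_shared)
  r <- ref[shared, , drop = FALSE]
  b <- beta[shared, , drop = FALSE]
  k <- ncol(r)
  rtr <- crossprod(r)
  rtb_all <- crossprod(r, b)          # k x samples
  out <- matrix(NA_real_, ncol(b), k,
                dimnames = list(colnames(b), colnames(r)))
  for (j in seq_len(ncol(b)))
    out[j, ] <- simplex_ls(rtr, rtb_all[, j], k)
  out
}

#' Correct beta-values for cell-type composition
#'
#' Per CpG, regresses beta on the cell fractions (dropping the last
#' fraction column to remove the sum-to-one collinearity) and returns the
#' residuals plus the CpG grand mean, clipped to [0, 1] to preserve the
#' beta-value interpretation.
#'
#' @param beta CpGs x samples matrix.
#' @param fractions samples x cell-types matrix aligned with the columns
#'   of `beta`.
#' @return corrected beta matrix, same shape as `beta`.
#' @export
correct_for_cell_types <- function(beta, fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != ncol(beta))
    stopf("fractions rows (%d) must match beta columns (%d)",
          nrow(fractions), ncol(beta))
  x <- fractions[, -ncol(fractions), drop = FALSE]
  keep <- matrixStats::colSds(x) > 1e-10
  if (!all(keep)) {
    warnf("dropping %d constant cell-fraction column(s)", sum(!keep))
    x <- x[, keep, drop = FALSE]
  }
  design <- cbind(1, x)
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    warnf("rank-deficient cell-fraction design; dropping dependent columns")
    design <- design[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(design)
  }
  out <- beta
  mu <- rowMeans(beta)
  for (ch in chunk_indices(nrow(beta), GEN_CHUNK)) {
    yt <- t(beta[ch, , drop = FALSE])
    res <- yt - qr.fitted(qx, yt)
    out[ch, ] <- t(res) + mu[ch]
  }
  clip01(out)
}

#' Select a variance-ranked, mutually uncorrelated CpG subset
#'
#' Ranks CpGs by descending variance (CpG-id tiebreak), then greedily keeps
#' a CpG only if its absolute Pearson correlation with every
#' already-kept CpG is below `r_threshold`. Deterministic given the input.
#'
#' @param beta CpGs x samples matrix.
#' @param top_n_variance number of top-variance candidate CpGs.
#' @param r_threshold absolute-correlation exclusion threshold in (0, 1].
#' @return character vector of kept CpG ids.
#' @export
select_uncorrelated_cpgs <- function(beta, top_n_variance = 5000L,
                                     r_threshold = 0.2) {
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold > 1)
    stopf("domain error: r_threshold must be in (0, 1]")
  if (top_n_variance > nrow(beta))
    stopf("top_n_variance (%d) exceeds the number of CpGs (%d)",
          top_n_variance, nrow(beta))
  v <- matrixStats::rowVars(beta)
  ord <- order(-v, rownames(beta))[seq_len(top_n_variance)]
  cand <- beta[ord, , drop = FALSE]
  n <- ncol(cand)
  ## Row-standardize so correlation is a scaled inner product.
  s <- matrixStats::rowSds(cand)
  ok <- s > 1e-12
  cand <- (cand - rowMeans(cand)) / pmax(s, 1e-300)
  kept <- matrix(NA_real_, nrow = n, ncol = top_n_variance)
  kept_ids <- character(top_n_variance)
  n_kept <- 0L
  for (i in seq_len(nrow(cand))) {
    if (!ok[i]) next
    x <- cand[i, ]
    if (n_kept > 0L) {
      r <- crossprod(kept[, seq_len(n_kept), drop = FALSE], x) / (n - 1)
      if (any(abs(r) >= r_threshold)) next
    }
    n_kept <- n_kept + 1L
    kept[, n_kept] <- x
    kept_ids[n_kept] <- rownames(cand)[i]
  }
  kept_ids[seq_len(n_kept)]
}

#' Methylation principal-component covariates
#'
#' PCA on the column-standardized (per-CpG) subset of the beta matrix;
#' returns the first `k` sample scores, which have zero mean over samples.
#' `k = NULL` selects the number of PCs needed to explain
#' `var_explained` of the subset variance, capped at `max_k`.
#'
#' @param beta CpGs x samples matrix.
#' @param cpg_subset CpG ids to use (e.g. from
#'   [select_uncorrelated_cpgs()]).
#' @param k number of PCs, or `NULL` for automatic selection.
#' @param var_explained variance target for automatic selection.
#' @param max_k cap on the automatic selection (default 12).
#' @return samples x k matrix of PC scores (columns `PC1`, `PC2`, ...).
#' @export
compute_dnam_pcs <- function(beta, cpg_subset, k = NULL,
                             var_explained = 0.8, max_k = 12L) {
  x <- t(beta[cpg_subset, , drop = FALSE])   # samples x CpGs
  st <- standardize_columns(x)
  x <- st$x
  n <- nrow(x)
  max_rank <- min(n - 1L, ncol(x))
  sv <- svd(x, nu = max_rank, nv = 0L)
  d2 <- sv$d[seq_len(max_rank)]^2
  if (is.null(k)) {
    k <- which(cumsum(d2) / sum(sv$d^2) >= var_explained)[1]
    if (is.na(k)) k <- max_rank
    k <- min(k, max_k)
  }
  if (k > max_rank) {
    warnf("k = %d exceeds the matrix rank; truncated to %d", k, max_rank)
    k <- max_rank
  }
  if (k == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(rownames(x), NULL)))
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = n)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  scores
}

#' One-call preprocessing for a cohort
#'
#' Estimates cell fractions against the reference, corrects the beta
#' matrix for composition, selects the uncorrelated CpG subset, and
#' computes the methylation PC covariates.
#'
#' @inheritParams estimate_cell_fractions
#' @inheritParams compute_dnam_pcs
#' @param top_n_variance,r_threshold passed to
#'   [select_uncorrelated_cpgs()].
#' @return list with `fractions`, `beta_corrected`, `cpg_subset`, `pcs`.
#' @export
preprocess_cohort <- function(beta, ref, k = NULL, top_n_variance = 5000L,
                              r_threshold = 0.2, max_k = 12L) {
  fr <- estimate_cell_fractions(beta, ref)
  bc <- correct_for_cell_types(beta, fr)
  subset <- select_uncorrelated_cpgs(bc, min(top_n_variance, nrow(bc)),
                                     r_threshold)
  pcs <- compute_dnam_pcs(bc, subset, k = k, max_k = max_k)
  list(fractions = fr, beta_corrected = bc, cpg_subset = subset, pcs = pcs)
}
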