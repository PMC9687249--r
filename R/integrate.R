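## Downstream characterization of hit CpGs: cis-mQTL scan, genetic-control
## flags, DNAm-mRNA correlation in paired brain samples, cross-tissue
## correlation map, and static prior-evidence joins.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `p_adj_(i) = min_{j >= i} min(1, m p_(j) / j)`
#' over the sorted p-values. Implemented directly (not via a wrapper) so
#' its behaviour is pinned by the package's own tests.
#'
#' @param p vector of p-values (NA allowed, passed through).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- pmin(1, ps * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out[ok[o]] <- adj
  out
}

#' Cis-mQTL scan
#'
#' Tests every (SNP, CpG) pair on the same chromosome with
#' `|pos_snp - pos_cpg| <= window` (inclusive at the boundary) with an
#' additive linear model `beta_cpg ~ intercept + dosage + covariates`.
#' When `cell_fractions` are supplied, beta-values are pre-adjusted for
#' cell-type composition before the scan. Monomorphic SNPs are skipped and
#' counted.
#'
#' @param beta CpGs x samples matrix.
#' @param genotypes SNPs x samples dosage matrix (values in \[0, 2\]).
#' @param cpg_annot data.frame `cpg_id`, `chrom`, `pos`.
#' @param snp_annot data.frame `snp_id`, `chrom`, `pos`.
#' @param covariates optional covariates (see [run_ewas()]).
#' @param window cis window in bp (default 1e6).
#' @param cell_fractions optional samples x cell-types matrix for
#'   pre-adjustment via [correct_for_cell_types()].
#' @return data.frame `snp_id`, `cpg_id`, `beta_additive`, `se`, `t`, `p`,
#'   `distance`, `n`; attribute `n_monomorphic`.
#' @export
cis_mqtl_scan <- function(beta, genotypes, cpg_annot, snp_annot,
                          covariates = NULL, window = 1e6,
                          cell_fractions = NULL) {
  if (window <= 0) stopf("window must be positive")
  ids <- intersect(colnames(beta), colnames(genotypes))
  design <- covariate_design(covariates)
  if (!is.null(design))
    ids <- intersect(ids, rownames(design)[complete.cases(design)])
  if (length(ids) < 5L) stopf("too few shared samples (%d)", length(ids))
  g <- genotypes[, ids, drop = FALSE]
  if (any(g < 0 | g > 2, na.rm = TRUE))
    stopf("dosages must lie in [0, 2]")
  b <- beta[, ids, drop = FALSE]
  if (!is.null(cell_fractions))
    b <- correct_for_cell_types(b, as.matrix(cell_fractions)[ids, ,
                                                             drop = FALSE])

  ## Enumerate cis pairs per chromosome (symmetric window).
  ca <- cpg_annot[cpg_annot$cpg_id %in% rownames(b), ]
  sa <- snp_annot[snp_annot$snp_id %in% rownames(g), ]
  pairs <- do.call(rbind, lapply(intersect(unique(ca$chrom),
                                           unique(sa$chrom)), function(ch) {
    cc <- ca[ca$chrom == ch, ]
    ss <- sa[sa$chrom == ch, ]
    idx <- which(abs(outer(ss$pos, cc$pos, "-")) <= window, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(snp_id = ss$snp_id[idx[, 1]], cpg_id = cc$cpg_id[idx[, 2]],
               distance = ss$pos[idx[, 1]] - cc$pos[idx[, 2]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- data.frame(snp_id = character(), cpg_id = character(),
                      beta_additive = numeric(), se = numeric(),
                      t = numeric(), p = numeric(), distance = numeric(),
                      n = integer())
    attr(out, "n_monomorphic") <- 0L
    return(out)
  }

  n <- length(ids)
  x0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(design)) design[ids, , drop = FALSE])
  q0 <- qr(x0)
  df <- n - ncol(x0) - 1L
  ## Residualize each involved dosage and beta row once.
  snps <- unique(pairs$snp_id)
  mono <- snps[matrixStats::rowSds(g[snps, , drop = FALSE]) < 1e-12]
  pairs <- pairs[!pairs$snp_id %in% mono, ]
  snps <- setdiff(snps, mono)
  cpgs <- unique(pairs$cpg_id)
  g_r <- t(qr.resid(q0, t(g[snps, , drop = FALSE])))
  b_r <- t(qr.resid(q0, t(b[cpgs, , drop = FALSE])))
  gi <- match(pairs$snp_id, snps)
  bi <- match(pairs$cpg_id, cpgs)
  sxx <- rowSums(g_r^2)[gi]
  syy <- rowSums(b_r^2)[bi]
  sxy <- rowSums(g_r[gi, , drop = FALSE] * b_r[bi, , drop = FALSE])
  coef <- sxy / sxx
  rss <- pmax(syy - coef^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tv <- coef / se
  out <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                    beta_additive = coef, se = se, t = tv,
                    p = 2 * pt(-abs(tv), df = df),
                    distance = pairs$distance, n = n,
                    stringsAsFactors = FALSE)
  attr(out, "n_monomorphic") <- length(mono)
  out
}

#' Flag CpGs under genetic control
#'
#' Applies BH-FDR across all tested cis pairs; a CpG is "under genetic
#' control" if at least one of its pairs passes the FDR threshold. Hit
#' CpGs without any cis SNP are flagged "untestable".
#'
#' @param mqtl [cis_mqtl_scan()] result.
#' @param hit_cpgs CpG ids of interest.
#' @param fdr FDR level (default 0.05).
#' @return data.frame `cpg_id`, `status` in
#'   `{genetic_control, not_significant, untestable}`, `min_q`,
#'   `n_cis_snps`.
#' @export
genetic_control_flags <- function(mqtl, hit_cpgs, fdr = 0.05) {
  q <- bh_adjust(mqtl$p)
  res <- lapply(hit_cpgs, function(cpg) {
    i <- which(mqtl$cpg_id == cpg)
    if (length(i) == 0L)
      return(data.frame(cpg_id = cpg, status = "untestable",
                        min_q = NA_real_, n_cis_snps = 0L))
    mq <- min(q[i], na.rm = TRUE)
    data.frame(cpg_id = cpg,
               status = if (mq < fdr) "genetic_control" else
                 "not_significant",
               min_q = mq, n_cis_snps = length(i))
  })
  do.call(rbind, res)
}

#' DNAm-mRNA correlation for CpG-gene pairs
#'
#' Spearman rank correlation between the methylation of each CpG and the
#' normalized expression of its annotated gene over matched samples, with
#' BH-FDR adjustment across the pair family. Pairs with fewer than
#' `min_n` matched samples or zero-variance expression give NA records.
#'
#' @param brain_beta CpGs x samples matrix.
#' @param expression genes x samples matrix.
#' @param pairs data.frame `cpg_id`, `gene`.
#' @param min_n minimum matched samples per pair (default 10).
#' @return data.frame `cpg_id`, `gene`, `rho`, `p`, `q`, `n`.
#' @export
dnam_mrna_correlation <- function(brain_beta, expression, pairs,
                                  min_n = 10L) {
  ids <- intersect(colnames(brain_beta), colnames(expression))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cpg <- pairs$cpg_id[i]
    gene <- pairs$gene[i]
    if (!cpg %in% rownames(brain_beta) || !gene %in% rownames(expression))
      return(data.frame(cpg_id = cpg, gene = gene, rho = NA_real_,
                        p = NA_real_, n = 0L))
    x <- brain_beta[cpg, ids]
    y <- expression[gene, ids]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n || sd(y[ok]) < 1e-12 || sd(x[ok]) < 1e-12)
      return(data.frame(cpg_id = cpg, gene = gene, rho = NA_real_,
                        p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(cpg_id = cpg, gene = gene, rho = unname(ct$estimate),
               p = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Cross-tissue per-CpG correlation map
#'
#' Pearson correlation per CpG across matched individuals between two
#' tissues, classified as low (|r| < 0.3), moderate (0.3 <= |r| < 0.5) or
#' high (|r| >= 0.5); the cut-points are configurable.
#'
#' @param tissue_a_beta,tissue_b_beta CpGs x samples matrices with sample
#'   ids naming matched individuals.
#' @param cutpoints two increasing |r| cut-points (default 0.3, 0.5).
#' @param min_n minimum matched individuals (default 10).
#' @return data.frame `cpg_id`, `r`, `class`.
#' @export
cross_tissue_map <- function(tissue_a_beta, tissue_b_beta,
                             cutpoints = c(0.3, 0.5), min_n = 10L) {
  ids <- intersect(colnames(tissue_a_beta), colnames(tissue_b_beta))
  if (length(ids) < min_n)
    stopf("only %d matched individuals (need >= %d)", length(ids), min_n)
  dropped <- (ncol(tissue_a_beta) - length(ids)) +
    (ncol(tissue_b_beta) - length(ids))
  if (dropped > 0)
    message(sprintf("cross_tissue_map: %d unmatched samples dropped",
                    dropped))
  cpgs <- intersect(rownames(tissue_a_beta), rownames(tissue_b_beta))
  a <- tissue_a_beta[cpgs, ids, drop = FALSE]
  b <- tissue_b_beta[cpgs, ids, drop = FALSE]
  az <- (a - rowMeans(a)) / pmax(matrixStats::rowSds(a), 1e-300)
  bz <- (b - rowMeans(b)) / pmax(matrixStats::rowSds(b), 1e-300)
  r <- rowSums(az * bz) / (length(ids) - 1)
  cls <- cut(abs(r), breaks = c(-Inf, cutpoints, Inf),
             labels = c("low", "moderate", "high"), right = FALSE)
  data.frame(cpg_id = cpgs, r = r, class = as.character(cls),
             stringsAsFactors = FALSE)
}

#' Join hit CpGs against a static prior-evidence table
#'
#' Left-joins hits against a user-supplied evidence table keyed by
#' `cpg_id` (preferred) or `gene`, and flags direction concordance where
#' both sides carry signed effects (`effect` in the hits, `direction`
#' +1/-1 or `+`/`-` in the evidence).
#'
#' @param hits data.frame with `cpg_id` (optionally `gene`, `effect`).
#' @param evidence data.frame with `cpg_id` or `gene` plus annotation
#'   columns (e.g. `source`, `phenotype`, `direction`).
#' @return `hits` with evidence columns appended (suffix `_evidence`).
#' @export
prior_evidence_join <- function(hits, evidence) {
  if (!any(c("cpg_id", "gene") %in% names(evidence)))
    stopf("schema error: evidence file needs a 'cpg_id' or 'gene' column; found: %s",
          paste(names(evidence), collapse = ", "))
  key <- if ("cpg_id" %in% names(evidence)) "cpg_id" else "gene"
  if (!key %in% names(hits))
    stopf("hits table lacks the join key '%s'", key)
  out <- merge(hits, evidence, by = key, all.x = TRUE,
               suffixes = c("", "_evidence"))
  if ("effect" %in% names(out) && "direction" %in% names(out)) {
    dir_num <- ifelse(out$direction %in% c("+", "1", "up"), 1,
                      ifelse(out$direction %in% c("-", "-1", "down"), -1,
                             suppressWarnings(as.numeric(out$direction))))
    out$direction_concordant <- ifelse(
      is.na(dir_num) | is.na(out$effect), NA,
      sign(out$effect) == sign(dir_num))
  }
  out[order(match(out[[key]], hits[[key]])), ]
}
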