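## Per-CpG association: linear model with the memory phenotype as the
## continuous outcome and methylation as the predictor, plus inflation
## diagnostics and significance tiers.

#' Significance tiers for array-scale EWAS
#'
#' Epigenome-wide significance at 9e-8 (EPIC-array-wide threshold) and a
#' suggestive tier at 1e-5; classification uses strict inequalities.
#'
#' @param epigenome_wide,suggestive tier thresholds.
#' @return a `mem_tiers` list.
#' @export
significance_tiers <- function(epigenome_wide = 9e-8, suggestive = 1e-5) {
  if (epigenome_wide >= suggestive)
    stopf("epigenome_wide threshold must be below the suggestive threshold")
  structure(list(epigenome_wide = epigenome_wide, suggestive = suggestive),
            class = "mem_tiers")
}

## Convert a covariate data.frame/matrix into a numeric design block
## (no intercept). Character/factor columns are expanded to treatment
## dummies; sample ids come from rownames or a sample_id column.
covariate_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  if ("sample_id" %in% names(cv)) {
    rownames(cv) <- cv$sample_id
    cv$sample_id <- NULL
  }
  if (ncol(cv) == 0L) return(NULL)
  mm <- stats::model.matrix(~ ., data = cv)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  rownames(mm) <- rownames(cv)
  mm
}

align_samples <- function(beta, phenotype, design) {
  ids <- colnames(beta)
  ids <- intersect(ids, names(phenotype)[is.finite(phenotype)])
  if (!is.null(design))
    ids <- intersect(ids, rownames(design)[complete.cases(design)])
  ids
}

#' Per-CpG linear-model association scan
#'
#' For each CpG fits `phenotype ~ intercept + beta_cpg + covariates` by
#' least squares and reports the methylation coefficient, its standard
#' error, t statistic and two-sided p-value from the t distribution with
#' the full-model residual degrees of freedom. The computation is
#' vectorized over CpGs via the Frisch-Waugh-Lovell projection and is
#' numerically identical to per-CpG `lm()` fits. Samples missing the
#' phenotype or any covariate are dropped listwise; constant beta rows get
#' an NA row with a reason code.
#'
#' @param beta CpGs x samples matrix.
#' @param phenotype named numeric vector (names are sample ids).
#' @param covariates optional data.frame/matrix of covariates with sample
#'   ids as rownames (or a `sample_id` column); character columns are
#'   expanded to dummies.
#' @param cohort label stored in the result.
#' @return data.frame `cpg_id`, `effect`, `se`, `t`, `p`, `n`, `cohort`,
#'   `reason` (NA for clean fits).
#' @export
run_ewas <- function(beta, phenotype, covariates = NULL,
                     cohort = "cohort") {
  design <- covariate_design(covariates)
  ids <- align_samples(beta, phenotype, design)
  n <- length(ids)
  x <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(design)) design[ids, , drop = FALSE])
  p_model <- ncol(x) + 1L   # + the CpG term
  if (n <= p_model + 1L)
    stopf("only %d aligned samples for %d model parameters", n, p_model)
  y <- phenotype[ids]
  qx <- qr(x)
  y_r <- qr.resid(qx, y)
  syy <- sum(y_r^2)
  df <- n - p_model

  n_cpg <- nrow(beta)
  eff <- se <- tv <- pv <- rep(NA_real_, n_cpg)
  reason <- rep(NA_character_, n_cpg)
  for (ch in chunk_indices(n_cpg, GEN_CHUNK)) {
    b <- t(beta[ch, ids, drop = FALSE])
    b_r <- b - qr.fitted(qx, b)
    sxx <- colSums(b_r^2)
    sxy <- colSums(b_r * y_r)
    const <- sxx < n * 1e-20
    coef <- ifelse(const, NA_real_, sxy / sxx)
    rss <- pmax(syy - coef^2 * sxx, 0)
    s2 <- rss / df
    eff[ch] <- coef
    se[ch] <- sqrt(s2 / sxx)
    reason[ch][const] <- "constant_beta"
  }
  tv <- eff / se
  pv <- 2 * pt(-abs(tv), df = df)
  data.frame(cpg_id = rownames(beta), effect = eff, se = se, t = tv,
             p = pv, n = n, cohort = cohort, reason = reason,
             stringsAsFactors = FALSE)
}

#' Genomic inflation factor of a p-value distribution
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`; values
#' near 1 indicate well-calibrated tests.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param min_p minimum count required (default 100).
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(p_values, min_p = 100L) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < min_p)
    stopf("need at least %d p-values for a stable lambda", min_p)
  if (any(p_values <= 0) || any(p_values > 1))
    stopf("p-values must lie in (0, 1]")
  chi <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Classify association results into significance tiers
#'
#' Adds a `tier` column in `{epigenome_wide, suggestive, none}` using
#' strict inequalities at both thresholds.
#'
#' @param results data.frame with a `p` column.
#' @param tiers a [significance_tiers()].
#' @return `results` with a `tier` column.
#' @export
classify_hits <- function(results, tiers = significance_tiers()) {
  tier <- rep("none", nrow(results))
  tier[!is.na(results$p) & results$p < tiers$suggestive] <- "suggestive"
  tier[!is.na(results$p) & results$p < tiers$epigenome_wide] <-
    "epigenome_wide"
  results$tier <- tier
  results
}

#' Plot-ready Manhattan table
#'
#' Joins results to the CpG annotation, keeps autosomes only, and adds
#' `-log10(p)`, a cumulative genome coordinate (strictly increasing within
#' and across ordered chromosomes), and a gene label for suggestive CpGs.
#'
#' @param results EWAS/meta result data.frame with `cpg_id` and `p`.
#' @param annotation data.frame `cpg_id`, `chrom`, `pos`, `gene`.
#' @param tiers a [significance_tiers()].
#' @return data.frame ordered by genome position.
#' @export
manhattan_table <- function(results, annotation,
                            tiers = significance_tiers()) {
  m <- merge(results, annotation[c("cpg_id", "chrom", "pos", "gene")],
             by = "cpg_id")
  dropped <- nrow(results) - nrow(m)
  m$chrom <- suppressWarnings(as.integer(m$chrom))
  auto <- !is.na(m$chrom) & m$chrom >= 1L & m$chrom <= 22L
  dropped <- dropped + sum(!auto)
  if (dropped > 0)
    message(sprintf("manhattan_table: excluded %d unannotated/non-autosomal CpGs",
                    dropped))
  m <- m[auto & !is.na(m$p), ]
  m <- m[order(m$chrom, m$pos), ]
  offsets <- c(0, cumsum(AUTOSOME_LENGTHS))[m$chrom]
  m$cum_pos <- offsets + m$pos
  m$neg_log10_p <- -log10(m$p)
  m$label <- ifelse(m$p < tiers$suggestive, m$gene, "")
  m
}
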