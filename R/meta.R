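## Fixed-effect meta-analysis across cohorts and cross-tissue concordance
## of EWAS test statistics.

#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-cohort EWAS results by CpG id with inverse-variance
#' weights `w_i = 1/se_i^2`: pooled effect `sum(w b)/sum(w)`, pooled
#' standard error `1/sqrt(sum(w))`, z-based two-sided p, Cochran's
#' `Q = sum(w (b - bhat)^2)` and `I^2 = max(0, (Q - (k-1))/Q)`. CpGs
#' present in a single study are passed through with `k_studies = 1`;
#' studies with non-positive or missing standard errors are excluded per
#' CpG.
#'
#' @param per_study named list of [run_ewas()] result data.frames.
#' @return data.frame `cpg_id`, `effect`, `se`, `z`, `p`, `k_studies`,
#'   `direction` (one `+`/`-`/`?` per contributing study), `Q`, `I2`.
#' @export
fixed_effect_meta <- function(per_study) {
  if (length(per_study) < 1L) stopf("need at least one study")
  if (is.null(names(per_study)))
    names(per_study) <- paste0("study", seq_along(per_study))
  dt <- data.table::rbindlist(lapply(names(per_study), function(nm) {
    d <- per_study[[nm]]
    data.table::data.table(cpg_id = d$cpg_id, effect = d$effect,
                           se = d$se, study = nm)
  }))
  dt <- dt[is.finite(effect) & is.finite(se) & se > 0]
  data.table::setorder(dt, cpg_id, study)
  agg <- dt[, {
    w <- 1 / se^2
    bhat <- sum(w * effect) / sum(w)
    sehat <- 1 / sqrt(sum(w))
    q <- sum(w * (effect - bhat)^2)
    k <- .N
    list(effect = bhat, se = sehat, z = bhat / sehat,
         p = 2 * pnorm(-abs(bhat / sehat)), k_studies = k,
         direction = paste(ifelse(effect > 0, "+",
                                  ifelse(effect < 0, "-", "?")),
                           collapse = ""),
         Q = q, I2 = if (k > 1L && q > 0) max(0, (q - (k - 1)) / q) else 0)
  }, by = cpg_id]
  as.data.frame(agg)
}

#' Sample-size-weighted z meta-analysis
#'
#' Alternative combination: `z = sum(sqrt(n_i) z_i sign-free) /
#' sqrt(sum n_i)` using per-study z = effect/se and weights sqrt(n).
#' Reported for sensitivity only; the fixed-effect estimator is the
#' default.
#'
#' @param per_study named list of [run_ewas()] result data.frames with an
#'   `n` column.
#' @return data.frame `cpg_id`, `z`, `p`, `k_studies`.
#' @export
weighted_z_meta <- function(per_study) {
  dt <- data.table::rbindlist(lapply(per_study, function(d)
    data.table::data.table(cpg_id = d$cpg_id, z = d$effect / d$se,
                           n = d$n)))
  dt <- dt[is.finite(z)]
  agg <- dt[, {
    zc <- sum(sqrt(n) * z) / sqrt(sum(n))
    list(z = zc, p = 2 * pnorm(-abs(zc)), k_studies = .N)
  }, by = cpg_id]
  as.data.frame(agg)
}

#' Cross-phenotype hit report
#'
#' For each CpG suggestive in one phenotype's meta-analysis, reports the
#' other phenotype's effect and p-value and flags nominal (`p < 0.05`,
#' strict) concordance and sign agreement — the structure of a two-panel
#' suggestive-hit table.
#'
#' @param meta_cross,meta_long meta-analysis result data.frames.
#' @param tiers a [significance_tiers()].
#' @param annotation optional CpG annotation (`cpg_id`, `chrom`, `pos`,
#'   `gene`) for location columns.
#' @return data.frame with one row per suggestive CpG per panel.
#' @export
cross_tabulate_phenotypes <- function(meta_cross, meta_long,
                                      tiers = significance_tiers(),
                                      annotation = NULL) {
  one_panel <- function(primary, other, panel) {
    hits <- primary[!is.na(primary$p) & primary$p < tiers$suggestive, ]
    if (nrow(hits) == 0L) return(NULL)
    i <- match(hits$cpg_id, other$cpg_id)
    out <- data.frame(panel = panel, cpg_id = hits$cpg_id,
                      effect_primary = hits$effect, p_primary = hits$p,
                      effect_other = other$effect[i], p_other = other$p[i],
                      stringsAsFactors = FALSE)
    out$nominal_other <- !is.na(out$p_other) & out$p_other < 0.05
    out$sign_concordant <- !is.na(out$effect_other) &
      sign(out$effect_primary) == sign(out$effect_other)
    out$concordant <- out$nominal_other & out$sign_concordant
    out
  }
  out <- rbind(one_panel(meta_cross, meta_long, "cross_sectional"),
               one_panel(meta_long, meta_cross, "longitudinal"))
  if (is.null(out))
    out <- data.frame(panel = character(), cpg_id = character(),
                      effect_primary = numeric(), p_primary = numeric(),
                      effect_other = numeric(), p_other = numeric(),
                      nominal_other = logical(),
                      sign_concordant = logical(), concordant = logical())
  if (!is.null(annotation) && nrow(out) > 0L) {
    i <- match(out$cpg_id, annotation$cpg_id)
    out$location <- sprintf("chr%s:%d", annotation$chrom[i],
                            as.integer(annotation$pos[i]))
    out$gene <- annotation$gene[i]
  }
  out[order(out$panel, out$p_primary), ]
}

#' Correlation of test statistics between two analyses
#'
#' Pearson correlation of per-CpG t statistics over the CpGs shared by two
#' result tables — a summary of cross-tissue (or cross-analysis)
#' concordance.
#'
#' @param results_a,results_b result data.frames with `cpg_id` and `t`.
#' @param min_shared warn below this overlap (default 1000).
#' @return list with `r`, `p`, `n_shared`.
#' @export
tissue_statistic_correlation <- function(results_a, results_b,
                                         min_shared = 1000L) {
  m <- merge(results_a[c("cpg_id", "t")], results_b[c("cpg_id", "t")],
             by = "cpg_id", suffixes = c("_a", "_b"))
  m <- m[is.finite(m$t_a) & is.finite(m$t_b), ]
  if (nrow(m) < 3L) stopf("fewer than 3 shared CpGs")
  if (nrow(m) < min_shared)
    warnf("only %d shared CpGs (< %d); correlation may be unstable",
          nrow(m), min_shared)
  ct <- cor.test(m$t_a, m$t_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = nrow(m))
}
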