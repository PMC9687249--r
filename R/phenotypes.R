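## Episodic-memory phenotype construction.
##
## Cross-sectional phenotype: first principal component of the memory test
## scores (correlation-matrix PCA), residualized on age at the assessment
## used. Longitudinal phenotype: mean annual percentage change (APC) of the
## test scores between baseline and follow-up.

#' First principal component of a test-score matrix
#'
#' Column-standardizes the score matrix (correlation-matrix PCA; constant
#' columns are dropped with a warning), imputes missing entries at the
#' column mean of the standardized scale (zero), and returns the sample
#' scores on the first principal axis. The sign is fixed so that PC1
#' correlates positively with the row mean of the standardized scores
#' ("higher = better performance").
#'
#' @param scores samples x tests numeric matrix.
#' @return numeric vector of PC1 scores, one per row of `scores`.
#' @export
compute_pc1 <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) stopf("need at least 2 tests for a PC1")
  if (nrow(scores) < 3L) stopf("need at least 3 samples for a PC1")
  st <- standardize_columns(scores)
  if (length(st$dropped) > 0L) {
    warnf("dropping %d constant test column(s) before PCA",
          length(st$dropped))
    if (ncol(st$x) < 1L) stopf("all test columns are constant")
  }
  x <- st$x
  x[is.na(x)] <- 0
  sv <- svd(x, nu = 1L, nv = 1L)
  pc1 <- sv$u[, 1L] * sv$d[1L]
  rm <- rowMeans(x)
  if (sum(pc1 * rm) < 0) pc1 <- -pc1
  pc1
}

#' Residualize a phenotype on age
#'
#' Ordinary least squares of `phenotype ~ intercept + age`; the residuals
#' are returned and are orthogonal to both the constant and `age`. With a
#' constant age vector the mean-centered phenotype is returned with a
#' warning.
#'
#' @param phenotype numeric vector.
#' @param age numeric vector (years), same length.
#' @return residual vector.
#' @export
residualize_on_age <- function(phenotype, age) {
  if (length(phenotype) != length(age))
    stopf("phenotype and age must have equal length")
  if (length(phenotype) < 3L) stopf("need at least 3 samples")
  if (sd(age) < 1e-12) {
    warnf("age vector is constant; returning mean-centered phenotype")
    return(phenotype - mean(phenotype))
  }
  as.numeric(project_out(phenotype, cbind(1, age)))
}

#' Annual percentage change of a test score
#'
#' `100 * ((followup - baseline) / baseline) / interval`, i.e. the relative
#' change per year in percent. Undefined (NA) when the baseline is zero or
#' the interval is not positive.
#'
#' @param baseline,followup scores (vectorized).
#' @param interval years between assessments.
#' @return percent change per year.
#' @export
annual_percentage_change <- function(baseline, followup, interval) {
  out <- 100 * ((followup - baseline) / baseline) / interval
  out[!is.finite(out) | baseline == 0 | interval <= 0] <- NA_real_
  out
}

#' Paired t-test on score change
#'
#' Two-sided paired t-test of `followup - baseline`, computed in closed
#' form (`t = mean(d) / (sd(d) / sqrt(n))`, n - 1 degrees of freedom).
#'
#' @param baseline,followup paired numeric vectors, complete observations.
#' @return list with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_change_test <- function(baseline, followup) {
  ok <- is.finite(baseline) & is.finite(followup)
  d <- followup[ok] - baseline[ok]
  n <- length(d)
  if (n < 3L) stopf("need at least 3 complete pairs")
  s <- sd(d)
  if (s < 1e-14) {
    warnf("zero variance of paired differences; p undefined")
    return(list(t = NA_real_, p = NA_real_, df = n - 1L,
                mean_diff = mean(d), n = n))
  }
  tv <- mean(d) / (s / sqrt(n))
  list(t = tv, p = 2 * pt(-abs(tv), df = n - 1L), df = n - 1L,
       mean_diff = mean(d), n = n)
}

## Locate test score columns test<k>_t1 / test<k>_t2 in a sample sheet.
test_columns <- function(sheet, timepoint) {
  cols <- grep(sprintf("^test[0-9]+_t%d$", timepoint), names(sheet),
               value = TRUE)
  cols[order(as.integer(sub("^test([0-9]+)_.*$", "\\1", cols)))]
}

#' Build the phenotype table for one cohort
#'
#' The cross-sectional phenotype `em_cross` is the age-residualized PC1 of
#' the test scores at the assessment used for DNA sampling (follow-up
#' scores when a follow-up assessment exists, otherwise the single
#' timepoint). The longitudinal phenotype `em_long` is the mean APC across
#' tests for samples with both timepoints. Samples need at least half of
#' the tests non-missing to receive `em_cross`.
#'
#' @param sheet sample sheet data.frame (one cohort) with columns
#'   `sample_id`, `age_baseline`, `age_followup` and `test<k>_t1/_t2`.
#' @param residualize_long also residualize `em_long` on age (off by
#'   default: the longitudinal phenotype is already a rate).
#' @return data.frame `sample_id`, `em_cross`, `em_long`, `age`,
#'   `interval_years` plus pass-through covariate columns.
#' @export
build_phenotypes <- function(sheet, residualize_long = FALSE) {
  t1c <- test_columns(sheet, 1L)
  t2c <- test_columns(sheet, 2L)
  if (length(t1c) == 0L) stopf("no test score columns found")
  has_t2 <- length(t2c) > 0L && any(is.finite(as.matrix(sheet[t2c])))
  cross_cols <- if (has_t2) t2c else t1c
  cross_scores <- as.matrix(sheet[cross_cols])
  age <- if (has_t2) sheet$age_followup else sheet$age_baseline

  n_ok <- rowSums(is.finite(cross_scores))
  eligible <- n_ok >= ceiling(length(cross_cols) / 2) & is.finite(age)
  em_cross <- rep(NA_real_, nrow(sheet))
  if (sum(eligible) >= 3L) {
    pc1 <- compute_pc1(cross_scores[eligible, , drop = FALSE])
    em_cross[eligible] <- residualize_on_age(pc1, age[eligible])
  }

  em_long <- rep(NA_real_, nrow(sheet))
  interval <- rep(NA_real_, nrow(sheet))
  if (has_t2) {
    interval <- sheet$age_followup - sheet$age_baseline
    apc <- sapply(seq_along(t1c), function(k)
      annual_percentage_change(sheet[[t1c[k]]], sheet[[t2c[k]]], interval))
    em_long <- rowMeans(apc, na.rm = TRUE)
    em_long[!is.finite(em_long)] <- NA_real_
    if (residualize_long) {
      ok <- is.finite(em_long) & is.finite(age)
      if (sum(ok) >= 3L)
        em_long[ok] <- residualize_on_age(em_long[ok], age[ok])
    }
  }

  keep <- intersect(c("cohort", "tissue", "batch", "sex"), names(sheet))
  out <- data.frame(sample_id = sheet$sample_id, em_cross = em_cross,
                    em_long = em_long, age = age,
                    interval_years = interval, stringsAsFactors = FALSE)
  cbind(out, sheet[keep])
}
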