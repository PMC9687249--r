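## Poly-epigenetic scores from external EWAS summary statistics and
## multi-tissue epigenetic-clock age estimation with acceleration
## association.

#' Forward age transform of the multi-tissue clock
#'
#' Calibrated-age transform: `log((age + 1)/(adult_age + 1))` below the
#' adult-age knot, `(age - adult_age)/(adult_age + 1)` above it.
#'
#' @param age chronological age in years.
#' @param adult_age knot (default 20 years).
#' @return transformed age.
#' @export
horvath_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse age transform of the multi-tissue clock
#'
#' Maps the clock's linear predictor back to years:
#' `(1 + adult_age) * exp(x) - 1` for `x < 0`, else
#' `(1 + adult_age) * x + adult_age`. Continuous and monotone, with
#' `x = 0` mapping exactly to `adult_age`.
#'
#' @param x linear predictor.
#' @param adult_age knot (default 20 years).
#' @return age in years.
#' @export
horvath_inverse <- function(x, adult_age = 20) {
  ifelse(x < 0,
         (1 + adult_age) * exp(x) - 1,
         (1 + adult_age) * x + adult_age)
}

#' Compute a poly-epigenetic score
#'
#' Per-sample weighted sum of beta-values over the CpGs whose external
#' association p-value is strictly below `p_threshold` and which are
#' present in the beta matrix. With `z_weights = TRUE` the external z
#' statistic (`weight/se`-style column `z`) is used instead of the effect
#' size.
#'
#' @param beta CpGs x samples matrix.
#' @param stats data.frame `cpg_id`, `weight`, `p` (optionally `z`).
#' @param p_threshold inclusion threshold on the external p-value.
#' @param z_weights use the `z` column as weights.
#' @return named numeric vector of scores with attribute `n_cpgs_used`.
#' @export
compute_pes <- function(beta, stats, p_threshold = 1, z_weights = FALSE) {
  if (anyDuplicated(stats$cpg_id)) stopf("duplicate cpg_ids in summary stats")
  sel <- stats[stats$p < p_threshold & stats$cpg_id %in% rownames(beta), ]
  if (nrow(sel) == 0L)
    stopf("no usable CpGs at threshold %g", p_threshold)
  w <- if (z_weights) sel$z else sel$weight
  score <- as.numeric(crossprod(beta[sel$cpg_id, , drop = FALSE], w))
  names(score) <- colnames(beta)
  attr(score, "n_cpgs_used") <- nrow(sel)
  score
}

## Shared single-predictor association with covariate adjustment; returns
## the predictor coefficient, se, t, p, n, and the incremental R^2 of the
## predictor over the covariate-only model.
predictor_association <- function(predictor, phenotype, covariates = NULL) {
  design <- covariate_design(covariates)
  ids <- names(phenotype)[is.finite(phenotype)]
  ids <- intersect(ids, names(predictor)[is.finite(predictor)])
  if (!is.null(design))
    ids <- intersect(ids, rownames(design)[complete.cases(design)])
  y <- phenotype[ids]
  s <- predictor[ids]
  n <- length(ids)
  if (n < 4L) stopf("too few aligned samples (%d)", n)
  if (sd(s) < 1e-12)
    return(list(effect = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, incremental_r2 = NA_real_, n = n,
                reason = "constant_predictor"))
  x0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(design)) design[ids, , drop = FALSE])
  q0 <- qr(x0)
  y_r <- qr.resid(q0, y)
  s_r <- qr.resid(q0, s)
  sxx <- sum(s_r^2)
  coef <- sum(s_r * y_r) / sxx
  rss1 <- sum(y_r^2) - coef^2 * sxx
  df <- n - ncol(x0) - 1L
  se <- sqrt(rss1 / df / sxx)
  tv <- coef / se
  tss <- sum((y - mean(y))^2)
  r2_0 <- 1 - sum(y_r^2) / tss
  r2_1 <- 1 - rss1 / tss
  list(effect = coef, se = se, t = tv, p = 2 * pt(-abs(tv), df = df),
       incremental_r2 = r2_1 - r2_0, n = n, reason = NA_character_)
}

#' Association of a poly-epigenetic score with a phenotype
#'
#' Fits `phenotype ~ covariates + score` and reports the score
#' coefficient, its two-sided p-value, the incremental R^2 of the score
#' over the covariate-only model, and the Bonferroni-adjusted p-value for
#' `n_tests` independent tests (default ten).
#'
#' @param scores named score vector (e.g. from [compute_pes()]).
#' @param phenotype named phenotype vector.
#' @param covariates optional covariates (see [run_ewas()]).
#' @param n_tests Bonferroni family size.
#' @return one-row data.frame `effect`, `se`, `t`, `p`, `p_adjusted`,
#'   `incremental_r2`, `n`, `n_cpgs_used`.
#' @export
pes_association <- function(scores, phenotype, covariates = NULL,
                            n_tests = 10L) {
  a <- predictor_association(scores, phenotype, covariates)
  data.frame(effect = a$effect, se = a$se, t = a$t, p = a$p,
             p_adjusted = pmin(1, n_tests * a$p),
             incremental_r2 = a$incremental_r2, n = a$n,
             n_cpgs_used = attr(scores, "n_cpgs_used") %||% NA_integer_,
             reason = a$reason, stringsAsFactors = FALSE)
}

#' Epigenetic (DNAm) age from a linear clock
#'
#' Computes the clock's linear predictor
#' `intercept + sum(coef * beta)` per sample and maps it to years with
#' [horvath_inverse()]. At least 80% of the clock CpGs must be present in
#' the beta matrix; missing CpGs are imputed at the clock's training mean
#' if provided, else at 0.5 (logged).
#'
#' @param beta CpGs x samples matrix.
#' @param clock a clock model: list with `intercept`, `adult_age` and a
#'   `coefficients` data.frame (`cpg_id`, `coefficient`, optional `mean`).
#' @param min_coverage minimum fraction of clock CpGs required.
#' @return named vector of DNAm ages (years).
#' @export
dnam_age <- function(beta, clock, min_coverage = 0.8) {
  co <- clock$coefficients
  present <- co$cpg_id %in% rownames(beta)
  if (mean(present) < min_coverage)
    stopf("%d of %d clock CpGs missing from the beta matrix (coverage %.0f%% < %.0f%%)",
          sum(!present), nrow(co), 100 * mean(present), 100 * min_coverage)
  b <- matrix(NA_real_, nrow(co), ncol(beta),
              dimnames = list(co$cpg_id, colnames(beta)))
  b[present, ] <- beta[co$cpg_id[present], , drop = FALSE]
  if (any(!present)) {
    fill <- if (!is.null(co$mean)) co$mean[!present] else 0.5
    message(sprintf("dnam_age: imputing %d missing clock CpGs", sum(!present)))
    b[!present, ] <- fill
  }
  x <- clock$intercept + as.numeric(crossprod(b, co$coefficient))
  setNames(horvath_inverse(x, clock$adult_age %||% 20), colnames(beta))
}

#' Epigenetic age acceleration
#'
#' Residual of a linear regression of DNAm age on chronological age
#' (reuses [residualize_on_age()]); positive values mean the methylome
#' looks older than expected for the chronological age.
#'
#' @param dnam_age_years DNAm age vector.
#' @param chron_age chronological age vector, aligned.
#' @return residual vector (years).
#' @export
age_acceleration <- function(dnam_age_years, chron_age) {
  out <- residualize_on_age(dnam_age_years, chron_age)
  names(out) <- names(dnam_age_years)
  out
}

#' Association of age acceleration with a phenotype
#'
#' Single linear model `phenotype ~ covariates + acceleration` (cell
#' fractions are passed as ordinary covariate columns); reports the
#' acceleration coefficient and its two-sided p-value.
#'
#' @param accel named acceleration vector.
#' @param phenotype named phenotype vector.
#' @param covariates optional covariates, typically including cell
#'   fractions.
#' @return one-row data.frame `effect`, `se`, `t`, `p`, `n`.
#' @export
acceleration_association <- function(accel, phenotype, covariates = NULL) {
  a <- predictor_association(accel, phenotype, covariates)
  data.frame(effect = a$effect, se = a$se, t = a$t, p = a$p, n = a$n,
             reason = a$reason, stringsAsFactors = FALSE)
}

#' Read a clock coefficient file
#'
#' Tab-delimited with columns `cpg_id` and `coefficient` (optional
#' `mean`); the rows named `.intercept` and `.adult_age` carry the model
#' intercept and adult-age knot.
#'
#' @param path file path.
#' @return a `mem_clock` model list.
#' @export
read_clock <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("cpg_id", "coefficient")
  if (!all(need %in% names(d)))
    stopf("clock file must have columns %s", paste(need, collapse = ", "))
  ic <- d$cpg_id == ".intercept"
  aa <- d$cpg_id == ".adult_age"
  if (!any(ic)) stopf("clock file is missing the .intercept row")
  model <- list(intercept = d$coefficient[ic][1],
                adult_age = if (any(aa)) d$coefficient[aa][1] else 20,
                coefficients = d[!ic & !aa, , drop = FALSE])
  class(model) <- "mem_clock"
  model
}

#' Write a clock coefficient file
#' @param clock a `mem_clock` model.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clock <- function(clock, path) {
  co <- clock$coefficients[c("cpg_id", "coefficient")]
  head_rows <- data.frame(cpg_id = c(".intercept", ".adult_age"),
                          coefficient = c(clock$intercept,
                                          clock$adult_age %||% 20))
  data.table::fwrite(rbind(head_rows, co), path, sep = "\t", quote = FALSE)
  invisible(path)
}
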