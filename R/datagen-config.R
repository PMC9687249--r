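#' Describe one synthetic cohort
#'
#' A cohort is one tissue/batch stratum of the study design: a number of
#' samples, an age distribution (truncated normal), a fraction of females,
#' and optionally a longitudinal subset that received a baseline assessment
#' in addition to the follow-up one.
#'
#' Ages are the ages at the DNA-sampling assessment (the follow-up visit for
#' longitudinal cohorts); baseline ages are derived by subtracting the
#' follow-up interval.
#'
#' @param name cohort label, used in sample ids and file names.
#' @param n number of samples with cross-sectional data.
#' @param n_longitudinal number of samples (<= n) that also have baseline
#'   test scores; 0 for single-timepoint cohorts.
#' @param tissue tissue label ("buccal" or "blood").
#' @param batch laboratory batch label.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution
#'   in years at the sampling assessment.
#' @param frac_female fraction of female samples in [0, 1].
#' @return a `mem_cohort` list.
#' @export
cohort_spec <- function(name, n, n_longitudinal = 0L, tissue = "buccal",
                        batch = name, age_mean = 70, age_sd = 5,
                        age_min = 30, age_max = 95, frac_female = 0.5) {
  assert_number(n, "n", min = 1)
  assert_number(n_longitudinal, "n_longitudinal", min = 0, max = n)
  assert_number(frac_female, "frac_female", min = 0, max = 1)
  if (age_min >= age_max) stopf("cohort '%s': age_min must be < age_max", name)
  structure(list(
    name = as.character(name), n = as.integer(n),
    n_longitudinal = as.integer(n_longitudinal),
    tissue = tissue, batch = as.character(batch),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    frac_female = frac_female
  ), class = "mem_cohort")
}

#' Default cohort layout of the emulated two-site study
#'
#' Three buccal cohorts that enter the cross-sectional meta-analysis
#' (433 + 245 + 341 = 1019 samples, of which 403 + 223 = 626 carry
#' longitudinal data) plus a blood cohort (800 cross-sectional, 735
#' longitudinal) analyzed separately. Ages follow the published cohort
#' descriptors: the two aging-study batches have follow-up ages of
#' 76 +/- 4 years, the younger site spans 30-67 years (54 +/- 7).
#'
#' @return list of [cohort_spec()] objects.
#' @export
default_cohorts <- function() {
  list(
    cohort_spec("buccal1", n = 433, n_longitudinal = 403, tissue = "buccal",
                batch = "batch1", age_mean = 76, age_sd = 4,
                age_min = 65, age_max = 86, frac_female = 0.52),
    cohort_spec("buccal2", n = 245, n_longitudinal = 223, tissue = "buccal",
                batch = "batch2", age_mean = 76, age_sd = 4,
                age_min = 66, age_max = 90, frac_female = 0.50),
    cohort_spec("bbhi", n = 341, n_longitudinal = 0, tissue = "buccal",
                batch = "batch3", age_mean = 54, age_sd = 7,
                age_min = 30, age_max = 67, frac_female = 0.46),
    cohort_spec("blood", n = 800, n_longitudinal = 735, tissue = "blood",
                batch = "batch4", age_mean = 76, age_sd = 4,
                age_min = 65, age_max = 90, frac_female = 0.50)
  )
}

#' Default planted-effect table
#'
#' Modest suggestive-tier loci: three cross-sectional only, three
#' longitudinal only, three associated with both phenotypes (same sign),
#' mirroring the overlap pattern seen in EWAS hit tables. Indices are
#' spread over the array proportionally to `n_cpgs`.
#'
#' @param n_cpgs array size the indices are scaled to.
#' @return data.frame `cpg_index`, `rho_cross`, `rho_long`.
#' @export
default_planted_effects <- function(n_cpgs = 20000L) {
  idx <- unique(pmax(1L, pmin(n_cpgs, as.integer(
    round(seq(0.005, 0.8, length.out = 9) * n_cpgs)))))
  k <- length(idx)
  data.frame(
    cpg_index = idx,
    rho_cross = c(0.16, 0.15, 0.14, 0, 0, 0, 0.14, 0.13, 0.12)[seq_len(k)],
    rho_long  = c(0, 0, 0, 0.15, 0.14, 0.13, 0.12, 0.11, 0.10)[seq_len(k)]
  )
}

#' Build a generator configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' that reproduce the emulated study's printed descriptors: cohort sizes
#' and age distributions from the sample table, a 5.4 +/- 0.5 year
#' follow-up interval, a target correlation of 0.42 between the
#' cross-sectional and longitudinal memory phenotypes, mean test-score
#' decline such that three of four tests show significant paired decline,
#' a poly-epigenetic score planted to explain 0.8% of phenotype variance,
#' and 23 CpG-gene expression pairs of which two carry a true Spearman
#' correlation of 0.34.
#'
#' @param cohorts list of [cohort_spec()]; default [default_cohorts()].
#' @param n_cpgs number of array CpGs (desk-scale default 20000; the full
#'   850k array is configuration only).
#' @param n_tests number of memory tests per timepoint.
#' @param loadings factor loadings of the tests on the latent memory level.
#' @param test_noise_sd test-specific (uniqueness) noise sd on the
#'   standardized scale; kept small so the latent correlation target
#'   transfers to the observed phenotypes.
#' @param test_scale_mean,test_scale_sd location/scale of raw test scores.
#' @param age_slope cross-sectional decline of the latent memory level per
#'   year of age (standard deviations).
#' @param follow_up_mean,follow_up_sd follow-up interval distribution in
#'   years.
#' @param decline_means per-test mean decline over the follow-up interval
#'   (sd units); the last test is near zero so that only three of four
#'   tests decline significantly.
#' @param decline_loading loading of the latent longitudinal factor on the
#'   per-test decline.
#' @param decline_noise_sd per-test decline noise (sd units).
#' @param target_phenotype_correlation latent correlation between the
#'   cross-sectional level residual and the longitudinal factor.
#' @param planted_effects data.frame with columns `cpg_index`, `rho_cross`,
#'   `rho_long`: planted standardized effects (correlations between the CpG's
#'   residual methylation and the latent phenotype). `NULL` for none.
#' @param noise_sd residual beta-value noise sd.
#' @param batch_effect_sd sd of per-batch per-CpG mean shifts.
#' @param cell_types cell-type names of the reference.
#' @param cell_concentration Dirichlet concentration of sample cell
#'   fractions.
#' @param cell_props named list of base cell proportions per tissue.
#' @param ref_between_sd sd of between-cell-type differences in reference
#'   mean methylation.
#' @param mqtl_fraction fraction of CpGs with a controlling cis SNP.
#' @param mqtl_effect additive per-allele effect on beta.
#' @param maf_range minor-allele-frequency range of simulated SNPs.
#' @param pes_n_cpgs number of CpGs in the external summary statistics.
#' @param pes_r2 phenotype variance fraction explained by the planted
#'   poly-epigenetic score (0 disables the plant).
#' @param clock_n_cpgs,clock_noise_sd,clock_accel_sd,clock_adult_age toy
#'   epigenetic-clock geometry: number of clock CpGs, their beta noise, the
#'   sd of true age acceleration (years), and the clock's adult-age knot.
#' @param brain_n number of individuals with paired brain samples.
#' @param brain_shared_fraction fraction of CpGs whose methylation
#'   covaries between buccal and brain.
#' @param brain_shared_r cross-tissue correlation at shared CpGs.
#' @param expression_pairs,expression_planted,expression_rho CpG-gene
#'   correlation family: total pairs evaluated, planted non-null pairs,
#'   planted Spearman correlation.
#' @param seed integer RNG seed.
#' @return a validated `mem_generator_config` list.
#' @export
generator_config <- function(cohorts = default_cohorts(),
                             n_cpgs = 20000L,
                             n_tests = 4L,
                             loadings = c(0.65, 0.70, 0.75, 0.80),
                             test_noise_sd = 0.25,
                             test_scale_mean = 50,
                             test_scale_sd = 5,
                             age_slope = 0.03,
                             follow_up_mean = 5.4,
                             follow_up_sd = 0.5,
                             decline_means = c(0.25, 0.20, 0.15, 0.01),
                             decline_loading = 0.5,
                             decline_noise_sd = 0.15,
                             target_phenotype_correlation = 0.42,
                             planted_effects = default_planted_effects(n_cpgs),
                             noise_sd = 0.03,
                             batch_effect_sd = 0.02,
                             cell_types = c("Epi", "Fib", "IC"),
                             cell_concentration = 30,
                             cell_props = list(
                               buccal = c(0.65, 0.10, 0.25),
                               blood = c(0.05, 0.05, 0.90)),
                             ref_between_sd = 0.12,
                             mqtl_fraction = 0.02,
                             mqtl_effect = 0.05,
                             maf_range = c(0.1, 0.5),
                             pes_n_cpgs = 200L,
                             pes_r2 = 0.008,
                             clock_n_cpgs = 10L,
                             clock_noise_sd = 0.01,
                             clock_accel_sd = 2.5,
                             clock_adult_age = 20,
                             brain_n = 120L,
                             brain_shared_fraction = 0.2,
                             brain_shared_r = 0.7,
                             expression_pairs = 23L,
                             expression_planted = 2L,
                             expression_rho = 0.34,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "mem_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (length(cfg$cohorts) == 0L)
    stopf("configuration error: at least one cohort is required")
  if (!all(vapply(cfg$cohorts, inherits, TRUE, "mem_cohort")))
    stopf("all cohorts must be built with cohort_spec()")
  nm <- vapply(cfg$cohorts, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("cohort names must be unique")
  assert_number(cfg$n_cpgs, "n_cpgs", min = 1)
  cfg$n_cpgs <- as.integer(cfg$n_cpgs)
  assert_number(cfg$n_tests, "n_tests", min = 2)
  if (length(cfg$loadings) != cfg$n_tests ||
      length(cfg$decline_means) != cfg$n_tests)
    stopf("loadings and decline_means must have length n_tests = %d",
          cfg$n_tests)
  assert_number(cfg$noise_sd, "noise_sd", min = 0)
  assert_number(cfg$batch_effect_sd, "batch_effect_sd", min = 0)
  assert_number(cfg$target_phenotype_correlation,
                "target_phenotype_correlation", min = -1, max = 1)
  assert_number(cfg$mqtl_fraction, "mqtl_fraction", min = 0, max = 1)
  assert_number(cfg$pes_r2, "pes_r2", min = 0, max = 1)
  assert_number(cfg$brain_shared_fraction, "brain_shared_fraction",
                min = 0, max = 1)
  if (length(cfg$cell_types) < 2L) stopf("need at least 2 cell types")
  for (tis in unique(vapply(cfg$cohorts, `[[`, "", "tissue")))
    if (is.null(cfg$cell_props[[tis]]) ||
        length(cfg$cell_props[[tis]]) != length(cfg$cell_types))
      stopf("cell_props is missing base proportions for tissue '%s'", tis)
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe) > 0L) {
    need <- c("cpg_index", "rho_cross", "rho_long")
    if (!all(need %in% names(pe)))
      stopf("planted_effects needs columns %s", paste(need, collapse = ", "))
    if (anyDuplicated(pe$cpg_index))
      stopf("planted effect CpG indices must be unique")
    if (any(pe$cpg_index < 1L) || any(pe$cpg_index > cfg$n_cpgs))
      stopf("planted effect CpG indices must lie in 1..n_cpgs")
    if (any(abs(pe$rho_cross) >= 1) || any(abs(pe$rho_long) >= 1))
      stopf("planted standardized effects must have |rho| < 1")
  }
  if (cfg$expression_planted > cfg$expression_pairs)
    stopf("expression_planted must be <= expression_pairs")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
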