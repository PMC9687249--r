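# memewas

An R package implementing a complete epigenome-wide association study
(EWAS) pipeline for **episodic-memory (EM) performance** from DNA
methylation β-values, aimed at analysts working with multi-cohort
aging-study designs (several array batches, buccal and blood tissue,
cognitive testing at up to two timepoints). Individual-level data of this
kind are typically access-restricted, so the package also ships a
synthetic multi-cohort generator with a *truth channel*, making every
stage of the pipeline testable end to end.

## What it computes

For samples *s* and CpGs *c* with methylation fraction
β<sub>sc</sub> ∈ [0, 1]:

- **Phenotypes** — cross-sectional EM = residual of PC1 of the memory
  test battery (correlation-matrix PCA, sign-fixed) on age;
  longitudinal EM = mean annual percentage change,
  APC = 100·((follow − base)/base)/Δt, averaged over tests.
- **Preprocessing** — cell-type fractions per sample by constrained least
  squares against a reference (min ‖β<sub>s</sub> − R f‖², f ≥ 0,
  Σf = 1, solved exactly); per-CpG correction to residual + grand mean;
  DNAm principal components from a variance-ranked, correlation-pruned
  CpG subset as technical covariates.
- **EWAS** — per CpG, `phenotype ~ intercept + β_c + covariates` by least
  squares (vectorized, numerically identical to per-CpG `lm()`), with
  genomic inflation λ = median(χ²)/0.4549 and strict significance tiers
  (epigenome-wide p < 9×10⁻⁸, suggestive p < 1×10⁻⁵).
- **Meta-analysis** — inverse-variance fixed effect
  (β̂ = Σwᵢβᵢ/Σwᵢ, w = 1/se², se = 1/√Σw) with Cochran's Q and I²,
  cross-phenotype hit tables, and cross-tissue test-statistic
  correlation.
- **Scores** — poly-epigenetic scores Σ wⱼ β<sub>sj</sub> over CpGs
  passing an external p-value threshold, with incremental R² and
  Bonferroni adjustment; multi-tissue epigenetic clock with the
  calibrated-age transform and age acceleration (residual of DNAm age on
  chronological age).
- **Integration** — cis-mQTL scan (±1 Mb, additive dosage model),
  genetic-control flags at BH-FDR 0.05, Spearman DNAm–mRNA correlation in
  paired brain samples, buccal–brain per-CpG correlation map, and static
  prior-evidence joins.

See `vignettes/memory-ewas-methods.Rmd` for the full model description,
the synthetic world's assumptions, and design rationale.

## Worked example

Generate a default-sized synthetic study (three buccal cohorts,
n = 433 + 245 + 341) at 5 000 CpGs, run the per-cohort EWAS on the
cross-sectional phenotype, and meta-analyze:

```r
library(memewas)
ds  <- generate_dataset(generator_config(n_cpgs = 5000L, seed = 1L))
cos <- c("buccal1", "buccal2", "bbhi")
ph  <- lapply(ds$samples[cos], build_phenotypes)
pp  <- lapply(cos, function(co)
  preprocess_cohort(ds$beta[[co]], ds$cell_reference,
                    top_n_variance = 2000L))
names(pp) <- cos
per <- lapply(cos, function(co)
  run_ewas(pp[[co]]$beta_corrected,
           setNames(ph[[co]]$em_cross, ph[[co]]$sample_id),
           covariates = pp[[co]]$pcs, cohort = co))
m <- classify_hits(fixed_effect_meta(per))
genomic_inflation(m$p)
m[m$tier != "none", ]
```

Output (as printed by the code above):

```
lambda (meta): 0.991
     cpg_id effect   se    z        p k_studies direction           tier
 cg00003503  13.77 1.91 7.21 5.63e-13         3       +++ epigenome_wide
 cg00003006  12.06 1.91 6.30 2.90e-10         3       +++ epigenome_wide
 cg00004000  10.32 2.01 5.15 2.67e-07         3       +++     suggestive
 cg00000025  10.11 1.98 5.10 3.46e-07         3       +++     suggestive
 cg00000522   8.96 1.97 4.55 5.41e-06         3       +++     suggestive
 cg00004750   8.77 1.98 4.43 9.44e-06         3       +++     suggestive
```

λ = 0.991 says the scan is well calibrated. Five of the six flagged CpGs
are planted loci (`ds$truth$planted`); the CpGs planted in *both*
phenotypes (e.g. cg00003503) rank strongest because the two latent
phenotypes are correlated (0.42), so their effects add. cg00004750 is a
chance suggestive signal — at 5 000 null CpGs and p < 10⁻⁵ one borderline
false positive per few runs is expected, and the truth table is exactly
what lets a test distinguish the two. Effects are in phenotype units
(unit-variance latent scale) per unit β.

The one-command driver runs everything — phenotypes, preprocessing,
per-cohort EWAS, meta-analysis, Manhattan/hit tables, poly-epigenetic
scores, clock, mQTL, expression correlation — and writes a manifest with
λ values, hit counts and file checksums:

```r
mf <- run_pipeline(pipeline_config(dataset = ds, out_dir = "out"))
```

A CLI wrapper lives at `inst/cli/memewas`
(`memewas simulate|phenotype|run|version`).

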