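---
title: "Methods: an EWAS pipeline for episodic-memory phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EWAS pipeline for episodic-memory phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`memewas` implements an epigenome-wide association study (EWAS) of
episodic-memory (EM) performance from Illumina-array DNA methylation
beta-values, for the common two-site aging-cohort design: several buccal
batches plus a blood cohort, with memory assessed at up to two timepoints
roughly five years apart. Because individual-level cohort data of this
kind are access-restricted, the package ships a synthetic-data generator
that emulates the statistical structure every downstream stage assumes,
with a truth channel for parameter-recovery testing. All analysis stages
are deterministic given their inputs; only the generator consumes a seed.

## Phenotypes

*Cross-sectional EM* (`em_cross`): the first principal component of the
memory test battery, computed on the correlation matrix (each test
standardized, because tests are scored on different scales), with the sign
fixed so that higher PC1 means better performance, then residualized on
age at the assessment used (the follow-up visit for cohorts sampled at
follow-up, the single visit otherwise). The residual is the phenotype, so
`em_cross` has mean zero within each cohort by construction.

*Longitudinal EM* (`em_long`): the annual percentage change (APC) of each
test, `100 * ((follow - base)/base) / interval`, averaged over tests with
valid values (baseline non-zero, positive interval). A sample needs at
least half of its tests non-missing to receive a phenotype; missing
entries of the standardized matrix are mean-imputed before the PCA.
`em_long` is *not* age-residualized by default — it is already a rate, and
age enters the association models through the methylation-PC covariates —
but a flag (`residualize_long`) enables it.

## Preprocessing

Cell-type composition is estimated per sample by constrained least
squares against a reference of per-cell-type mean beta-values:
minimize `||beta_s - R f||^2` subject to `f >= 0` and `sum(f) = 1`. The
solver enumerates support sets, which is exact and cheap for the small
panels (2–6 cell types) used in methylation deconvolution. Beta-values
are then corrected per CpG by regressing on the fractions (dropping one
column to remove the simplex collinearity) and keeping residual + grand
mean, clipped to [0, 1] to preserve the beta interpretation.

Technical covariates are the first K principal components of the
corrected beta-values over a subset of mutually uncorrelated CpGs: the
top `top_n_variance` (default 5 000) CpGs by variance, greedily pruned at
absolute pairwise correlation `r_threshold` (default 0.2; deterministic
given the variance ranking, with a CpG-id tiebreak). K defaults to the
number of PCs explaining 80% of subset variance, capped at 12, matching
the 8–12 PCs typically retained per dataset in this design.

## Association, meta-analysis, tiers

Each CpG is tested with `phenotype ~ intercept + beta + covariates`
(phenotype as the continuous outcome). The scan is vectorized through the
Frisch–Waugh–Lovell projection but numerically identical to per-CpG
`lm()` fits; p-values use the t distribution with the full-model residual
degrees of freedom. Calibration is summarized by the genomic inflation
factor `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`.

Cohorts are combined by inverse-variance fixed-effect meta-analysis
(`w = 1/se^2`), with Cochran's Q and I^2 reported; CpGs observed in one
study pass through flagged `k = 1`. A sample-size-weighted z combination
is available behind a flag. Significance tiers are strict:
epigenome-wide at `p < 9e-8` (array-wide threshold for EPIC-scale data)
and suggestive at `p < 1e-5`.

A calibration subtlety worth knowing: when batches are pooled, the
cohort-wise residualized phenotype is *exactly* orthogonal to
between-batch methylation structure, which makes an unadjusted scan
conservative (lambda well below 1). The methylation PCs absorb that
structure and restore lambda to ~1.00; this is tested explicitly.

## Scores and the epigenetic clock

Poly-epigenetic scores are weighted sums of beta-values over CpGs whose
external association p-value passes an inclusion threshold (defaults
1e-5, 1e-3, 0.01, 0.05, 0.5, 1.0 — nested by construction). Effect-size
weights are the default; z-statistic weights sit behind a flag, because
published summary files vary in which they provide. Score associations
report the incremental R^2 over the covariate-only model and a
Bonferroni-adjusted p for ten tests by default.

The multi-tissue clock is a linear model on clock CpGs with the
calibrated-age transform: linear predictor `x` maps to
`(1 + a) exp(x) - 1` below zero and `(1 + a) x + a` above, `a = 20`
years (continuous, monotone, `x = 0 -> 20`). At least 80% of clock CpGs
must be present; missing ones are imputed at the training mean if the
clock file carries one, else at 0.5 (logged). Age acceleration is the
residual of DNAm age on chronological age; its association model includes
cell fractions as covariates. The package bundles only a synthetic toy
clock through the generator — real clock coefficient files are user
input, never downloaded.

## Integration

cis-mQTL pairs are all (SNP, CpG) pairs on one chromosome within ±1 Mb
(inclusive at exactly 1 Mb), tested additively on dosage 0/1/2 with
covariates, on composition-pre-adjusted beta-values. Two significance
conventions are kept separate: a genome-wide rule `p < 1e-15` and a
BH-FDR 0.05 look-up rule under which a CpG counts as "under genetic
control" if any of its cis pairs passes. DNAm–mRNA correlation uses
Spearman rank correlation per CpG-gene pair with BH adjustment across the
pair family. The cross-tissue map reports per-CpG Pearson correlations
across matched individuals, classified low/moderate/high at |r| cut-points
0.3 and 0.5 — the cut-points are this package's own convention (the
upstream literature says only "moderate to high") and are configurable.
BH-FDR is implemented in-package (`bh_adjust`) and pinned against a
brute-force step-up oracle in the tests.

# The synthetic world

The generator's defaults are the cohort descriptors of the emulated
design: buccal cohorts of 433, 245 and 341 samples (the first two with
longitudinal subsets of 403 and 223, together the 626-sample longitudinal
set; the third single-timepoint, ages 30–67) and a blood cohort of
800/735. Follow-up intervals are `N(5.4, 0.5^2)` years (truncated ±3 sd).
Follow-up ages for the aging cohorts are `N(76, 4^2)` truncated to the
published ranges; baseline age is follow-up minus interval. The
cohort-size and interval targets are exact or near-exact by construction;
the pooled cross-sectional mean age computes to ≈68.6 years against the
published rounded 69.

Methylation is built per CpG as cell-type mixture mean + batch shift +
mQTL dosage effect + planted phenotype effect + Gaussian noise, clipped
to [0, 1]:

* Reference profiles: a shared level per CpG (uniform 0.10–0.90) plus
  cell-type offsets (sd 0.12), clamped to [0.05, 0.95] so that means stay
  off the boundary and Gaussian beta-noise (sd 0.03) with clipping is an
  adequate approximation. Real beta-values are heteroscedastic and
  boundary-inflated; the generator intentionally is not.
* Cell fractions: Dirichlet draws around tissue-specific base proportions
  (buccal 0.65/0.10/0.25 epithelial/fibroblast/immune, blood
  0.05/0.05/0.90, concentration 30).
* Batch shifts: per-batch per-CpG `N(0, 0.02^2)` mean shifts, shared
  across cohorts with the same batch label.
* mQTLs: 2% of CpGs get a cis SNP (placed within ±500 kb) with an
  additive +0.05 per-allele effect; allele frequencies uniform 0.1–0.5,
  Hardy–Weinberg dosages.
* Planted effects: specified as standardized effects — the slope is
  scaled so the correlation between the CpG's residual methylation and
  the latent phenotype equals the configured `rho`. The default set is
  nine modest loci (rho 0.10–0.16): three per phenotype plus three shared
  with concordant signs, so default runs produce suggestive-tier but not
  epigenome-wide hits.

Memory tests are a one-factor model: four tests with loadings
0.65–0.80 on the latent level, test-specific noise sd 0.25 (standardized
scale), raw scale 50 ± 5. Follow-up scores load on the level factor;
baseline = follow-up + decline, with per-test mean declines of 0.25,
0.20, 0.15 and 0.01 sd over the interval — so three of four tests show a
clearly significant paired decline and one does not, mirroring the
design's descriptive finding. The decline also loads (0.5) on a latent
longitudinal factor drawn with correlation 0.42 to the age-independent
level residual.

Two calibration choices deserve explanation:

* *Why such small test noise?* The published quantity is the correlation
  between the **observed** phenotypes (0.42). The generator draws the
  latent factors at that correlation and keeps measurement attenuation
  through PC1 and the APC below ~3% (closed-form reliability of the
  4-test composite ≈ 0.99), so the observed correlation lands at
  ≈0.42–0.44 without any post-hoc retuning. Realistic test reliabilities
  (~0.75) would attenuate the observed correlation well below target; we
  trade realism of the noise decomposition for fidelity of the published
  summary statistic, which is what downstream stages consume.
* *The APC denominator couples the phenotypes upward by roughly +0.01*:
  higher-level individuals have larger baselines, hence less negative
  APCs. This is left in — it is a real property of the APC definition.

The planted poly-epigenetic score mixes the standardized weighted sum of
the (effect-free) score CpGs into the latent level so that it explains
exactly `pes_r2` (default 0.008) of its variance. The toy clock writes
each sample's transformed `(age + accel)`, `accel ~ N(0, 2.5^2)` years,
into 10 dedicated CpGs with coefficients that invert exactly in
expectation (clock noise sd 0.01 ≈ 1.3 years MAE). Brain pairs: 120
individuals from the largest cohort; 20% of CpGs are "shared" with
cross-tissue correlation 0.7, the rest independent. Expression: 23
CpG-gene pairs, two planted at Spearman ≈ 0.34 — note that at n = 120
this sits near the BH-0.05 detection boundary (per-pair power ~0.75), so
tests of the correlation machinery use a stronger planted value and the
default world is checked by rank.

## What a green test does not establish

The generator contains no probe-level artifacts (type I/II chemistry,
detection failures), no sex chromosomes, no age-associated methylation
outside the clock CpGs, no population structure behind the SNPs, no
missing data in the beta matrices, and independent individuals across
tissues (the real design's buccal/blood overlap is not modeled). Passing
tests certify the statistical machinery and its calibration under the
stated world — not robustness to array artifacts upstream of the beta
matrix, which are declared out of scope.

# Numerical choices

* All least-squares paths go through QR (or exact support enumeration for
  the simplex); the vectorized EWAS is algebraically identical to per-CpG
  `lm()` and is tested to 1e-8 against a normal-equations oracle.
* Constant beta rows give NA rows with reason codes rather than errors;
  constant predictors likewise.
* Threshold comparisons are strict (`p < 9e-8`, `p < 1e-5`, `p < 0.05`),
  and the cis window is inclusive at exactly ±1 Mb.
* Corrected beta-values are clipped to [0, 1]; comparisons against the
  OLS oracle account for the clip.
* PC sign conventions: PC1 of test scores is sign-fixed against mean
  performance; methylation PCs are reported as SVD scores (sign
  arbitrary, irrelevant to their covariate role).
* Coordinates are 1-based inclusive everywhere; beta files are CpG rows ×
  sample columns (a transposed orientation flag exists on the reader).

# Known limitations

* Deconvolution assumes the reference spans the true cell types; with a
  misspecified reference the fractions are a projection, as with any
  reference-based method.
* The fixed-effect meta-analysis treats all cohorts alike; cohorts with a
  different age range (the 30–67-year site) are not reweighted, and only
  Q/I^2 flag heterogeneity.
* The mQTL stage's covariates in the pipeline are sex and batch (plus
  composition pre-adjustment); genotype-derived genetic PCs are supported
  as covariate columns but not simulated.
* `em_long` inherits the APC's sensitivity to small baselines; tests with
  baseline near zero are excluded per sample rather than stabilized.
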