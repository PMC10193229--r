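---
title: "Methods: uEV transcriptomics and the kidney stress score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uEV transcriptomics and the kidney stress score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uevstress)
```

# Scope and assumptions

`uevstress` analyses bulk mRNA-seq of urinary extracellular vesicles (uEV)
in diabetic kidney disease. The package consumes gene-by-sample count
matrices, per-sample clinical metadata, sequencing QC summaries and
longitudinal creatinine/eGFR visit tables; read alignment and counting are
upstream and out of scope. The analysis assumes counts are adequately
described by a negative-binomial (NB) model with gene-wise dispersion
(var = μ + φμ²), that between-sample composition differences are corrected
by TMM scaling, and that clinical group effects of interest are
log-additive on expression.

# Sample quality control

Two metric-based rules exclude a sample: an intergenic-read fraction (reads
within 10 kb up/downstream of coding regions) strictly above 5%, or a
bioanalyzer degradation flag. Both reasons are recorded when both apply; a
missing intergenic fraction produces an explicit error record
(`included = NA`) rather than a silent pass.

Expression outliers are then flagged in the space of the first two
principal components of the gene-standardized log2CPM matrix. A sample is
an outlier when its Euclidean distance from the (PC1, PC2) centroid exceeds
`k_sd` (default 3) times the robust SD of the distances, computed as
1.4826 × the median absolute distance (MAD about zero). We use the MAD
about zero rather than about the median deliberately: centroid distances
are non-negative and Rayleigh-like, so a median-centred MAD rule at k = 3
flags at least one sample in roughly a third of homogeneous cohorts,
while the zero-centred rule leaves homogeneous data untouched (0 false
flags in 200/200 simulated cohorts of n = 50) and still catches a sample
shifted by 10 sd on all genes. The rule re-applies once to the survivors,
and a guard rail refuses (with a warning) to remove more than 20% of
samples.

# Robust transcriptome and normalization

The robust uEV gene set keeps genes with count ≥ 1 in strictly more than
90% of samples, a literal reading of the inclusion rule: 65 of 72 samples
(90.3%) passes, 64 of 72 (88.9%) fails. A `strict = FALSE` toggle makes
the boundary inclusive. For tissue-similarity statistics a stricter
detection rule applies — count ≥ 1 in *all* samples (`detected_genes()`) —
and both rules are exposed because they answer different questions.

TMM factors follow the published trimmed-mean-of-M-values definition: the
reference sample is the one whose upper quartile of count proportions is
closest to the mean upper quartile; per sample, log2 ratios (M) and average
log2 abundances (A) against the reference are computed over genes positive
in both; genes outside the central 40% of M-ranks (trim 0.30 per side) or
the central 90% of A-ranks (trim 0.05) are discarded; the factor is 2 to
the precision-weighted mean of the surviving M-values, and factors are
rescaled to geometric mean 1. The implementation is verified against an
independently coded brute-force evaluation on small matrices (tolerance
1e-6) and agrees with edgeR's `calcNormFactors` to 1e-10 on larger ones.

log2CPM uses a prior count of 1 (a documented package default), so a zero count maps to 0 on the log scale, and raw
CPM columns sum to exactly 10⁶ before the prior.

The rank-based inverse normal transform (INT) is
z = Φ⁻¹((r − c)/(n − 2c + 1)) with the Blom offset c = 0.375 and average
ranks for ties; the offset is a documented default, not a claim about the
original analysis. With `standardize = TRUE` (default) the result is
centred and scaled to unit SD, i.e. "converted to Z score". Gene-wise
standardization is computed across all included samples (not per cohort);
when several cohorts are scored, the score is computed within each cohort
and pooled afterwards.

# Differential expression

Per gene, an NB log-linear model with offset log(library size × TMM factor)
is fitted for the group contrast (default macroalbuminuria vs
normoalbuminuria) adjusting for age, BMI, diabetes duration and urine
collection protocol. Dispersion is estimated per gene by method of moments
from Poisson-fit residuals, clamped to [0, 10], then shrunk 50% toward a
lowess trend of dispersion on mean log2CPM — a stabilisation needed at
n ≈ 54 without importing a published DE package, which this module
re-implements by design. The Wald statistic on the contrast coefficient is
referred to a t distribution on the residual degrees of freedom: with
estimated-but-plugged-in dispersion the normal reference is slightly
anticonservative at these sample sizes, and the t reference holds the
empirical type-I error at 0.046 (pooled over three 2000-gene null
simulations; the acceptance band is [0.03, 0.07]). A likelihood-ratio
refit is available behind `test = "lrt"` and agrees with the Wald p within
a factor of two for ≥95% of genes in simulation.

Genes with zero counts in more than half the samples of every contrast
group are not fitted (convergence guard) and appear with
`fit_status = "low_count"`; fit failures are flagged, never dropped.
Multiple testing uses Bonferroni only: threshold = α / n_tested, with
n_tested the genes that actually produced a p-value. Published genome-wide
uEV thresholds do not always match their stated gene count (3.85×10⁻⁶
corresponds to 12,987 tests, not the 10,596 genes analysed alongside it),
so the package always derives the threshold from its own n_tested and never
accepts an externally printed cutoff.

qPCR validation utilities implement ΔCt = mean Ct(target) − mean
Ct(reference), relative expression 2^−ΔCt (and 2^−ΔΔCt against a
calibrator group), excluding records with fewer than 2 successful
replicates or ΔCt > 19, and per-gene Spearman concordance between −ΔCt and
log2CPM.

# Tissue similarity

Gene-set detection is plain arithmetic — 100 × |detected ∩ set| / |set|,
reported to one decimal — against kidney-enriched, specific
kidney-enriched and kidney-depleted sets: with sets of 413, 190 and 4,631
genes of which 247, 77 and 200 are detected, the statistics are 59.8%,
40.5% and 4.3%.
The PCA co-embedding concatenates uEV log2CPM with a log-scale tissue
reference on common genes (optionally a subset such as the kidney-depleted
genes), standardizes each gene across the combined samples (correlation
PCA — a fixed, documented scaling choice), and
assigns each uEV sample the tissue with the nearest (PC1, PC2) centroid;
the number of PCs is configurable.

# Stress score and longitudinal analysis

The stress score is the per-sample mean of INT-standardized expression of
GPX3, NOX4, MSRB1, MSRA, HRSP12 and CRYAB — six oxidative/cellular-stress
response genes among the 13 DKD candidates. Being rank-based it is
invariant under any strictly monotone per-gene transformation. Quartiles
are empirical within the scored cohort with lower-inclusive boundaries (a
score equal to the 25th percentile opens the second quartile); the binary
stratification is lowest quartile (≤ 25%) vs the rest.

eGFR uses the CKD-EPI 2009 creatinine equation
(141 × min(Scr/κ,1)^α × max(Scr/κ,1)^−1.209 × 0.993^age × 1.018[female] ×
1.159[black]); the ethnicity multiplier defaults to off for Finnish
cohorts, and creatinine above 30 is auto-treated as µmol/L with a warning.
Annual eGFR means are arithmetic means within calendar years, never
imputed. Group slopes are OLS fits of the per-year group-mean trajectory
on calendar year (one slope ± SE per group), restricted to persons with
more than 8 annual values; per-person OLS slopes are computed alongside
because the downstream ROC and regression need person-level decline; both
variants are exposed since either could reasonably summarise a cohort. CKD stage 3–5 requires at least two annual means below 60 within
at least five years of data. The decliner ROC uses the Mann–Whitney rank
formulation (ties 0.5) with the decline threshold (−0.5 or −3.07 per year)
as a configuration constant. The adjusted regression
inverse-normal-transforms the per-person slope and all predictors (score,
DBP, HbA1c, SBP, baseline eGFR) to sd units before a multiple OLS; a
condition-number guard warns on near-collinearity and falls back to a
flagged small-ridge solution.

Albuminuria classification supports the three cohort rule sets (24-h AER
with the 2-of-3-collections requirement; overnight AER/ACR at the last
visit with normo requiring all visits clean; sex-specific KDIGO ACR
bands). Boundary values on "< x" bounds go to the lower category and the
30–300 mg/24h micro interval is closed, documented choices where the rules
leave membership open.

# The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws NB counts with log-normal gene baselines and
library sizes, plants the 13 DKD marker genes at log2 fold changes 2
(macro) and 1 (micro) by default, and couples the six stress-panel genes
to a per-person latent stress trait (standard normal plus group shifts
0 / 0.8 / 1.6 sd for normo/micro/macro). HbA1c is rho·latent + noise with
rho = 0.4; per-person eGFR slopes are −0.5 − 0.6 × latent ± 0.3, observed
over yearly visits 2004–2018 with visit noise sd 2 mL/min/1.73m² and 10%
record dropout; QC contamination affects 5% of samples. Defaults mirror
the discovery-cohort setting this package models (group sizes 37/13/17,
the 13 marker genes, the macro > micro > normo effect ordering, the
2004–2018 visit window); quantities no study reports (dispersion scale,
couplings, within-group stress variance) are one-time, field-realistic
choices: dispersion median 0.16
matches a typical bulk RNA-seq biological CV of ~0.4, library sizes are
scaled to the 2000-gene simulated universe, and the slope model brackets
reported clinical decline rates (−0.58 to −3.55 mL/min/1.73m² per year).

A green recovery test therefore establishes that the pipeline detects the
structure the generator plants at realistic noise levels — not that the
published effect sizes are correct, and not robustness to features the
generator omits: confounding between covariates and expression, batch
effects beyond protocol, informative missingness in visits, non-NB count
artefacts, or sex-chromosome expression structure (sex is a metadata
column only). The hyperfiltration device (an elevated-baseline band for
the 25–50th latent-stress percentiles) is off by default and only shapes
baselines, not slopes.

# Numerical choices and degenerate inputs

* TMM: geometric-mean rescaling to 1 (tolerance 1e-9 in tests); samples
  with no positive shared genes or all-zero M-values get factor 1; zero
  library sizes are an error.
* INT: constant vectors are an error (ranks undefined) — callers decide
  the fallback; fewer than 3 finite values are an error; NAs pass through.
* Dispersion estimates are floored at 1e-4 and capped at 10; the lowess
  trend needs ≥ 20 genes, otherwise the median raw dispersion is used.
* CV% is NA for genes with zero mean; expression strata are percentile
  bands (0–25 / 26–74 / 75–100) of mean expression.
* Perfectly linear trajectories give slope SE 0; groups with fewer than
  two usable years are an error.
* `roc_auc` requires both classes; ties contribute 0.5 by the average-rank
  construction.

# Known limitations

The DE dispersion shrinkage (50% toward the trend) is a fixed blend, not
an empirical-Bayes weight; at much larger sample sizes it over-shrinks
relative to per-gene ML. Group-mean-trajectory slopes ignore within-person
correlation in their SE (as does simple OLS on annual means); mixed-effects
longitudinal models are out of scope. The tissue reference is synthetic by
construction and labelled as such; conclusions about real tissue
similarity require an external (GTEx-like) matrix supplied by the user.
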