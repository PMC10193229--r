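# uevstress

Urinary extracellular vesicles (uEV) carry kidney-derived mRNA and can act
as a "liquid kidney biopsy". **uevstress** implements, as a tested R
pipeline, the computational analysis used to study uEV mRNA-seq in diabetic
kidney disease (DKD): sample quality control, derivation of a robust uEV
transcriptome, covariate-adjusted differential expression, kidney
tissue-similarity mapping, a six-gene transcriptional **stress score**, and
its association with long-term decline of kidney function (eGFR). A
synthetic-cohort generator with planted effects stands in for patient-level
data, so every stage is testable offline.

It is aimed at computational nephrology / transcriptomics researchers who
consume gene-by-sample count matrices plus clinical metadata and want the
full analysis chain as composable, pipe-friendly functions.

## The model in brief

* **QC.** A sample is excluded when its intergenic-read fraction exceeds 5%
  or its RNA shows bioanalyzer degradation; expression outliers are removed
  by a robust distance rule on the first two principal components.
* **Robust transcriptome.** Genes with count ≥ 1 in > 90% of samples.
* **Normalization.** TMM scaling factors (doubly trimmed, precision-weighted
  mean of M-values against an upper-quartile reference) and
  log2CPM = log2(counts / (lib·factor) × 10⁶ + 1).
* **Differential expression.** Per gene, a negative-binomial GLM
  log μ = offset + β·case + covariates (age, BMI, diabetes duration, urine
  collection protocol), dispersion by method of moments shrunk 50% toward a
  lowess mean–dispersion trend, Wald test, Bonferroni threshold α/n_tested.
* **Stress score.** For the panel {GPX3, NOX4, MSRB1, MSRA, HRSP12, CRYAB}:
  per gene, rank-based inverse normal transform
  z = Φ⁻¹((r − 0.375)/(n + 0.25)) standardized to sd units; the score is the
  per-sample mean across the panel, stratified into quartiles.
* **Longitudinal.** eGFR from the CKD-EPI 2009 creatinine equation; annual
  per-person means; per-group OLS slope ± SE on the group-mean trajectory
  (persons with > 8 annual values); CKD stage 3–5 when ≥ 2 annual means
  < 60; decliner ROC AUC by the Mann–Whitney rank formulation; multiple OLS
  of inverse-normal-transformed per-person slope on score + clinical
  covariates.

## Worked example

```r
library(uevstress)

cohort <- generate_cohort(sim_config(seed = 42))   # 37/13/17 normo/micro/macro
pipeline <- run_uev_pipeline(cohort)
pipeline
#> uEV analysis pipeline
#>   samples: 67 in, 61 QC-passed (2 PCA outliers)
#>   robust genes: 1951; DE tested: 1951; Bonferroni p <= 2.56e-05; significant: 13
#>   stress score by group: Kruskal-Wallis p = 2.78e-10; rho(score, HbA1c) = 0.41
#>   decliner ROC AUC = 0.83; adjusted score beta = -0.42 (n = 61 persons)
```

Reading the output: of 67 simulated samples, 61 pass QC; all 13 planted DKD
marker genes clear the Bonferroni threshold in the macro-vs-normo contrast;
the stress score rises monotonically across albuminuria groups
(Kruskal–Wallis p ≈ 3×10⁻¹⁰) and correlates with HbA1c (ρ = 0.41); persons
in higher stress quartiles decline faster, giving an AUC of 0.83 for
detecting decliners and a negative adjusted regression coefficient of the
score on the eGFR slope.

Individual stages compose with the pipe:

```r
lcpm  <- log2_cpm(cohort$counts, tmm_factors(cohort$counts))
scores <- stress_score(lcpm) |> dplyr::inner_join(cohort$meta, by = "sample_id")
autoplot(scores, group_col = "group")
de <- nb_glm_de(cohort$counts, cohort$meta, c("macro", "normo"),
                covariates = c("age", "bmi", "duration", "protocol"))
tidy(de); glance(de); autoplot(de)
```

## Acceptance script

`scripts/acceptance.R` regenerates a 2000-gene, 90-sample synthetic cohort
from the given seed, runs the complete pipeline (QC → robust set → TMM/CPM
→ gene-set detection → tissue co-embedding → NB-GLM differential expression
→ stress score → longitudinal slopes, staging, ROC and adjusted
regression), prints the run summary and writes the JSON result:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/synth-cohort.R` – simulation config, cohort and tissue-reference generators
* `R/sample-qc.R` – metric-based exclusion, PCA outliers, mapped-read tests
* `R/expression-core.R` – robust gene set, TMM, CPM, inverse normal
  transform, CV strata, replicate concordance
* `R/differential-expression.R` – NB GLM DE, Bonferroni, ΔΔCt qPCR utilities
* `R/tissue-similarity.R` – gene-set detection, tissue PCA co-embedding,
  panel co-expression
* `R/stress-score.R`, `R/longitudinal.R` – score, group tests, CKD-EPI,
  slopes, staging, ROC, adjusted regression, albuminuria classification
* `vignettes/uev-stress-methods.Rmd` – the methods vignette
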