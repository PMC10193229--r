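#' Run the full uEV analysis pipeline on a cohort
#'
#' Chains every stage on a (synthetic or real) cohort: sample QC (intergenic
#' fraction, degradation flag, PCA outliers), robust gene set, TMM/log2CPM
#' normalization, kidney gene-set detection, tissue PCA co-embedding against
#' a synthetic reference, negative-binomial differential expression
#' (macro vs normo, covariate-adjusted), the six-gene stress score, group
#' comparison, clinical correlation with HbA1c, and the longitudinal eGFR
#' analysis (annual means, quartile slopes, CKD staging, decliner ROC,
#' adjusted slope regression).
#'
#' @param cohort A `uev_cohort` from [generate_cohort()], or a compatible
#'   list with `counts`, `meta`, `qc`, `longitudinal`, `gene_sets`.
#' @param covariates DE adjustment covariates present in `meta`.
#'   Default `c("age", "bmi", "duration", "protocol")`.
#' @param decline_threshold Per-person slope at or below which a person is
#'   labelled a decliner for the ROC analysis (mL/min/1.73m^2 per year).
#'   Default -0.5.
#' @param min_years Strict minimum of annual data points for slope
#'   eligibility. Default 8.
#' @param seed Seed for the synthetic tissue reference. Default 1.
#' @return A list of class `uev_pipeline` with the per-stage results and a
#'   `summary` element (plain named list, JSON-serializable).
#' @export
run_uev_pipeline <- function(cohort,
                             covariates = c("age", "bmi", "duration",
                                            "protocol"),
                             decline_threshold = -0.5, min_years = 8,
                             seed = 1L) {
  # 1. QC: metric-based exclusion, then PCA outliers among survivors.
  qc_dec <- qc_filter(cohort$qc)
  keep1 <- qc_dec$sample_id[!is.na(qc_dec$included) & qc_dec$included]
  counts1 <- cohort$counts[, keep1, drop = FALSE]
  robust <- robust_gene_set(counts1)
  f1 <- tmm_factors(counts1[robust, , drop = FALSE])
  lcpm1 <- log2_cpm(counts1[robust, , drop = FALSE], f1)
  pca_res <- pca_outlier_filter(lcpm1)
  keep <- pca_res$retained
  counts <- counts1[, keep, drop = FALSE]
  meta <- dplyr::filter(cohort$meta, .data$sample_id %in% keep)

  # 2. Normalization on QC-passed samples.
  robust <- robust_gene_set(counts)
  rcounts <- counts[robust, , drop = FALSE]
  factors <- tmm_factors(rcounts)
  lcpm <- log2_cpm(rcounts, factors)

  # 3. Tissue similarity.
  det <- detected_genes(counts)
  detection <- purrr::imap_dfr(cohort$gene_sets, function(set, nm) {
    dplyr::mutate(gene_set_detection(det, set), set = nm, .before = 1)
  })
  ref <- generate_tissue_reference(rownames(cohort$counts),
                                   cohort$gene_sets$kidney_enriched,
                                   cohort$gene_sets$kidney_depleted,
                                   seed = seed)
  embed <- tissue_pca_embed(lcpm, ref)

  # 4. Differential expression, macro vs normo.
  de <- nb_glm_de(rcounts, meta, contrast = c("macro", "normo"),
                  covariates = covariates, factors = factors)

  # 5. Stress score on all QC-passed diabetic samples.
  scores <- stress_score(lcpm)
  scored <- dplyr::inner_join(scores, meta, by = "sample_id")
  score_test <- compare_score_groups(scored)
  hba1c_cor <- clinical_correlation(
    dplyr::select(scored, "sample_id", "score"),
    dplyr::select(meta, "sample_id", "hba1c"))

  # 6. Longitudinal analysis by stress quartile.
  annual <- annual_egfr_means(cohort$longitudinal)
  person_map <- dplyr::select(meta, "person_id", "sample_id")
  quart <- scored |>
    dplyr::select("person_id", group = "quartile")
  slopes <- group_slope(annual, quart, min_years = min_years)
  per_person <- attr(slopes, "per_person")
  stages <- ckd_stage(annual)
  roc_dat <- per_person |>
    dplyr::inner_join(dplyr::select(scored, "person_id", "score"),
                      by = "person_id")
  roc <- roc_auc(roc_dat$score, roc_dat$slope <= decline_threshold)
  baseline <- annual |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(egfr_baseline = .data$egfr_mean[which.max(.data$year)],
                     .groups = "drop")
  reg_dat <- per_person |>
    dplyr::inner_join(dplyr::select(scored, "person_id", "score", "dbp",
                                    "hba1c", "sbp"), by = "person_id") |>
    dplyr::inner_join(baseline, by = "person_id")
  regression <- adjusted_slope_regression(reg_dat)

  summary <- list(
    n_samples_input = ncol(cohort$counts),
    n_samples_qc_passed = length(keep),
    n_pca_outliers = length(pca_res$outliers),
    n_robust_genes = length(robust),
    detection = as.data.frame(detection),
    n_tested = attr(de, "n_tested"),
    bonferroni_threshold = attr(de, "threshold"),
    n_significant = sum(de$significant, na.rm = TRUE),
    score_group_p = score_test$p_value,
    score_hba1c_rho = hba1c_cor$rho,
    roc_auc_decliner = roc$auc,
    score_slope_beta = regression$estimate[regression$term == "score"],
    n_slope_persons = nrow(per_person)
  )
  structure(
    list(qc = qc_dec, pca_outliers = pca_res$outliers, robust_genes = robust,
         factors = factors, log2cpm = lcpm, detection = detection,
         embedding = embed, de = de, scores = scored,
         score_test = score_test, annual = annual, slopes = slopes,
         ckd_stages = stages, roc = roc, regression = regression,
         summary = summary),
    class = "uev_pipeline"
  )
}

#' @export
print.uev_pipeline <- function(x, ...) {
  s <- x$summary
  cat("uEV analysis pipeline\n")
  cat(sprintf("  samples: %d in, %d QC-passed (%d PCA outliers)\n",
              s$n_samples_input, s$n_samples_qc_passed, s$n_pca_outliers))
  cat(sprintf("  robust genes: %d; DE tested: %d; Bonferroni p <= %.3g; significant: %d\n",
              s$n_robust_genes, s$n_tested, s$bonferroni_threshold,
              s$n_significant))
  cat(sprintf("  stress score by group: Kruskal-Wallis p = %.3g; rho(score, HbA1c) = %.2f\n",
              s$score_group_p, s$score_hba1c_rho))
  cat(sprintf("  decliner ROC AUC = %.2f; adjusted score beta = %.2f (n = %d persons)\n",
              s$roc_auc_decliner, s$score_slope_beta, s$n_slope_persons))
  invisible(x)
}
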