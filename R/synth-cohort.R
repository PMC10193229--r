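#' Simulation configuration for a synthetic uEV cohort
#'
#' Collects the parameters of the synthetic-cohort generator.  Defaults
#' emulate the discovery-cohort setting: 37 normo-, 13 micro- and 17
#' macroalbuminuric type 1 diabetic men, 13 planted DKD marker genes
#' upregulated macro > micro > normo, negative-binomial counts with
#' log-normal gene-wise dispersions, HbA1c coupled to a per-person latent
#' stress trait, and 15-year eGFR trajectories (calendar years 2004-2018)
#' whose slopes steepen with latent stress.
#'
#' @param n_per_group Named integer vector of group sizes, names among
#'   `normo`, `micro`, `macro`, `control`.
#' @param n_genes Number of genes in the simulated universe.
#' @param n_kidney_enriched Size of the simulated kidney-enriched set; a 46%
#'   subset is labelled specific-kidney-enriched and twice as many
#'   low-abundance genes form the kidney-depleted set.
#' @param de_genes Data frame `gene`, `lfc_macro`, `lfc_micro` of planted
#'   log2 fold effects relative to normoalbuminuria.  Defaults to the 13
#'   DKD marker genes with lfc 2 (macro) and 1 (micro).
#' @param stress_shift Named vector of group shifts of the latent stress
#'   trait (sd units). Default `c(control = 0, normo = 0, micro = 0.8,
#'   macro = 1.6)`.
#' @param stress_expr_coupling log2 expression shift of the six stress-panel
#'   genes per sd of within-group latent-stress residual. Default 0.35.
#' @param dispersion_median,dispersion_shape Median and log-sd of the
#'   log-normal gene-wise NB dispersion (var = mu + phi mu^2).
#'   Defaults 0.16 and 0.5.
#' @param lib_size_log_mean,lib_size_log_sd Log-normal library-size
#'   parameters. Defaults `log(4e5)` and 0.35 (scaled to the simulated gene
#'   universe, not to full-depth sequencing).
#' @param hba1c_coupling Correlation strength between latent stress and
#'   HbA1c. Default 0.4.
#' @param slope_model List `base_slope`, `stress_slope_effect`,
#'   `hyperfiltration_offset`, `slope_noise_sd`, `visit_noise_sd`
#'   (mL/min/1.73m^2 units).  Per-person slope = base +
#'   effect x latent stress + N(0, slope_noise_sd); `hyperfiltration_offset`
#'   (default 0 = off) raises the baseline eGFR of persons in the 25-50
#'   latent-stress percentile band.
#' @param qc_contamination_rate Probability that a sample carries an
#'   intergenic fraction > 5% and/or a degradation flag. Default 0.05.
#' @param dropout_rate Probability that a longitudinal visit record is
#'   missing completely at random. Default 0.1.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A list of class `uev_sim_config`.
#' @export
sim_config <- function(n_per_group = c(normo = 37, micro = 13, macro = 17,
                                       control = 0),
                       n_genes = 2000,
                       n_kidney_enriched = 80,
                       de_genes = NULL,
                       stress_shift = c(control = 0, normo = 0,
                                        micro = 0.8, macro = 1.6),
                       stress_expr_coupling = 0.35,
                       dispersion_median = 0.16,
                       dispersion_shape = 0.5,
                       lib_size_log_mean = log(4e5),
                       lib_size_log_sd = 0.35,
                       hba1c_coupling = 0.4,
                       slope_model = list(base_slope = -0.5,
                                          stress_slope_effect = -0.6,
                                          hyperfiltration_offset = 0,
                                          slope_noise_sd = 0.3,
                                          visit_noise_sd = 2),
                       qc_contamination_rate = 0.05,
                       dropout_rate = 0.1,
                       seed = 1L) {
  if (is.null(de_genes)) {
    de_genes <- tibble(gene = DKD_GENES_DEFAULT, lfc_macro = 2, lfc_micro = 1)
  }
  cfg <- list(
    n_per_group = n_per_group, n_genes = n_genes,
    n_kidney_enriched = n_kidney_enriched, de_genes = as_tibble(de_genes),
    stress_shift = stress_shift, stress_expr_coupling = stress_expr_coupling,
    dispersion_median = dispersion_median, dispersion_shape = dispersion_shape,
    lib_size_log_mean = lib_size_log_mean, lib_size_log_sd = lib_size_log_sd,
    hba1c_coupling = hba1c_coupling, slope_model = slope_model,
    qc_contamination_rate = qc_contamination_rate,
    dropout_rate = dropout_rate, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "uev_sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n_per_group < 0) || sum(cfg$n_per_group) == 0) {
    abort("sim_config: group sizes must be >= 0 and sum > 0.")
  }
  probs <- c(cfg$qc_contamination_rate, cfg$dropout_rate, cfg$hba1c_coupling)
  if (any(probs < 0) || any(probs > 1)) {
    abort("sim_config: rates/couplings must lie in [0, 1].")
  }
  if (cfg$dispersion_median <= 0 || cfg$dispersion_shape <= 0) {
    abort("sim_config: dispersion parameters must be positive.")
  }
  de <- cfg$de_genes
  if (nrow(de) > 0 && any(de$lfc_macro < de$lfc_micro | de$lfc_micro < 0)) {
    abort("sim_config: planted effects must satisfy macro >= micro >= normo (0).")
  }
  invisible(cfg)
}

#' Generate a synthetic uEV cohort
#'
#' Draws a full cohort from a [sim_config()]: a gene x sample NB count
#' matrix with planted group effects, clinical metadata with HbA1c coupled
#' to a per-person latent stress trait, a QC metric table with a configurable
#' contamination rate, kidney gene sets, 15-year longitudinal eGFR/HbA1c
#' visit records, and a truth table of every planted quantity.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `uev_cohort` with elements `counts` (matrix),
#'   `meta`, `qc`, `longitudinal` (tibbles), `gene_sets` (named list of
#'   character vectors), and `truth` (list with `genes` and `persons`
#'   tibbles).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  npg <- cfg$n_per_group[cfg$n_per_group > 0]
  groups <- rep(names(npg), npg)
  n <- length(groups)
  sample_id <- sprintf("S%03d", seq_len(n))
  person_id <- sprintf("P%03d", seq_len(n))

  # Gene universe: planted DKD genes plus background genes.
  de <- cfg$de_genes
  if (!all(de$gene %in% c(DKD_GENES_DEFAULT, de$gene))) {
    abort("generate_cohort(): invalid de_genes table.")
  }
  n_bg <- cfg$n_genes - nrow(de)
  if (n_bg < 0) abort("generate_cohort(): n_genes smaller than de_genes.")
  genes <- c(de$gene, sprintf("GENE%05d", seq_len(n_bg)))
  if (anyDuplicated(genes)) abort("generate_cohort(): duplicate gene labels.")

  # Baseline relative abundances (log-normal), dispersions (log-normal).
  base <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.5)
  # Planted genes at moderate abundance so power analyses are meaningful.
  base[seq_len(nrow(de))] <- exp(stats::rnorm(nrow(de), mean = 0.5, sd = 0.3))
  base <- base / sum(base)
  names(base) <- genes
  phi <- rlnorm(cfg$n_genes, meanlog = log(cfg$dispersion_median),
                sdlog = cfg$dispersion_shape)

  # Latent stress: standard normal + group shift.
  shift <- cfg$stress_shift[groups]
  shift[is.na(shift)] <- 0
  latent <- rnorm(n) + as.numeric(shift)

  lib <- rlnorm(n, cfg$lib_size_log_mean, cfg$lib_size_log_sd)

  # Per-sample log2 effects: group lfc on planted genes; stress-panel genes
  # additionally track the within-group latent residual.
  lfc <- matrix(0, nrow = cfg$n_genes, ncol = n, dimnames = list(genes, NULL))
  if (nrow(de) > 0) {
    lfc[de$gene, groups == "macro"] <- de$lfc_macro
    lfc[de$gene, groups == "micro"] <- de$lfc_micro
    panel <- intersect(de$gene, STRESS_PANEL_DEFAULT)
    if (length(panel) > 0 && cfg$stress_expr_coupling != 0) {
      resid <- latent - as.numeric(shift)
      lfc[panel, ] <- lfc[panel, , drop = FALSE] +
        matrix(cfg$stress_expr_coupling * resid, nrow = length(panel),
               ncol = n, byrow = TRUE)
    }
  }
  mu <- (base * 2^lfc) %*% diag(lib, n)
  counts <- matrix(
    rnbinom(cfg$n_genes * n, mu = as.numeric(mu), size = rep(1 / phi, n)),
    nrow = cfg$n_genes, dimnames = list(genes, sample_id)
  )
  storage.mode(counts) <- "integer"

  # HbA1c: rho x standardized latent + sqrt(1-rho^2) x noise, on a clinical
  # scale (%); non-diabetic controls sit lower with minimal coupling.
  lz <- as.numeric(scale(latent))
  rho <- cfg$hba1c_coupling
  hba1c_z <- rho * lz + sqrt(1 - rho^2) * rnorm(n)
  hba1c <- ifelse(groups == "control", 5.4 + 0.3 * rnorm(n),
                  7.8 + 1.2 * hba1c_z)

  aer <- dplyr::case_when(
    groups == "macro" ~ runif(n, 320, 1500),
    groups == "micro" ~ runif(n, 35, 280),
    TRUE ~ runif(n, 3, 25)
  )
  meta <- tibble(
    sample_id = sample_id,
    person_id = person_id,
    group = factor(groups, levels = intersect(
      c("control", "normo", "micro", "macro"), unique(groups))),
    cohort = "discovery",
    protocol = sample(c("overnight", "24h"), n, replace = TRUE),
    sex = "male",
    age = round(pmax(rnorm(n, 47, 10), 20), 1),
    bmi = round(pmax(rnorm(n, 26, 3), 17), 1),
    duration = ifelse(groups == "control", 0,
                      round(pmax(rnorm(n, 30, 8), 2), 1)),
    hba1c = round(hba1c, 2),
    sbp = round(rnorm(n, 135, 15), 0),
    dbp = round(rnorm(n, 80, 9), 0),
    ace_or_bb = rbinom(n, 1, 0.5) == 1,
    aer_mg_24h = round(aer, 1)
  )

  qc <- generate_qc_metrics(sample_id, meta$sex, cfg$qc_contamination_rate, n)

  gene_sets <- build_gene_sets(genes, base, cfg$n_kidney_enriched, nrow(de))

  long <- generate_longitudinal(person_id, groups, latent, meta, cfg)

  truth <- list(
    genes = de |>
      dplyr::mutate(baseline_proportion = base[de$gene],
                    dispersion = phi[match(de$gene, genes)]),
    persons = tibble(
      person_id = person_id, sample_id = sample_id, group = groups,
      latent_stress = latent,
      true_slope = attr(long, "true_slope"),
      egfr0 = attr(long, "egfr0")
    )
  )

  structure(
    list(counts = counts, meta = meta, qc = qc, longitudinal = long,
         gene_sets = gene_sets, truth = truth, config = cfg),
    class = "uev_cohort"
  )
}

generate_qc_metrics <- function(sample_id, sex, contamination_rate, n) {
  contaminated <- runif(n) < contamination_rate
  mode <- ifelse(contaminated, sample(1:3, n, replace = TRUE), 0L)
  intergenic <- ifelse(mode %in% c(1L, 3L), runif(n, 0.06, 0.20),
                       stats::rbeta(n, 1.5, 1500))
  degradation <- mode %in% c(2L, 3L)
  mapped <- stats::rbeta(n, 200, 22)           # ~0.90 uniquely mapped
  rest <- 1 - mapped
  multim <- rest * runif(n, 0.4, 0.6)
  tibble(
    sample_id = sample_id,
    raw_reads = round(rlnorm(n, log(11.5e6), 0.35)),
    uniquely_mapped_fraction = mapped,
    multimapped_fraction = multim,
    unmapped_fraction = rest - multim,
    cds_fraction = (1 - intergenic) * 0.736,
    utr3_fraction = (1 - intergenic) * 0.145,
    utr5_fraction = (1 - intergenic) * 0.116,
    intronic_fraction = pmax((1 - intergenic) * 0.003, 0),
    intergenic_fraction = intergenic,
    degradation_flag = degradation,
    sex = sex
  )
}

build_gene_sets <- function(genes, base, n_enriched, n_de) {
  n_enriched <- min(n_enriched, length(genes) - n_de)
  bg <- setdiff(genes, genes[seq_len(n_de)])
  # Enriched genes drawn from mid/high abundance background genes so most
  # are detected; depleted genes from the low-abundance tail so most are not.
  ord <- bg[order(base[bg], decreasing = TRUE)]
  enriched <- ord[seq_len(n_enriched)]
  specific <- enriched[seq_len(max(2, round(0.46 * n_enriched)))]
  n_depl <- min(2 * n_enriched, length(ord) - n_enriched)
  depleted <- rev(ord)[seq_len(n_depl)]
  list(kidney_enriched = enriched,
       specific_kidney_enriched = specific,
       kidney_depleted = depleted)
}

generate_longitudinal <- function(person_id, groups, latent, meta, cfg) {
  sm <- cfg$slope_model
  n <- length(person_id)
  diabetic <- groups != "control"
  slope <- sm$base_slope + sm$stress_slope_effect * latent +
    rnorm(n, 0, sm$slope_noise_sd)
  egfr0 <- rnorm(n, 95, 10)
  if (sm$hyperfiltration_offset != 0) {
    pr <- rank(latent) / (n + 1)
    band <- pr >= 0.25 & pr < 0.50
    egfr0[band] <- egfr0[band] + sm$hyperfiltration_offset
  }
  years <- 2004:2018
  rows <- purrr::map_dfr(which(diabetic), function(i) {
    jit <- round(runif(length(years), 0, 330))
    egfr <- egfr0[i] + slope[i] * (years - years[1]) +
      rnorm(length(years), 0, sm$visit_noise_sd)
    egfr <- pmax(egfr, 5)
    tibble(
      person_id = person_id[i],
      date = as.Date(sprintf("%d-01-01", years)) + jit,
      egfr = round(egfr, 1),
      scr_mg_dl = round(creatinine_from_egfr(egfr, meta$age[i], meta$sex[i]), 3),
      hba1c = round(meta$hba1c[i] + rnorm(length(years), 0, 0.4), 2)
    )
  })
  keep <- runif(nrow(rows)) >= cfg$dropout_rate
  out <- rows[keep, ]
  attr(out, "true_slope") <- ifelse(diabetic, slope, NA_real_)
  attr(out, "egfr0") <- ifelse(diabetic, egfr0, NA_real_)
  out
}

# Invert the CKD-EPI 2009 creatinine equation (used only by the generator,
# so simulated visit tables can carry serum creatinine).
creatinine_from_egfr <- function(egfr, age, sex, black = FALSE) {
  p <- ckd_epi_params()
  female <- sex == "female"
  kappa <- ifelse(female, p$kappa_female, p$kappa_male)
  alpha <- ifelse(female, p$alpha_female, p$alpha_male)
  a <- 141 * p$age_base^age * ifelse(female, p$female_mult, 1) *
    ifelse(black, p$black_mult, 1)
  ratio_low <- (egfr / a)^(1 / alpha)    # branch Scr <= kappa
  ratio_high <- (egfr / a)^(1 / p$slope_exp_max)
  ifelse(ratio_low <= 1, ratio_low, ratio_high) * kappa
}

#' Generate a synthetic multi-tissue expression reference
#'
#' Builds a GTEx-like log2-scale expression matrix over the cohort's gene
#' universe with one tissue designated `kidney_cortex`: kidney-enriched
#' genes are planted at least 2-fold (1 log2 unit, plus margin) above the
#' across-tissue median in kidney cortex, and kidney-depleted genes sit
#' below the detection threshold there.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param kidney_enriched,kidney_depleted Character vectors of gene-set
#'   members (subsets of `gene_ids`).
#' @param n_tissues Number of tissues (>= 2); the first is `kidney_cortex`.
#'   Default 17.
#' @param n_samples_per_tissue Samples per tissue (>= 1). Default 5.
#' @param seed Integer seed.
#' @return A list of class `uev_tissue_ref`: `expr` (log2 matrix, genes x
#'   tissue samples), `tissue` (character vector along columns),
#'   `provenance = "synthetic"`.
#' @export
generate_tissue_reference <- function(gene_ids, kidney_enriched,
                                      kidney_depleted, n_tissues = 17,
                                      n_samples_per_tissue = 5, seed = 1L) {
  if (n_tissues < 2) abort("generate_tissue_reference(): n_tissues >= 2.")
  if (n_samples_per_tissue < 1) {
    abort("generate_tissue_reference(): n_samples_per_tissue >= 1.")
  }
  withr::with_seed(as.integer(seed), {
    tissue_names <- c("kidney_cortex", "prostate", "bladder", "testis",
                      "liver", "lung", "heart", "muscle", "brain", "skin",
                      "colon", "spleen", "pancreas", "stomach", "thyroid",
                      "adipose", "esophagus", "nerve", "pituitary", "ovary")
    tissues <- tissue_names[seq_len(min(n_tissues, length(tissue_names)))]
    if (n_tissues > length(tissue_names)) {
      tissues <- c(tissues, sprintf("tissue%02d",
                                    seq_len(n_tissues - length(tissue_names))))
    }
    g <- length(gene_ids)
    gene_base <- rnorm(g, 5, 2)
    tissue_fx <- matrix(rnorm(g * n_tissues, 0, 0.8), nrow = g)
    mu <- gene_base + tissue_fx            # log2 tissue means
    rownames(mu) <- gene_ids
    enr <- intersect(kidney_enriched, gene_ids)
    dep <- intersect(kidney_depleted, gene_ids)
    mu[enr, 1] <- apply(mu[enr, , drop = FALSE], 1, median) + 2.5 +
      abs(rnorm(length(enr), 0, 0.5))
    mu[dep, 1] <- pmax(rnorm(length(dep), 0.1, 0.1), 0)
    cols <- rep(seq_len(n_tissues), each = n_samples_per_tissue)
    expr <- mu[, cols, drop = FALSE] +
      matrix(rnorm(g * length(cols), 0, 0.3), nrow = g)
    expr[dep, cols == 1] <- pmax(expr[dep, cols == 1], 0)
    colnames(expr) <- sprintf("%s_%02d", tissues[cols],
                              sequence(rep(n_samples_per_tissue, n_tissues)))
    structure(list(expr = expr, tissue = tissues[cols],
                   provenance = "synthetic"),
              class = "uev_tissue_ref")
  })
}

#' @export
print.uev_cohort <- function(x, ...) {
  cat("Synthetic uEV cohort\n")
  cat(sprintf("  counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:",
      paste(sprintf("%s=%d", names(table(x$meta$group)),
                    as.integer(table(x$meta$group))), collapse = ", "), "\n")
  cat(sprintf("  longitudinal: %d visit records, %d persons\n",
              nrow(x$longitudinal), length(unique(x$longitudinal$person_id))))
  cat(sprintf("  gene sets: %s\n",
              paste(sprintf("%s (%d)", names(x$gene_sets),
                            lengths(x$gene_sets)), collapse = ", ")))
  invisible(x)
}
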