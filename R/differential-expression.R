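#' Bonferroni family-wise significance threshold
#'
#' @param n_tested Number of genes tested (>= 1).
#' @param alpha Family-wise error rate. Default 0.05.
#' @return `alpha / n_tested`.
#' @export
bonferroni_threshold <- function(n_tested, alpha = 0.05) {
  stopifnot(n_tested >= 1, alpha > 0, alpha < 1)
  alpha / n_tested
}

#' Negative-binomial GLM differential expression
#'
#' Per-gene count model `log mu = offset + beta0 + beta_g x case + covariates`
#' with `offset = log(library size x TMM factor)`.  The gene-wise NB
#' dispersion (var = mu + phi mu^2) is estimated by method of moments from
#' Poisson-fit residuals and shrunk 50% toward a lowess mean-dispersion
#' trend; the contrast is tested by a Wald test on the case coefficient,
#' referred to a t distribution on the residual degrees of freedom.
#' Significance is called at the Bonferroni threshold `alpha / n_tested`.
#'
#' Genes with zero counts in more than half the samples of every contrast
#' group are not fitted (convergence guard) and are reported with
#' `fit_status = "low_count"`; genes whose fit fails are reported with
#' `fit_status = "failed"` and a missing p-value, never dropped silently.
#'
#' @param counts Count matrix, genes x samples; typically already restricted
#'   to the robust gene set and QC-passed samples.
#' @param meta Data frame of per-sample covariates; rows matched to the
#'   columns of `counts` by a `sample_id` column.
#' @param contrast Character vector `c(case, control)` of levels of
#'   `group_col`, e.g. `c("macro", "normo")`.  The case side may contain
#'   several levels, which are pooled (see [combined_group_contrast()]).
#' @param covariates Character vector of adjustment columns in `meta`
#'   (e.g. age, BMI, diabetes duration, urine collection protocol).
#' @param group_col Name of the group column in `meta`. Default `"group"`.
#' @param factors Optional per-sample TMM factors (aligned with the columns
#'   of `counts`); default `NULL` computes them with [tmm_factors()].
#' @param alpha Family-wise error rate for the Bonferroni call. Default 0.05.
#' @param test `"wald"` (default) or `"lrt"` (likelihood-ratio refit).
#' @return A tibble of class `uev_de` with columns `gene`, `log2fc`,
#'   `p_value`, `significant`, `dispersion`, `fit_status`, and attributes
#'   `n_tested`, `threshold`, `alpha`, `contrast`, `n_case`, `n_control`.
#' @export
nb_glm_de <- function(counts, meta, contrast, covariates = character(0),
                      group_col = "group", factors = NULL, alpha = 0.05,
                      test = c("wald", "lrt")) {
  test <- match.arg(test)
  counts <- validate_counts(counts)
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta),
            group_col %in% names(meta), length(contrast) >= 2)
  control <- contrast[length(contrast)]
  case <- contrast[-length(contrast)]
  meta <- as.data.frame(meta)
  rownames(meta) <- meta$sample_id
  ids <- colnames(counts)
  if (is.null(ids)) abort("nb_glm_de(): counts must have sample ids as colnames.")
  meta <- meta[ids, , drop = FALSE]
  grp <- as.character(meta[[group_col]])
  sel <- grp %in% c(case, control)
  if (!any(grp[sel] %in% case) || !any(grp[sel] == control)) {
    abort("nb_glm_de(): both contrast sides must be non-empty.")
  }
  counts <- counts[, sel, drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  grp <- grp[sel]
  if (is.null(factors)) {
    factors <- tmm_factors(counts)
  } else {
    factors <- factors[sel]
  }
  offset <- log(colSums(counts) * factors)
  is_case <- as.numeric(grp %in% case)

  bad <- setdiff(covariates, names(meta))
  if (length(bad)) abort(paste0("nb_glm_de(): covariates not in meta: ",
                                paste(bad, collapse = ", ")))
  xdf <- data.frame(.case = is_case)
  for (cv in covariates) {
    v <- meta[[cv]]
    xdf[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  x <- model.matrix(~ ., data = xdf)
  case_col <- which(colnames(x) == ".case")

  # Convergence guard: a gene must have counts in at least half the samples
  # of at least one group.
  zero_heavy <- vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    all(vapply(split(y, is_case), function(yy) mean(yy == 0) > 0.5, logical(1)))
  }, logical(1))

  disp <- estimate_dispersions(counts, x, offset, fit_mask = !zero_heavy)

  n <- ncol(counts)
  p <- ncol(x)
  df_resid <- n - p
  fit_one <- function(g) {
    y <- counts[g, ]
    theta <- 1 / max(disp$shrunk[g], 1e-6)
    fit <- tryCatch(
      suppressWarnings(glm.fit(x, y, family = MASS::negative.binomial(theta),
                               offset = offset)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(c(NA_real_, NA_real_))
    }
    beta <- fit$coefficients[case_col]
    if (test == "wald") {
      xtwx <- crossprod(x * fit$weights, x)
      se <- tryCatch(sqrt(diag(chol2inv(chol(xtwx))))[case_col],
                     error = function(e) NA_real_)
      if (!is.finite(se) || se <= 0) return(c(beta / log(2), NA_real_))
      pval <- 2 * stats::pt(-abs(beta / se), df = df_resid)
    } else {
      fit0 <- tryCatch(
        suppressWarnings(glm.fit(x[, -case_col, drop = FALSE], y,
                                 family = MASS::negative.binomial(theta),
                                 offset = offset)),
        error = function(e) NULL)
      if (is.null(fit0)) return(c(beta / log(2), NA_real_))
      dev <- max(fit0$deviance - fit$deviance, 0)
      pval <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
    }
    c(beta / log(2), pval)
  }

  res <- matrix(NA_real_, nrow = nrow(counts), ncol = 2)
  for (g in which(!zero_heavy)) res[g, ] <- fit_one(g)

  status <- rep("ok", nrow(counts))
  status[zero_heavy] <- "low_count"
  status[!zero_heavy & is.na(res[, 2])] <- "failed"
  n_tested <- sum(status == "ok")
  thr <- bonferroni_threshold(max(n_tested, 1), alpha)
  out <- tibble(
    gene = rownames(counts),
    log2fc = res[, 1],
    p_value = res[, 2],
    significant = !is.na(res[, 2]) & res[, 2] <= thr,
    dispersion = disp$shrunk,
    fit_status = status
  )
  structure(
    out,
    class = c("uev_de", class(out)),
    n_tested = n_tested,
    threshold = thr,
    alpha = alpha,
    contrast = paste(paste(case, collapse = "+"), "vs", control),
    n_case = sum(is_case == 1),
    n_control = sum(is_case == 0)
  )
}

# Method-of-moments NB dispersions from Poisson-fit residuals, shrunk 50%
# toward a lowess trend on mean log2CPM.
estimate_dispersions <- function(counts, x, offset, fit_mask) {
  n <- ncol(counts)
  p <- ncol(x)
  raw <- rep(NA_real_, nrow(counts))
  for (g in which(fit_mask)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(glm.fit(x, y, family = poisson(), offset = offset)),
      error = function(e) NULL)
    if (is.null(fit)) next
    mu <- fit$fitted.values
    raw[g] <- sum((y - mu)^2 - mu) * (n / (n - p)) / sum(mu^2)
  }
  raw <- pmin(pmax(raw, 0), 10)
  mean_log_cpm <- log2(rowMeans(sweep(counts, 2, exp(offset), "/")) * 1e6 + 0.5)
  ok <- is.finite(raw) & is.finite(mean_log_cpm)
  trend <- rep(stats::median(raw[ok], na.rm = TRUE), nrow(counts))
  if (sum(ok) >= 20) {
    lw <- lowess(mean_log_cpm[ok], log(raw[ok] + 1e-3), f = 0.5)
    tr <- approx(lw$x, lw$y, xout = mean_log_cpm, rule = 2)$y
    trend <- exp(tr) - 1e-3
  }
  trend <- pmin(pmax(trend, 1e-4), 10)
  shrunk <- ifelse(is.finite(raw), 0.5 * raw + 0.5 * trend, trend)
  shrunk <- pmin(pmax(shrunk, 1e-4), 10)
  list(raw = raw, trend = trend, shrunk = shrunk)
}

#' Pooled albuminuria contrast
#'
#' Differential expression of the combined micro- and macroalbuminuria group
#' against the normoalbuminuric group; a thin wrapper over [nb_glm_de()]
#' with the case levels pooled into one indicator.
#'
#' @inheritParams nb_glm_de
#' @param case_groups Levels pooled as the case side.
#'   Default `c("micro", "macro")`.
#' @param control_group Control level. Default `"normo"`.
#' @return See [nb_glm_de()].
#' @export
combined_group_contrast <- function(counts, meta,
                                    case_groups = c("micro", "macro"),
                                    control_group = "normo", ...) {
  nb_glm_de(counts, meta, contrast = c(case_groups, control_group), ...)
}

#' Relative expression from qPCR Ct values (delta-delta-Ct)
#'
#' Per sample and target gene, `delta Ct = mean Ct(target) - mean
#' Ct(reference)`; relative expression is `2^-deltaCt`.  A sample x gene
#' record is excluded when it has fewer than `min_replicates` successful
#' (non-missing) Ct replicates for either side, or when its delta Ct exceeds
#' `max_delta_ct`.  If a calibrator group is given, `2^-ddCt` against the
#' calibrator-group mean delta Ct is added.
#'
#' @param records Long data frame with columns `sample_id`, `gene`, `ct`
#'   (one row per technical replicate; `NA` = failed replicate).
#' @param reference_gene Name of the normalizer gene (GAPDH role).
#' @param max_delta_ct Exclusion threshold on delta Ct. Default 19.
#' @param min_replicates Minimum successful replicates per sample x gene.
#'   Default 2.
#' @param sample_groups Optional data frame `sample_id`, `group` for the
#'   ddCt calibration.
#' @param calibrator_group Group whose mean delta Ct calibrates ddCt.
#' @return A tibble with `sample_id`, `gene`, `delta_ct`, `rel_expr`,
#'   `excluded`, `reasons` (list-column), and `ddct`/`rel_expr_ddct` when a
#'   calibrator was given.
#' @export
ddct_relative_expression <- function(records, reference_gene = "GAPDH",
                                     max_delta_ct = 19, min_replicates = 2,
                                     sample_groups = NULL,
                                     calibrator_group = NULL) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "gene", "ct") %in% names(records)))
  if (any(records$ct <= 0, na.rm = TRUE)) {
    abort("ddct_relative_expression(): Ct values must be positive.")
  }
  summ <- records |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(mean_ct = mean(.data$ct, na.rm = TRUE),
                     n_ok = sum(!is.na(.data$ct)), .groups = "drop")
  ref <- summ |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample_id", ref_ct = "mean_ct", ref_n = "n_ok")
  tgt <- summ |> dplyr::filter(.data$gene != reference_gene)
  missing_ref <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(missing_ref)) {
    abort(paste0("ddct_relative_expression(): no reference-gene Ct for: ",
                 paste(missing_ref, collapse = ", ")))
  }
  out <- tgt |>
    dplyr::left_join(ref, by = "sample_id") |>
    dplyr::mutate(
      delta_ct = .data$mean_ct - .data$ref_ct,
      reasons = purrr::pmap(
        list(.data$n_ok, .data$ref_n, .data$delta_ct),
        function(nt, nr, dct) {
          r <- character(0)
          if (nt < min_replicates || nr < min_replicates) {
            r <- c(r, "insufficient_replicates")
          }
          if (is.finite(dct) && dct > max_delta_ct) r <- c(r, "high_delta_ct")
          r
        }),
      excluded = lengths(.data$reasons) > 0,
      rel_expr = ifelse(.data$excluded, NA_real_, 2^(-.data$delta_ct))
    ) |>
    dplyr::select("sample_id", "gene", "delta_ct", "rel_expr",
                  "excluded", "reasons")
  if (!is.null(calibrator_group)) {
    if (is.null(sample_groups)) {
      abort("ddct_relative_expression(): ddCt requested without sample_groups.")
    }
    out <- out |>
      dplyr::left_join(sample_groups, by = "sample_id") |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(
        cal_mean = mean(.data$delta_ct[.data$group == calibrator_group &
                                         !.data$excluded], na.rm = TRUE),
        ddct = .data$delta_ct - .data$cal_mean,
        rel_expr_ddct = ifelse(.data$excluded, NA_real_, 2^(-.data$ddct))
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-"cal_mean", -"group")
    if (all(!is.finite(out$ddct))) {
      abort("ddct_relative_expression(): calibrator group has no usable records.")
    }
  }
  out
}

#' Concordance between sequencing and qPCR expression
#'
#' Per-gene Spearman correlation between qPCR `-deltaCt` and sequencing
#' log2CPM across paired samples.
#'
#' @param ddct Data frame with `sample_id`, `gene`, `delta_ct` (from
#'   [ddct_relative_expression()]).
#' @param log2cpm Expression matrix, genes x samples (log2CPM).
#' @return A tibble with `gene`, `n`, `spearman_r`, `p_value`.
#' @export
seq_qpcr_concordance <- function(ddct, log2cpm) {
  stopifnot(is.data.frame(ddct), is.matrix(log2cpm))
  genes <- intersect(unique(ddct$gene), rownames(log2cpm))
  if (!length(genes)) abort("seq_qpcr_concordance(): no shared genes.")
  purrr::map_dfr(genes, function(g) {
    d <- ddct[ddct$gene == g & !is.na(ddct$delta_ct), ]
    common <- intersect(d$sample_id, colnames(log2cpm))
    if (length(common) < 5) {
      abort(sprintf("seq_qpcr_concordance(): < 5 paired samples for %s.", g))
    }
    xs <- -d$delta_ct[match(common, d$sample_id)]
    ys <- log2cpm[g, common]
    if (sd(xs) == 0 || sd(ys) == 0) {
      abort(sprintf("seq_qpcr_concordance(): constant values for %s.", g))
    }
    ct <- suppressWarnings(cor.test(xs, ys, method = "spearman"))
    tibble(gene = g, n = length(common),
           spearman_r = unname(ct$estimate), p_value = ct$p.value)
  })
}
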