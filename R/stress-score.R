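#' Six-gene uEV transcriptional stress score
#'
#' Per sample, the average of the inverse-rank-normalized (and z-scored)
#' expression values of a panel of stress-response genes; the default panel
#' is GPX3, NOX4, MSRB1, MSRA, HRSP12 and CRYAB.  Samples are stratified
#' into empirical quartiles of the score within the scored cohort
#' (lower-inclusive boundaries) and into the binary low (<= 25th percentile)
#' vs mid/high (> 25th) band.
#'
#' Being rank-based, the score is invariant under any strictly monotone
#' per-gene transformation of the expression matrix.
#'
#' @param expr Expression matrix, genes x samples (typically log2CPM), with
#'   >= 3 samples.
#' @param panel Character vector of panel genes (>= 2), all present in
#'   `expr`. Default the six-gene stress panel.
#' @param offset Blom offset for the inverse normal transform. Default 0.375.
#' @return A tibble of class `uev_scores` with `sample_id`, `score`
#'   (sd units), `quartile` (factor Q0_25..Q75_100) and `band`
#'   (low / mid_high); the panel is kept as attribute `"panel"`.
#' @export
stress_score <- function(expr, panel = STRESS_PANEL_DEFAULT, offset = 0.375) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3) abort("stress_score(): need >= 3 samples.")
  if (length(panel) < 2) abort("stress_score(): panel needs >= 2 genes.")
  missing <- setdiff(panel, rownames(expr))
  if (length(missing)) {
    abort(paste0("stress_score(): panel genes absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  z <- vapply(panel, function(g) {
    inverse_normal_transform(expr[g, ], offset = offset, standardize = TRUE)
  }, numeric(ncol(expr)))
  score <- rowMeans(z)
  q <- quantile(score, c(0.25, 0.5, 0.75))
  labels <- c("Q0_25", "Q25_50", "Q50_75", "Q75_100")
  quartile <- cut(score, breaks = c(-Inf, q, Inf), labels = labels,
                  right = FALSE)
  # cut(right = FALSE) makes boundaries lower-inclusive: a score equal to an
  # empirical quartile opens the next stratum.
  out <- tibble(
    sample_id = colnames(expr) %||% as.character(seq_len(ncol(expr))),
    score = score,
    quartile = quartile,
    band = factor(ifelse(quartile == "Q0_25", "low", "mid_high"),
                  levels = c("low", "mid_high"))
  )
  structure(out, class = c("uev_scores", class(out)), panel = panel)
}

#' Compare stress scores between groups
#'
#' Two-sided Kruskal-Wallis (>= 2 groups) or Mann-Whitney (exactly 2 groups)
#' test of score by group.
#'
#' @param data Data frame with the score and group columns.
#' @param score_col,group_col Column names. Defaults `"score"`, `"group"`.
#' @param test `"kruskal_wallis"` (default) or `"mann_whitney"`.
#' @return A tibble with `test`, `statistic`, `p_value`, `n_groups`, `n`.
#' @export
compare_score_groups <- function(data, score_col = "score",
                                 group_col = "group",
                                 test = c("kruskal_wallis", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(data),
            all(c(score_col, group_col) %in% names(data)))
  x <- data[[score_col]]
  g <- factor(as.character(data[[group_col]]))
  tab <- table(g)
  if (any(tab < 3)) abort("compare_score_groups(): every group needs >= 3.")
  if (length(tab) < 2) abort("compare_score_groups(): need >= 2 groups.")
  if (test == "mann_whitney") {
    if (length(tab) != 2) {
      abort("compare_score_groups(): Mann-Whitney needs exactly 2 groups.")
    }
    ht <- suppressWarnings(
      wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]], exact = FALSE))
  } else {
    ht <- kruskal.test(x, g)
  }
  tibble(test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = length(tab), n = length(x))
}

#' Clinical correlations of expression features
#'
#' Spearman correlation (two-sided) between expression features (gene
#' expression or the stress score) and continuous clinical variables, with
#' both sides inverse-rank-transformed first.
#'
#' @param features Data frame or matrix of features: samples in rows for a
#'   data frame with `sample_id`, or genes x samples for a matrix.
#' @param clinical Data frame with `sample_id` and numeric clinical columns
#'   (e.g. hba1c, egfr, sbp, dbp, age, bmi, duration, aer).
#' @param clinical_vars Clinical columns to correlate; default all numeric.
#' @param min_pairs Minimum paired observations. Default 5.
#' @return A tibble with `feature`, `variable`, `n`, `rho`, `p_value`.
#' @export
clinical_correlation <- function(features, clinical, clinical_vars = NULL,
                                 min_pairs = 5) {
  stopifnot("sample_id" %in% names(clinical))
  if (is.matrix(features)) {
    feat <- as_tibble(t(features))
    feat$sample_id <- colnames(features)
  } else {
    stopifnot("sample_id" %in% names(features))
    feat <- as_tibble(features)
  }
  if (is.null(clinical_vars)) {
    clinical_vars <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  }
  fvars <- setdiff(names(feat)[vapply(feat, is.numeric, logical(1))],
                   clinical_vars)
  merged <- dplyr::inner_join(feat, clinical, by = "sample_id")
  purrr::map_dfr(fvars, function(fv) {
    purrr::map_dfr(clinical_vars, function(cv) {
      ok <- is.finite(merged[[fv]]) & is.finite(merged[[cv]])
      if (sum(ok) < min_pairs) {
        abort(sprintf("clinical_correlation(): < %d pairs for %s vs %s.",
                      min_pairs, fv, cv))
      }
      xs <- merged[[fv]][ok]; ys <- merged[[cv]][ok]
      if (length(unique(xs)) < 2 || length(unique(ys)) < 2) {
        abort(sprintf("clinical_correlation(): constant variable (%s/%s).",
                      fv, cv))
      }
      xt <- inverse_normal_transform(xs)
      yt <- inverse_normal_transform(ys)
      ct <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
      tibble(feature = fv, variable = cv, n = sum(ok),
             rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
}

#' ROC curve and AUC by the rank formulation
#'
#' AUC computed as the Mann-Whitney U statistic divided by `n1 x n0`, ties
#' counted 0.5; curve points (FPR, TPR) at every threshold for plotting.
#'
#' @param score Numeric predictor (higher = more likely positive).
#' @param label Binary outcome (logical or 0/1), e.g. fast eGFR decliner.
#' @return A list of class `uev_roc`: `auc`, `curve` (tibble with
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  ok <- is.finite(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) abort("roc_auc(): both classes must be present.")
  r <- rank(score, ties.method = "average")
  u <- sum(r[label]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  curve <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(score[label] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(score[!label] >= t), numeric(1))
  )
  structure(list(auc = auc, curve = curve, n_pos = n1, n_neg = n0),
            class = "uev_roc")
}

#' @export
print.uev_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
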