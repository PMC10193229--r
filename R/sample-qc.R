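#' Sample inclusion/exclusion from sequencing QC metrics
#'
#' A uEV sample is excluded when its intergenic-read fraction (reads mapping
#' within 10 kb up/downstream of coding regions) exceeds the threshold, or
#' when its RNA shows degradation on the bioanalyzer trace (consumed here as
#' a boolean flag).  Both reasons are recorded when both apply.  A missing
#' intergenic fraction yields an explicit error record (`included = NA`,
#' reason `missing_intergenic`), never a silent pass.
#'
#' @param metrics Data frame with columns `sample_id`,
#'   `intergenic_fraction` and `degradation_flag` (logical).
#' @param intergenic_threshold Exclusion threshold on the intergenic
#'   fraction; samples strictly above it are excluded. Default 0.05 (5%).
#' @return A tibble with columns `sample_id`, `included` (logical, `NA` when
#'   the decision could not be made) and `reasons` (list-column of character
#'   vectors, empty iff included).
#' @export
qc_filter <- function(metrics, intergenic_threshold = 0.05) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0)
  stopifnot(intergenic_threshold > 0, intergenic_threshold < 1)
  need <- c("sample_id", "intergenic_fraction", "degradation_flag")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols)) {
    abort(paste0("qc_filter(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  reasons <- purrr::map2(
    metrics$intergenic_fraction, metrics$degradation_flag,
    function(ig, deg) {
      r <- character(0)
      if (is.na(ig)) r <- c(r, "missing_intergenic")
      else if (ig > intergenic_threshold) r <- c(r, "intergenic_gt_5pct")
      if (isTRUE(deg)) r <- c(r, "degradation")
      r
    }
  )
  included <- purrr::map_lgl(reasons, function(r) {
    if ("missing_intergenic" %in% r) NA else length(r) == 0
  })
  tibble(sample_id = metrics$sample_id, included = included, reasons = reasons)
}

#' PCA-based expression outlier detection
#'
#' Samples are projected onto the first two principal components of the
#' gene-standardized log2CPM matrix; a sample is flagged when its Euclidean
#' distance from the (PC1, PC2) centroid exceeds `k_sd` times the robust SD
#' of the distances (1.4826 x median absolute distance).  After removing
#' flagged samples the rule is re-applied once on the survivors.
#'
#' @param log_expr Numeric matrix of log2CPM values, genes x samples.
#' @param k_sd Multiplier on the robust SD. Default 3. `Inf` retains all.
#' @param max_outlier_fraction Guard rail: if the rule would remove more than
#'   this fraction of samples, nothing is removed and a warning is emitted.
#'   Default 0.2.
#' @return A list with character vectors `retained` and `outliers`, and the
#'   per-sample distances of the first pass as attribute `"distances"`.
#' @export
pca_outlier_filter <- function(log_expr, k_sd = 3, max_outlier_fraction = 0.2) {
  stopifnot(is.matrix(log_expr))
  n <- ncol(log_expr)
  if (n < 10) abort("pca_outlier_filter(): need at least 10 samples.")
  ids <- colnames(log_expr) %||% as.character(seq_len(n))
  colnames(log_expr) <- ids

  pass <- function(m) {
    keep_genes <- apply(m, 1, sd) > 0
    z <- t(scale(t(m[keep_genes, , drop = FALSE])))
    pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
    sc <- pc$x[, 1:2, drop = FALSE]
    d <- sqrt(rowSums(sweep(sc, 2, colMeans(sc))^2))
    list(d = d, flag = d > k_sd * 1.4826 * median(d))
  }

  p1 <- pass(log_expr)
  out <- ids[p1$flag]
  if (length(out) > max_outlier_fraction * n) {
    warn(sprintf(
      "pca_outlier_filter(): rule would remove %d of %d samples (> %.0f%%); not removing any.",
      length(out), n, 100 * max_outlier_fraction))
    out <- character(0)
  } else if (length(out) > 0 && n - length(out) >= 10) {
    p2 <- pass(log_expr[, setdiff(ids, out), drop = FALSE])
    extra <- setdiff(ids, out)[p2$flag]
    if (length(c(out, extra)) <= max_outlier_fraction * n) {
      out <- c(out, extra)
    }
  }
  res <- list(retained = setdiff(ids, out), outliers = out)
  attr(res, "distances") <- p1$d
  res
}

#' Mapped-read comparison between two sample groups
#'
#' Median fold difference in mapped read counts between two groups (e.g.
#' whole urine vs isolated uEV) with a two-sided Mann-Whitney test.
#'
#' @param reads_a,reads_b Numeric vectors of mapped read counts, >= 3 each.
#' @return A tibble with `median_fold` (median(a)/median(b)), `statistic`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
mapped_read_group_test <- function(reads_a, reads_b) {
  if (length(reads_a) < 3 || length(reads_b) < 3) {
    abort("mapped_read_group_test(): need >= 3 samples per group.")
  }
  if (all(reads_a == 0) || all(reads_b == 0)) {
    abort("mapped_read_group_test(): a group is constant zero; fold undefined.")
  }
  wt <- suppressWarnings(wilcox.test(reads_a, reads_b, exact = FALSE))
  tibble(
    median_fold = median(reads_a) / median(reads_b),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(reads_a),
    n_b = length(reads_b)
  )
}
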