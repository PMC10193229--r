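#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_line
#'   geom_hline geom_vline geom_abline geom_jitter labs theme_minimal
#'   scale_color_brewer stat_summary
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object A `uev_de` object.
#' @param label_top Number of top genes to label. Default 13.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uev_de
#' @export
autoplot.uev_de <- function(object, label_top = 13, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$p_value))
  thr <- attr(object, "threshold")
  top <- head(d, label_top)
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p_value),
                color = .data$significant)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::geom_text(data = top, aes(label = .data$gene),
                       vjust = -0.6, size = 2.8, show.legend = FALSE) +
    scale_color_brewer(palette = "Set1", direction = -1) +
    labs(x = "log2 fold change", y = "-log10 p",
         title = attr(object, "contrast"),
         subtitle = sprintf("Bonferroni p <= %.3g (%d genes tested)",
                            thr, attr(object, "n_tested"))) +
    theme_minimal()
}

#' Stress score by group
#'
#' @param object A `uev_scores` tibble that carries a `group` column (e.g.
#'   after joining sample metadata).
#' @param group_col Grouping column. Default `"group"`, falling back to
#'   `"quartile"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uev_scores
#' @export
autoplot.uev_scores <- function(object, group_col = NULL, ...) {
  if (is.null(group_col)) {
    group_col <- if ("group" %in% names(object)) "group" else "quartile"
  }
  ggplot(object, aes(x = .data[[group_col]], y = .data$score)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    labs(x = NULL, y = "stress score (sd units)") +
    theme_minimal()
}

#' Group-mean eGFR trajectories with fitted slopes
#'
#' @param object A `uev_slopes` object from [group_slope()].
#' @param ... Unused.
#' @return A ggplot of per-year group means with OLS trend lines, annotated
#'   slope +/- SE per group.
#' @method autoplot uev_slopes
#' @export
autoplot.uev_slopes <- function(object, ...) {
  am <- attr(object, "annual_means")
  lab <- sprintf("%s: %.2f ± %.2f", object$group, object$slope,
                 object$se)
  ggplot(am, aes(x = .data$year, y = .data$egfr_mean,
                 color = .data$group)) +
    geom_point(size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    scale_color_brewer(palette = "Dark2", labels = lab) +
    labs(x = "calendar year", y = "mean eGFR (mL/min/1.73m²)",
         color = "slope ± SE") +
    theme_minimal()
}

#' ROC curve
#'
#' @param object A `uev_roc` object from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot uev_roc
#' @export
autoplot.uev_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.2f", object$auc)) +
    theme_minimal()
}

#' Tissue co-embedding plot
#'
#' @param object A `uev_embed` object from [tissue_pca_embed()].
#' @param ... Unused.
#' @return A ggplot of PC1/PC2 with reference tissues colored and uEV
#'   samples in black.
#' @method autoplot uev_embed
#' @export
autoplot.uev_embed <- function(object, ...) {
  sc <- object$scores
  ggplot() +
    geom_point(data = dplyr::filter(sc, .data$source == "reference"),
               aes(x = .data$PC1, y = .data$PC2, color = .data$tissue),
               alpha = 0.7) +
    geom_point(data = dplyr::filter(sc, .data$source == "uev"),
               aes(x = .data$PC1, y = .data$PC2), shape = 17, size = 2) +
    labs(color = "tissue",
         title = sprintf("uEV / tissue PCA (%d genes)", object$n_genes)) +
    theme_minimal()
}
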