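#' Gene-set detection statistic
#'
#' Fraction of a curated gene set (e.g. kidney-enriched, specific
#' kidney-enriched or kidney-depleted genes) present among the genes
#' detected in uEV: `percent = 100 x |detected n set| / |set|`, reported to
#' one decimal.  For tissue-of-origin statistics detection is typically the
#' strict "count >= 1 in all samples" rule (see [detected_genes()]), which
#' differs from the >90%-of-samples robust-transcriptome rule.
#'
#' @param detected Character vector of detected gene identifiers.
#' @param gene_set Character vector, the gene set (non-empty).
#' @return A tibble with `n_detected`, `n_set`, `percent` (one decimal).
#' @export
gene_set_detection <- function(detected, gene_set) {
  if (!length(gene_set)) abort("gene_set_detection(): empty gene set.")
  if (!length(detected)) abort("gene_set_detection(): empty detected list.")
  gene_set <- unique(gene_set)
  n_hit <- length(intersect(detected, gene_set))
  tibble(
    n_detected = n_hit,
    n_set = length(gene_set),
    percent = round(100 * n_hit / length(gene_set), 1)
  )
}

#' Genes detected in all samples
#'
#' Strict detection rule used for the tissue-similarity statistics: a gene
#' is detected when it has at least `min_count` reads in every sample.
#'
#' @param counts Count matrix, genes x samples.
#' @param min_count Minimum count per sample. Default 1.
#' @return Character vector of gene identifiers.
#' @export
detected_genes <- function(counts, min_count = 1) {
  counts <- validate_counts(counts)
  rownames(counts)[rowSums(counts >= min_count) == ncol(counts)]
}

#' PCA co-embedding of uEV samples with a tissue reference
#'
#' Concatenates uEV log2CPM profiles with a (GTEx-like) multi-tissue
#' reference on their common genes (optionally restricted to a gene subset,
#' e.g. kidney-depleted or specific kidney-enriched), standardizes each gene
#' across the combined samples, and runs PCA.  Each uEV sample is assigned
#' the tissue whose centroid in (PC1, PC2) is nearest.
#'
#' @param uev_log2cpm uEV expression matrix, genes x samples (log2CPM).
#' @param reference A `uev_tissue_ref` (from [generate_tissue_reference()])
#'   or a list with `expr` (log2 matrix) and `tissue` labels.
#' @param gene_subset Optional character vector restricting the embedding.
#' @param n_pcs Number of PCs used for the nearest-tissue rule. Default 2.
#' @param min_common_genes Minimum common genes required. Default 50.
#' @return A list of class `uev_embed`: `scores` (tibble: sample, source,
#'   tissue, PC1, PC2, ...), `nearest` (tibble: sample, nearest_tissue,
#'   distance), `sdev`, `n_genes`.
#' @export
tissue_pca_embed <- function(uev_log2cpm, reference, gene_subset = NULL,
                             n_pcs = 2, min_common_genes = 50) {
  stopifnot(is.matrix(uev_log2cpm))
  ref_expr <- reference$expr
  tissue <- reference$tissue
  if (length(unique(tissue)) < 2) {
    abort("tissue_pca_embed(): reference must contain >= 2 tissues.")
  }
  common <- intersect(rownames(uev_log2cpm), rownames(ref_expr))
  if (!is.null(gene_subset)) common <- intersect(common, gene_subset)
  if (length(common) < min_common_genes) {
    abort(sprintf("tissue_pca_embed(): only %d common genes (< %d).",
                  length(common), min_common_genes))
  }
  comb <- cbind(uev_log2cpm[common, , drop = FALSE],
                ref_expr[common, , drop = FALSE])
  keep <- apply(comb, 1, sd) > 0
  z <- t(scale(t(comb[keep, , drop = FALSE])))
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
  n_uev <- ncol(uev_log2cpm)
  source <- rep(c("uev", "reference"), c(n_uev, ncol(ref_expr)))
  scores <- as_tibble(sc) |>
    dplyr::mutate(
      sample = colnames(comb),
      source = source,
      tissue = c(rep(NA_character_, n_uev), tissue),
      .before = 1
    )
  centroids <- scores |>
    dplyr::filter(source == "reference") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop")
  cen_mat <- as.matrix(centroids[, -1])
  uev_sc <- sc[seq_len(n_uev), , drop = FALSE]
  nearest <- purrr::map_dfr(seq_len(n_uev), function(i) {
    d <- sqrt(rowSums(sweep(cen_mat, 2, uev_sc[i, ])^2))
    j <- which.min(d)
    tibble(sample = colnames(uev_log2cpm)[i],
           nearest_tissue = centroids$tissue[j],
           distance = d[j])
  })
  structure(list(scores = scores, nearest = nearest,
                 sdev = pc$sdev, n_genes = sum(keep)),
            class = "uev_embed")
}

#' Pairwise co-expression of a gene panel
#'
#' Spearman correlation matrix over a panel of genes (e.g. the 13 DKD
#' candidate genes) across samples; symmetric with unit diagonal.
#'
#' @param expr Expression matrix, genes x samples (>= 5 samples).
#' @param gene_panel Character vector of panel genes present in `expr`.
#' @return Correlation matrix, panel x panel.
#' @export
pairwise_coexpression <- function(expr, gene_panel) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 5) abort("pairwise_coexpression(): need >= 5 samples.")
  missing <- setdiff(gene_panel, rownames(expr))
  if (length(missing)) {
    abort(paste0("pairwise_coexpression(): genes absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  sub <- expr[gene_panel, , drop = FALSE]
  if (any(apply(sub, 1, sd) == 0)) {
    abort("pairwise_coexpression(): constant gene in panel.")
  }
  cor(t(sub), method = "spearman")
}
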