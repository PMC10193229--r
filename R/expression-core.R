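#' Robust gene set: genes detected in most samples
#'
#' The robust uEV transcriptome is defined as the genes with at least
#' `min_count` reads in more than `min_sample_fraction` of samples.  With the
#' defaults (count >= 1 in > 90% of samples) this reproduces the inclusion
#' rule used to call ~10,000 protein-coding genes robustly expressed in uEV.
#'
#' @param counts Integer matrix of raw counts, genes in rows (rownames = gene
#'   identifiers), samples in columns.
#' @param min_count Minimum count for a gene to be called detected in a
#'   sample. Default 1.
#' @param min_sample_fraction Fraction of samples in which the gene must be
#'   detected. Default 0.9.
#' @param strict If `TRUE` (default) the fraction must strictly exceed
#'   `min_sample_fraction` (so 65/72 = 90.3% passes and 64/72 = 88.9% fails);
#'   if `FALSE`, ties pass.
#' @return Character vector of retained gene identifiers, in input order.
#' @export
robust_gene_set <- function(counts, min_count = 1, min_sample_fraction = 0.9,
                            strict = TRUE) {
  counts <- validate_counts(counts)
  frac <- rowMeans(counts >= min_count)
  keep <- if (strict) frac > min_sample_fraction else frac >= min_sample_fraction
  rownames(counts)[keep]
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization for between-sample composition
#' differences.  For each sample, log2 ratios (M) and average log2 abundances
#' (A) against a reference sample are computed on library-size-normalized
#' proportions; genes in the upper/lower `trim_m` tail of M and `trim_a` tail
#' of A are discarded; the factor is 2 to the precision-weighted mean of the
#' surviving M-values.  Factors are rescaled to have geometric mean 1.
#'
#' The reference sample is the one whose 75th count percentile (upper
#' quartile, on proportions) is closest to the mean upper quartile across
#' samples.
#'
#' @param counts Count matrix, genes x samples.
#' @param trim_m Two-sided trim fraction on M-values. Default 0.30.
#' @param trim_a Two-sided trim fraction on A-values. Default 0.05.
#' @param ref_column Optional explicit reference column (index or name);
#'   default `NULL` uses the upper-quartile rule.
#' @return Named numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        ref_column = NULL) {
  counts <- validate_counts(counts)
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    abort("tmm_factors(): every sample must have a positive library size.")
  }
  if (is.null(ref_column)) {
    uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  ref <- counts[, ref_column]
  nref <- lib[ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], lib[j], ref, nref, trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: doubly trimmed, precision-weighted mean
# of M-values (Robinson-Oshlack weights from the delta method on log counts).
tmm_pair_factor <- function(obs, nobs, ref, nref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / nobs) / (r / nref))
  a <- (log2(o / nobs) + log2(r / nref)) / 2
  w <- (nobs - o) / (nobs * o) + (nref - r) / (nref * r)
  if (max(abs(m)) < 1e-6) return(1)
  # Keep genes inside both trimmed ranks (edgeR-style rank trimming).
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra_ <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(sel) || all(w[sel] == 0)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

#' Counts per million and log2-CPM
#'
#' CPM for gene g in sample s is `counts / (library size x factor) x 1e6`;
#' with `log = TRUE` the result is `log2(CPM + prior_count)`.  With prior 0
#' the raw CPM columns each sum to exactly 1e6.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Per-sample TMM scaling factors (default all 1).
#' @param log Return log2-transformed values? Default `TRUE`.
#' @param prior_count Pseudo-count added before the log transform. Default 1.
#' @return Numeric matrix with the dimensions and dimnames of `counts`.
#' @export
log2_cpm <- function(counts, factors = NULL, log = TRUE, prior_count = 1) {
  counts <- validate_counts(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  eff <- colSums(counts) * factors
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  if (log) log2(cpm + prior_count) else cpm
}

#' Rank-based inverse normal transform
#'
#' Maps a vector to standard-normal quantiles through its ranks:
#' `z_i = qnorm((r_i - c) / (n - 2c + 1))` with average ranks for ties and
#' the Blom offset `c = 0.375` by default.  With `standardize = TRUE` the
#' result is additionally centred and scaled to unit sample SD ("Z score"
#' / sd units).
#'
#' @param x Numeric vector with at least 3 finite values, not all equal.
#' @param offset Rank offset c in `[0, 0.5]`. Default 0.375 (Blom).
#' @param standardize Centre and scale the transformed values? Default `TRUE`.
#' @return Numeric vector of z-scores; `NA` positions are preserved.
#' @export
inverse_normal_transform <- function(x, offset = 0.375, standardize = TRUE) {
  stopifnot(offset >= 0, offset <= 0.5)
  ok <- is.finite(x)
  if (sum(ok) < 3) {
    abort("inverse_normal_transform(): need at least 3 finite values.")
  }
  if (length(unique(x[ok])) < 2) {
    abort("inverse_normal_transform(): input is constant; ranks undefined.")
  }
  r <- rank(x[ok], ties.method = "average")
  n <- length(r)
  z <- qnorm((r - offset) / (n - 2 * offset + 1))
  if (standardize) z <- as.numeric(scale(z))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}

#' Coefficient of variation by expression stratum
#'
#' Per-gene CV% (100 x SD / mean) with each gene assigned to a stratum of its
#' mean expression: low = 0-25th percentile, medium = 26th-74th, high =
#' 75th-100th.  Genes with mean 0 have undefined CV and are reported `NA`.
#'
#' @param expr Numeric matrix, genes x samples (any linear-scale expression
#'   measure, e.g. CPM).
#' @return A tibble with columns `gene`, `mean`, `cv_pct`, `stratum`.
#' @export
cv_by_stratum <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  mu <- unname(rowMeans(expr))
  s <- unname(apply(expr, 1, sd))
  cv <- ifelse(mu > 0, 100 * s / mu, NA_real_)
  pr <- 100 * (rank(mu, ties.method = "average") - 1) / (length(mu) - 1)
  stratum <- dplyr::case_when(
    pr <= 25 ~ "low",
    pr < 75 ~ "medium",
    TRUE ~ "high"
  )
  tibble(
    gene = rownames(expr) %||% as.character(seq_along(mu)),
    mean = mu,
    cv_pct = cv,
    stratum = factor(stratum, levels = c("low", "medium", "high"))
  )
}

#' Technical-replicate concordance
#'
#' For labelled replicate groups (duplicates/triplicates of the same urine
#' sample re-processed through the pipeline), computes the pairwise Spearman
#' correlation within each group and, from average-linkage hierarchical
#' clustering of Euclidean distances on the z-scored expression matrix,
#' whether each group is monophyletic (its members form an exact clade).
#'
#' @param expr_z Numeric matrix, genes x samples, typically inverse-normal
#'   z-scores or standardized log2CPM.
#' @param pair_labels Vector along columns; samples sharing a non-`NA` label
#'   form a replicate group.
#' @return A list with `pairs` (tibble: label, sample_a, sample_b,
#'   spearman_r) and `groups` (tibble: label, n_members, monophyletic), plus
#'   the `hclust` object as attribute `"hclust"`.
#' @export
replicate_concordance <- function(expr_z, pair_labels) {
  stopifnot(is.matrix(expr_z), length(pair_labels) == ncol(expr_z))
  labs <- as.character(pair_labels)
  groups <- split(which(!is.na(labs)), labs[!is.na(labs)])
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 1) {
    abort("replicate_concordance(): need at least one group with >= 2 members.")
  }
  sample_ids <- colnames(expr_z) %||% as.character(seq_len(ncol(expr_z)))
  pairs <- purrr::map_dfr(names(groups), function(g) {
    idx <- groups[[g]]
    cmb <- utils::combn(idx, 2)
    tibble(
      label = g,
      sample_a = sample_ids[cmb[1, ]],
      sample_b = sample_ids[cmb[2, ]],
      spearman_r = apply(cmb, 2, function(ij) {
        cor(expr_z[, ij[1]], expr_z[, ij[2]], method = "spearman")
      })
    )
  })
  hc <- hclust(dist(t(expr_z)), method = "average")
  clades <- hclust_clades(hc)
  grp <- tibble(
    label = names(groups),
    n_members = unname(lengths(groups)),
    monophyletic = purrr::map_lgl(groups, function(idx) {
      any(purrr::map_lgl(clades, ~ setequal(.x, idx)))
    })
  )
  out <- list(pairs = pairs, groups = grp)
  attr(out, "hclust") <- hc
  out
}

# All clades (leaf index sets below each merge node) of an hclust tree.
hclust_clades <- function(hc) {
  n <- length(hc$order)
  clades <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- integer(0)
    for (child in hc$merge[i, ]) {
      members <- c(members, if (child < 0) -child else clades[[child]])
    }
    clades[[i]] <- members
  }
  clades
}

validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    abort("empty count matrix.")
  }
  if (any(counts < 0)) abort("counts must be non-negative.")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts))) {
    abort("duplicate gene identifiers in count matrix.")
  }
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    abort("duplicate sample identifiers in count matrix.")
  }
  counts
}
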