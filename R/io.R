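#' Write a synthetic cohort to a directory of plain-text files
#'
#' Serializes a [generate_cohort()] result as TSV tables (`counts.tsv` with
#' genes in rows and a leading `gene` column, `meta.tsv`, `qc.tsv`,
#' `longitudinal.tsv`, `truth_genes.tsv`, `truth_persons.tsv`) plus the gene
#' sets in standard GMT format (`gene_sets.gmt`) and the generating
#' configuration (`config.json`).
#'
#' @param cohort A `uev_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "uev_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(cohort$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(cohort$qc, file.path(dir, "qc.tsv"))
  readr::write_tsv(cohort$longitudinal, file.path(dir, "longitudinal.tsv"))
  readr::write_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(cohort$truth$persons, file.path(dir, "truth_persons.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  cfg <- cohort$config
  cfg$de_genes <- as.data.frame(cfg$de_genes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a gene x sample count matrix as TSV
#'
#' The on-disk format has a header row of sample identifiers and a leading
#' `gene` column.
#'
#' @param path TSV file path.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  validate_counts(m)
}

#' @rdname read_count_matrix
#' @param counts Count matrix to write.
#' @export
write_count_matrix <- function(counts, path) {
  df <- as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene identifiers.
#' No installed package in this stack parses GMT, so the (trivial) format is
#' handled here directly.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
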