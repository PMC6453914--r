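# Plain-text I/O for the pipeline's tabular containers.

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a `gene_id` column, sample columns named `CROSS_SEX_REP`, and
#' optionally a `chromosome_class` column; alternatively supply a separate
#' two-column annotation table (`gene_id`, `chromosome_class`) to join.
#'
#' @param path TSV file path.
#' @param annotation Optional annotation tibble or TSV path.
#' @return A count-matrix tibble.
#' @export
read_count_matrix <- function(path, annotation = NULL) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(counts)) {
    stop("Count table must have a `gene_id` column.", call. = FALSE)
  }
  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      annotation <- readr::read_tsv(annotation, show_col_types = FALSE)
    }
    counts <- dplyr::left_join(counts, annotation, by = "gene_id")
  }
  dplyr::relocate(counts, "gene_id",
                  dplyr::any_of("chromosome_class"))
}

#' Read an allele-specific count table from TSV
#'
#' Columns: `gene_id`, `unit`, `cor_count`, `wl_count`, `n_snps`.
#'
#' @param path TSV file path.
#' @return An ASE tibble.
#' @export
read_ase_counts <- function(path) {
  ase <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("gene_id", "unit", "cor_count", "wl_count", "n_snps")
  missing <- setdiff(needed, names(ase))
  if (length(missing) > 0) {
    stop("ASE table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ase
}

#' Write any pipeline tibble as TSV
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hyb_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

# Published reference tables -------------------------------------------

published_table <- function(file) {
  readr::read_tsv(system.file("extdata", file, package = "hybmode",
                              mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Published inheritance-classification counts
#'
#' Per-tissue, per-group gene counts for the six inheritance modes as
#' reported by a published RNA-seq study of day-old White Leghorn x Cornish
#' chickens and their reciprocal F1 hybrids. Useful as a realistic input to
#' the category-count tests and for worked examples.
#'
#' @return Tibble `tissue`, `group`, `mode`, `n`.
#' @export
published_mode_counts <- function() published_table("published_mode_counts.tsv")

#' Published parental expression-divergence counts
#'
#' Per-tissue totals of detected genes and of significantly up- and
#' down-regulated genes between the two parental breeds (layer relative to
#' broiler, FDR < 0.05) from the same published chicken-cross study.
#'
#' @return Tibble `tissue`, `n_detected`, `n_up`, `n_down`.
#' @export
published_divergence_counts <- function() {
  published_table("published_divergence_counts.tsv")
}

#' Published cross-group consistency counts
#'
#' Per-tissue numbers of genes classified with the same inheritance mode in
#' all four analysis groups, and how many of those were conserved, from the
#' same published chicken-cross study.
#'
#' @return Tibble `tissue`, `n_consistent`, `n_consistent_conserved`.
#' @export
published_consolidation_counts <- function() {
  published_table("published_consolidation_counts.tsv")
}
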