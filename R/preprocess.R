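# Replicate averaging, percent-of-total normalization and gene filters.

#' Parse sample descriptors from count-matrix column names
#'
#' Column names follow `CROSS_SEX_REP` (e.g. `CL_M_2`): cross in
#' `CC`/`CW`/`CL`/`LC`, sex `M`/`F`, replicate index. The breed-sex unit
#' (`CL_M`) is the grouping used throughout classification.
#'
#' @param samples Character vector of sample names.
#' @return Tibble with columns `sample`, `cross`, `sex`, `replicate`, `unit`.
#' @export
sample_info <- function(samples) {
  parts <- stringr::str_match(samples, "^(CC|CW|CL|LC)_(M|F)_(\\d+)$")
  if (anyNA(parts[, 1])) {
    stop("Malformed sample names (expect CROSS_SEX_REP): ",
         paste(samples[is.na(parts[, 1])], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    sample = samples,
    cross = parts[, 2],
    sex = parts[, 3],
    replicate = as.integer(parts[, 4]),
    unit = paste(parts[, 2], parts[, 3], sep = "_")
  )
}

count_sample_names <- function(counts) {
  setdiff(names(counts), c("gene_id", "chromosome_class"))
}

#' Remove Z-linked and never-expressed genes
#'
#' Drops (a) genes annotated to the Z chromosome — chicken dosage
#' compensation is incomplete, so Z genes carry a sex effect that would
#' confound sex-stratified parent-hybrid comparisons — and (b) genes with
#' zero counts in every sample of the table (genes not expressed under any
#' condition). Row order is preserved.
#'
#' @param counts Count-matrix tibble with a `chromosome_class` column
#'   (`"autosome"` or `"Z"`).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts) {
  if (!"chromosome_class" %in% names(counts)) {
    stop("`counts` must carry a `chromosome_class` annotation column.", call. = FALSE)
  }
  mat <- as.matrix(counts[, count_sample_names(counts), drop = FALSE])
  keep <- counts$chromosome_class != "Z" & rowSums(mat) > 0
  counts[keep, , drop = FALSE]
}

#' Average replicate counts within each breed-sex unit
#'
#' Arithmetic mean of the mapped reads over the replicates of each
#' (cross, sex) unit; means may be non-integer.
#'
#' @param counts Count-matrix tibble.
#' @return Tibble `gene_id`, `chromosome_class` (if present), then one mean
#'   column per unit (e.g. `CC_M`).
#' @export
average_replicates <- function(counts) {
  samples <- count_sample_names(counts)
  if (length(samples) == 0) stop("No sample columns found.", call. = FALSE)
  info <- sample_info(samples)
  out <- counts[, intersect(c("gene_id", "chromosome_class"), names(counts)),
                drop = FALSE]
  for (u in unique(info$unit)) {
    cols <- info$sample[info$unit == u]
    out[[u]] <- rowMeans(as.matrix(counts[, cols, drop = FALSE]))
  }
  out
}

#' Normalize unit means to percentage expression
#'
#' Divides each gene's mean mapped reads by the unit's total mapped reads
#' over all retained genes and multiplies by 100, so every unit column sums
#' to 100. This total-count scaling removes expression differences due
#' solely to sequencing depth; apply it after [filter_genes()] so the
#' denominator is consistent across units.
#'
#' @param group_means Output of [average_replicates()].
#' @return An expression profile: `gene_id` plus one percentage column per
#'   unit.
#' @export
normalize_percent <- function(group_means) {
  units <- count_sample_names(group_means)
  out <- group_means[, intersect(c("gene_id", "chromosome_class"),
                                 names(group_means)), drop = FALSE]
  for (u in units) {
    total <- sum(group_means[[u]])
    if (total <= 0) {
      stop("Unit ", u, " has zero total expression; cannot normalize.", call. = FALSE)
    }
    out[[u]] <- 100 * group_means[[u]] / total
  }
  out
}

#' Filter, average and normalize in the standard order
#'
#' Convenience wrapper running [filter_genes()], [average_replicates()] and
#' [normalize_percent()] in sequence.
#'
#' @param counts Count-matrix tibble.
#' @return Expression-profile tibble (columns sum to 100 per unit).
#' @export
preprocess_counts <- function(counts) {
  counts |> filter_genes() |> average_replicates() |> normalize_percent()
}
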