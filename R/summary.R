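# Cross-group consolidation, Venn partitions, category-count tests and
# divergence summaries.

#' Consolidate inheritance calls across the four analysis groups
#'
#' Per gene, records the mode in each group, flags genes classified
#' identically in all four groups, and assigns a consolidated mode by the
#' majority rule: a gene showing the same mode in two or more groups is
#' considered to show that mode. A 2-2 split between two modes is
#' `ambiguous`; a gene with no mode reaching two groups is `none`.
#' `unclassified_zero` calls are treated as missing in the group they occur.
#'
#' @param calls Call tibble from [classify_all()] (one tissue).
#' @return Tibble: `gene_id`, one mode column per group, `consistent_all_four`,
#'   `assigned_mode`.
#' @export
consolidate <- function(calls) {
  if (anyDuplicated(calls[, c("gene_id", "group")]) > 0) {
    stop("Duplicate (gene, group) calls in input.", call. = FALSE)
  }
  wide <- calls |>
    dplyr::mutate(mode = dplyr::na_if(.data$mode, "unclassified_zero")) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "group",
                       values_from = "mode")
  groups <- setdiff(names(wide), "gene_id")
  mode_mat <- as.matrix(wide[, groups, drop = FALSE])
  consistent <- apply(mode_mat, 1, function(m) {
    sum(!is.na(m)) == 4 && length(unique(m)) == 1
  })
  assigned <- apply(mode_mat, 1, function(m) {
    tab <- table(m[!is.na(m)])
    tab <- tab[tab >= 2]
    if (length(tab) == 0) return("none")
    if (length(tab) > 1) return("ambiguous")
    names(tab)
  })
  wide$consistent_all_four <- unname(consistent)
  wide$assigned_mode <- unname(assigned)
  wide
}

#' Count the intersection regions of up to four gene sets
#'
#' Enumerates every non-empty combination of set memberships (15 regions
#' for four sets) and counts the genes falling exclusively in each region,
#' as displayed in a four-way Venn diagram. Region counts sum to the size
#' of the union.
#'
#' @param gene_sets Named list of character vectors (e.g. the genes of one
#'   mode in each of MC, FC, MR, FR).
#' @return Tibble: one logical membership column per set, `region` (ampersand
#'   label), `n`.
#' @export
venn_partition <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 2, !is.null(names(gene_sets)))
  universe <- unique(unlist(gene_sets))
  membership <- vapply(gene_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(gene_sets)))
  combos <- tidyr::expand_grid(!!!setNames(
    rep(list(c(TRUE, FALSE)), length(gene_sets)), names(gene_sets)
  )) |>
    dplyr::filter(dplyr::if_any(dplyr::everything()))
  combos$n <- apply(combos, 1, function(combo) {
    sum(apply(membership, 1, function(row) all(row == combo)))
  })
  combos$region <- apply(combos[, names(gene_sets)], 1, function(combo) {
    paste(names(gene_sets)[as.logical(combo)], collapse = "&")
  })
  dplyr::relocate(combos, "region")
}

#' Nonparametric tests on per-group category counts
#'
#' Runs the two tests used to compare classification tallies, taking each
#' group's count as one observation (four observations per tissue):
#' a Kruskal-Wallis test of mis-expressed (over- plus under-dominant) gene
#' counts across tissues, and per-tissue Mann-Whitney (Wilcoxon rank-sum)
#' tests of Cor-dominant versus WL-dominant counts. Exact p-values are used
#' where there are no ties.
#'
#' @param count_table Tibble `tissue`, `group`, `mode`, `n` (e.g. from
#'   [count_modes()] bound over tissues).
#' @return Tibble: `test`, `tissue`, `statistic`, `p_value`.
#' @export
test_category_counts <- function(count_table) {
  mis <- count_table |>
    dplyr::filter(.data$mode %in% c("over_dominant", "under_dominant")) |>
    dplyr::group_by(.data$tissue, .data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  if (any(table(mis$tissue) < 2) || dplyr::n_distinct(mis$tissue) < 2) {
    stop("Need >= 2 tissues with >= 2 group observations each.", call. = FALSE)
  }
  kw <- kruskal.test(mis$n, factor(mis$tissue))
  out <- tibble::tibble(test = "kruskal_wallis_misexpressed",
                        tissue = NA_character_,
                        statistic = unname(kw$statistic),
                        p_value = kw$p.value)
  dom <- count_table |>
    dplyr::filter(.data$mode %in% c("cor_dominant", "wl_dominant"))
  for (tis in unique(dom$tissue)) {
    d <- dom[dom$tissue == tis, ]
    cor_n <- d$n[d$mode == "cor_dominant"]
    wl_n <- d$n[d$mode == "wl_dominant"]
    if (length(cor_n) < 2 || length(wl_n) < 2) {
      stop("Tissue ", tis, " has fewer than 2 observations per dominant class.",
           call. = FALSE)
    }
    mw <- suppressWarnings(wilcox.test(cor_n, wl_n))
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = "mann_whitney_dominant_direction", tissue = tis,
      statistic = unname(mw$statistic), p_value = mw$p.value))
  }
  out
}

#' Summarize expression divergence between the parental breeds
#'
#' Converts per-tissue counts of detected and differentially expressed
#' genes into the fractions reported for parental divergence: up- and
#' down-regulated percentages (two decimals) and their total (one decimal).
#'
#' @param divergence_counts Tibble `tissue`, `n_detected`, `n_up`, `n_down`.
#' @return The input with `frac_up`, `frac_down`, `frac_total_divergent`
#'   percentage columns appended.
#' @export
summarize_divergence <- function(divergence_counts) {
  d <- divergence_counts
  if (any(d$n_up + d$n_down > d$n_detected)) {
    stop("n_up + n_down exceeds n_detected.", call. = FALSE)
  }
  d |>
    dplyr::mutate(
      frac_up = round(100 * .data$n_up / .data$n_detected, 2),
      frac_down = round(100 * .data$n_down / .data$n_detected, 2),
      frac_total_divergent =
        round(100 * (.data$n_up + .data$n_down) / .data$n_detected, 1)
    )
}
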