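# Allele-specific expression analysis of dominant genes.

#' Filter genes with insufficient allele-specific coverage
#'
#' Drops genes whose depth-standardized informative total
#' (`cor_count + wl_count`, rescaled so every hybrid unit has the same
#' total — the same total-count scaling used for expression normalization)
#' falls below `min_normalized_reads`. The boundary value is kept.
#'
#' @param ase ASE tibble (`gene_id`, `unit`, `cor_count`, `wl_count`,
#'   `n_snps`).
#' @param min_normalized_reads Minimum standardized informative reads
#'   (default 10).
#' @param target_depth Total to which each unit is rescaled; defaults to
#'   the mean per-unit total, so an average-depth unit is unchanged.
#' @return The filtered ASE tibble with a `normalized_total` column added.
#' @export
filter_ase <- function(ase, min_normalized_reads = 10, target_depth = NULL) {
  if (nrow(ase) == 0) {
    return(dplyr::mutate(ase, normalized_total = numeric(0)))
  }
  totals <- ase |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(unit_total = sum(.data$cor_count + .data$wl_count))
  if (is.null(target_depth)) target_depth <- mean(totals$unit_total)
  ase |>
    dplyr::left_join(totals, by = "unit") |>
    dplyr::mutate(normalized_total = (.data$cor_count + .data$wl_count) *
                    target_depth / .data$unit_total) |>
    dplyr::filter(.data$normalized_total >= min_normalized_reads) |>
    dplyr::select(-"unit_total")
}

#' Split dominant genes by parental expression direction
#'
#' Dominant genes are analysed separately for the two parental patterns —
#' Cornish above White Leghorn (`cor_gt_wl`) and below (`cor_lt_wl`) — so
#' that opposite-signed allelic effects cannot cancel. Genes with exactly
#' equal parental values carry no direction and are dropped with a warning.
#'
#' @param dominant_calls Call tibble restricted to `cor_dominant` /
#'   `wl_dominant` modes.
#' @return Named list of two `gene_id` vectors: `cor_gt_wl`, `cor_lt_wl`.
#' @export
split_by_parental_direction <- function(dominant_calls) {
  bad <- setdiff(unique(dominant_calls$mode), c("cor_dominant", "wl_dominant"))
  if (length(bad) > 0) {
    stop("Non-dominant modes in input: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ties <- dominant_calls$p_cor == dominant_calls$p_wl
  if (any(ties)) {
    warning(sum(ties), " gene(s) with equal parental expression excluded ",
            "from the direction split.", call. = FALSE)
  }
  list(
    cor_gt_wl = dominant_calls$gene_id[dominant_calls$p_cor > dominant_calls$p_wl],
    cor_lt_wl = dominant_calls$gene_id[dominant_calls$p_cor < dominant_calls$p_wl]
  )
}

#' Regress White Leghorn on Cornish expression for parents and hybrid alleles
#'
#' For a subset of dominant genes, fits ordinary least squares of
#' `log2(WL value)` on `log2(Cor value)` twice: on the parents' normalized
#' expression and on the hybrid's allele-specific counts. A slope near 1
#' and intercept near 0 in the allele stratum means the two alleles are
#' expressed at similar levels inside the hybrid (trans-like regulation);
#' allele ratios tracking parental ratios indicate cis effects, quantified
#' by the Pearson correlation between `log2(Cor/WL)` parental and allelic
#' ratios. Genes with a zero on either side of a log are excluded and
#' counted.
#'
#' @param parent_profile Expression profile holding the parental units.
#' @param ase ASE tibble (typically after [filter_ase()]).
#' @param subset Character vector of gene ids (e.g. one side of
#'   [split_by_parental_direction()]).
#' @param cor_unit,wl_unit Parental profile columns.
#' @param hybrid_unit ASE unit to analyse.
#' @param subset_label Label stored with the fits (e.g. `"Cor>WL"`).
#' @return An object of class `ase_fit`; see [tidy.ase_fit()] and
#'   [glance.ase_fit()].
#' @export
ase_regression <- function(parent_profile, ase, subset,
                           cor_unit = "CC_M", wl_unit = "CW_M",
                           hybrid_unit = "CL_M", subset_label = NA_character_) {
  par <- parent_profile |>
    dplyr::filter(.data$gene_id %in% subset) |>
    dplyr::transmute(gene_id = .data$gene_id,
                     x = .data[[cor_unit]], y = .data[[wl_unit]])
  al <- ase |>
    dplyr::filter(.data$unit == hybrid_unit, .data$gene_id %in% subset) |>
    dplyr::transmute(gene_id = .data$gene_id,
                     x = as.numeric(.data$cor_count),
                     y = as.numeric(.data$wl_count))

  points <- list()
  fit_stratum <- function(d, stratum) {
    usable <- d$x > 0 & d$y > 0
    n_dropped <- sum(!usable)
    d <- d[usable, , drop = FALSE]
    if (nrow(d) < 3) {
      stop("Fewer than 3 usable genes in the ", stratum, " stratum.",
           call. = FALSE)
    }
    lx <- log2(d$x)
    ly <- log2(d$y)
    points[[stratum]] <<- tibble::tibble(stratum = stratum,
                                         gene_id = d$gene_id,
                                         log2_cor = lx, log2_wl = ly)
    fit <- lm(ly ~ lx)
    ct <- suppressWarnings(cor.test(lx, ly))
    tibble::tibble(
      stratum = stratum, subset = subset_label,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      pearson_r = unname(ct$estimate), p_value = ct$p.value,
      n = nrow(d), n_dropped_zero = n_dropped
    )
  }
  fits <- dplyr::bind_rows(fit_stratum(par, "parents"),
                           fit_stratum(al, "hybrid_alleles"))

  # cis signal: parental log-ratio vs allelic log-ratio, paired by gene
  both <- dplyr::inner_join(par, al, by = "gene_id",
                            suffix = c("_par", "_al")) |>
    dplyr::filter(.data$x_par > 0, .data$y_par > 0,
                  .data$x_al > 0, .data$y_al > 0)
  ratio_test <- NULL
  if (nrow(both) >= 3) {
    rt <- suppressWarnings(cor.test(log2(both$x_par / both$y_par),
                                    log2(both$x_al / both$y_al)))
    ratio_test <- list(pearson_r = unname(rt$estimate),
                       p_value = rt$p.value, n = nrow(both))
  }
  structure(list(fits = fits, ratio_test = ratio_test,
                 points = dplyr::bind_rows(points),
                 subset = subset_label, hybrid_unit = hybrid_unit,
                 log_base = 2),
            class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, ...) {
  cat("ASE log-ratio regression (", x$subset, ", ", x$hybrid_unit, ")\n", sep = "")
  print(x$fits)
  if (!is.null(x$ratio_test)) {
    cat(sprintf("Parental vs allelic log2 ratio: r = %.4f, p = %.3g (n = %d)\n",
                x$ratio_test$pearson_r, x$ratio_test$p_value, x$ratio_test$n))
  }
  invisible(x)
}

#' Tidy an ASE regression fit
#'
#' One row per stratum (parents, hybrid alleles) with slope, intercept,
#' Pearson r, p-value and sample sizes.
#'
#' @param x An `ase_fit` from [ase_regression()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ase_fit <- function(x, ...) x$fits

#' One-line summary of an ASE regression fit
#'
#' Reports the cis-signal statistics: Pearson correlation between parental
#' and allelic log2 ratios, its p-value and the number of paired genes.
#'
#' @param x An `ase_fit` from [ase_regression()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ase_fit <- function(x, ...) {
  if (is.null(x$ratio_test)) {
    return(tibble::tibble(subset = x$subset, ratio_pearson_r = NA_real_,
                          ratio_p_value = NA_real_, n_paired = 0L))
  }
  tibble::tibble(subset = x$subset,
                 ratio_pearson_r = x$ratio_test$pearson_r,
                 ratio_p_value = x$ratio_test$p_value,
                 n_paired = x$ratio_test$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
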