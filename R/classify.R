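# Six-way inheritance-mode classification under the 1.25-fold rule.

#' Symmetric fold ratio between two non-negative expression values
#'
#' `max(a, b) / min(a, b)`, with the zero conventions the classifier needs:
#' two zeros are identical (ratio 1); exactly one zero is infinitely
#' different (`Inf`). Equivalent to thresholding `|log(a/b)|` without
#' taking logs of zero.
#'
#' @param a,b Non-negative numeric vectors (recycled).
#' @return Numeric vector of ratios `>= 1` (possibly `Inf`).
#' @export
#' @examples
#' fold_ratio(2, 1)     # 2
#' fold_ratio(0, 0)     # 1
#' fold_ratio(0, 0.5)   # Inf
fold_ratio <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("Expression values must be non-negative.", call. = FALSE)
  }
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  as.numeric(out)
}

#' Classify one gene's inheritance mode from parental and hybrid expression
#'
#' Applies the fold-change decision rule to the normalized expression of the
#' Cornish parent (`p_cor`), White Leghorn parent (`p_wl`) and hybrid (`h`).
#' Two values are *similar* when their symmetric fold ratio is strictly
#' below `threshold` (the boundary itself counts as different). Then:
#'
#' * all three zero: `unclassified_zero` (excluded from statistics);
#' * hybrid similar to both parents: `conserved`;
#' * hybrid similar to exactly one parent: `cor_dominant` / `wl_dominant`;
#' * hybrid different from both and strictly between them: `additive`;
#' * hybrid above both: `over_dominant`; below both: `under_dominant`.
#'
#' All arguments are vectorized.
#'
#' @param p_cor,p_wl,h Non-negative normalized expression values.
#' @param threshold Fold-change similarity cutoff (default 1.25).
#' @return Character vector of mode labels.
#' @export
#' @examples
#' classify_gene(2.0, 1.0, 1.5)   # additive
#' classify_gene(2.0, 1.0, 2.1)   # cor_dominant
#' classify_gene(2.0, 1.0, 3.0)   # over_dominant
classify_gene <- function(p_cor, p_wl, h, threshold = 1.25) {
  if (threshold <= 1) stop("`threshold` must exceed 1.", call. = FALSE)
  sim_c <- fold_ratio(h, p_cor) < threshold
  sim_w <- fold_ratio(h, p_wl) < threshold
  dplyr::case_when(
    p_cor == 0 & p_wl == 0 & h == 0 ~ "unclassified_zero",
    sim_c & sim_w ~ "conserved",
    sim_c ~ "cor_dominant",
    sim_w ~ "wl_dominant",
    h > pmin(p_cor, p_wl) & h < pmax(p_cor, p_wl) ~ "additive",
    h > pmax(p_cor, p_wl) ~ "over_dominant",
    TRUE ~ "under_dominant"
  )
}

#' The four parent-hybrid analysis groups
#'
#' Each group binds a White Leghorn parental unit, a Cornish parental unit
#' and one sex of one hybrid cross: Male Cross `MC` (WL M, Cor M, CL M),
#' Female Cross `FC` (WL F, Cor F, CL F), and the reciprocal-cross groups
#' `MR` and `FR` using `LC` hybrids.
#'
#' @return Tibble with columns `group`, `sex`, `cor_unit`, `wl_unit`,
#'   `hybrid_unit`.
#' @export
group_designs <- function() {
  tibble::tibble(
    group = c("MC", "FC", "MR", "FR"),
    sex = c("M", "F", "M", "F"),
    cor_unit = c("CC_M", "CC_F", "CC_M", "CC_F"),
    wl_unit = c("CW_M", "CW_F", "CW_M", "CW_F"),
    hybrid_unit = c("CL_M", "CL_F", "LC_M", "LC_F")
  )
}

#' Classify every gene in every analysis group
#'
#' Runs [classify_gene()] over an expression profile for each group design,
#' recording the three expression values and the hybrid-parent fold ratios
#' that justify each call.
#'
#' @param profile Expression profile from [normalize_percent()].
#' @param designs Tibble as returned by [group_designs()].
#' @param threshold Fold-change similarity cutoff.
#' @return Tibble of calls: `gene_id`, `group`, `mode`, `p_cor`, `p_wl`,
#'   `h`, `fold_h_cor`, `fold_h_wl`.
#' @export
classify_all <- function(profile, designs = group_designs(), threshold = 1.25) {
  needed <- unique(c(designs$cor_unit, designs$wl_unit, designs$hybrid_unit))
  missing <- setdiff(needed, names(profile))
  if (length(missing) > 0) {
    stop("Profile is missing unit columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  purrr::pmap_dfr(designs, function(group, sex, cor_unit, wl_unit, hybrid_unit, ...) {
    p_cor <- profile[[cor_unit]]
    p_wl <- profile[[wl_unit]]
    h <- profile[[hybrid_unit]]
    tibble::tibble(
      gene_id = profile$gene_id,
      group = group,
      mode = classify_gene(p_cor, p_wl, h, threshold),
      p_cor = p_cor, p_wl = p_wl, h = h,
      fold_h_cor = fold_ratio(h, p_cor),
      fold_h_wl = fold_ratio(h, p_wl)
    )
  })
}

#' Tabulate mode counts by group
#'
#' Counts classified genes per (group, mode), excluding the
#' `unclassified_zero` genes, which carry no statistical information.
#'
#' @param calls Call tibble from [classify_all()].
#' @return Tibble `group`, `mode`, `n`, with modes in canonical order.
#' @export
count_modes <- function(calls) {
  calls |>
    dplyr::filter(.data$mode != "unclassified_zero") |>
    dplyr::mutate(mode = factor(.data$mode, levels = inheritance_modes())) |>
    dplyr::count(.data$group, .data$mode, .drop = FALSE) |>
    dplyr::mutate(mode = as.character(.data$mode))
}

#' Significance-based similarity classification (alternative rule)
#'
#' Instead of the fold-change cutoff, declares hybrid and parent similar
#' when a per-gene binomial test of the hybrid's mean reads against the
#' parent's (proportion test against the library-size expectation, BH
#' corrected per group and contrast) yields an FDR above `fdr_similar`.
#' The downstream decision tree is identical to [classify_gene()]. Offered
#' for sensitivity analysis; the fold rule is the default pipeline path.
#'
#' @param group_means Unnormalized unit means from [average_replicates()]
#'   (counts are rounded to integers for testing).
#' @param designs Tibble as returned by [group_designs()].
#' @param fdr_similar FDR above which two expression levels are deemed
#'   similar (default 0.005).
#' @return Call tibble as in [classify_all()] (without fold columns).
#' @export
classify_all_binomial <- function(group_means, designs = group_designs(),
                                  fdr_similar = 0.005) {
  purrr::pmap_dfr(designs, function(group, sex, cor_unit, wl_unit, hybrid_unit, ...) {
    h <- round(group_means[[hybrid_unit]])
    p_cor <- round(group_means[[cor_unit]])
    p_wl <- round(group_means[[wl_unit]])
    sim_c <- binom_similar(h, p_cor, fdr_similar)
    sim_w <- binom_similar(h, p_wl, fdr_similar)
    tibble::tibble(
      gene_id = group_means$gene_id,
      group = group,
      mode = dplyr::case_when(
        p_cor == 0 & p_wl == 0 & h == 0 ~ "unclassified_zero",
        sim_c & sim_w ~ "conserved",
        sim_c ~ "cor_dominant",
        sim_w ~ "wl_dominant",
        h > pmin(p_cor, p_wl) & h < pmax(p_cor, p_wl) ~ "additive",
        h > pmax(p_cor, p_wl) ~ "over_dominant",
        TRUE ~ "under_dominant"
      ),
      p_cor = p_cor, p_wl = p_wl, h = h
    )
  })
}

# Per-gene binomial test: is the hybrid's share of (hybrid + parent) reads
# compatible with the two libraries' relative depths? High FDR => similar.
binom_similar <- function(x, y, fdr_similar) {
  tot_x <- sum(x)
  tot_y <- sum(y)
  p0 <- tot_x / (tot_x + tot_y)
  pv <- vapply(seq_along(x), function(i) {
    n <- x[i] + y[i]
    if (n == 0) return(1)
    binom.test(x[i], n, p = p0)$p.value
  }, numeric(1))
  p.adjust(pv, method = "BH") > fdr_similar
}
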