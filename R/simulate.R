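# Synthetic-data generator: parental/hybrid count matrices, allele-specific
# counts and toy variant data with known per-gene ground truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a day-old chicken cross experiment: ~15,000 genes, two pure-bred parental
#' lines (Cornish `CC`, White Leghorn `CW`) and the two reciprocal F1 hybrids
#' (`CL` = Cor male x WL female, `LC` = WL male x Cor female), three
#' replicates per sex per cross, negative-binomial counts at a library depth
#' of 3.6 million mapped reads, and mostly sub-two-fold parental divergence.
#'
#' @param n_genes Number of simulated genes.
#' @param mode_proportions Named numeric vector over
#'   [inheritance_modes()]; must be non-negative and sum to 1.
#' @param n_replicates Replicates per (cross, sex) group.
#' @param mean_log2_expression,sd_log2_expression Location and spread of the
#'   per-gene baseline log2 relative expression.
#' @param parental_log2_divergence Baseline log2 effect size between the
#'   Cornish and White Leghorn means for non-conserved genes; per-gene
#'   divergences sit above this (or above the mode's geometric floor) with
#'   an exponential log2 spread, so most are below two-fold.
#' @param nb_dispersion Negative-binomial size parameter shared by all genes
#'   (larger = closer to Poisson).
#' @param library_size Expected mapped reads per sample.
#' @param frac_z_linked Fraction of genes placed on the Z chromosome.
#' @param frac_all_zero Fraction of genes silent in every sample.
#' @param cis_fraction Fraction of dominant genes whose hybrid allelic ratio
#'   mirrors the parental expression ratio (cis-driven); the rest are
#'   trans-like with balanced alleles.
#' @param snps_per_gene Poisson mean of informative SNPs per gene.
#' @param margin_nonconserved Minimum fold separation enforced between any
#'   two values the classifier must call different (keeps simulated effects
#'   clear of the 1.25-fold decision boundary).
#' @param margin_conserved Maximum fold separation between values the
#'   classifier must call similar.
#' @param seed Integer seed; the single source of randomness, split
#'   internally per sub-generator.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 7)
#' truth <- simulate_truth(cfg)
sim_config <- function(n_genes = 15000,
                       mode_proportions = c(conserved = 0.55, additive = 0.06,
                                            cor_dominant = 0.13, wl_dominant = 0.11,
                                            over_dominant = 0.08, under_dominant = 0.07),
                       n_replicates = 3,
                       mean_log2_expression = 5,
                       sd_log2_expression = 2,
                       parental_log2_divergence = 0.8,
                       nb_dispersion = 100,
                       library_size = 3.6e6,
                       frac_z_linked = 0.04,
                       frac_all_zero = 0.02,
                       cis_fraction = 0.5,
                       snps_per_gene = 2.6,
                       margin_nonconserved = 1.5,
                       margin_conserved = 1.1,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    stop("`n_genes` must be a positive integer.", call. = FALSE)
  }
  if (is.null(names(mode_proportions)) ||
      !all(names(mode_proportions) %in% inheritance_modes())) {
    stop("`mode_proportions` must be named with inheritance_modes().", call. = FALSE)
  }
  if (any(mode_proportions < 0) || abs(sum(mode_proportions) - 1) > 1e-9) {
    stop("`mode_proportions` must be non-negative and sum to 1.", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1.", call. = FALSE)
  for (nm in c("sd_log2_expression", "parental_log2_divergence", "nb_dispersion")) {
    if (get(nm) <= 0) stop(sprintf("`%s` must be strictly positive.", nm), call. = FALSE)
  }
  for (nm in c("frac_z_linked", "frac_all_zero", "cis_fraction")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("`%s` must lie in [0, 1].", nm), call. = FALSE)
  }
  if (margin_nonconserved <= 1.25) {
    stop("`margin_nonconserved` must exceed the 1.25-fold boundary.", call. = FALSE)
  }
  if (margin_conserved < 1 || margin_conserved >= 1.25) {
    stop("`margin_conserved` must lie in [1, 1.25).", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    mode_proportions = mode_proportions[inheritance_modes()],
    n_replicates = as.integer(n_replicates),
    mean_log2_expression = mean_log2_expression,
    sd_log2_expression = sd_log2_expression,
    parental_log2_divergence = parental_log2_divergence,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    frac_z_linked = frac_z_linked,
    frac_all_zero = frac_all_zero,
    cis_fraction = cis_fraction,
    snps_per_gene = snps_per_gene,
    margin_nonconserved = margin_nonconserved,
    margin_conserved = margin_conserved,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# sub-generator seeds derived from the single config seed
sim_seed <- function(config, stage) {
  offset <- c(truth = 0L, counts = 1L, ase = 2L, variants = 3L)[[stage]]
  (config$seed + offset) %% .Machine$integer.max
}

#' Draw per-gene ground truth
#'
#' Assigns each gene an inheritance mode (multinomially, per
#' `mode_proportions`), expected expression for the Cornish parent, White
#' Leghorn parent and hybrid, a chromosome class and a cis-ratio. Expected
#' means respect the mode definitions with a safety margin: contrasts the
#' classifier must call different are at least `margin_nonconserved`-fold,
#' contrasts it must call similar at most `margin_conserved`-fold. A
#' `frac_all_zero` slice of genes is silent everywhere. For additive genes
#' the hybrid mean is the arithmetic mid-parent, which forces the parental
#' ratio to at least `max(2 * m - 1, m / (2 - m))` for margin `m`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `true_mode`,
#'   `mu_cor`, `mu_wl`, `mu_hybrid` (relative expression scale),
#'   `cis_ratio`, `chromosome_class`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "truth"))
  n <- config$n_genes
  m_nc <- config$margin_nonconserved * 1.05  # slack above the enforced margin
  m_c <- config$margin_conserved

  n_zero <- round(config$frac_all_zero * n)
  modes <- rep("all_zero", n)
  live <- if (n_zero > 0) seq_len(n)[-sample.int(n, n_zero)] else seq_len(n)
  modes[live] <- sample(inheritance_modes(), length(live),
                        replace = TRUE, prob = config$mode_proportions)

  base <- 2^rnorm(n, config$mean_log2_expression, config$sd_log2_expression)
  # Parental ratio per gene: exponential spread in log2 above a per-mode
  # floor, so divergences vary across genes but never approach the decision
  # boundary. The floor for additive genes is whatever keeps the arithmetic
  # mid-parent at least the margin away from both parents.
  div <- 2^config$parental_log2_divergence
  spread <- 2^stats::rexp(n, rate = 1 / 0.4)
  ratio <- rep(1, n)
  cons <- modes == "conserved"
  ratio[cons] <- 2^runif(sum(cons), -log2(m_c) / 2, log2(m_c) / 2)
  nc <- modes %in% c("cor_dominant", "wl_dominant")
  ratio[nc] <- pmax(div, m_nc) * spread[nc]
  add <- modes == "additive"
  ratio[add] <- pmax(div, 2 * m_nc - 1, m_nc / (2 - m_nc)) * spread[add]
  od <- modes %in% c("over_dominant", "under_dominant")
  ratio[od] <- div * spread[od]
  # random direction of the parental difference
  hi_is_cor <- sample(c(TRUE, FALSE), n, replace = TRUE)
  mu_hi <- base * sqrt(ratio)
  mu_lo <- base / sqrt(ratio)
  mu_cor <- ifelse(hi_is_cor, mu_hi, mu_lo)
  mu_wl <- ifelse(hi_is_cor, mu_lo, mu_hi)

  mu_hybrid <- dplyr::case_when(
    modes == "conserved" ~ sqrt(mu_cor * mu_wl),
    modes == "additive" ~ (mu_cor + mu_wl) / 2,
    modes == "cor_dominant" ~ mu_cor,
    modes == "wl_dominant" ~ mu_wl,
    modes == "over_dominant" ~ pmax(mu_cor, mu_wl) * m_nc,
    modes == "under_dominant" ~ pmin(mu_cor, mu_wl) / m_nc,
    TRUE ~ 0
  )
  mu_cor[modes == "all_zero"] <- 0
  mu_wl[modes == "all_zero"] <- 0

  dominant <- modes %in% c("cor_dominant", "wl_dominant")
  cis <- dominant & runif(n) < config$cis_fraction
  cis_ratio <- ifelse(cis, mu_cor / mu_wl, 1)
  cis_ratio[modes == "all_zero"] <- 1

  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    true_mode = modes,
    mu_cor = mu_cor,
    mu_wl = mu_wl,
    mu_hybrid = mu_hybrid,
    cis_ratio = cis_ratio,
    chromosome_class = ifelse(runif(n) < config$frac_z_linked, "Z", "autosome")
  )
}

#' Simulate a read-count matrix from ground truth
#'
#' Draws one negative-binomial count per gene and sample. Samples are the
#' full cross design: crosses `CC` (Cornish), `CW` (White Leghorn), `CL` and
#' `LC` (reciprocal hybrids) times sexes `M`/`F` times `n_replicates`
#' replicates, columns named `CROSS_SEX_REP` (e.g. `CL_M_2`). Each sample's
#' expected counts are the cross-appropriate expected expression rescaled so
#' the sample's expected total equals `library_size`.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A count-matrix tibble: `gene_id`, `chromosome_class`, then one
#'   integer column per sample.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  set.seed(sim_seed(config, "counts"))
  mu_by_cross <- list(CC = truth$mu_cor, CW = truth$mu_wl,
                      CL = truth$mu_hybrid, LC = truth$mu_hybrid)
  out <- tibble::tibble(gene_id = truth$gene_id,
                        chromosome_class = truth$chromosome_class)
  for (cross in hyb_crosses()) {
    mu_rel <- mu_by_cross[[cross]]
    mu <- mu_rel / sum(mu_rel) * config$library_size
    for (sex in c("M", "F")) {
      for (rep_i in seq_len(config$n_replicates)) {
        out[[paste(cross, sex, rep_i, sep = "_")]] <-
          rnbinom(nrow(truth), mu = mu, size = config$nb_dispersion)
      }
    }
  }
  out
}

#' Simulate allele-specific counts for hybrid samples
#'
#' For each gene, draws a Poisson number of informative (breed-diagnostic)
#' SNPs; genes with none are absent from the output. For every hybrid unit
#' (cross x sex), the gene's reads across that unit's replicates are taken
#' as the informative total and split between the Cornish and White Leghorn
#' alleles binomially with success probability
#' `cis_ratio / (1 + cis_ratio)` for the Cor allele.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param counts Count matrix from [simulate_counts()] (hybrid columns used).
#' @param config The same [sim_config()].
#' @return Tibble: `gene_id`, `unit` (e.g. `CL_M`), `cor_count`, `wl_count`,
#'   `n_snps`.
#' @export
simulate_ase <- function(truth, counts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "ase"))
  n_snps <- rpois(nrow(truth), config$snps_per_gene)
  keep <- n_snps > 0
  info <- sample_info(count_sample_names(counts))
  hyb_units <- unique(info$unit[info$cross %in% c("CL", "LC")])
  p_cor <- truth$cis_ratio / (1 + truth$cis_ratio)

  purrr::map_dfr(hyb_units, function(u) {
    cols <- info$sample[info$unit == u]
    total <- rowSums(as.matrix(counts[, cols, drop = FALSE]))
    idx <- which(keep)
    cor_count <- rbinom(length(idx), size = total[idx], prob = p_cor[idx])
    tibble::tibble(
      gene_id = truth$gene_id[idx],
      unit = u,
      cor_count = cor_count,
      wl_count = as.integer(total[idx]) - cor_count,
      n_snps = n_snps[idx]
    )
  })
}

#' Simulate a toy reference and breed-diagnostic SNP table
#'
#' Generates random chromosome sequences and a set of biallelic SNVs with
#' per-breed supporting read depths, for exercising the depth filter and
#' pseudo-genome substitution at toy scale. Depths are Poisson with the
#' given means, so a realistic minority of sites falls below the retention
#' thresholds.
#'
#' @param config A [sim_config()] (only the seed is used).
#' @param chrom_lengths Named integer vector of chromosome lengths; names
#'   containing `"Z"` are treated as Z-linked.
#' @param n_snps Number of SNV records to draw.
#' @param mean_depth Poisson mean of the per-breed supporting depth.
#' @return A list with `reference` (a [Biostrings::DNAStringSet]) and
#'   `snps` (a tibble of `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `depth_cor`, `depth_wl`, `chromosome_class`).
#' @export
simulate_variants <- function(config, chrom_lengths = c(chr1 = 1000L, Z = 600L),
                              n_snps = 60L, mean_depth = 15) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "variants"))
  bases <- c("A", "C", "G", "T")
  reference <- Biostrings::DNAStringSet(vapply(
    chrom_lengths,
    function(len) paste(sample(bases, len, replace = TRUE), collapse = ""),
    character(1)
  ))
  names(reference) <- names(chrom_lengths)

  chrom <- sample(names(chrom_lengths), n_snps, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- vapply(chrom, function(ch) sample.int(chrom_lengths[[ch]], 1L), integer(1))
  # one record per site
  key <- paste(chrom, pos)
  dup <- duplicated(key)
  chrom <- chrom[!dup]; pos <- pos[!dup]
  ref_allele <- vapply(seq_along(chrom), function(i) {
    as.character(Biostrings::subseq(reference[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
  alt_allele <- vapply(ref_allele, function(b) sample(setdiff(bases, b), 1L), character(1))
  snps <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref_allele = ref_allele, alt_allele = alt_allele,
    depth_cor = rpois(length(chrom), mean_depth),
    depth_wl = rpois(length(chrom), mean_depth),
    chromosome_class = ifelse(grepl("Z", chrom), "Z", "autosome")
  )
  list(reference = reference, snps = snps)
}
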