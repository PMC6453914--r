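test_that("degenerate mixtures and forced fractions behave as constructed", {
  cfg <- sim_config(n_genes = 10, frac_all_zero = 0,
                    mode_proportions = c(conserved = 1, additive = 0,
                                         cor_dominant = 0, wl_dominant = 0,
                                         over_dominant = 0, under_dominant = 0),
                    seed = 3)
  truth <- simulate_truth(cfg)
  expect_equal(nrow(truth), 10)
  expect_true(all(truth$true_mode == "conserved"))
  expect_true(all(abs(log2(truth$mu_cor / truth$mu_wl)) <= log2(1.1)))

  cfg0 <- sim_config(n_genes = 100, frac_all_zero = 0.1, seed = 4)
  truth0 <- simulate_truth(cfg0)
  zero <- truth0$true_mode == "all_zero"
  expect_equal(sum(zero), 10)
  expect_true(all(truth0$mu_cor[zero] == 0 & truth0$mu_wl[zero] == 0 &
                    truth0$mu_hybrid[zero] == 0))
})

test_that("mode composition is multinomial around the configured proportions", {
  cfg <- sim_config(
    n_genes = 1000, frac_all_zero = 0,
    mode_proportions = c(conserved = 0.5, additive = 0.1, cor_dominant = 0.1,
                         wl_dominant = 0.1, over_dominant = 0.1,
                         under_dominant = 0.1),
    seed = 5)
  truth <- simulate_truth(cfg)
  n_cons <- sum(truth$true_mode == "conserved")
  # central 99% binomial interval for Binomial(1000, 0.5)
  expect_gte(n_cons, qbinom(0.005, 1000, 0.5))
  expect_lte(n_cons, qbinom(0.995, 1000, 0.5))
})

test_that("expected means respect the per-mode margins", {
  truth <- simulate_truth(sim_config(n_genes = 3000, seed = 6))
  live <- truth[truth$true_mode != "all_zero", ]
  hi <- pmax(live$mu_cor, live$mu_wl)
  lo <- pmin(live$mu_cor, live$mu_wl)
  with_mode <- function(m) live[live$true_mode == m, ]
  a <- with_mode("additive")
  expect_true(all(a$mu_hybrid > a$mu_cor | a$mu_hybrid > a$mu_wl))
  expect_true(all(a$mu_hybrid < pmax(a$mu_cor, a$mu_wl)))
  expect_true(all(pmax(a$mu_cor, a$mu_wl) / a$mu_hybrid >= 1.5 - 1e-9))
  expect_true(all(a$mu_hybrid / pmin(a$mu_cor, a$mu_wl) >= 1.5 - 1e-9))
  d <- with_mode("cor_dominant")
  expect_true(all(d$mu_hybrid == d$mu_cor))
  expect_true(all(fold_ratio(d$mu_hybrid, d$mu_wl) >= 1.5 - 1e-9))
  o <- with_mode("over_dominant")
  expect_true(all(o$mu_hybrid >= pmax(o$mu_cor, o$mu_wl) * 1.5 - 1e-9))
  u <- with_mode("under_dominant")
  expect_true(all(u$mu_hybrid <= pmin(u$mu_cor, u$mu_wl) / 1.5 + 1e-9))
  cns <- with_mode("conserved")
  expect_true(all(fold_ratio(cns$mu_hybrid, cns$mu_cor) <= 1.1 + 1e-9))
  expect_true(all(fold_ratio(cns$mu_hybrid, cns$mu_wl) <= 1.1 + 1e-9))
})

test_that("counts are deterministic, zero for silent genes, unbiased near Poisson", {
  cfg <- sim_config(n_genes = 300, nb_dispersion = 1e6, library_size = 1e6,
                    frac_all_zero = 0.05, seed = 7)
  truth <- simulate_truth(cfg)
  counts1 <- simulate_counts(truth, cfg)
  counts2 <- simulate_counts(truth, cfg)
  expect_identical(counts1, counts2)

  zero <- truth$true_mode == "all_zero"
  mat <- as.matrix(counts1[, setdiff(names(counts1),
                                     c("gene_id", "chromosome_class"))])
  expect_true(all(mat[zero, ] == 0))

  # per-gene, per-cross sample means within 3 SE of the scaled expectation
  mu_by_cross <- list(CC = truth$mu_cor, CW = truth$mu_wl,
                      CL = truth$mu_hybrid, LC = truth$mu_hybrid)
  checks <- c()
  for (cross in c("CC", "CW", "CL", "LC")) {
    mu <- mu_by_cross[[cross]] / sum(mu_by_cross[[cross]]) * cfg$library_size
    cols <- grep(paste0("^", cross, "_"), colnames(mat))
    obs <- rowMeans(mat[, cols])
    se <- sqrt(mu + mu^2 / cfg$nb_dispersion) / sqrt(length(cols))
    ok <- abs(obs - mu) <= 3 * se
    checks <- c(checks, ok[mu > 0])
  }
  expect_gte(mean(checks), 0.99)
})

test_that("allele counts conserve totals and track the cis-ratio", {
  cfg <- sim_config(n_genes = 200, snps_per_gene = 5, seed = 8,
                    library_size = 2e5)
  truth <- simulate_truth(cfg)
  counts <- simulate_counts(truth, cfg)
  ase <- simulate_ase(truth, counts, cfg)
  expect_identical(simulate_ase(truth, counts, cfg), ase)

  # conservation: cor + wl equals the informative total from the counts
  info <- sample_info(setdiff(names(counts), c("gene_id", "chromosome_class")))
  for (u in c("CL_M", "LC_F")) {
    cols <- info$sample[info$unit == u]
    totals <- rowSums(as.matrix(counts[, cols]))
    a <- ase[ase$unit == u, ]
    expect_equal(a$cor_count + a$wl_count,
                 unname(totals[match(a$gene_id, counts$gene_id)]))
  }

  # balanced genes split close to one half
  bal <- dplyr::inner_join(ase[ase$unit == "CL_M", ],
                           truth[truth$cis_ratio == 1, "gene_id"], by = "gene_id")
  bal <- bal[bal$cor_count + bal$wl_count > 500, ]
  share <- sum(bal$cor_count) / sum(bal$cor_count + bal$wl_count)
  n_tot <- sum(bal$cor_count + bal$wl_count)
  expect_gte(share, qbinom(0.005, n_tot, 0.5) / n_tot)
  expect_lte(share, qbinom(0.995, n_tot, 0.5) / n_tot)
})

test_that("a gene with cis-ratio 3 and ~4000 informative reads shows a ~0.75 Cor share", {
  cfg <- sim_config(n_genes = 1, n_replicates = 1, snps_per_gene = 10, seed = 9)
  truth <- tibble::tibble(gene_id = "g1", true_mode = "cor_dominant",
                          mu_cor = 3, mu_wl = 1, mu_hybrid = 3,
                          cis_ratio = 3, chromosome_class = "autosome")
  counts <- tibble::tibble(gene_id = "g1", chromosome_class = "autosome",
                           CC_M_1 = 4000L, CW_M_1 = 4000L,
                           CL_M_1 = 4000L, LC_M_1 = 4000L,
                           CC_F_1 = 4000L, CW_F_1 = 4000L,
                           CL_F_1 = 4000L, LC_F_1 = 4000L)
  ase <- simulate_ase(truth, counts, cfg)
  a <- ase[ase$unit == "CL_M", ]
  expect_equal(nrow(a), 1)
  share <- a$cor_count / (a$cor_count + a$wl_count)
  expect_gt(share, 0.72)
  expect_lt(share, 0.78)

  cfg0 <- sim_config(n_genes = 1, n_replicates = 1, snps_per_gene = 0, seed = 9)
  expect_equal(nrow(simulate_ase(truth, counts, cfg0)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mode_proportions = c(conserved = 0.9)), "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "strictly positive")
  expect_error(sim_config(frac_all_zero = 1.5), "0, 1")
  expect_error(sim_config(margin_conserved = 1.3), "1.25")
})
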