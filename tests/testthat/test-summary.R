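make_calls <- function(modes_by_group, gene_id = "g1") {
  tibble::tibble(gene_id = gene_id,
                 group = c("MC", "FC", "MR", "FR"),
                 mode = modes_by_group)
}

test_that("consolidation flags consistency and applies the >=2-group rule", {
  res <- consolidate(make_calls(rep("conserved", 4)))
  expect_true(res$consistent_all_four)
  expect_equal(res$assigned_mode, "conserved")

  res <- consolidate(make_calls(c("cor_dominant", "cor_dominant",
                                  "cor_dominant", "conserved")))
  expect_false(res$consistent_all_four)
  expect_equal(res$assigned_mode, "cor_dominant")

  res <- consolidate(make_calls(c("conserved", "conserved",
                                  "additive", "additive")))
  expect_equal(res$assigned_mode, "ambiguous")

  res <- consolidate(make_calls(c("conserved", "additive",
                                  "over_dominant", "under_dominant")))
  expect_equal(res$assigned_mode, "none")

  # unclassified_zero counts as missing, so three matching groups suffice
  res <- consolidate(make_calls(c("additive", "additive", "additive",
                                  "unclassified_zero")))
  expect_false(res$consistent_all_four)
  expect_equal(res$assigned_mode, "additive")

  expect_error(consolidate(dplyr::bind_rows(make_calls(rep("conserved", 4)),
                                            make_calls(rep("conserved", 4)))),
               "Duplicate")
})

test_that("consolidation counts are ordered: all-four <= assigned <= total", {
  set.seed(51)
  n <- 300
  calls <- tidyr::expand_grid(gene_id = sprintf("g%03d", 1:n),
                              group = c("MC", "FC", "MR", "FR")) |>
    dplyr::mutate(mode = sample(inheritance_modes(), dplyr::n(),
                                replace = TRUE, prob = c(.5, .1, .1, .1, .1, .1)))
  res <- consolidate(calls)
  n_all4 <- sum(res$consistent_all_four)
  n_assigned <- sum(!res$assigned_mode %in% c("ambiguous", "none"))
  expect_lte(n_all4, n_assigned)
  expect_lte(n_assigned, n)
})

test_that("venn regions match brute-force enumeration and sum to the union", {
  sets <- list(MC = letters[1:10], FC = letters[1:10],
               MR = letters[1:10], FR = letters[1:10])
  v <- venn_partition(sets)
  expect_equal(sum(v$n), 10)
  expect_equal(v$n[v$region == "MC&FC&MR&FR"], 10)
  expect_true(all(v$n[v$region != "MC&FC&MR&FR"] == 0))

  disjoint <- list(MC = letters[1:3], FC = letters[4:6],
                   MR = letters[7:9], FR = letters[10:12])
  v2 <- venn_partition(disjoint)
  expect_equal(sum(v2$n), 12)
  expect_true(all(v2$n[v2$region %in% c("MC", "FC", "MR", "FR")] == 3))

  set.seed(52)
  rand <- purrr::map(setNames(1:4, c("MC", "FC", "MR", "FR")),
                     ~sample(sprintf("g%02d", 1:40), 20))
  v3 <- venn_partition(rand)
  want <- oracle_venn(rand)
  expect_equal(sum(v3$n), length(unique(unlist(rand))))
  for (reg in names(want)) {
    expect_equal(v3$n[v3$region == reg], unname(want[[reg]]),
                 info = reg)
  }
  expect_equal(sum(v3$n[!v3$region %in% names(want)]), 0)
})

test_that("category-count tests reproduce known rank statistics", {
  # the three tissues carry identical group-count samples: no tissue effect
  flat <- tidyr::expand_grid(tissue = c("brain", "liver", "muscle"),
                             group = c("MC", "FC", "MR", "FR"),
                             mode = c("over_dominant", "under_dominant",
                                      "cor_dominant", "wl_dominant"))
  flat$n <- c(10L, 5L, 8L, 9L)[match(flat$group, c("MC", "FC", "MR", "FR"))] *
    c(1L, 2L, 1L, 1L)[match(flat$mode, c("over_dominant", "under_dominant",
                                         "cor_dominant", "wl_dominant"))]
  res <- test_category_counts(flat)
  kw <- res[res$test == "kruskal_wallis_misexpressed", ]
  expect_equal(kw$statistic, 0, tolerance = 1e-12)

  # complete separation of four vs four gives the extreme exact p
  sep <- tidyr::expand_grid(tissue = "brain", group = c("MC", "FC", "MR", "FR"),
                            mode = c("cor_dominant", "wl_dominant",
                                     "over_dominant", "under_dominant"))
  sep$n <- dplyr::case_when(
    sep$mode == "cor_dominant" ~ c(1L, 2L, 3L, 4L)[match(sep$group, c("MC", "FC", "MR", "FR"))],
    sep$mode == "wl_dominant" ~ c(5L, 6L, 7L, 8L)[match(sep$group, c("MC", "FC", "MR", "FR"))],
    TRUE ~ 1L
  )
  sep2 <- dplyr::mutate(sep, tissue = "liver")
  res2 <- test_category_counts(dplyr::bind_rows(sep, sep2))
  mw <- res2[res2$test == "mann_whitney_dominant_direction" &
               res2$tissue == "brain", ]
  expect_equal(mw$statistic, 0)            # U = 0: every Cor count below WL
  expect_equal(mw$p_value, 2 / 70, tolerance = 1e-12)

  expect_error(test_category_counts(sep), ">= 2 tissues")
})

test_that("divergence summaries reproduce the printed percentages", {
  d <- summarize_divergence(tibble::tibble(
    tissue = c("liver", "brain", "none"),
    n_detected = c(20943, 24267, 100),
    n_up = c(1502, 104, 0),
    n_down = c(1704, 91, 0)
  ))
  expect_equal(d$frac_up, c(7.17, 0.43, 0))
  expect_equal(d$frac_down, c(8.14, 0.37, 0))
  expect_equal(d$frac_total_divergent, c(15.3, 0.8, 0))
  expect_error(summarize_divergence(tibble::tibble(
    tissue = "x", n_detected = 10, n_up = 8, n_down = 5)), "exceeds")
})
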