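# Clone-size spectra, downsampling comparison, strata, enrichment.

test_that("clone_size_spectrum recomputes sizes within the subset", {
  cells <- cells_from_sizes(c(2, 1, 1))
  spec <- clone_size_spectrum(cells)
  expect_equal(spec$clone_size, c(1L, 2L))
  expect_equal(spec$n_clonotypes, c(2L, 1L))

  # a pooled clonotype of size 5 with 2 cells in the restricted sample
  pooled <- dplyr::bind_rows(
    cells_from_sizes(3, sample_id = "A", prefix = "P"),
    cells_from_sizes(2, sample_id = "B", prefix = "P"))
  restricted <- clone_size_spectrum(pooled[pooled$sample_id == "B", ])
  expect_equal(restricted$clone_size, 2L)

  # conservation on random subsets
  set.seed(3)
  pool <- sim_cell_pool(400, seed = 9)
  sub <- pool[sample.int(400, 150), ]
  s <- clone_size_spectrum(sub)
  expect_equal(sum(s$clone_size * s$n_clonotypes), 150)
})

test_that("downsampling comparison is 1 on identical groups, deterministic, and symmetric", {
  a <- sim_cell_pool(250, geom_p = 0.7, big_cell_frac = 0.1, seed = 21)
  b <- sim_cell_pool(300, geom_p = 0.7, seed = 22, key_offset = 90000L)

  same <- downsample_compare(a, a, n_iter = 10, seed = 5)
  expect_true(all(same$p_values == 1))
  expect_equal(same$median_p, 1)

  r1 <- downsample_compare(a, b, n_iter = 15, seed = 5)
  r2 <- downsample_compare(a, b, n_iter = 15, seed = 5)
  expect_identical(r1$p_values, r2$p_values)
  expect_equal(r1$n_draw, 250)

  swapped <- downsample_compare(b, a, n_iter = 15, seed = 5)
  expect_identical(r1$p_values, swapped$p_values)

  r3 <- downsample_compare(a, b, n_iter = 15, seed = 6)
  expect_false(identical(r1$p_values, r3$p_values))
})

test_that("iterations with fewer than two clone-size bins are excluded with a warning", {
  # all singletons in both groups: the union of observed sizes is {1}
  a <- cells_from_sizes(rep(1, 30), prefix = "A")
  b <- cells_from_sizes(rep(1, 30), prefix = "B")
  expect_warning(res <- downsample_compare(a, b, n_iter = 5, seed = 1),
                 "fewer than 2")
  expect_true(all(is.na(res$p_values)))
})

test_that("strata percentages match hand counts and sum to 100", {
  cells <- dplyr::bind_rows(
    cells_from_sizes(c(4, 1, 1, 1, 1)),            # 8 paired cells
    tibble::tibble(
      barcode = c("na1", "na2"), sample_id = "S1",
      alpha_cdr3 = NA_character_, beta_cdr3 = NA_character_,
      alpha_v = NA_character_, alpha_j = NA_character_,
      beta_v = NA_character_, beta_j = NA_character_,
      has_pair = FALSE, tissue = "blood", condition = "PD",
      cluster = NA_character_, embed_x = NA_real_, embed_y = NA_real_,
      clonotype_id = NA_character_, clone_size = NA_integer_))
  st <- strata_percentages(cells)
  cum <- st[st$view == "cumulative", ]
  expect_equal(cum$percent[cum$stratum == "NA"], 20)
  expect_equal(cum$percent[cum$stratum == "=1"], 40)
  expect_equal(cum$percent[cum$stratum == ">=2"], 40)
  expect_equal(cum$percent[cum$stratum == ">=20"], 0)
  dis <- st[st$view == "disjoint", ]
  expect_equal(sum(dis$percent), 100)

  # cumulative nesting on a generated repertoire
  pool <- sim_cell_pool(500, big_cell_frac = 0.2, seed = 2)
  st2 <- strata_percentages(pool)
  cum2 <- st2[st2$view == "cumulative", ]
  expect_gte(cum2$percent[cum2$stratum == ">=2"],
             cum2$percent[cum2$stratum == ">=20"])
  expect_gte(cum2$percent[cum2$stratum == ">=20"],
             cum2$percent[cum2$stratum == ">=100"])
  dis2 <- st2[st2$view == "disjoint", ]
  expect_equal(sum(dis2$percent), 100)
})

test_that("mean clone size reproduces published count pairs and edge cases", {
  expect_equal(round(mean_clone_size(n_cells = 2301, n_clonotypes = 371), 1),
               6.2)
  expect_equal(round(mean_clone_size(n_cells = 829, n_clonotypes = 258), 1),
               3.2)
  singletons <- cells_from_sizes(rep(1, 12))
  expect_equal(mean_clone_size(singletons), 1)
  expect_error(mean_clone_size(singletons[0, ]), "empty")
  bad <- singletons
  bad$clonotype_id[1] <- NA
  expect_error(mean_clone_size(bad), "clonotyped")
})

test_that("per-cluster Fisher enrichment matches the hypergeometric oracle", {
  # cluster whose expanded fraction equals the global fraction: p ~ 1
  balanced <- dplyr::bind_rows(
    cells_from_sizes(c(rep(2, 10), rep(1, 20)), condition = "PD",
                     cluster = "C1", prefix = "P"),
    cells_from_sizes(c(rep(2, 10), rep(1, 20)), condition = "HC",
                     cluster = "C1", prefix = "H"))
  res <- cluster_expansion_enrichment(balanced)
  expect_gt(res$p_value[1], 0.9)
  expect_equal(round(res$odds_ratio[1], 2), 1)

  # printed table [[30,10],[10,30]] via a synthetic cluster
  tab_cells <- dplyr::bind_rows(
    cells_from_sizes(c(rep(2, 15), rep(1, 10)), condition = "PD",
                     cluster = "CX", prefix = "P"),
    cells_from_sizes(c(rep(2, 5), rep(1, 30)), condition = "HC",
                     cluster = "CX", prefix = "H"))
  res2 <- cluster_expansion_enrichment(tab_cells)
  tab <- matrix(c(30, 10, 10, 30), nrow = 2, byrow = TRUE)
  expect_equal(unname(unlist(res2[1, c("n_exp_a", "n_non_a",
                                       "n_exp_b", "n_non_b")])),
               c(30, 10, 10, 30))
  expect_equal(res2$p_value[1], oracle_fisher_p(tab))

  # degenerate margin: no expanded cells at all in the cluster
  degen <- dplyr::bind_rows(
    cells_from_sizes(rep(1, 10), condition = "PD", cluster = "C0",
                     prefix = "P"),
    cells_from_sizes(rep(1, 10), condition = "HC", cluster = "C0",
                     prefix = "H"))
  res3 <- cluster_expansion_enrichment(degen)
  expect_true(res3$degenerate[1])
  expect_equal(res3$p_value[1], 1)
  expect_true(is.na(res3$odds_ratio[1]))
})

test_that("BH-adjusted FDRs are monotone in p-value rank", {
  set.seed(5)
  cells <- dplyr::bind_rows(lapply(1:6, function(i) {
    dplyr::bind_rows(
      cells_from_sizes(c(rep(2, sample(2:12, 1)), rep(1, 20)),
                       condition = "PD", cluster = paste0("C", i),
                       prefix = paste0("P", i)),
      cells_from_sizes(c(rep(2, 4), rep(1, 20)), condition = "HC",
                       cluster = paste0("C", i),
                       prefix = paste0("H", i)))
  }))
  res <- cluster_expansion_enrichment(cells)
  ord <- order(res$p_value)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
})

test_that("pd_by_cluster design restricts the table to PD cells", {
  cells <- dplyr::bind_rows(
    cells_from_sizes(c(rep(3, 10), rep(1, 5)), condition = "PD",
                     cluster = "C6", prefix = "A"),
    cells_from_sizes(rep(1, 30), condition = "PD", cluster = "C1",
                     prefix = "B"),
    cells_from_sizes(rep(2, 20), condition = "HC", cluster = "C1",
                     prefix = "H"))
  res <- cluster_expansion_enrichment(cells, design = "pd_by_cluster")
  c6 <- res[res$cluster == "C6", ]
  # HC cells must not appear in any margin
  expect_equal(c6$n_exp_a + c6$n_non_a + c6$n_exp_b + c6$n_non_b, 65)
  expect_lt(c6$p_value, 0.001)
})

test_that("composition by clone size yields normalized fractions", {
  one_cluster <- cells_from_sizes(c(3, 1), cluster = "C1")
  comp <- composition_by_clone_size(one_cluster)
  expect_true(all(comp$fraction == 1))

  # 12 cells in 2 clusters: one size-6 clonotype split 4/2, six singletons 2/4
  cells <- cells_from_sizes(c(6, rep(1, 6)))
  cells$cluster <- c(rep("C1", 4), rep("C2", 2), rep("C1", 2), rep("C2", 4))
  comp2 <- composition_by_clone_size(cells)
  big <- comp2[comp2$stratum == "2-19", ]
  expect_equal(big$fraction[big$cluster == "C1"], 4 / 6)
  expect_equal(big$fraction[big$cluster == "C2"], 2 / 6)
  sums <- comp2 |>
    dplyr::group_by(sample_id, stratum) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
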