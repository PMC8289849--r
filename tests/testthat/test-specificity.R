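# CDR3 similarity rules and specificity grouping.

test_that("cdr3_match implements the one-substitution / one-indel rules", {
  expect_true(cdr3_match("CASSLGETQYF", "CASSLGETQYF", "TRBV5-1", "TRBV5-1"))
  expect_true(cdr3_match("CASSLGETQYF", "CASSLGDTQYF", "TRBV5-1", "TRBV5-1"))
  expect_false(cdr3_match("CASSLGETQYF", "CASSLGETQYF", "TRBV5-1", "TRBV7-2"))
  # allele suffixes are stripped before comparison
  expect_true(cdr3_match("CASSLGETQYF", "CASSLGETQYF", "TRBV5-1*01",
                         "TRBV5-1*02"))
  # one deletion, zero extra mismatches
  expect_true(cdr3_match("CASSLGETQYF", "CASSLGETQY"))
  expect_true(cdr3_match("CASSLGETQY", "CASSLGETQYF"))
  # two substitutions rejected
  expect_false(cdr3_match("CASSLGETQYF", "CASSMGDTQYF"))
  # deletion plus substitution rejected when strict, allowed otherwise
  expect_false(cdr3_match("CASSLGETQYF", "CASSMGETQY"))
  expect_true(cdr3_match("CASSLGETQYF", "CASSMGETQY", strict = FALSE))
  # length difference of 2 always rejected
  expect_false(cdr3_match("CASSLGETQYF", "CASSLGETQ"))
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:50) {
    a <- random_cdr3s(1)
    b <- if (i %% 2) substitute_at(a, 3) else random_cdr3s(1)
    expect_equal(cdr3_match(a, b), cdr3_match(b, a))
  }
})

test_that("single linkage chains transitively within one V gene", {
  tcrs <- tibble::tibble(
    cdr3 = c("CASSLGETQYF",   # A
             "CASSLGDTQYF",   # B: 1 sub from A
             "CASSMGDTQYF",   # C: 1 sub from B, 2 from A
             "CASSLGETQYF"),  # same as A, other V gene
    v_gene = c("TRBV5-1", "TRBV5-1", "TRBV5-1", "TRBV7-2"),
    sample_id = c("P1", "P2", "P3", "P4"),
    tissue = "blood", condition = "PD")
  groups <- build_specificity_groups(tcrs)
  expect_equal(dplyr::n_distinct(groups$group_id), 1)
  expect_equal(nrow(groups), 3)
  expect_setequal(groups$sample_id, c("P1", "P2", "P3"))
  # no group mixes V genes
  expect_equal(dplyr::n_distinct(strip_allele(groups$v_gene)), 1)
})

test_that("bucketed grouping equals the exhaustive all-pairs oracle", {
  set.seed(42)
  for (rep in 1:3) {
    n_random <- 150
    members <- tibble::tibble(
      cdr3 = random_cdr3s(n_random),
      v_gene = sample(sprintf("TRBV%d", 1:8), n_random, replace = TRUE),
      sample_id = sample(c("P1", "P2", "N1", "N2"), n_random, replace = TRUE),
      tissue = sample(c("blood", "CSF"), n_random, replace = TRUE),
      condition = sample(c("PD", "HC"), n_random, replace = TRUE))
    # plant 3 families of single-substitution variants
    planted <- dplyr::bind_rows(lapply(1:3, function(f) {
      center <- random_cdr3s(1, 14, 14)
      tibble::tibble(
        cdr3 = c(center, vapply(2:4, function(p) substitute_at(center, p),
                                character(1))),
        v_gene = paste0("TRBV2", f), sample_id = c("P1", "P2", "N1", "N2"),
        tissue = "blood", condition = "PD")
    }))
    members <- dplyr::bind_rows(members, planted)
    members <- dplyr::distinct(members, cdr3, v_gene, sample_id,
                               .keep_all = TRUE)

    groups <- build_specificity_groups(members)
    got <- unname(lapply(group_sets_from_membership(groups, members), sort))
    want <- lapply(oracle_groups(members), function(ix) {
      sort(member_labels(members)[ix])
    })
    expect_setequal(got, want)
  }
})

test_that("grouping is invariant to input order and ids are deterministic", {
  set.seed(9)
  center <- random_cdr3s(1, 13, 13)
  members <- tibble::tibble(
    cdr3 = c(center, substitute_at(center, 4), substitute_at(center, 5),
             random_cdr3s(20)),
    v_gene = c(rep("TRBV9", 3), rep("TRBV3", 20)),
    sample_id = "P1", tissue = "blood", condition = "PD")
  g1 <- build_specificity_groups(members)
  g2 <- build_specificity_groups(members[rev(seq_len(nrow(members))), ])
  expect_equal(dplyr::arrange(g1, cdr3), dplyr::arrange(g2, cdr3))
  expect_equal(unique(g1$group_id), "G1")
})

test_that("every group member matches at least one other member", {
  set.seed(13)
  members <- tibble::tibble(
    cdr3 = random_cdr3s(100, 11, 13),
    v_gene = sample(sprintf("TRBV%d", 1:3), 100, replace = TRUE),
    sample_id = "P1", tissue = "blood", condition = "PD")
  center <- random_cdr3s(1, 12, 12)
  members <- dplyr::bind_rows(members, tibble::tibble(
    cdr3 = c(center, substitute_at(center, 3), substitute_at(center, 6)),
    v_gene = "TRBV1", sample_id = c("P1", "P2", "P3"),
    tissue = "blood", condition = "PD"))
  groups <- build_specificity_groups(members)
  for (gid in unique(groups$group_id)) {
    g <- groups[groups$group_id == gid, ]
    for (i in seq_len(nrow(g))) {
      others <- g[-i, ]
      hits <- mapply(cdr3_match, g$cdr3[i], others$cdr3,
                     g$v_gene[i], others$v_gene)
      expect_true(any(hits))
    }
  }
})

test_that("the PD-specific screen keeps only blood+CSF PD bridging groups", {
  center1 <- "CASSAAAAAAAQYF"
  center2 <- "CASSGGGGGGGQYF"
  members <- tibble::tibble(
    cdr3 = c(center1, substitute_at(center1, 5),
             center2, substitute_at(center2, 5)),
    v_gene = c("TRBV1", "TRBV1", "TRBV2", "TRBV2"),
    sample_id = c("P1", "PD1", "N1", "N2"),
    tissue = c("blood", "CSF", "blood", "blood"),
    condition = c("PD", "PD", "HC", "HC"))
  groups <- build_specificity_groups(members)
  expect_equal(dplyr::n_distinct(groups$group_id), 2)
  pd <- screen_pd_specific(groups)
  expect_equal(dplyr::n_distinct(pd$group_id), 1)
  expect_setequal(pd$sample_id, c("P1", "PD1"))
})

test_that("beta_tcrs deduplicates receptors within a sample", {
  cells <- dplyr::bind_rows(
    cells_from_sizes(c(3, 1), sample_id = "P1"),
    cells_from_sizes(c(2), sample_id = "P2"))
  tcrs <- beta_tcrs(cells)
  expect_equal(nrow(tcrs), 3)  # 2 distinct in P1, 1 in P2
  expect_true(all(table(paste(tcrs$cdr3, tcrs$sample_id)) == 1))
})
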