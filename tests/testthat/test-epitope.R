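# Sliding-window peptides and TCR-HLA-peptide linkage.

test_that("window_peptides enumerates, deduplicates and filters windows", {
  prot <- tibble::tibble(accession = "P1",
                         sequence = "ACDEFGHIKLMNPQRSTVWY")
  w9 <- window_peptides(prot, 9)
  expect_equal(nrow(w9), 12)  # L - k + 1 = 12, no repeated windows here

  # identical sequences collapse to one source set
  dup <- dplyr::bind_rows(prot, dplyr::mutate(prot, accession = "P2"))
  w9dup <- window_peptides(dup, 9)
  expect_equal(w9dup$peptide, w9$peptide)
  expect_true(all(w9dup$accessions == "P1;P2"))

  # the documented 15-mer epitope falls out of the toy protein
  toy <- tibble::tibble(accession = "SYN",
                        sequence = "KTKEGVLYVGSKTKEGVVH")
  w15 <- window_peptides(toy, 15)
  expect_true("KTKEGVLYVGSKTKE" %in% w15$peptide)

  # windows containing X are dropped; short sequences log a message
  with_x <- tibble::tibble(accession = c("A", "B"),
                           sequence = c("ACDEFGHIKXACDEFGHIK", "ACD"))
  expect_message(wx <- window_peptides(with_x, 9), "shorter than 9")
  expect_false(any(grepl("X", wx$peptide)))
  # the two windows clear of the X are the same 9-mer, deduplicated
  expect_equal(wx$peptide, "ACDEFGHIK")

  # idempotence: windowing the window set returns the same peptides
  again <- window_peptides(
    tibble::tibble(accession = w9$peptide, sequence = w9$peptide), 9)
  expect_setequal(again$peptide, w9$peptide)
})

test_that("allele normalization and class assignment", {
  expect_equal(normalize_hla_allele(c("HLA-A*02:01:01", "A02:01",
                                      "HLA-C06:02", "HLA-DRB1*15:01")),
               c("HLA-A02:01", "HLA-A02:01", "HLA-C06:02", "HLA-DRB115:01"))
  expect_equal(hla_class(c("HLA-A02:01", "HLA-DRB115:01", "HLA-DQB106:02")),
               c("I", "II", "II"))
})

test_that("groups link to alleles carried by every member sample", {
  groups <- tibble::tibble(
    group_id = c("G1", "G1", "G2", "G2", "G3"),
    cdr3 = c("CASSA", "CASSB", "CASSC", "CASSD", "CASSE"),
    v_gene = "TRBV1",
    sample_id = c("P1", "P4", "P1", "P2", "P9"),
    tissue = "blood", condition = "PD")
  typing <- tibble::tibble(
    sample_id = c("P1", "P1", "P4", "P2"),
    allele = c("HLA-C06:02", "HLA-A02:01", "HLA-C06:02", "HLA-B07:02"))
  expect_warning(links <- link_groups_to_alleles(groups, typing), "G3")
  # G1: both P1 and P4 carry HLA-C06:02; only P1 carries A02:01
  expect_equal(links$group_id, "G1")
  expect_equal(links$allele, "HLA-C06:02")
  expect_equal(links$shared_samples, "P1;P4")
  # G2: P2 lacks HLA-C06:02 entirely, no common allele -> no link
  expect_false("G2" %in% links$group_id)
})

test_that("linkage equals the exhaustive oracle and is anti-monotone in min_shared", {
  set.seed(6)
  samples <- paste0("P", 1:8)
  alleles <- paste0("HLA-A", sprintf("%02d:01", 1:6))
  typing <- dplyr::bind_rows(lapply(samples, function(s) {
    tibble::tibble(sample_id = s, allele = sample(alleles, 3))
  }))
  groups <- dplyr::bind_rows(lapply(1:10, function(g) {
    n <- sample(2:4, 1)
    tibble::tibble(group_id = sprintf("G%02d", g),
                   cdr3 = sprintf("CASS%02d%dF", g, seq_len(n)),
                   v_gene = "TRBV1",
                   sample_id = sample(samples, n),
                   tissue = "blood", condition = "PD")
  }))
  links <- link_groups_to_alleles(groups, typing, min_shared = 2)
  # brute force over all (group, allele) pairs
  carrier <- split(typing$allele, typing$sample_id)
  expected <- list()
  for (g in unique(groups$group_id)) {
    ss <- sort(unique(groups$sample_id[groups$group_id == g]))
    if (length(ss) < 2) next
    for (a in alleles) {
      if (all(vapply(ss, function(s) a %in% carrier[[s]], logical(1)))) {
        expected[[length(expected) + 1]] <- paste(g, a)
      }
    }
  }
  expect_setequal(paste(links$group_id, links$allele), unlist(expected))

  links3 <- link_groups_to_alleles(groups, typing, min_shared = 3)
  expect_true(all(paste(links3$group_id, links3$allele) %in%
                    paste(links$group_id, links$allele)))
})

test_that("attach_peptides respects the binder flag and rank threshold", {
  links <- tibble::tibble(group_id = c("G1", "G2"),
                          allele = c("HLA-C06:02", "HLA-B08:01"),
                          n_shared = 2L, shared_samples = "P1;P4")
  binding <- tibble::tibble(
    peptide = c("KTKEGVLYV", "AAAAAAAAA", "CCCCCCCCC"),
    allele = c("HLA-C06:02", "HLA-C06:02", "HLA-C06:02"),
    score = c(0.9, 0.1, 0.2),
    rank_percent = c(0.5, 40, 1.5),
    binder = c(TRUE, FALSE, FALSE))
  strict <- attach_peptides(links, binding, rank_threshold = 0)
  expect_equal(strict$peptides[1], "KTKEGVLYV")
  expect_equal(strict$n_peptides, c(1L, 0L))
  expect_equal(strict$allele_in_binding, c(TRUE, FALSE))
  expect_equal(strict$has_peptides, c(TRUE, FALSE))

  relaxed <- attach_peptides(links, binding, rank_threshold = 2)
  expect_setequal(strsplit(relaxed$peptides[1], ";")[[1]],
                  c("KTKEGVLYV", "CCCCCCCCC"))

  # randomized table vs a hand filter
  set.seed(2)
  rnd <- tibble::tibble(
    peptide = random_cdr3s(30, 9, 9),
    allele = "HLA-C06:02",
    score = runif(30), rank_percent = runif(30, 0, 20),
    binder = sample(c(TRUE, FALSE), 30, replace = TRUE))
  got <- attach_peptides(links[1, ], rnd, rank_threshold = 5)
  want <- sort(unique(rnd$peptide[rnd$binder | rnd$rank_percent <= 5]))
  expect_equal(strsplit(got$peptides, ";")[[1]], want)
})

test_that("binding reader drops class-mismatched rows and readers round-trip", {
  dir <- withr::local_tempdir()
  binding <- tibble::tibble(
    peptide = c("AAAAAAAAA", "AAAAAAAAAAAAAAA", "AAAAAAAAA"),
    allele = c("HLA-A02:01", "HLA-DRB115:01", "HLA-DRB115:01"),
    score = c(0.5, 0.6, 0.7), rank_percent = c(1, 2, 3),
    binder = c(TRUE, TRUE, TRUE))
  readr::write_tsv(binding, file.path(dir, "binding.tsv"))
  expect_warning(rd <- read_binding_table(file.path(dir, "binding.tsv")),
                 "mismatch")
  expect_equal(nrow(rd), 2)

  typing <- tibble::tibble(sample_id = c("P1", "P1"),
                           allele = c("HLA-A*02:01:03", "HLA-DRB1*15:01"))
  readr::write_tsv(typing, file.path(dir, "hla.tsv"))
  ty <- read_hla_typing(file.path(dir, "hla.tsv"))
  expect_setequal(ty$allele, c("HLA-A02:01", "HLA-DRB115:01"))

  prot <- Biostrings::AAStringSet(c(
    "SYN_1 alpha-synuclein toy" = "MDVFMKGLSKAKEGV",
    "MT_1 mitochondrial toy" = "MLRAAARSTLQRSFS"))
  Biostrings::writeXStringSet(prot, file.path(dir, "prot.fasta"))
  pr <- read_proteins(file.path(dir, "prot.fasta"))
  expect_equal(pr$accession, c("SYN_1", "MT_1"))
  expect_equal(pr$source_tag, c("alpha_synuclein", "mitochondrial"))
})
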