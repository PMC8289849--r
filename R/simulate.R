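# Synthetic paired-chain repertoire generator with full ground truth, so
# every pipeline stage is testable without sequencing data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic repertoire generator. Defaults mirror
#' a two-compartment case/control cohort: 8 PD and 8 HC blood samples plus
#' 6 PD and 9 HC cerebrospinal-fluid samples, heavier clonal expansion in the
#' PD clone-size law, a fixed fraction of gamma/delta cells without an
#' alpha-beta receptor, planted multi-cluster clonotypes, planted CDR3 motif
#' families obeying the specificity-grouping rules, per-sample HLA
#' allotypes with planted group-allele co-carriage, and toy proteins carrying
#' known epitope windows.
#'
#' @param n_blood Named integer vector: blood samples per condition.
#' @param n_csf Named integer vector: CSF samples per condition.
#' @param cells_per_blood_sample,cells_per_csf_sample Cells per sample.
#' @param clone_size_law Per-condition law: `geom_p` (geometric success
#'   probability for sizes `1 + Geom(p)`), `big_cell_frac` (fraction of
#'   cells placed in large clones) and `big_range` (size range of those
#'   clones). A big-cell budget smaller than `big_range[1]` is bumped up to
#'   one clone of the minimum size.
#' @param frac_na_cells Fraction of cells emitted as gamma/delta-only
#'   (no alpha-beta receptor; the NA stratum).
#' @param cluster_labels Transcriptomic cluster labels for alpha-beta cells.
#' @param gd_cluster Cluster label given to gamma/delta cells.
#' @param expanded_cluster_weights Named weights biasing the cluster of
#'   expanded (size >= 2) PD clonotypes; unnamed clusters get weight 1.
#' @param lineage_plants List of `list(n=, clusters=, size=)`: clonotypes
#'   whose cells are spread to cover a cluster set (planted in PD blood).
#' @param motif_plants List of `list(size=, pd_bridging=)`: CDR3 motif
#'   families of single-substitution variants sharing one V gene; bridging
#'   families get members in both PD blood and PD CSF.
#' @param hla_pool Character vector of HLA alleles (normalized form).
#' @param n_class1_per_sample,n_class2_per_sample Alleles drawn per sample.
#' @param planted_links List of `list(group=, allele=)`: all samples hosting
#'   members of motif family `group` are forced to carry `allele`.
#' @param proteins Tibble `accession`, `sequence`, `source_tag` of toy
#'   proteins (synthetic stand-ins; defaults carry known epitope windows).
#' @param planted_binders List of `list(allele=, peptide=)` rows marked as
#'   binders in the generated binding table.
#' @param n_decoy_binding_rows Non-binder rows added to the binding table.
#' @param cdr3_lengths,cdr3_length_weights CDR3 length distribution
#'   (default 10-20, mode near 14, as in human beta-chain repertoires).
#' @param second_contig_frac Fraction of alpha-beta cells given a second,
#'   lower-UMI beta contig (exercises the chain tie-break).
#' @param seed Root seed; the whole bundle is a deterministic function of it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_blood = c(PD = 8, HC = 8),
                       n_csf = c(PD = 6, HC = 9),
                       cells_per_blood_sample = 3000,
                       cells_per_csf_sample = 300,
                       clone_size_law = list(
                         PD = list(geom_p = 0.7, big_cell_frac = 0.05,
                                   big_range = c(20, 150)),
                         HC = list(geom_p = 0.7, big_cell_frac = 0,
                                   big_range = c(20, 150))),
                       frac_na_cells = 0.07,
                       cluster_labels = c("C1", "C3", "C5", "C6", "C9",
                                          "C13", "C15"),
                       gd_cluster = "C10",
                       expanded_cluster_weights = c(C6 = 6, C3 = 4),
                       lineage_plants = list(
                         list(n = 5, clusters = c("C15", "C3", "C6"),
                              size = 6)),
                       motif_plants = c(
                         rep(list(list(size = 4, pd_bridging = TRUE)), 3),
                         rep(list(list(size = 4, pd_bridging = FALSE)), 2)),
                       hla_pool = c("HLA-A01:01", "HLA-A02:01", "HLA-B07:02",
                                    "HLA-B08:01", "HLA-C06:02", "HLA-C07:01",
                                    "HLA-C07:02", "HLA-DRB101:01",
                                    "HLA-DRB103:01", "HLA-DRB115:01",
                                    "HLA-DQB102:01", "HLA-DQB106:02"),
                       n_class1_per_sample = 4,
                       n_class2_per_sample = 3,
                       planted_links = list(
                         list(group = 1, allele = "HLA-C06:02"),
                         list(group = 2, allele = "HLA-DRB115:01")),
                       proteins = default_sim_proteins(),
                       planted_binders = list(
                         list(allele = "HLA-C06:02", peptide = "KTKEGVLYV"),
                         list(allele = "HLA-DRB115:01",
                              peptide = "KTKEGVLYVGSKTKE")),
                       n_decoy_binding_rows = 50,
                       cdr3_lengths = 10:20,
                       cdr3_length_weights = c(1, 2, 4, 7, 9, 8, 6, 4, 2, 1, 1),
                       second_contig_frac = 0.02,
                       seed = 17) {
  config <- list(
    n_blood = n_blood, n_csf = n_csf,
    cells_per_blood_sample = cells_per_blood_sample,
    cells_per_csf_sample = cells_per_csf_sample,
    clone_size_law = clone_size_law, frac_na_cells = frac_na_cells,
    cluster_labels = cluster_labels, gd_cluster = gd_cluster,
    expanded_cluster_weights = expanded_cluster_weights,
    lineage_plants = lineage_plants, motif_plants = motif_plants,
    hla_pool = hla_pool, n_class1_per_sample = n_class1_per_sample,
    n_class2_per_sample = n_class2_per_sample,
    planted_links = planted_links, proteins = proteins,
    planted_binders = planted_binders,
    n_decoy_binding_rows = n_decoy_binding_rows,
    cdr3_lengths = cdr3_lengths,
    cdr3_length_weights = cdr3_length_weights,
    second_contig_frac = second_contig_frac, seed = seed)
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

#' @keywords internal
default_sim_proteins <- function() {
  tibble(
    accession = c("SYN_TOY", "MITO_TOY"),
    sequence = c(
      # synthetic alpha-synuclein-like toy: imperfect KTKEGV repeats
      "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTKEQVTNVGGAVVTGVTAVAQ",
      # synthetic mitochondrial-like toy
      "MLRAAARSTLQRSFSTSAAQNHVKLVEGLPQRLWAEENPGKTAVDLMQKHGFDEVSTRAGLKV"),
    source_tag = c("alpha_synuclein", "mitochondrial")
  )
}

validate_sim_config <- function(config) {
  stopifnot(all(c("PD", "HC") %in% names(config$n_blood)),
            all(c("PD", "HC") %in% names(config$n_csf)))
  if (config$frac_na_cells < 0 || config$frac_na_cells >= 1) {
    stop("frac_na_cells must lie in [0, 1)", call. = FALSE)
  }
  for (cond in c("PD", "HC")) {
    law <- config$clone_size_law[[cond]]
    if (is.null(law) || law$geom_p <= 0 || law$geom_p > 1 ||
        law$big_cell_frac < 0 || law$big_cell_frac > 1) {
      stop(sprintf("clone_size_law for %s is invalid", cond), call. = FALSE)
    }
  }
  for (mp in config$motif_plants) {
    if (mp$size < 2) stop("motif families need at least 2 members", call. = FALSE)
  }
  for (pl in config$planted_links) {
    if (pl$group < 1 || pl$group > length(config$motif_plants)) {
      stop("planted_links refers to a motif family that does not exist",
           call. = FALSE)
    }
    if (!pl$allele %in% config$hla_pool) {
      stop("planted_links allele must come from hla_pool", call. = FALSE)
    }
  }
  n_pd_blood <- config$n_blood[["PD"]]
  planted_cells <- sum(vapply(config$lineage_plants,
                              function(p) p$n * p$size, numeric(1)))
  budget <- n_pd_blood * config$cells_per_blood_sample *
    (1 - config$frac_na_cells) * 0.5
  if (planted_cells > budget) {
    stop("lineage plants exceed the PD blood cell budget", call. = FALSE)
  }
  if (config$n_class1_per_sample + config$n_class2_per_sample >
      length(config$hla_pool)) {
    stop("more alleles per sample than the HLA pool provides", call. = FALSE)
  }
  invisible(config)
}

# ---- low-level draws ------------------------------------------------------

# Clone sizes summing exactly to n_cells: a `big_cell_frac` share of cells in
# clones of size `big_range`, the rest 1 + Geom(geom_p); last clone truncated
# to land exactly on n_cells.
draw_clone_sizes <- function(n_cells, geom_p, big_cell_frac = 0,
                             big_range = c(20, 150)) {
  stopifnot(n_cells >= 1)
  big_sizes <- integer(0)
  budget <- round(big_cell_frac * n_cells)
  while (budget > 0) {
    s <- sample(big_range[1]:big_range[2], 1)
    if (s > budget) s <- max(big_range[1], budget)
    s <- min(s, n_cells - sum(big_sizes))
    if (s <= 0) break
    big_sizes <- c(big_sizes, s)
    budget <- budget - s
  }
  fill <- n_cells - sum(big_sizes)
  small_sizes <- integer(0)
  while (fill > 0) {
    draw <- 1L + rgeom(max(64L, ceiling(fill)), geom_p)
    cum <- cumsum(draw)
    if (cum[length(cum)] >= fill) {
      keep <- which(cum >= fill)[1]
      draw <- draw[seq_len(keep)]
      draw[keep] <- draw[keep] - (sum(draw) - fill)
      small_sizes <- c(small_sizes, draw[draw > 0])
      fill <- 0
    } else {
      small_sizes <- c(small_sizes, draw)
      fill <- fill - cum[length(cum)]
    }
  }
  c(big_sizes, small_sizes)
}

# Deterministic, collision-free amino-acid code for an integer index.
index_to_aa <- function(i, width = 6) {
  vapply(i, function(x) {
    digits <- integer(width)
    for (p in seq_len(width)) {
      digits[p] <- x %% 20L
      x <- x %/% 20L
    }
    paste(AA_ALPHABET[digits + 1L], collapse = "")
  }, character(1))
}

# Random CDR3s with conserved C...F framing, unique within the returned set
# and disjoint from `avoid`.
rand_cdr3 <- function(n, lengths, length_weights, avoid = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    ls <- if (length(lengths) == 1) {
      rep(lengths, need)
    } else {
      sample(lengths, need, replace = TRUE, prob = length_weights)
    }
    mids <- vapply(ls, function(l) {
      paste(sample(AA_ALPHABET, l - 2L, replace = TRUE), collapse = "")
    }, character(1))
    cand <- paste0("C", mids, "F")
    out <- unique(c(out, setdiff(cand, avoid)))
  }
  out[seq_len(n)]
}

# One-substitution variants of a center CDR3 (positions inside the framing).
motif_variants <- function(center, n_variants) {
  l <- nchar(center)
  stopifnot(l >= 5, n_variants <= (l - 2))
  out <- character(n_variants)
  for (i in seq_len(n_variants)) {
    pos <- 1L + i  # distinct interior positions
    old <- substr(center, pos, pos)
    new <- sample(setdiff(AA_ALPHABET, old), 1)
    out[i] <- paste0(substr(center, 1, pos - 1), new,
                     substr(center, pos + 1, l))
  }
  out
}

codon_map <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

aa_to_nt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) {
    paste(codon_map[ch], collapse = "")
  }, character(1))
}

#' Minimal synthetic cell pool under a clone-size law
#'
#' Fast generator of an annotated-cell tibble for resampling and enrichment
#' experiments: clone sizes follow the law, CDR3 keys are synthetic but
#' unique, and no files are involved.
#'
#' @param n_cells Number of cells.
#' @param geom_p,big_cell_frac,big_range Clone-size law (see [sim_config()]).
#' @param sample_id,condition,tissue Annotations stamped on every cell.
#' @param seed Seed; the pool is a deterministic function of it.
#' @param key_offset Integer offset for the synthetic CDR3 codes, so pools
#'   drawn with different offsets share no clonotype keys.
#' @return Cell tibble compatible with the expansion functions
#'   (`has_pair = TRUE`, `clone_size` filled in).
#' @export
sim_cell_pool <- function(n_cells, geom_p = 0.7, big_cell_frac = 0,
                          big_range = c(20, 150), sample_id = "S1",
                          condition = "PD", tissue = "blood", seed = 1,
                          key_offset = 0L) {
  with_seed(seed, {
    sizes <- draw_clone_sizes(n_cells, geom_p, big_cell_frac, big_range)
    idx <- seq_along(sizes) + key_offset
    beta <- paste0("CASS", index_to_aa(idx), "F")
    alpha <- paste0("CAV", index_to_aa(idx), "F")
    tibble(
      barcode = sprintf("%s_%06d", sample_id, seq_len(sum(sizes))),
      sample_id = sample_id,
      alpha_cdr3 = rep(alpha, sizes),
      beta_cdr3 = rep(beta, sizes),
      alpha_v = "TRAV1", alpha_j = "TRAJ1",
      beta_v = "TRBV1", beta_j = "TRBJ1",
      has_pair = TRUE,
      tissue = tissue, condition = condition,
      cluster = NA_character_,
      embed_x = NA_real_, embed_y = NA_real_,
      clonotype_id = rep(paste0("sim", idx), sizes),
      clone_size = rep(sizes, sizes)
    )
  })
}

# ---- the full generator ---------------------------------------------------

#' Simulate a full input bundle with ground truth
#'
#' Generates, deterministically from `config$seed`: per-sample contig tables
#' in the Cell Ranger dialect, a cell metadata table, per-sample HLA
#' typings, toy protein FASTA, a peptide-allele binding table, and a ground
#' truth record of every planted structure. When `outdir` is given the
#' bundle is also written to disk (`<sample>_contigs.csv`, `meta.tsv`,
#' `hla_typing.tsv`, `proteins.fasta`, `binding.tsv`,
#' `ground_truth.json`).
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with `samples`, `contigs` (named list of per-sample
#'   tibbles), `meta`, `hla`, `proteins`, `binding` and `truth`.
#' @export
simulate_repertoire <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bundle <- with_seed(config$seed, simulate_repertoire_impl(config))
  if (!is.null(outdir)) write_sim_bundle(bundle, outdir)
  bundle
}

simulate_repertoire_impl <- function(config) {
  samples <- bind_rows(
    tibble(sample_id = paste0("P", seq_len(config$n_blood[["PD"]])),
           tissue = "blood", condition = "PD",
           n_cells = config$cells_per_blood_sample),
    tibble(sample_id = paste0("N", seq_len(config$n_blood[["HC"]])),
           tissue = "blood", condition = "HC",
           n_cells = config$cells_per_blood_sample),
    tibble(sample_id = paste0("PD", seq_len(config$n_csf[["PD"]])),
           tissue = "CSF", condition = "PD",
           n_cells = config$cells_per_csf_sample),
    tibble(sample_id = paste0("HC", seq_len(config$n_csf[["HC"]])),
           tissue = "CSF", condition = "HC",
           n_cells = config$cells_per_csf_sample))

  pd_blood <- samples$sample_id[samples$condition == "PD" &
                                  samples$tissue == "blood"]
  pd_csf <- samples$sample_id[samples$condition == "PD" &
                                samples$tissue == "CSF"]
  hc_blood <- samples$sample_id[samples$condition == "HC" &
                                  samples$tissue == "blood"]

  # --- planted motif families (singleton clonotypes) -----------------------
  v_pool_beta <- sprintf("TRBV%d", 1:30)
  v_pool_alpha <- sprintf("TRAV%d", 1:30)
  motif_rows <- list()
  for (f in seq_along(config$motif_plants)) {
    mp <- config$motif_plants[[f]]
    center <- rand_cdr3(1, 14L, 1, avoid = character(0))
    cdr3s <- c(center, motif_variants(center, mp$size - 1L))
    v <- sample(v_pool_beta, 1)
    hosts <- if (isTRUE(mp$pd_bridging)) {
      # alternate blood / CSF so the family bridges both PD compartments
      as.vector(rbind(rep_len(pd_blood, ceiling(mp$size / 2)),
                      rep_len(pd_csf, ceiling(mp$size / 2))))[seq_len(mp$size)]
    } else {
      rep_len(hc_blood, mp$size)
    }
    motif_rows[[f]] <- tibble(family = paste0("F", f), beta_cdr3 = cdr3s,
                              beta_v = v, sample_id = hosts)
  }
  motif_df <- bind_rows(motif_rows)

  # --- planted lineage (multi-cluster) clonotypes --------------------------
  lineage_rows <- list()
  li <- 0L
  for (lp in config$lineage_plants) {
    for (j in seq_len(lp$n)) {
      li <- li + 1L
      lineage_rows[[li]] <- tibble(
        span_id = paste0("L", li),
        sample_id = pd_blood[(li - 1L) %% length(pd_blood) + 1L],
        size = max(lp$size, length(lp$clusters)),
        clusters = list(lp$clusters))
    }
  }
  lineage_df <- bind_rows(lineage_rows)

  # --- clonotype registry --------------------------------------------------
  registry <- list()
  for (si in seq_len(nrow(samples))) {
    s <- samples[si, ]
    n_na <- round(config$frac_na_cells * s$n_cells)
    n_motif <- sum(motif_df$sample_id == s$sample_id)
    n_lineage <- if (nrow(lineage_df)) {
      sum(lineage_df$size[lineage_df$sample_id == s$sample_id])
    } else 0L
    n_fill <- s$n_cells - n_na - n_motif - n_lineage
    if (n_fill < 0) {
      stop(sprintf("sample %s cannot host its planted cells", s$sample_id),
           call. = FALSE)
    }
    law <- config$clone_size_law[[s$condition]]
    sizes <- if (n_fill > 0) {
      draw_clone_sizes(n_fill, law$geom_p, law$big_cell_frac, law$big_range)
    } else integer(0)
    registry[[si]] <- tibble(sample_id = s$sample_id, size = as.integer(sizes),
                             kind = "fill", family = NA_character_,
                             span_id = NA_character_, n_na = 0L)
  }
  registry <- bind_rows(registry)
  if (nrow(motif_df)) {
    registry <- bind_rows(registry,
      tibble(sample_id = motif_df$sample_id, size = 1L, kind = "motif",
             family = motif_df$family, span_id = NA_character_, n_na = 0L))
  }
  if (nrow(lineage_df)) {
    registry <- bind_rows(registry,
      tibble(sample_id = lineage_df$sample_id,
             size = as.integer(lineage_df$size), kind = "lineage",
             family = NA_character_, span_id = lineage_df$span_id,
             n_na = 0L))
  }
  registry$clone_uid <- paste0("T", seq_len(nrow(registry)))

  # --- receptor sequences --------------------------------------------------
  n_clones <- nrow(registry)
  avoid <- motif_df$beta_cdr3
  betas <- rand_cdr3(n_clones, config$cdr3_lengths,
                     config$cdr3_length_weights, avoid = avoid)
  alphas <- rand_cdr3(n_clones, config$cdr3_lengths,
                      config$cdr3_length_weights, avoid = character(0))
  registry$beta_cdr3 <- betas
  registry$alpha_cdr3 <- alphas
  registry$beta_v <- sample(v_pool_beta, n_clones, replace = TRUE)
  registry$alpha_v <- sample(v_pool_alpha, n_clones, replace = TRUE)
  is_motif <- registry$kind == "motif"
  registry$beta_cdr3[is_motif] <- motif_df$beta_cdr3
  registry$beta_v[is_motif] <- motif_df$beta_v
  registry$beta_j <- sample(sprintf("TRBJ%d-%d", 1:2, 1:2), n_clones,
                            replace = TRUE)
  registry$alpha_j <- sample(sprintf("TRAJ%d", 1:20), n_clones,
                             replace = TRUE)

  # --- cluster assignment (one label per clonotype; lineage plants spread) -
  registry <- registry %>%
    left_join(select(samples, "sample_id", "condition", "tissue"),
              by = "sample_id")
  weights <- rep(1, length(config$cluster_labels))
  names(weights) <- config$cluster_labels
  known <- intersect(names(config$expanded_cluster_weights),
                     config$cluster_labels)
  weights[known] <- config$expanded_cluster_weights[known]
  registry$cluster <- ifelse(
    registry$condition == "PD" & registry$size >= 2 &
      registry$kind == "fill",
    sample(config$cluster_labels, n_clones, replace = TRUE, prob = weights),
    sample(config$cluster_labels, n_clones, replace = TRUE))

  # --- expand to cells -----------------------------------------------------
  cells <- registry[rep(seq_len(n_clones), registry$size), ]
  cells <- cells %>%
    group_by(.data$clone_uid) %>%
    mutate(cell_index = row_number()) %>%
    ungroup()
  # lineage clonotypes cover their planted cluster set
  if (nrow(lineage_df)) {
    span_clusters <- stats::setNames(lineage_df$clusters, lineage_df$span_id)
    is_lin <- which(!is.na(cells$span_id))
    lin_ids <- cells$span_id[is_lin]
    for (sid in unique(lin_ids)) {
      ix <- is_lin[lin_ids == sid]
      cells$cluster[ix] <- rep_len(span_clusters[[sid]], length(ix))
    }
  }

  # NA-stratum gamma/delta cells
  na_cells <- samples %>%
    mutate(n = round(config$frac_na_cells * .data$n_cells)) %>%
    filter(.data$n > 0)
  gd <- if (nrow(na_cells)) {
    gd_rows <- na_cells[rep(seq_len(nrow(na_cells)), na_cells$n), ]
    tibble(sample_id = gd_rows$sample_id, size = NA_integer_,
           kind = "gd", family = NA_character_, span_id = NA_character_,
           clone_uid = NA_character_, beta_cdr3 = NA_character_,
           alpha_cdr3 = NA_character_, beta_v = NA_character_,
           alpha_v = NA_character_, beta_j = NA_character_,
           alpha_j = NA_character_, condition = gd_rows$condition,
           tissue = gd_rows$tissue, cluster = config$gd_cluster,
           cell_index = NA_integer_, n_na = 0L)
  } else NULL
  cells <- bind_rows(cells, gd)

  # barcodes and embedding coordinates
  cells <- cells %>%
    group_by(.data$sample_id) %>%
    mutate(barcode = sprintf("%s_%05d", .data$sample_id, row_number())) %>%
    ungroup()
  all_clusters <- sort(unique(c(config$cluster_labels, config$gd_cluster)))
  cx <- stats::setNames(((seq_along(all_clusters) - 1) %% 4) * 3, all_clusters)
  cy <- stats::setNames(((seq_along(all_clusters) - 1) %/% 4) * 3, all_clusters)
  cells$embed_x <- cx[cells$cluster] + rnorm(nrow(cells), sd = 0.6)
  cells$embed_y <- cy[cells$cluster] + rnorm(nrow(cells), sd = 0.6)

  meta <- cells %>%
    select("barcode", "sample_id", "tissue", "condition", "cluster",
           "embed_x", "embed_y")

  # --- contig tables -------------------------------------------------------
  contigs <- lapply(split(cells, cells$sample_id), build_contigs,
                    config = config)
  contigs <- contigs[samples$sample_id]

  # --- HLA typing ----------------------------------------------------------
  class1 <- config$hla_pool[hla_class(config$hla_pool) == "I"]
  class2 <- config$hla_pool[hla_class(config$hla_pool) == "II"]
  hla <- bind_rows(lapply(samples$sample_id, function(s) {
    tibble(sample_id = s,
           allele = c(sample(class1, config$n_class1_per_sample),
                      sample(class2, config$n_class2_per_sample)))
  }))
  for (pl in config$planted_links) {
    hosts <- unique(motif_df$sample_id[motif_df$family ==
                                         paste0("F", pl$group)])
    hla <- bind_rows(hla, tibble(sample_id = hosts, allele = pl$allele))
  }
  hla <- hla %>% distinct(.data$sample_id, .data$allele) %>%
    arrange(.data$sample_id, .data$allele)

  # --- binding table -------------------------------------------------------
  binding <- build_binding_table(config)

  # --- ground truth --------------------------------------------------------
  truth <- list(
    seed = config$seed,
    clonotypes = cells %>%
      filter(!is.na(.data$clone_uid)) %>%
      select("barcode", "sample_id", true_clonotype = "clone_uid",
             "alpha_cdr3", "beta_cdr3"),
    clone_sizes = registry %>%
      select("clone_uid", "sample_id", "size", "kind"),
    groups = motif_df %>%
      left_join(select(samples, "sample_id", "tissue", "condition"),
                by = "sample_id") %>%
      select("family", cdr3 = "beta_cdr3", v_gene = "beta_v",
             "sample_id", "tissue", "condition"),
    spans = if (nrow(lineage_df)) {
      lineage_df %>%
        left_join(select(registry, "span_id", "alpha_cdr3", "beta_cdr3"),
                  by = "span_id") %>%
        mutate(clusters = vapply(.data$clusters, paste,
                                 character(1), collapse = ",")) %>%
        select("span_id", "sample_id", "size", "clusters",
               "alpha_cdr3", "beta_cdr3")
    } else tibble(),
    links = true_links(motif_df, hla),
    span_targets = unique(unlist(lapply(config$lineage_plants,
                                        function(p) list(p$clusters)),
                          recursive = FALSE))
  )

  list(samples = samples, contigs = contigs, meta = meta, hla = hla,
       proteins = config$proteins, binding = binding, truth = truth,
       config = config)
}

# Every (family, allele) pair where all host samples carry the allele and at
# least two samples host the family — the exhaustive containment truth.
true_links <- function(motif_df, hla) {
  if (nrow(motif_df) == 0) {
    return(tibble(family = character(), allele = character(),
                  n_shared = integer(), shared_samples = character()))
  }
  carriers <- split(hla$sample_id, hla$allele)
  fams <- split(motif_df$sample_id, motif_df$family)
  rows <- lapply(names(fams), function(f) {
    hosts <- sort(unique(fams[[f]]))
    if (length(hosts) < 2) return(NULL)
    alleles <- names(carriers)[vapply(carriers,
                                      function(cs) all(hosts %in% cs),
                                      logical(1))]
    if (length(alleles) == 0) return(NULL)
    tibble(family = f, allele = alleles, n_shared = length(hosts),
           shared_samples = paste(hosts, collapse = ";"))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(family = character(), allele = character(),
                  n_shared = integer(), shared_samples = character()))
  }
  arrange(out, .data$family, .data$allele)
}

build_contigs <- function(sample_cells, config) {
  ab <- sample_cells %>% filter(!is.na(.data$clone_uid))
  gd <- sample_cells %>% filter(is.na(.data$clone_uid))
  rows <- list()
  if (nrow(ab)) {
    umis_a <- 3L + rpois(nrow(ab), 4)
    umis_b <- 3L + rpois(nrow(ab), 6)
    rows$tra <- tibble(
      barcode = ab$barcode, is_cell = "True",
      contig_id = paste0(ab$barcode, "_contig_1"), chain = "TRA",
      v_gene = ab$alpha_v, d_gene = "None", j_gene = ab$alpha_j,
      cdr3 = ab$alpha_cdr3, cdr3_nt = aa_to_nt(ab$alpha_cdr3),
      productive = "True", umis = umis_a)
    rows$trb <- tibble(
      barcode = ab$barcode, is_cell = "True",
      contig_id = paste0(ab$barcode, "_contig_2"), chain = "TRB",
      v_gene = ab$beta_v, d_gene = "TRBD1", j_gene = ab$beta_j,
      cdr3 = ab$beta_cdr3, cdr3_nt = aa_to_nt(ab$beta_cdr3),
      productive = "True", umis = umis_b)
    # secondary low-UMI beta contigs exercising the tie-break
    n_extra <- round(config$second_contig_frac * nrow(ab))
    if (n_extra > 0) {
      pick <- sample.int(nrow(ab), n_extra)
      extra_cdr3 <- rand_cdr3(n_extra, config$cdr3_lengths,
                              config$cdr3_length_weights,
                              avoid = c(ab$beta_cdr3, ab$alpha_cdr3))
      rows$extra <- tibble(
        barcode = ab$barcode[pick], is_cell = "True",
        contig_id = paste0(ab$barcode[pick], "_contig_3"), chain = "TRB",
        v_gene = sample(sprintf("TRBV%d", 1:30), n_extra, replace = TRUE),
        d_gene = "TRBD1", j_gene = "TRBJ1-1", cdr3 = extra_cdr3,
        cdr3_nt = aa_to_nt(extra_cdr3), productive = "True",
        umis = 1L)
    }
  }
  if (nrow(gd)) {
    gd_cdr3g <- rand_cdr3(nrow(gd), 10:14, rep(1, 5), avoid = character(0))
    gd_cdr3d <- rand_cdr3(nrow(gd), 10:14, rep(1, 5), avoid = character(0))
    rows$trg <- tibble(
      barcode = gd$barcode, is_cell = "True",
      contig_id = paste0(gd$barcode, "_contig_1"), chain = "TRG",
      v_gene = "TRGV9", d_gene = "None", j_gene = "TRGJ1",
      cdr3 = gd_cdr3g, cdr3_nt = aa_to_nt(gd_cdr3g),
      productive = "True", umis = 3L + rpois(nrow(gd), 3))
    rows$trd <- tibble(
      barcode = gd$barcode, is_cell = "True",
      contig_id = paste0(gd$barcode, "_contig_2"), chain = "TRD",
      v_gene = "TRDV2", d_gene = "TRDD3", j_gene = "TRDJ1",
      cdr3 = gd_cdr3d, cdr3_nt = aa_to_nt(gd_cdr3d),
      productive = "True", umis = 3L + rpois(nrow(gd), 3))
  }
  bind_rows(rows) %>% arrange(.data$barcode, .data$contig_id)
}

build_binding_table <- function(config) {
  planted <- bind_rows(lapply(config$planted_binders, function(pb) {
    tibble(peptide = pb$peptide, allele = pb$allele,
           score = 0.9, rank_percent = 0.5, binder = TRUE)
  }))
  class1 <- config$hla_pool[hla_class(config$hla_pool) == "I"]
  class2 <- config$hla_pool[hla_class(config$hla_pool) == "II"]
  pep9 <- window_peptides(config$proteins, 9)$peptide
  pep15 <- window_peptides(config$proteins, 15)$peptide
  n <- config$n_decoy_binding_rows
  decoys <- tibble(
    peptide = c(sample(pep9, ceiling(n / 2), replace = TRUE),
                sample(pep15, floor(n / 2), replace = TRUE)),
    allele = c(sample(class1, ceiling(n / 2), replace = TRUE),
               sample(class2, floor(n / 2), replace = TRUE)),
    score = round(runif(n, 0, 0.3), 4),
    rank_percent = round(runif(n, 10, 90), 2),
    binder = FALSE)
  bind_rows(planted, decoys) %>%
    distinct(.data$peptide, .data$allele, .keep_all = TRUE) %>%
    arrange(.data$allele, .data$peptide)
}

write_sim_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(bundle$contigs)) {
    readr::write_csv(bundle$contigs[[s]],
                     file.path(outdir, paste0(s, "_contigs.csv")))
  }
  readr::write_tsv(bundle$meta, file.path(outdir, "meta.tsv"))
  readr::write_tsv(bundle$hla, file.path(outdir, "hla_typing.tsv"))
  aa <- Biostrings::AAStringSet(
    stats::setNames(bundle$proteins$sequence,
                    paste(bundle$proteins$accession,
                          bundle$proteins$source_tag)))
  Biostrings::writeXStringSet(aa, file.path(outdir, "proteins.fasta"))
  readr::write_tsv(bundle$binding, file.path(outdir, "binding.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Recovery report against ground truth
#'
#' Compares pipeline outputs with the generator's ground truth: exact
#' clonotype partition recovery, exact membership recovery of planted motif
#' families, planted multi-cluster clonotypes, and (family, allele) links,
#' plus effect-direction checks for diversity and expansion.
#'
#' @param truth `truth` element of a [simulate_repertoire()] bundle.
#' @param cells Annotated cell tibble recovered by the pipeline.
#' @param clonotypes Clonotype tibble from [call_clonotypes()].
#' @param groups Membership tibble from [build_specificity_groups()].
#' @param spans Output of [shared_clonotypes()] for the planted target set.
#' @param links Output of [link_groups_to_alleles()].
#' @return Named list of recovery rates (1 = perfect) and direction checks.
#' @export
evaluate_recovery <- function(truth, cells, clonotypes, groups, spans,
                              links) {
  # clonotypes: every true clonotype's cell set is exactly one recovered one
  truth_cl <- as_tibble(truth$clonotypes)
  rec <- cells %>% filter(!is.na(.data$clonotype_id)) %>%
    select("barcode", "sample_id", "clonotype_id")
  cmp <- truth_cl %>%
    left_join(rec, by = c("barcode", "sample_id"))
  by_true <- split(cmp$clonotype_id, cmp$true_clonotype)
  by_rec <- split(cmp$true_clonotype, cmp$clonotype_id)
  rec_pure <- vapply(by_rec, function(x) length(unique(x)) == 1, logical(1))
  clonotype_recovery <- mean(vapply(by_true, function(x) {
    if (anyNA(x) || length(unique(x)) != 1) return(FALSE)
    isTRUE(rec_pure[[x[1]]])
  }, logical(1)))

  # groups: exact member-set recovery
  truth_groups <- as_tibble(truth$groups)
  truth_sets <- lapply(split(truth_groups, truth_groups$family), function(g) {
    sort(paste(g$cdr3, strip_allele(g$v_gene), g$sample_id))
  })
  rec_sets <- lapply(split(groups, groups$group_id), function(g) {
    sort(paste(g$cdr3, strip_allele(g$v_gene), g$sample_id))
  })
  group_recall <- if (length(truth_sets)) {
    mean(vapply(truth_sets, function(ts) {
      any(vapply(rec_sets, identical, logical(1), ts))
    }, logical(1)))
  } else NA_real_
  group_precision <- if (length(rec_sets)) {
    mean(vapply(rec_sets, function(rs) {
      any(vapply(truth_sets, identical, logical(1), rs))
    }, logical(1)))
  } else NA_real_

  # spans: recovered clonotype keys vs planted
  truth_spans <- as_tibble(truth$spans)
  truth_keys <- if (nrow(truth_spans)) {
    paste(truth_spans$alpha_cdr3, truth_spans$beta_cdr3)
  } else character(0)
  rec_keys <- if (nrow(spans)) {
    key_map <- clonotypes %>%
      mutate(key = paste(.data$alpha_cdr3, .data$beta_cdr3))
    key_map$key[match(spans$clonotype_id, key_map$clonotype_id)]
  } else character(0)
  span_recall <- if (length(truth_keys)) {
    mean(truth_keys %in% rec_keys)
  } else NA_real_
  span_precision <- if (length(rec_keys)) {
    mean(rec_keys %in% truth_keys)
  } else NA_real_

  # links: recovered (group, allele) mapped to families
  truth_links <- as_tibble(truth$links)
  fam_of_group <- vapply(names(rec_sets), function(gid) {
    hit <- vapply(truth_sets, identical, logical(1), rec_sets[[gid]])
    if (any(hit)) names(truth_sets)[which(hit)[1]] else NA_character_
  }, character(1))
  rec_link_keys <- if (nrow(links)) {
    paste(fam_of_group[links$group_id], links$allele)
  } else character(0)
  truth_link_keys <- if (nrow(truth_links)) {
    paste(truth_links$family, truth_links$allele)
  } else character(0)
  link_recall <- if (length(truth_link_keys)) {
    mean(truth_link_keys %in% rec_link_keys)
  } else NA_real_
  link_precision <- if (length(rec_link_keys)) {
    mean(rec_link_keys %in% truth_link_keys)
  } else NA_real_

  # effect directions
  blood <- cells %>% filter(.data$tissue == "blood")
  d50_tbl <- sample_d50(blood)
  cond <- blood %>% distinct(.data$sample_id, .data$condition)
  d50_tbl <- d50_tbl %>% left_join(cond, by = "sample_id")
  d50_direction <- median(d50_tbl$d50[d50_tbl$condition == "PD"]) <
    median(d50_tbl$d50[d50_tbl$condition == "HC"])
  exp_frac <- blood %>% filter(!is.na(.data$clone_size)) %>%
    group_by(.data$condition) %>%
    summarise(f = mean(.data$clone_size >= 2), .groups = "drop")
  expansion_direction <-
    exp_frac$f[exp_frac$condition == "PD"] >
    exp_frac$f[exp_frac$condition == "HC"]

  list(clonotype_recovery = clonotype_recovery,
       group_recall = group_recall, group_precision = group_precision,
       span_recall = span_recall, span_precision = span_precision,
       link_recall = link_recall, link_precision = link_precision,
       d50_direction_pd_lower = d50_direction,
       expansion_direction_pd_higher = expansion_direction)
}
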