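# End-to-end pipeline: simulate (or read) an input bundle, run every
# analysis stage, and write deterministic tabular outputs.

#' Run the full repertoire pipeline on a simulated bundle
#'
#' Simulates an input bundle from `config`, writes it under
#' `file.path(out_dir, "inputs")`, reads it back through the package's own
#' readers, and runs the complete analysis chain: chain pairing, clonotype
#' calling, per-sample D50 and diversity comparison, clone-size spectra and
#' strata, the downsampling expansion comparison, per-cluster Fisher
#' enrichment, specificity grouping with the PD-specific screen,
#' multi-cluster spanning clonotypes, clonotype centroids, grid composition,
#' and HLA/peptide linkage. All outputs are written as TSV plus a
#' `summary.json`; given the same `config` (including its seed) the output
#' files are byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param n_iter Downsampling iterations (default 100).
#' @param min_shared Minimum shared samples for group-allele links.
#' @param rank_threshold Rank-percent cutoff passed to [attach_peptides()].
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), n_iter = 100,
                         min_shared = 2, rank_threshold = 0) {
  input_dir <- file.path(out_dir, "inputs")
  bundle <- simulate_repertoire(config, outdir = input_dir)

  contig_files <- file.path(input_dir,
                            paste0(bundle$samples$sample_id, "_contigs.csv"))
  contigs <- bind_rows(mapply(read_contigs, contig_files,
                              bundle$samples$sample_id,
                              SIMPLIFY = FALSE))
  meta <- read_cell_meta(file.path(input_dir, "meta.tsv"))
  cells <- pair_chains(contigs, meta)
  clonotypes <- call_clonotypes(cells)
  cells <- annotate_clonotypes(cells, clonotypes)

  d50_tbl <- sample_d50(cells) %>%
    left_join(distinct(meta, .data$sample_id, .data$tissue,
                       .data$condition), by = "sample_id")
  blood <- d50_tbl %>% filter(.data$tissue == "blood")
  diversity_test <- compare_diversity(blood$d50, blood$condition)

  blood_cells <- cells %>% filter(.data$tissue == "blood")
  ds <- downsample_compare(
    blood_cells %>% filter(.data$condition == "PD"),
    blood_cells %>% filter(.data$condition == "HC"),
    n_iter = n_iter, seed = config$seed)

  spectrum_pd <- clone_size_spectrum(
    blood_cells %>% filter(.data$condition == "PD"))
  spectrum_hc <- clone_size_spectrum(
    blood_cells %>% filter(.data$condition == "HC"))
  strata <- strata_percentages(cells)
  enrichment <- cluster_expansion_enrichment(blood_cells)
  composition <- composition_by_clone_size(cells)

  groups <- build_specificity_groups(beta_tcrs(cells))
  pd_groups <- screen_pd_specific(groups)

  span_targets <- bundle$truth$span_targets
  spans <- if (length(span_targets)) {
    shared_clonotypes(cells, span_targets[[1]])
  } else tibble()
  centroids <- clonotype_centroids(cells)
  grid <- grid_composition(cells, k = 10)

  hla <- read_hla_typing(file.path(input_dir, "hla_typing.tsv"))
  binding <- read_binding_table(file.path(input_dir, "binding.tsv"))
  proteins <- read_proteins(file.path(input_dir, "proteins.fasta"))
  links_all <- link_groups_to_alleles(groups, hla, min_shared = min_shared)
  links_all <- attach_peptides(links_all, binding,
                               rank_threshold = rank_threshold)
  links <- links_all %>%
    filter(.data$group_id %in% unique(pd_groups$group_id))

  recovery <- evaluate_recovery(bundle$truth, cells, clonotypes, groups,
                                spans, links_all)

  # ---- deterministic outputs ---------------------------------------------
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  write_clonotypes(cells, clonotypes, file.path(res_dir, "clonotypes.tsv"))
  readr::write_tsv(d50_tbl, file.path(res_dir, "d50.tsv"))
  readr::write_tsv(tibble(iteration = seq_along(ds$p_values),
                          p_value = ds$p_values),
                   file.path(res_dir, "downsampling_iterations.tsv"))
  readr::write_tsv(bind_rows(mutate(spectrum_pd, condition = "PD"),
                             mutate(spectrum_hc, condition = "HC")),
                   file.path(res_dir, "clone_size_spectrum.tsv"))
  readr::write_tsv(strata, file.path(res_dir, "strata.tsv"))
  readr::write_tsv(enrichment, file.path(res_dir, "enrichment.tsv"))
  readr::write_tsv(composition, file.path(res_dir, "composition.tsv"))
  readr::write_tsv(groups, file.path(res_dir, "specificity_groups.tsv"))
  spans_flat <- if (nrow(spans)) {
    spans %>% mutate(clusters = vapply(.data$clusters, paste, character(1),
                                       collapse = ","))
  } else tibble(clonotype_id = character(), n_cells = integer(),
                clusters = character())
  readr::write_tsv(spans_flat, file.path(res_dir, "spanning_clonotypes.tsv"))
  readr::write_tsv(centroids, file.path(res_dir, "clonotype_centroids.tsv"))
  readr::write_tsv(grid, file.path(res_dir, "grid_composition.tsv"))
  readr::write_tsv(links, file.path(res_dir, "tcr_hla_links.tsv"))

  summary <- list(
    seed = config$seed,
    n_cells = nrow(cells),
    n_clonotypes = nrow(clonotypes),
    n_expanded_clonotypes = sum(clonotypes$size >= 2),
    diversity_test = as.list(diversity_test),
    downsampling_median_p = ds$median_p,
    downsampling_n_draw = ds$n_draw,
    n_specificity_groups = dplyr::n_distinct(groups$group_id),
    n_pd_specific_groups = dplyr::n_distinct(pd_groups$group_id),
    n_spanning_clonotypes = nrow(spans),
    n_links = nrow(links),
    top_enriched_cluster = enrichment$cluster[1],
    top_enriched_fdr = enrichment$fdr[1],
    recovery = recovery)
  jsonlite::write_json(summary, file.path(res_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(bundle = bundle, cells = cells, clonotypes = clonotypes,
                 d50 = d50_tbl, diversity_test = diversity_test,
                 downsampling = ds, strata = strata,
                 enrichment = enrichment, composition = composition,
                 groups = groups, pd_groups = pd_groups, spans = spans,
                 centroids = centroids, grid = grid, links = links,
                 recovery = recovery, summary = summary))
}
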