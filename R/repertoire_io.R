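# Reading single-cell V(D)J contig tables, pairing chains per cell, and
# calling paired-chain clonotypes pooled across samples.

#' Read a Cell Ranger-style filtered contig annotation table
#'
#' Reads one sample's `filtered_contig_annotations.csv` (or any delimited
#' table in that dialect) and returns one row per contig. Mandatory columns
#' are `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3` and `productive`;
#' extra columns are ignored, `cdr3_nt` and `umis` are carried through when
#' present.
#'
#' @param path Path to a CSV/TSV contig annotation file.
#' @param sample_id Sample identifier attached to every contig from this file.
#' @param require_productive Drop contigs whose `productive` flag is false or
#'   `"None"` (default `TRUE`). Productive contigs with a CDR3 outside the
#'   20-letter amino-acid alphabet (e.g. `"None"`) are also dropped, with a
#'   warning.
#'
#' @return A tibble with columns `barcode`, `sample_id`, `chain`, `cdr3`,
#'   `cdr3_nt`, `v_gene`, `j_gene`, `productive`, `umis`.
#' @export
read_contigs <- function(path, sample_id, require_productive = TRUE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive")
  assert_columns(df, required, what = sprintf("contig file '%s'", path))
  if (nrow(df) == 0) {
    warning(sprintf("contig file '%s' contains no rows", path), call. = FALSE)
  }
  out <- tibble(
    barcode = df$barcode,
    sample_id = sample_id,
    chain = df$chain,
    cdr3 = toupper(df$cdr3),
    cdr3_nt = if ("cdr3_nt" %in% names(df)) toupper(df$cdr3_nt) else NA_character_,
    v_gene = df$v_gene,
    j_gene = df$j_gene,
    productive = tolower(df$productive) %in% c("true", "t", "1", "yes"),
    umis = if ("umis" %in% names(df)) {
      u <- suppressWarnings(as.integer(df$umis))
      ifelse(is.na(u), 1L, u)
    } else 1L
  )
  if (require_productive) {
    out <- out[out$productive, , drop = FALSE]
    bad <- !is_valid_aa(out$cdr3)
    if (any(bad)) {
      warning(sprintf(
        "dropping %d productive contig(s) with non-amino-acid CDR3 in '%s'",
        sum(bad), path), call. = FALSE)
      out <- out[!bad, , drop = FALSE]
    }
  }
  out
}

#' Read a per-cell metadata table
#'
#' Tab-separated table with one row per cell: `barcode`, `sample_id`,
#' `tissue` (`blood`/`CSF`), `condition` (`PD`/`HC`) and optional `cluster`,
#' `embed_x`, `embed_y` (2-D embedding or trajectory coordinates).
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with one validated row per cell.
#' @export
read_cell_meta <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("barcode", "sample_id", "tissue", "condition"),
                 what = sprintf("metadata file '%s'", path))
  if (anyDuplicated(df[c("barcode", "sample_id")]) > 0) {
    stop("metadata contains duplicate (barcode, sample_id) pairs", call. = FALSE)
  }
  if (!all(df$tissue %in% c("blood", "CSF"))) {
    stop("metadata 'tissue' must be one of: blood, CSF", call. = FALSE)
  }
  if (!all(df$condition %in% c("PD", "HC"))) {
    stop("metadata 'condition' must be one of: PD, HC", call. = FALSE)
  }
  if (!"cluster" %in% names(df)) df$cluster <- NA_character_
  has_x <- "embed_x" %in% names(df)
  has_y <- "embed_y" %in% names(df)
  if (has_x != has_y) {
    stop("metadata must contain both embed_x and embed_y, or neither",
         call. = FALSE)
  }
  if (!has_x) {
    df$embed_x <- NA_real_
    df$embed_y <- NA_real_
  }
  as_tibble(df[c("barcode", "sample_id", "tissue", "condition",
                 "cluster", "embed_x", "embed_y")])
}

#' Pair TCR chains per cell
#'
#' Collapses contigs to one cell per `(barcode, sample_id)`, keeping at most
#' one TRA and one TRB contig. When several contigs of the same chain compete
#' within one cell, the one with the highest UMI count is kept; ties go to the
#' longer CDR3, then to the lexicographically smallest CDR3, so the result is
#' deterministic. Cells whose contigs are all gamma/delta (TRG/TRD) are kept
#' with both alpha and beta absent — the "NA" stratum of cells with no
#' alpha-beta receptor detected.
#'
#' @param contigs Contig tibble from [read_contigs()] (one or several samples
#'   row-bound together).
#' @param meta Cell metadata from [read_cell_meta()].
#' @param unannotated What to do with cells absent from `meta`: `"error"`
#'   (default) or `"drop"`.
#'
#' @return A tibble with one row per cell: chain CDR3s and V/J genes (`NA`
#'   when the chain is absent), `has_pair` (both chains present), and the
#'   metadata columns.
#' @export
pair_chains <- function(contigs, meta, unannotated = c("error", "drop")) {
  unannotated <- match.arg(unannotated)
  assert_columns(contigs, c("barcode", "sample_id", "chain", "cdr3",
                            "v_gene", "j_gene", "umis"), "contigs")

  best <- contigs %>%
    filter(.data$chain %in% c("TRA", "TRB")) %>%
    arrange(desc(.data$umis), desc(nchar(.data$cdr3)), .data$cdr3) %>%
    distinct(.data$barcode, .data$sample_id, .data$chain, .keep_all = TRUE)

  wide <- best %>%
    select("barcode", "sample_id", "chain", "cdr3", "v_gene", "j_gene") %>%
    pivot_wider(names_from = "chain",
                values_from = c("cdr3", "v_gene", "j_gene"),
                names_glue = "{chain}_{.value}")
  for (col in c("TRA_cdr3", "TRA_v_gene", "TRA_j_gene",
                "TRB_cdr3", "TRB_v_gene", "TRB_j_gene")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }

  all_cells <- distinct(contigs, .data$barcode, .data$sample_id)
  cells <- all_cells %>%
    left_join(wide, by = c("barcode", "sample_id")) %>%
    transmute(
      barcode = .data$barcode,
      sample_id = .data$sample_id,
      alpha_cdr3 = .data$TRA_cdr3, alpha_v = .data$TRA_v_gene,
      alpha_j = .data$TRA_j_gene,
      beta_cdr3 = .data$TRB_cdr3, beta_v = .data$TRB_v_gene,
      beta_j = .data$TRB_j_gene,
      has_pair = !is.na(.data$TRA_cdr3) & !is.na(.data$TRB_cdr3)
    )

  matched <- cells %>% inner_join(meta, by = c("barcode", "sample_id"))
  n_missing <- nrow(cells) - nrow(matched)
  if (n_missing > 0) {
    if (unannotated == "error") {
      stop(sprintf("%d cell(s) have no metadata row; use unannotated = 'drop' to discard them",
                   n_missing), call. = FALSE)
    }
    warning(sprintf("dropping %d cell(s) with no metadata row", n_missing),
            call. = FALSE)
  }
  matched
}

#' Call paired-chain clonotypes pooled across samples
#'
#' Cells with identical alpha- and beta-chain CDR3 amino-acid sequences form
#' one clonotype; cells lacking either chain are excluded from calling (they
#' remain available as the NA stratum). Pooling is across all samples and
#' tissues, so one clonotype can span samples. Identifiers are assigned
#' deterministically: `clonotype1` is the largest clonotype, ties broken by
#' the lexicographic (alpha, beta) key.
#'
#' @param cells Cell tibble from [pair_chains()].
#' @return A tibble with one row per clonotype: `clonotype_id`, `alpha_cdr3`,
#'   `beta_cdr3`, `size`, modal `alpha_v`/`beta_v` across member cells, and
#'   `n_samples`.
#' @export
call_clonotypes <- function(cells) {
  eligible <- filter(cells, .data$has_pair)
  if (nrow(eligible) == 0) {
    return(tibble(clonotype_id = character(), alpha_cdr3 = character(),
                  beta_cdr3 = character(), size = integer(),
                  alpha_v = character(), beta_v = character(),
                  n_samples = integer()))
  }
  eligible %>%
    group_by(.data$alpha_cdr3, .data$beta_cdr3) %>%
    summarise(size = n(),
              alpha_v = modal_value(.data$alpha_v),
              beta_v = modal_value(.data$beta_v),
              n_samples = n_distinct(.data$sample_id),
              .groups = "drop") %>%
    arrange(desc(.data$size), .data$alpha_cdr3, .data$beta_cdr3) %>%
    mutate(clonotype_id = paste0("clonotype", row_number())) %>%
    select("clonotype_id", "alpha_cdr3", "beta_cdr3", "size",
           "alpha_v", "beta_v", "n_samples")
}

#' Attach clonotype identity and clone size to cells
#'
#' @param cells Cell tibble from [pair_chains()].
#' @param clonotypes Clonotype tibble from [call_clonotypes()].
#' @return `cells` with `clonotype_id` and `clone_size` columns (`NA` for
#'   cells without a complete alpha-beta pair).
#' @export
annotate_clonotypes <- function(cells, clonotypes) {
  cells %>%
    left_join(select(clonotypes, "alpha_cdr3", "beta_cdr3",
                     "clonotype_id", clone_size = "size"),
              by = c("alpha_cdr3", "beta_cdr3"))
}

#' Per-group clonotype size breakdown
#'
#' Splits each clonotype's size over the levels of a grouping column
#' (`sample_id`, `cluster`, `tissue` or `condition`); the per-group counts of
#' each clonotype sum to its total size.
#'
#' @param cells Annotated cell tibble (see [annotate_clonotypes()]).
#' @param by Name of the grouping column.
#' @return A long tibble `clonotype_id` x group level with column `n`.
#' @export
clonotype_size_by <- function(cells, by = "sample_id") {
  stopifnot(by %in% names(cells))
  cells %>%
    filter(!is.na(.data$clonotype_id)) %>%
    count(.data$clonotype_id, .data[[by]], name = "n")
}

#' Write the clonotype table with wide per-sample counts
#'
#' @param cells Annotated cell tibble.
#' @param clonotypes Clonotype tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(cells, clonotypes, path) {
  wide <- clonotype_size_by(cells, "sample_id") %>%
    pivot_wider(names_from = "sample_id", values_from = "n",
                values_fill = 0L, names_sort = TRUE)
  out <- clonotypes %>% left_join(wide, by = "clonotype_id")
  readr::write_tsv(out, path)
  invisible(path)
}
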