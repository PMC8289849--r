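# Candidate epitopes by sliding windows, and TCR-group <-> HLA <-> peptide
# linkage through sample-set sharing.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Tibble `accession` (first word of the header), `sequence`,
#'   `source_tag` (`alpha_synuclein` / `mitochondrial` when the header
#'   mentions them, else `other`).
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  tag <- dplyr::case_when(
    grepl("alpha[-_ ]?synuclein|alpha_syn", headers, ignore.case = TRUE) ~ "alpha_synuclein",
    grepl("mitochondrial|mito", headers, ignore.case = TRUE) ~ "mitochondrial",
    TRUE ~ "other"
  )
  tibble(
    accession = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1),
    sequence = toupper(as.character(aa)),
    source_tag = tag
  )
}

#' Sliding-window candidate peptides
#'
#' Cuts every protein into all length-`k` windows at stride 1 (the 9-mer /
#' 15-mer candidates presented by MHC class I / class II). Proteins with
#' identical sequences are deduplicated first; windows containing a
#' non-standard residue (e.g. `X`) are dropped; the resulting peptide set is
#' globally deduplicated, each peptide retaining its source accessions.
#'
#' @param proteins Tibble from [read_proteins()] (columns `accession`,
#'   `sequence`).
#' @param k Window length, typically 9 or 15.
#' @return Tibble `peptide`, `accessions` (`;`-separated), `n_sources`.
#' @export
window_peptides <- function(proteins, k) {
  stopifnot(k >= 1)
  assert_columns(proteins, c("accession", "sequence"), "proteins")
  dedup <- proteins %>%
    group_by(.data$sequence) %>%
    summarise(accession = paste(sort(unique(.data$accession)), collapse = ";"),
              .groups = "drop")
  too_short <- nchar(dedup$sequence) < k
  if (any(too_short)) {
    message(sprintf("%d sequence(s) shorter than %d contribute no windows",
                    sum(too_short), k))
    dedup <- dedup[!too_short, , drop = FALSE]
  }
  if (nrow(dedup) == 0) {
    return(tibble(peptide = character(), accessions = character(),
                  n_sources = integer()))
  }
  rows <- lapply(seq_len(nrow(dedup)), function(i) {
    s <- dedup$sequence[i]
    l <- nchar(s)
    tibble(peptide = substring(s, 1:(l - k + 1), k:l),
           accession = dedup$accession[i])
  })
  bind_rows(rows) %>%
    filter(is_valid_aa(.data$peptide)) %>%
    tidyr::separate_longer_delim("accession", ";") %>%
    group_by(.data$peptide) %>%
    summarise(accessions = paste(sort(unique(.data$accession)), collapse = ";"),
              n_sources = n_distinct(.data$accession), .groups = "drop") %>%
    arrange(.data$peptide)
}

#' Normalize an HLA allele name
#'
#' Reduces allele strings to gene plus two-field code without the `*`
#' separator, e.g. `"HLA-A*02:01:01"` and `"A02:01"` both become
#' `"HLA-A02:01"`.
#'
#' @param allele Character vector of allele names.
#' @return Normalized character vector.
#' @export
normalize_hla_allele <- function(allele) {
  x <- gsub("\\*", "", allele)
  x <- ifelse(grepl("^HLA-", x), x, paste0("HLA-", x))
  # keep at most two colon-separated fields
  sub("^([^:]+:[^:]+).*$", "\\1", x)
}

#' MHC class of an HLA allele
#'
#' @param allele Normalized allele names.
#' @return `"I"` for classical class I genes (A/B/C/E/F/G), `"II"` for
#'   D-genes (DRB1, DQA1/DQB1, DPA1/DPB1, ...).
#' @export
hla_class <- function(allele) {
  ifelse(grepl("^HLA-D", allele), "II", "I")
}

#' Read a per-sample HLA typing table
#'
#' Tab-separated, columns `sample_id` and `allele`; allele names are
#' normalized with [normalize_hla_allele()].
#'
#' @param path Path to the typing TSV.
#' @return Tibble `sample_id`, `allele` (one row per carried allele).
#' @export
read_hla_typing <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("sample_id", "allele"),
                 what = sprintf("HLA typing file '%s'", path))
  df %>%
    mutate(allele = normalize_hla_allele(.data$allele)) %>%
    distinct(.data$sample_id, .data$allele)
}

#' Read a peptide-allele binding prediction table
#'
#' Tab-separated output of an external MHC binding predictor: columns
#' `peptide`, `allele`, `score`, `rank_percent`, `binder`. Rows whose
#' peptide length does not match the allele class (9-mers with class I,
#' 15-mers with class II) are dropped with a warning.
#'
#' @param path Path to the binding TSV.
#' @return Tibble with normalized alleles and logical `binder`.
#' @export
read_binding_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("peptide", "allele", "score", "rank_percent", "binder"),
                 what = sprintf("binding file '%s'", path))
  out <- df %>%
    mutate(allele = normalize_hla_allele(.data$allele),
           binder = tolower(as.character(.data$binder)) %in%
             c("true", "t", "1", "yes"))
  ok <- (nchar(out$peptide) == 9 & hla_class(out$allele) == "I") |
    (nchar(out$peptide) == 15 & hla_class(out$allele) == "II")
  if (any(!ok)) {
    warning(sprintf("dropping %d binding row(s) with peptide length / MHC class mismatch",
                    sum(!ok)), call. = FALSE)
    out <- out[ok, , drop = FALSE]
  }
  out
}

#' Link TCR specificity groups to HLA alleles by sample sharing
#'
#' A group is linked to an allele when every sample contributing a TCR to
#' the group carries that allele, and the group's sample set (restricted to
#' typed samples) has at least `min_shared` samples. This is the
#' sample-overlap construction: receptors converging across patients who
#' share an HLA allotype plausibly recognize a peptide presented by it.
#'
#' @param groups Membership tibble from [build_specificity_groups()].
#' @param typing Tibble from [read_hla_typing()].
#' @param min_shared Minimum number of (typed) samples in the group
#'   (default 2).
#' @return Tibble `group_id`, `allele`, `n_shared`, `shared_samples`
#'   (`;`-separated sample ids).
#' @export
link_groups_to_alleles <- function(groups, typing, min_shared = 2) {
  assert_columns(groups, c("group_id", "sample_id"), "groups")
  assert_columns(typing, c("sample_id", "allele"), "typing")
  typed <- unique(typing$sample_id)
  sample_sets <- groups %>%
    distinct(.data$group_id, .data$sample_id) %>%
    filter(.data$sample_id %in% typed)
  skipped <- setdiff(unique(groups$group_id), unique(sample_sets$group_id))
  if (length(skipped) > 0) {
    warning(sprintf("skipping %d group(s) with no typed samples: %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  carriers <- split(typing$sample_id, typing$allele)
  rows <- sample_sets %>%
    group_by(.data$group_id) %>%
    summarise(samples = list(sort(unique(.data$sample_id))),
              .groups = "drop")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    ss <- rows$samples[[i]]
    if (length(ss) < min_shared) return(NULL)
    alleles <- names(carriers)[vapply(carriers,
                                      function(cs) all(ss %in% cs),
                                      logical(1))]
    if (length(alleles) == 0) return(NULL)
    tibble(group_id = rows$group_id[i], allele = alleles,
           n_shared = length(ss),
           shared_samples = paste(ss, collapse = ";"))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(group_id = character(), allele = character(),
                  n_shared = integer(), shared_samples = character()))
  }
  arrange(out, .data$group_id, .data$allele)
}

#' Attach candidate peptides to group-allele links
#'
#' For each link, attaches the peptides the external predictor calls binders
#' for that allele (`binder` true, or `rank_percent <= rank_threshold` when a
#' positive threshold is given). Links whose allele is missing from the
#' binding table, or that gain no peptide, are retained and flagged.
#'
#' @param links Tibble from [link_groups_to_alleles()].
#' @param binding Tibble from [read_binding_table()].
#' @param rank_threshold Positive rank-percent cutoff, or 0 (default) to use
#'   the `binder` flag alone.
#' @return `links` with `peptides` (`;`-separated), `n_peptides`,
#'   `allele_in_binding`, `has_peptides`.
#' @export
attach_peptides <- function(links, binding, rank_threshold = 0) {
  assert_columns(links, c("group_id", "allele"), "links")
  assert_columns(binding, c("peptide", "allele", "rank_percent", "binder"),
                 "binding")
  hits <- binding %>%
    filter(.data$binder |
             (rank_threshold > 0 & .data$rank_percent <= rank_threshold)) %>%
    group_by(.data$allele) %>%
    summarise(peptides = paste(sort(unique(.data$peptide)), collapse = ";"),
              n_peptides = n_distinct(.data$peptide), .groups = "drop")
  links %>%
    left_join(hits, by = "allele") %>%
    mutate(allele_in_binding = .data$allele %in% unique(binding$allele),
           n_peptides = ifelse(is.na(.data$n_peptides), 0L, .data$n_peptides),
           peptides = ifelse(is.na(.data$peptides), "", .data$peptides),
           has_peptides = .data$n_peptides > 0)
}
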