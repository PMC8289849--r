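# Clonal expansion statistics: clone-size spectra, downsampling comparison,
# clone-size strata, per-cluster Fisher enrichment, mean clone size.

#' Clone-size spectrum
#'
#' Tabulates how many clonotypes have each clone size *within* the supplied
#' cell subset: sizes are recomputed on the subset by regrouping cells on
#' their (alpha, beta) CDR3 key, so a pooled clonotype with only two cells in
#' the subset contributes to size 2.
#'
#' @param cells Cell tibble (any subset); only cells with a complete
#'   alpha-beta pair contribute.
#' @return Tibble `clone_size`, `n_clonotypes`, sorted by size.
#' @export
clone_size_spectrum <- function(cells) {
  eligible <- filter(cells, .data$has_pair)
  if (nrow(eligible) == 0) {
    return(tibble(clone_size = integer(), n_clonotypes = integer()))
  }
  key <- paste(eligible$alpha_cdr3, eligible$beta_cdr3, sep = "_")
  spec <- spectrum_from_keys(key)
  tibble(clone_size = as.integer(names(spec)),
         n_clonotypes = as.integer(spec)) %>%
    arrange(.data$clone_size)
}

# named integer vector: clone size -> number of clonotypes
spectrum_from_keys <- function(key) {
  table(table(key))
}

#' Downsampling comparison of clone-size distributions
#'
#' Compares clonal expansion between two cell groups while controlling for
#' the number of detected cells: in each of `n_iter` iterations,
#' `min(|A|, |B|)` cells are drawn without replacement from each group,
#' clonotype sizes are recomputed within each draw, the number of clonotypes
#' per clone size is tabulated over the union of sizes observed in either
#' draw (absent sizes count 0), and the two tabulations are compared with a
#' two-sided paired Wilcoxon signed-rank test across the matched clone-size
#' bins. Iterations where every matched bin is identical return p = 1;
#' iterations with fewer than two bins are recorded as `NA` and excluded
#' from the median, with a warning.
#'
#' Reproducibility: the draw for each (iteration, group) uses an RNG
#' substream derived from the root seed, the iteration index, and a content
#' hash of the group's clonotype keys — so results are bit-identical for the
#' same inputs and seed, and symmetric under swapping the two groups.
#'
#' @param cells_a,cells_b Cell tibbles for the two groups (only cells with a
#'   complete alpha-beta pair are used).
#' @param n_iter Number of downsampling iterations (default 100).
#' @param seed Root seed for the iteration substreams.
#' @param log_counts Compare `log1p` of the per-bin clonotype counts instead
#'   of raw counts (default `FALSE`).
#' @return List with `median_p`, `p_values` (length `n_iter`), `n_draw` (the
#'   per-group draw size) and `n_iter`.
#' @export
downsample_compare <- function(cells_a, cells_b, n_iter = 100, seed = 17,
                               log_counts = FALSE) {
  stopifnot(n_iter >= 1)
  key_a <- clonotype_keys(cells_a)
  key_b <- clonotype_keys(cells_b)
  if (length(key_a) == 0 || length(key_b) == 0) {
    stop("both groups must contain cells with a complete alpha-beta pair",
         call. = FALSE)
  }
  m <- min(length(key_a), length(key_b))
  hash_a <- content_hash(key_a)
  hash_b <- content_hash(key_b)

  p_values <- vapply(seq_len(n_iter), function(i) {
    draw_a <- with_seed(derive_seed(seed, i, hash_a),
                        sample.int(length(key_a), m))
    draw_b <- with_seed(derive_seed(seed, i, hash_b),
                        sample.int(length(key_b), m))
    spec_a <- spectrum_from_keys(key_a[draw_a])
    spec_b <- spectrum_from_keys(key_b[draw_b])
    sizes <- sort(unique(as.integer(c(names(spec_a), names(spec_b)))))
    if (length(sizes) < 2) return(NA_real_)
    va <- as.numeric(spec_a[as.character(sizes)])
    vb <- as.numeric(spec_b[as.character(sizes)])
    va[is.na(va)] <- 0
    vb[is.na(vb)] <- 0
    if (log_counts) {
      va <- log1p(va)
      vb <- log1p(vb)
    }
    if (all(va == vb)) return(1)
    suppressWarnings(wilcox.test(va, vb, paired = TRUE,
                                 alternative = "two.sided")$p.value)
  }, numeric(1))

  n_na <- sum(is.na(p_values))
  if (n_na > 0) {
    warning(sprintf("%d iteration(s) had fewer than 2 clone-size bins and were excluded",
                    n_na), call. = FALSE)
  }
  list(median_p = median(p_values, na.rm = TRUE),
       p_values = p_values, n_draw = m, n_iter = n_iter)
}

clonotype_keys <- function(cells) {
  eligible <- filter(cells, .data$has_pair)
  paste(eligible$alpha_cdr3, eligible$beta_cdr3, sep = "_")
}

#' Per-sample clone-size strata percentages
#'
#' For each sample, the percentage of cells falling in the clone-size strata
#' NA (no complete alpha-beta receptor detected), = 1, >= 2, >= 20 and
#' >= 100 cells. Both views are returned: the cumulative strata as printed
#' (>= 2 includes >= 20 includes >= 100) and disjoint bands (1, 2-19, 20-99,
#' >= 100) which, together with NA, sum to 100% per sample.
#'
#' Clone sizes are the pooled clonotype sizes carried in `clone_size`
#' (see [annotate_clonotypes()]).
#'
#' @param cells Annotated cell tibble.
#' @return Tibble `sample_id`, `view` (`"cumulative"`/`"disjoint"`),
#'   `stratum`, `n_cells`, `percent`.
#' @export
strata_percentages <- function(cells) {
  per_sample <- split(cells, cells$sample_id)
  rows <- lapply(names(per_sample), function(s) {
    cs <- per_sample[[s]]
    sz <- ifelse(cs$has_pair, cs$clone_size, NA_integer_)
    total <- length(sz)
    cum <- c("NA" = sum(is.na(sz)),
             "=1" = sum(!is.na(sz) & sz == 1),
             ">=2" = sum(!is.na(sz) & sz >= 2),
             ">=20" = sum(!is.na(sz) & sz >= 20),
             ">=100" = sum(!is.na(sz) & sz >= 100))
    dis <- c("NA" = sum(is.na(sz)),
             "1" = sum(!is.na(sz) & sz == 1),
             "2-19" = sum(!is.na(sz) & sz >= 2 & sz <= 19),
             "20-99" = sum(!is.na(sz) & sz >= 20 & sz <= 99),
             ">=100" = sum(!is.na(sz) & sz >= 100))
    bind_rows(
      tibble(sample_id = s, view = "cumulative", stratum = names(cum),
             n_cells = as.integer(cum)),
      tibble(sample_id = s, view = "disjoint", stratum = names(dis),
             n_cells = as.integer(dis))
    ) %>% mutate(percent = 100 * .data$n_cells / total)
  })
  bind_rows(rows)
}

#' Per-cluster Fisher enrichment of clonally expanded cells
#'
#' Tests, cluster by cluster, whether clonal expansion (clone size >=
#' `expanded_threshold`) is enriched in one condition. Two 2x2 designs are
#' available:
#' \describe{
#'   \item{`condition_by_expanded` (default)}{within each cluster, rows are
#'     condition (PD vs HC) and columns expanded vs non-expanded — tests
#'     whether PD cells in the cluster are more expanded than HC cells.}
#'   \item{`pd_by_cluster`}{restricted to PD cells, rows are in-cluster vs
#'     out-of-cluster and columns expanded vs non-expanded.}
#' }
#' P-values are Benjamini-Hochberg adjusted across the cluster family.
#' A cluster with an empty table margin is flagged degenerate and reported
#' with p = 1 and an `NA` odds ratio.
#'
#' @param cells Annotated cell tibble with `cluster`, `condition` and
#'   `clone_size`; cells without a clonotype or cluster label are ignored.
#' @param design 2x2 construction, see above.
#' @param expanded_threshold Minimum clone size that counts as expanded
#'   (default 2).
#' @return Tibble sorted by `fdr`: `cluster`, the four table cells
#'   (`n_exp_a`, `n_non_a`, `n_exp_b`, `n_non_b` for rows a/b of the design),
#'   `odds_ratio`, `p_value`, `fdr`, `degenerate`.
#' @export
cluster_expansion_enrichment <- function(cells,
                                         design = c("condition_by_expanded",
                                                    "pd_by_cluster"),
                                         expanded_threshold = 2) {
  design <- match.arg(design)
  dat <- cells %>%
    filter(!is.na(.data$clone_size), !is.na(.data$cluster)) %>%
    mutate(expanded = .data$clone_size >= expanded_threshold)
  clusters <- sort(unique(dat$cluster))
  rows <- lapply(clusters, function(cl) {
    if (design == "condition_by_expanded") {
      sub <- dat[dat$cluster == cl, ]
      tab <- matrix(c(sum(sub$condition == "PD" & sub$expanded),
                      sum(sub$condition == "PD" & !sub$expanded),
                      sum(sub$condition == "HC" & sub$expanded),
                      sum(sub$condition == "HC" & !sub$expanded)),
                    nrow = 2, byrow = TRUE)
    } else {
      pd <- dat[dat$condition == "PD", ]
      inside <- pd$cluster == cl
      tab <- matrix(c(sum(inside & pd$expanded),
                      sum(inside & !pd$expanded),
                      sum(!inside & pd$expanded),
                      sum(!inside & !pd$expanded)),
                    nrow = 2, byrow = TRUE)
    }
    ft <- fisher_2x2(tab)
    tibble(cluster = cl,
           n_exp_a = tab[1, 1], n_non_a = tab[1, 2],
           n_exp_b = tab[2, 1], n_non_b = tab[2, 2],
           odds_ratio = ft$odds_ratio, p_value = ft$p_value,
           degenerate = ft$degenerate)
  })
  bind_rows(rows) %>%
    mutate(fdr = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$fdr, .data$cluster)
}

# Two-sided Fisher exact test on a 2x2 table of counts, with a degenerate
# policy for empty margins.
fisher_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       degenerate = FALSE)
}

#' Mean clone size of a cell subset
#'
#' Number of cells divided by the number of distinct clonotypes among them.
#' Either pass an annotated cell tibble, or the two counts directly (useful
#' for published count pairs).
#'
#' @param cells Annotated cell tibble (all cells must be clonotyped), or
#'   `NULL` when counts are given.
#' @param n_cells,n_clonotypes Counts used when `cells` is `NULL`.
#' @return Mean cells per clonotype (unrounded; display at one decimal).
#' @examples
#' mean_clone_size(n_cells = 2301, n_clonotypes = 371)  # 6.2
#' @export
mean_clone_size <- function(cells = NULL, n_cells = NULL, n_clonotypes = NULL) {
  if (!is.null(cells)) {
    if (nrow(cells) == 0) stop("cell subset is empty", call. = FALSE)
    if (any(is.na(cells$clonotype_id))) {
      stop("all cells in the subset must be clonotyped", call. = FALSE)
    }
    n_cells <- nrow(cells)
    n_clonotypes <- n_distinct(cells$clonotype_id)
  }
  stopifnot(is.numeric(n_cells), is.numeric(n_clonotypes))
  if (n_cells <= 0 || n_clonotypes <= 0) {
    stop("cell and clonotype counts must be positive", call. = FALSE)
  }
  n_cells / n_clonotypes
}

#' Cell-type composition by clone-size stratum
#'
#' For each sample and disjoint clone-size stratum (NA, 1, 2-19, 20-99,
#' >= 100), the fraction of cells carrying each cluster label. Fractions sum
#' to 1 within every (sample, stratum) that contains at least one labeled
#' cell.
#'
#' @param cells Annotated cell tibble with `cluster` labels.
#' @return Tibble `sample_id`, `stratum`, `cluster`, `n_cells`, `fraction`.
#' @export
composition_by_clone_size <- function(cells) {
  dat <- cells %>%
    filter(!is.na(.data$cluster)) %>%
    mutate(stratum = clone_size_stratum(ifelse(.data$has_pair,
                                               .data$clone_size,
                                               NA_integer_)))
  dat %>%
    count(.data$sample_id, .data$stratum, .data$cluster, name = "n_cells") %>%
    group_by(.data$sample_id, .data$stratum) %>%
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup()
}

clone_size_stratum <- function(sz) {
  dplyr::case_when(
    is.na(sz) ~ "NA",
    sz == 1 ~ "1",
    sz <= 19 ~ "2-19",
    sz <= 99 ~ "20-99",
    TRUE ~ ">=100"
  )
}
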