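# TCR-sharing lineage evidence: clonotypes spanning cluster sets, clonotype
# centroids in an embedding, and grid-based sample composition.

#' Clonotypes spanning a set of transcriptomic clusters
#'
#' A clonotype spans a target cluster set when its (optionally restricted)
#' cells cover every cluster in the set — TCR-sharing evidence that the
#' clusters lie on one differentiation path.
#'
#' @param cells Annotated cell tibble with `cluster` labels.
#' @param target_clusters Character vector of cluster labels that must all
#'   be covered.
#' @param condition,tissue Optional restriction applied before evaluating
#'   spans (e.g. `condition = "PD"`, `tissue = "blood"`).
#' @return Tibble of spanning clonotypes: `clonotype_id`, `n_cells`,
#'   `clusters` (list column of clusters the clonotype occupies). Empty,
#'   with a warning, when a target cluster is absent from the data.
#' @export
shared_clonotypes <- function(cells, target_clusters,
                              condition = NULL, tissue = NULL) {
  stopifnot(length(target_clusters) >= 1)
  dat <- cells %>% filter(!is.na(.data$clonotype_id), !is.na(.data$cluster))
  if (!is.null(condition)) dat <- dat[dat$condition %in% condition, ]
  if (!is.null(tissue)) dat <- dat[dat$tissue %in% tissue, ]
  absent <- setdiff(target_clusters, unique(dat$cluster))
  if (length(absent) > 0) {
    warning(sprintf("target cluster(s) absent from data: %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
    return(tibble(clonotype_id = character(), n_cells = integer(),
                  clusters = list()))
  }
  dat %>%
    group_by(.data$clonotype_id) %>%
    summarise(n_cells = n(),
              clusters = list(sort(unique(.data$cluster))),
              .groups = "drop") %>%
    filter(vapply(.data$clusters,
                  function(cl) all(target_clusters %in% cl), logical(1))) %>%
    arrange(desc(.data$n_cells), .data$clonotype_id)
}

#' Clonotype centroids in an embedding
#'
#' Each clonotype (optionally stratified by cluster) is placed at the
#' arithmetic mean of its member cells' embedding coordinates.
#'
#' @param cells Annotated cell tibble with `embed_x`/`embed_y`; cells
#'   missing coordinates are excluded with a message.
#' @param stratify_by_cluster One centroid per (clonotype, cluster) when
#'   `TRUE` (default), else one per clonotype.
#' @return Tibble `clonotype_id` (+ `cluster`), `x`, `y`, `size`.
#' @export
clonotype_centroids <- function(cells, stratify_by_cluster = TRUE) {
  dat <- cells %>% filter(!is.na(.data$clonotype_id))
  n_missing <- sum(is.na(dat$embed_x) | is.na(dat$embed_y))
  if (n_missing > 0) {
    message(sprintf("excluding %d cell(s) without embedding coordinates",
                    n_missing))
    dat <- dat %>% filter(!is.na(.data$embed_x), !is.na(.data$embed_y))
  }
  keys <- if (stratify_by_cluster) c("clonotype_id", "cluster") else "clonotype_id"
  dat %>%
    group_by(across(all_of(keys))) %>%
    summarise(x = mean(.data$embed_x), y = mean(.data$embed_y),
              size = n(), .groups = "drop")
}

#' Grid-based composition of an embedding
#'
#' Divides the embedding into a k x k grid of equal-width bins spanning the
#' data range on each axis (last bin closed on the right) and reports, per
#' occupied bin, the composition of cells by sample or condition.
#'
#' @param cells Cell tibble with `embed_x`/`embed_y`.
#' @param k Number of bins per axis (default 10).
#' @param by Composition key: `"sample_id"` (default) or `"condition"`.
#' @return Tibble `bin_x`, `bin_y`, the composition key, `n_cells`,
#'   `fraction` (fractions sum to 1 within a bin).
#' @export
grid_composition <- function(cells, k = 10, by = c("sample_id", "condition")) {
  by <- match.arg(by)
  stopifnot(k >= 1)
  dat <- cells %>% filter(!is.na(.data$embed_x), !is.na(.data$embed_y))
  if (nrow(dat) == 0) stop("no cells with embedding coordinates", call. = FALSE)
  bin_axis <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("degenerate embedding axis (max == min); using a single bin",
              call. = FALSE)
      return(rep(1L, length(v)))
    }
    breaks <- seq(rng[1], rng[2], length.out = k + 1)
    findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  dat$bin_x <- bin_axis(dat$embed_x)
  dat$bin_y <- bin_axis(dat$embed_y)
  dat %>%
    count(.data$bin_x, .data$bin_y, .data[[by]], name = "n_cells") %>%
    group_by(.data$bin_x, .data$bin_y) %>%
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup()
}
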