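# D50 repertoire diversity and between-condition comparison.

#' D50 repertoire diversity
#'
#' The D50 index is the percentage of top-ranked clonotypes that together
#' account for half of all detected receptor sequences: with clonotype
#' frequencies sorted in non-increasing order, D50 = 100 k*/n where k* is the
#' smallest k whose cumulative count reaches half the total and n is the
#' number of unique clonotypes. A perfectly even repertoire gives 50; the
#' more a few clones dominate, the closer the value falls to 0.
#'
#' Frequencies are sorted internally, so input order does not matter. A tie
#' at exactly half the total counts as reached.
#'
#' @param freqs Vector of positive clonotype frequencies (one entry per
#'   unique clonotype).
#' @return D50 as a percentage in (0, 50] (up to rounding of odd splits).
#' @examples
#' d50(rep(1, 10))      # uniform: 50
#' d50(c(5, 1, 1, 1))   # one dominant clone: 25
#' @export
d50 <- function(freqs) {
  if (length(freqs) == 0) stop("freqs must contain at least one frequency", call. = FALSE)
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("freqs must be positive and finite", call. = FALSE)
  }
  f <- sort(as.numeric(freqs), decreasing = TRUE)
  k <- which(cumsum(f) >= sum(f) / 2)[1]
  100 * k / length(f)
}

#' Per-sample repertoire frequency vectors
#'
#' @param cells Annotated cell tibble (see [annotate_clonotypes()]).
#' @param level Count unique paired-chain clonotypes (`"clonotype"`, default)
#'   or unique beta-chain CDR3s (`"beta"`).
#' @return Named list (by `sample_id`) of descending frequency vectors.
#' @export
repertoire_counts <- function(cells, level = c("clonotype", "beta")) {
  level <- match.arg(level)
  eligible <- if (level == "clonotype") {
    cells %>% filter(.data$has_pair) %>%
      mutate(key = paste(.data$alpha_cdr3, .data$beta_cdr3, sep = "_"))
  } else {
    cells %>% filter(!is.na(.data$beta_cdr3)) %>%
      mutate(key = .data$beta_cdr3)
  }
  split(eligible$key, eligible$sample_id) |>
    lapply(function(k) sort(as.integer(table(k)), decreasing = TRUE))
}

#' Per-sample D50 table
#'
#' @inheritParams repertoire_counts
#' @return Tibble with `sample_id`, `n` (unique clonotypes), `total_cells`,
#'   `d50`.
#' @export
sample_d50 <- function(cells, level = c("clonotype", "beta")) {
  counts <- repertoire_counts(cells, level)
  tibble(
    sample_id = names(counts),
    n = vapply(counts, length, integer(1)),
    total_cells = vapply(counts, sum, integer(1)),
    d50 = vapply(counts, d50, numeric(1))
  )
}

#' Compare repertoire diversity between two condition groups
#'
#' Two-sample test on per-sample D50 values. The default is a two-sided
#' Wilcoxon rank-sum test; a Welch t-test is also available since both are
#' in common use for this comparison.
#'
#' @param d50_values Numeric vector of per-sample D50 values.
#' @param condition Factor/character of the same length giving each sample's
#'   group; exactly two levels, each with at least two samples.
#' @param test `"wilcoxon"` (two-sided rank-sum, default) or `"t_test"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, group sizes and
#'   group medians.
#' @export
compare_diversity <- function(d50_values, condition,
                              test = c("wilcoxon", "t_test")) {
  test <- match.arg(test)
  stopifnot(length(d50_values) == length(condition))
  condition <- as.character(condition)
  levels <- sort(unique(condition))
  if (length(levels) != 2) {
    stop("condition must have exactly two groups", call. = FALSE)
  }
  a <- d50_values[condition == levels[1]]
  b <- d50_values[condition == levels[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("each condition needs at least two samples", call. = FALSE)
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  } else {
    t.test(a, b, alternative = "two.sided")
  }
  tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    group_a = levels[1], n_a = length(a), median_a = median(a),
    group_b = levels[2], n_b = length(b), median_b = median(b)
  )
}
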