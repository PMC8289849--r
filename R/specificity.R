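# CDR3 similarity clustering into antigen-specificity groups.

#' Strip the allele suffix from a V-gene name
#'
#' `"TRBV5-1*01"` becomes `"TRBV5-1"`. Allele-level suffixes are
#' pipeline artifacts; specificity groups span individuals, so V genes are
#' compared at gene level.
#'
#' @param v Character vector of V-gene names.
#' @return Character vector without `*NN` suffixes.
#' @export
strip_allele <- function(v) {
  sub("\\*.*$", "", v)
}

#' Do two beta CDR3s fall in the same specificity group?
#'
#' Two receptors match when their V genes are identical (allele suffixes
#' stripped) and their CDR3 amino-acid sequences are within one edit of each
#' other: either equal length with at most one substitution, or lengths
#' differing by one where the shorter is obtained from the longer by a
#' single deletion with no additional mismatch. With `strict = FALSE`, one
#' indel plus one substitution is also tolerated.
#'
#' @param cdr3_a,cdr3_b CDR3 amino-acid strings.
#' @param v_a,v_b V-gene names; when both `NULL` the V-gene condition is
#'   skipped.
#' @param strict Require total edit distance <= 1 (default); `FALSE` allows
#'   one indel and one substitution together.
#' @return Logical scalar.
#' @export
cdr3_match <- function(cdr3_a, cdr3_b, v_a = NULL, v_b = NULL, strict = TRUE) {
  if (!is.null(v_a) || !is.null(v_b)) {
    if (is.null(v_a) || is.null(v_b)) return(FALSE)
    if (strip_allele(v_a) != strip_allele(v_b)) return(FALSE)
  }
  la <- nchar(cdr3_a)
  lb <- nchar(cdr3_b)
  if (la == lb) {
    return(hamming(cdr3_a, cdr3_b) <= 1)
  }
  if (abs(la - lb) != 1) return(FALSE)
  longer <- if (la > lb) cdr3_a else cdr3_b
  shorter <- if (la > lb) cdr3_b else cdr3_a
  one_deletion_within(longer, shorter, max_mismatch = if (strict) 0L else 1L)
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# TRUE if deleting one residue of `longer` can yield `shorter` with at most
# `max_mismatch` additional substitutions. CDR3s are short, so the plain
# scan over deletion positions is cheap.
one_deletion_within <- function(longer, shorter, max_mismatch = 0L) {
  lo <- utf8ToInt(longer)
  sh <- utf8ToInt(shorter)
  if (length(lo) != length(sh) + 1L) return(FALSE)
  for (del in seq_along(lo)) {
    if (sum(lo[-del] != sh) <= max_mismatch) return(TRUE)
  }
  FALSE
}

#' Build antigen-specificity groups from beta-chain TCRs
#'
#' Members are distinct (CDR3, V gene, sample) tuples; identical receptors
#' observed in different samples are distinct members. The match graph
#' connects members that satisfy [cdr3_match()], and groups are its
#' single-linkage connected components with at least two members. Candidate
#' pairs are enumerated only within buckets of (V gene, length) and
#' (V gene, length +/- 1), which reproduces the exhaustive all-pairs result
#' at near-linear cost.
#'
#' Group identifiers are deterministic: `"G1"` is the group with most
#' members, ties broken by the lexicographically smallest member CDR3.
#'
#' @param tcrs Tibble with columns `cdr3`, `v_gene`, `sample_id`, `tissue`,
#'   `condition` (see [beta_tcrs()]).
#' @param strict Passed to [cdr3_match()].
#' @return Membership tibble: `group_id`, `cdr3`, `v_gene`, `sample_id`,
#'   `tissue`, `condition`, `n_members`, `pd_specific` (group has at least
#'   one PD blood member and one PD CSF member).
#' @export
build_specificity_groups <- function(tcrs, strict = TRUE) {
  assert_columns(tcrs, c("cdr3", "v_gene", "sample_id", "tissue", "condition"),
                 "tcrs")
  members <- tcrs %>%
    mutate(v_stripped = strip_allele(.data$v_gene)) %>%
    distinct(.data$cdr3, .data$v_stripped, .data$sample_id, .keep_all = TRUE)
  if (nrow(members) == 0) return(empty_groups())

  # Work at the level of unique (V, CDR3) sequences; members sharing one are
  # connected at distance zero by definition.
  seqs <- members %>% distinct(.data$v_stripped, .data$cdr3) %>%
    mutate(node = paste(.data$v_stripped, .data$cdr3, sep = "|"))
  edges <- match_edges(seqs, strict = strict)

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seqs$node, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  seqs$component <- unname(comp[seqs$node])

  members <- members %>%
    left_join(select(seqs, "v_stripped", "cdr3", "component"),
              by = c("v_stripped", "cdr3")) %>%
    group_by(.data$component) %>%
    mutate(n_members = n()) %>%
    ungroup() %>%
    filter(.data$n_members >= 2)
  if (nrow(members) == 0) return(empty_groups())

  ranking <- members %>%
    group_by(.data$component) %>%
    summarise(n_members = first(.data$n_members),
              min_cdr3 = min(.data$cdr3), .groups = "drop") %>%
    arrange(desc(.data$n_members), .data$min_cdr3) %>%
    mutate(group_id = paste0("G", row_number()))

  members %>%
    left_join(select(ranking, "component", "group_id"), by = "component") %>%
    group_by(.data$group_id) %>%
    mutate(pd_specific =
             any(.data$condition == "PD" & .data$tissue == "blood") &
             any(.data$condition == "PD" & .data$tissue == "CSF")) %>%
    ungroup() %>%
    arrange(as.integer(sub("^G", "", .data$group_id)), .data$cdr3,
            .data$sample_id) %>%
    select("group_id", "cdr3", "v_gene", "sample_id", "tissue",
           "condition", "n_members", "pd_specific")
}

empty_groups <- function() {
  tibble(group_id = character(), cdr3 = character(), v_gene = character(),
         sample_id = character(), tissue = character(),
         condition = character(), n_members = integer(),
         pd_specific = logical())
}

# Edge list (from, to) over sequence nodes, bucketed by (V, length).
match_edges <- function(seqs, strict = TRUE) {
  froms <- character(0)
  tos <- character(0)
  add <- function(a, b) {
    froms <<- c(froms, a)
    tos <<- c(tos, b)
  }
  for (v in unique(seqs$v_stripped)) {
    sv <- seqs[seqs$v_stripped == v, ]
    by_len <- split(sv, nchar(sv$cdr3))
    lens <- as.integer(names(by_len))
    for (l in lens) {
      bucket <- by_len[[as.character(l)]]
      # substitution edges within one length: hash-join on one-position masks
      if (nrow(bucket) > 1) {
        for (pos in seq_len(l)) {
          masked <- paste0(substr(bucket$cdr3, 1, pos - 1), ".",
                           substr(bucket$cdr3, pos + 1, l))
          groups <- split(bucket$node, masked)
          for (grp in groups[lengths(groups) > 1]) {
            pairs <- utils::combn(grp, 2)
            add(pairs[1, ], pairs[2, ])
          }
        }
      }
      # indel edges to the next shorter length
      shorter <- by_len[[as.character(l - 1L)]]
      if (!is.null(shorter)) {
        short_set <- stats::setNames(shorter$node, shorter$cdr3)
        for (i in seq_len(nrow(bucket))) {
          s <- bucket$cdr3[i]
          if (strict) {
            dels <- unique(vapply(seq_len(l), function(p) {
              paste0(substr(s, 1, p - 1), substr(s, p + 1, l))
            }, character(1)))
            hit <- short_set[dels]
            hit <- hit[!is.na(hit)]
            if (length(hit) > 0) add(rep(bucket$node[i], length(hit)),
                                     unname(hit))
          } else {
            for (j in seq_len(nrow(shorter))) {
              if (one_deletion_within(s, shorter$cdr3[j], max_mismatch = 1L)) {
                add(bucket$node[i], shorter$node[j])
              }
            }
          }
        }
      }
    }
  }
  data.frame(from = froms, to = tos, stringsAsFactors = FALSE)
}

#' Screen PD-specific specificity groups
#'
#' Keeps groups with at least one member from PD blood and one from PD CSF —
#' receptors plausibly patrolling between compartments in patients.
#'
#' @param groups Membership tibble from [build_specificity_groups()].
#' @return The PD-specific subset, group ids preserved.
#' @export
screen_pd_specific <- function(groups) {
  filter(groups, .data$pd_specific)
}

#' Extract deduplicated beta-chain TCRs from cells
#'
#' @param cells Cell tibble from [pair_chains()] (beta chain present).
#' @return Tibble `cdr3`, `v_gene`, `sample_id`, `tissue`, `condition` with
#'   one row per distinct (CDR3, V gene, sample).
#' @export
beta_tcrs <- function(cells) {
  cells %>%
    filter(!is.na(.data$beta_cdr3), !is.na(.data$beta_v)) %>%
    transmute(cdr3 = .data$beta_cdr3, v_gene = .data$beta_v,
              sample_id = .data$sample_id, tissue = .data$tissue,
              condition = .data$condition) %>%
    distinct(.data$cdr3, v_stripped = strip_allele(.data$v_gene),
             .data$sample_id, .keep_all = TRUE) %>%
    select(-"v_stripped")
}
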