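# Independent oracles and fixture builders used across the suite.

# Linear-scan D50 oracle: walk k = 1..n explicitly.
oracle_d50 <- function(freqs) {
  f <- sort(freqs, decreasing = TRUE)
  total <- sum(f)
  acc <- 0
  for (k in seq_along(f)) {
    acc <- acc + f[k]
    if (acc >= total / 2) return(100 * k / length(f))
  }
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive all-pairs specificity grouping oracle: edit distance via
# utils::adist, components via a plain union-find.
oracle_groups <- function(members, strict = TRUE) {
  # members: tibble with cdr3, v_gene, sample_id; returns list of member
  # index sets (groups of size >= 2), each sorted.
  n <- nrow(members)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  v <- clonoscope::strip_allele(members$v_gene)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v[i] != v[j]) next
      a <- members$cdr3[i]; b <- members$cdr3[j]
      if (abs(nchar(a) - nchar(b)) > 1) next
      d <- utils::adist(a, b)[1, 1]
      ok <- if (strict) d <= 1 else {
        d <= 1 || (abs(nchar(a) - nchar(b)) == 1 && d <= 2)
      }
      if (ok) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[lengths(comps) >= 2]
  unname(lapply(comps, sort))
}

# Canonical member labels for comparing groupings.
member_labels <- function(members) {
  paste(members$cdr3, clonoscope::strip_allele(members$v_gene),
        members$sample_id)
}

group_sets_from_membership <- function(groups, members) {
  lab <- member_labels(members)
  lapply(split(member_labels(groups), groups$group_id), sort)
}

# Random CDR3s for grouping tests.
random_cdr3s <- function(n, min_len = 10, max_len = 18) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    l <- if (min_len == max_len) min_len else sample(min_len:max_len, 1)
    paste0("C", paste(sample(aa, l - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

# Substitution variant at interior position `pos`.
substitute_at <- function(cdr3, pos) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old <- substr(cdr3, pos, pos)
  new <- sample(setdiff(aa, old), 1)
  paste0(substr(cdr3, 1, pos - 1), new, substr(cdr3, pos + 1, nchar(cdr3)))
}

# Minimal annotated cell tibble built from explicit clonotype sizes.
cells_from_sizes <- function(sizes, sample_id = "S1", condition = "PD",
                             tissue = "blood", cluster = NA_character_,
                             prefix = "K") {
  beta <- sprintf("CASS%s%04dF", prefix, seq_along(sizes))
  alpha <- sprintf("CAV%s%04dF", prefix, seq_along(sizes))
  n <- sum(sizes)
  tibble::tibble(
    barcode = sprintf("%s_%s_%05d", sample_id, prefix, seq_len(n)),
    sample_id = sample_id,
    alpha_cdr3 = rep(alpha, sizes), beta_cdr3 = rep(beta, sizes),
    alpha_v = "TRAV1", alpha_j = "TRAJ1",
    beta_v = "TRBV1", beta_j = "TRBJ1",
    has_pair = TRUE, tissue = tissue, condition = condition,
    cluster = cluster, embed_x = NA_real_, embed_y = NA_real_,
    clonotype_id = rep(sprintf("%s%d", prefix, seq_along(sizes)), sizes),
    clone_size = rep(sizes, sizes)
  )
}

# Write a small contig CSV fixture and return its path.
write_contig_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(rows, path)
  path
}

contig_row <- function(barcode, chain, cdr3, v_gene = "TRBV1",
                       j_gene = "TRBJ1", productive = "True", umis = 5,
                       is_cell = "True", sample_id = "S1") {
  tibble::tibble(barcode = barcode, sample_id = sample_id, is_cell = is_cell,
                 contig_id = paste0(barcode, "_", chain, "_", cdr3),
                 chain = chain, v_gene = v_gene, d_gene = "None",
                 j_gene = j_gene, cdr3 = cdr3,
                 cdr3_nt = strrep("GCT", nchar(cdr3)),
                 productive = productive, umis = umis)
}

meta_for <- function(barcodes, sample_id = "S1", tissue = "blood",
                     condition = "PD", cluster = NA_character_) {
  tibble::tibble(barcode = barcodes, sample_id = sample_id, tissue = tissue,
                 condition = condition, cluster = cluster,
                 embed_x = NA_real_, embed_y = NA_real_)
}
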