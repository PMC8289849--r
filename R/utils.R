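# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_valid_aa <- function(x) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

# Deterministic small hash of a character vector, order-independent.
# Used to derive RNG substreams that depend only on group *content*, so that
# resampling comparisons are symmetric under swapping the two groups.
content_hash <- function(x) {
  s <- paste(sort(as.character(x)), collapse = "|")
  if (!nzchar(s)) return(0L)
  v <- utf8ToInt(s)
  h <- sum(v * (seq_along(v) %% 97L + 1L)) %% 1000003
  as.integer(h)
}

derive_seed <- function(seed, iter, salt = 0L) {
  as.integer((as.numeric(seed) %% 1000003 * 69761 +
                as.numeric(iter) * 7919 +
                as.numeric(salt)) %% 2147483629)
}

# Evaluate `expr` with the global RNG seeded at `seed`, restoring any
# pre-existing RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Modal value of a character vector; ties broken lexicographically.
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- table(x)
  names(tab)[order(-as.integer(tab), names(tab))][1]
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
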