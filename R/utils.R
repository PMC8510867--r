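# Internal helpers shared across modules.

# Locale-independent (C byte order) ordering, so every tie-break and every
# written table is byte-identical across machines.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[order(x, method = "radix")]

# Ontology tag of a CURIE: the prefix before the first "_" or ":".
curie_ontology <- function(x) {
  stringi::stri_replace_first_regex(x, "[_:].*$", "")
}

# Canonical (lexicographically sorted, C locale) orientation of entity pairs.
canonicalise_pairs <- function(a, b) {
  swap <- stringi::stri_cmp(a, b) > 0
  tibble(
    entity_a = ifelse(swap, b, a),
    entity_b = ifelse(swap, a, b)
  )
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(paste0("`", what, "` must be a single non-empty string."))
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    abort(paste0("`", what, "` must be a single integer >= ", min, "."))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, what, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    abort(paste0(
      "`", what, "` must be a single number ",
      if (open) "strictly between 0 and 1." else "in [0, 1]."
    ))
  }
  invisible(as.numeric(x))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  invisible(df)
}
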