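#' Compile a dictionary matcher from a lexicon
#'
#' Builds a deterministic multi-term matcher in the style of lightweight
#' dictionary-based entity recognizers: given a lexicon of ontology terms, it
#' recognizes term occurrences in text and links them to their identifiers,
#' requiring no labelled training data and working for any language the
#' lexicon covers.
#'
#' @param lexicon Tibble with columns `term` and `entity_id` (one row per
#'   term-to-CURIE mapping), as returned by [load_lexicon()].
#' @param fold_case Fold letter case before matching (default `TRUE`), so
#'   `"Fever"` also matches `"fever"` and `"FEVER"`.
#' @param fold_diacritics Strip diacritics before matching (default `FALSE`:
#'   Portuguese and Spanish lexicon entries carry meaningful diacritics).
#'
#' @details Normalization is applied per Unicode code point with a
#'   same-length guard (a character whose folded form is not exactly one code
#'   point, such as the German sharp s, is left unchanged), so offsets in the
#'   normalized text map one-to-one onto the original text.  Terms that
#'   collide after normalization merge their identifier sets.
#'
#' @return An object of class `entity_matcher`.
#' @seealso [match_text()], [annotate_documents()]
#' @export
build_matcher <- function(lexicon, fold_case = TRUE, fold_diacritics = FALSE) {
  require_columns(lexicon, c("term", "entity_id"), "`lexicon`")
  lexicon <- distinct(as_tibble(lexicon), .data$term, .data$entity_id)
  if (nrow(lexicon) == 0L) {
    abort("Cannot build a matcher from an empty lexicon.")
  }
  if (any(!nzchar(lexicon$term)) || any(!nzchar(lexicon$entity_id))) {
    abort("Lexicon terms and entity ids must be non-empty.")
  }
  norm <- normalize_match_string(lexicon$term, fold_case, fold_diacritics)
  # Terms that normalize identically merge their CURIE sets.
  curies <- split(lexicon$entity_id, norm)
  curies <- purrr::map(curies, ~ radix_sort(unique(.x)))
  terms <- radix_sort(names(curies))
  structure(
    list(
      terms = terms,
      curies = curies[terms],
      fold_case = isTRUE(fold_case),
      fold_diacritics = isTRUE(fold_diacritics)
    ),
    class = "entity_matcher"
  )
}

#' @export
print.entity_matcher <- function(x, ...) {
  cat(
    "<entity_matcher> ", length(x$terms), " term(s), ",
    length(unique(unlist(x$curies))), " identifier(s); fold_case=",
    x$fold_case, ", fold_diacritics=", x$fold_diacritics, "\n",
    sep = ""
  )
  invisible(x)
}

#' Match lexicon terms in a text
#'
#' Finds non-overlapping term occurrences under the leftmost-longest rule: at
#' each position the longest matching term wins, and matching resumes after
#' its end.  Matches must be flanked by word boundaries — a match is rejected
#' when the character immediately before or after it is a letter or digit, so
#' `"ARS"` never matches inside `"SARS"`, while hyphenated units like
#' `"COVID-19"` match whole.
#'
#' @param matcher An `entity_matcher` from [build_matcher()].
#' @param text A single non-empty string.
#' @return Annotation tibble (`doc_id` = `NA`, `begin`, `end`, `surface`,
#'   `entity_id`, `ontology`): offsets are 0-based half-open in Unicode code
#'   points, spans are pairwise non-overlapping and sorted by `begin`, and a
#'   term mapping to several identifiers emits one row per identifier at the
#'   same span.
#' @export
match_text <- function(matcher, text) {
  if (!inherits(matcher, "entity_matcher")) {
    abort("`matcher` must be an `entity_matcher` (see build_matcher()).")
  }
  assert_string(text, "text")
  norm <- normalize_match_string(text, matcher$fold_case,
                                 matcher$fold_diacritics)
  n <- stringi::stri_length(norm)

  # Candidate occurrences of every term (fixed-pattern search on the
  # normalized text), then boundary filtering, then greedy leftmost-longest
  # resolution.
  occ <- stringi::stri_locate_all_fixed(norm, matcher$terms,
                                        overlap = TRUE)
  lens <- purrr::map_int(occ, ~ if (anyNA(.x[, 1L])) 0L else nrow(.x))
  if (sum(lens) == 0L) {
    return(empty_annotations())
  }
  starts <- unlist(purrr::map(occ[lens > 0L], ~ .x[, 1L]), use.names = FALSE)
  ends <- unlist(purrr::map(occ[lens > 0L], ~ .x[, 2L]), use.names = FALSE)
  term_idx <- rep(which(lens > 0L), lens[lens > 0L])

  alnum <- stringi::stri_detect_regex(
    stringi::stri_sub(norm, seq_len(n), seq_len(n)), "[\\p{L}\\p{N}]"
  )
  ok <- (starts == 1L | !alnum[pmax(starts - 1L, 1L)]) &
    (ends == n | !alnum[pmin(ends + 1L, n)])
  if (!any(ok)) {
    return(empty_annotations())
  }
  starts <- starts[ok]; ends <- ends[ok]; term_idx <- term_idx[ok]

  ord <- radix_order(starts, -ends)
  starts <- starts[ord]; ends <- ends[ord]; term_idx <- term_idx[ord]
  keep <- logical(length(starts))
  cur_end <- 0L # last selected match's exclusive end (1-based end offset)
  for (i in seq_along(starts)) {
    if (starts[i] > cur_end) {
      keep[i] <- TRUE
      cur_end <- ends[i]
    }
  }
  starts <- starts[keep]; ends <- ends[keep]; term_idx <- term_idx[keep]

  curie_sets <- matcher$curies[term_idx]
  n_ids <- lengths(curie_sets)
  begin0 <- rep(starts - 1L, n_ids)
  end0 <- rep(ends, n_ids)
  entity_id <- unlist(curie_sets, use.names = FALSE)
  out <- tibble(
    doc_id = NA_character_,
    begin = begin0,
    end = end0,
    surface = stringi::stri_sub(text, begin0 + 1L, end0),
    entity_id = entity_id,
    ontology = curie_ontology(entity_id)
  )
  out[radix_order(out$begin, out$entity_id), , drop = FALSE]
}

#' Annotate a collection of documents
#'
#' Runs [match_text()] over each document's abstract and stamps the document
#' id on every annotation.  Offsets are relative to the abstract.  Repeated
#' calls with different lexicons can be combined with [dplyr::bind_rows()]
#' to annotate against several vocabularies.
#'
#' @param docs Document tibble (see [read_documents()]).
#' @param matcher An `entity_matcher` from [build_matcher()].
#' @return Annotation tibble over all documents; documents with an empty
#'   abstract contribute nothing (with a warning).
#' @export
annotate_documents <- function(docs, matcher) {
  require_columns(docs, c("doc_id", "abstract"), "`docs`")
  empty <- !nzchar(docs$abstract) | is.na(docs$abstract)
  if (any(empty)) {
    warn(paste0(sum(empty), " document(s) have an empty abstract and were ",
                "not annotated."))
  }
  anns <- purrr::map2(
    docs$doc_id[!empty], docs$abstract[!empty],
    function(id, text) {
      a <- match_text(matcher, text)
      a$doc_id <- id
      a
    }
  )
  bind_rows(empty_annotations(), anns)
}

# Length-preserving normalization: per-code-point case folding and optional
# diacritic stripping.  Characters whose folded form is not exactly one code
# point are left unchanged so offsets survive normalization.
normalize_match_string <- function(x, fold_case, fold_diacritics) {
  if (!fold_case && !fold_diacritics) {
    return(x)
  }
  chars <- stringi::stri_split_boundaries(x, type = "character")
  uniq <- unique(unlist(chars, use.names = FALSE))
  if (length(uniq) == 0L) {
    return(x)
  }
  mapped <- uniq
  if (fold_case) {
    low <- stringi::stri_trans_tolower(mapped)
    one <- stringi::stri_length(low) == stringi::stri_length(mapped)
    mapped[one] <- low[one]
  }
  if (fold_diacritics) {
    folded <- stringi::stri_trans_general(mapped, "Latin-ASCII")
    one <- stringi::stri_length(folded) == stringi::stri_length(mapped)
    mapped[one] <- folded[one]
  }
  lut <- setNames(mapped, uniq)
  vapply(
    chars,
    function(ch) paste(lut[ch], collapse = ""),
    character(1L)
  )
}
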