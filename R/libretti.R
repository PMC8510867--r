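#' Build an author-entity ratings dataset from annotated documents
#'
#' Derives implicit-feedback rating triples from a corpus: users are the
#' authors of the documents, items are the entities recognized in them, and
#' `rating(user, item)` is the number of distinct documents the user
#' (co-)authored in which the item is mentioned.  Multiple mentions of an
#' entity within one document count once; all authors of a document receive
#' equal credit.
#'
#' @param docs Document tibble (see [read_documents()]); `authors` is a
#'   list-column.  Documents with empty author lists contribute nothing.
#' @param annotations Annotation tibble (see [annotate_documents()]); every
#'   `doc_id` must appear in `docs`.
#' @return Ratings tibble (`user_id`, `item_id`, `rating`) with unique
#'   `(user, item)` pairs and ratings >= 1, sorted by `(user_id, item_id)`.
#' @seealso [filter_min_ratings()], [dataset_stats()], [recommend()]
#' @export
build_ratings <- function(docs, annotations) {
  require_columns(docs, c("doc_id", "authors"), "`docs`")
  require_columns(annotations, c("doc_id", "entity_id"), "`annotations`")
  orphans <- radix_sort(unique(setdiff(annotations$doc_id, docs$doc_id)))
  if (length(orphans) > 0L) {
    abort(paste0(
      "Annotation(s) reference unknown doc_id(s): ",
      paste(head(orphans, 10L), collapse = ", "), "."
    ))
  }
  doc_entities <- distinct(as_tibble(annotations), .data$doc_id,
                           .data$entity_id)
  doc_authors <- tibble(
    doc_id = rep(docs$doc_id, lengths(docs$authors)),
    user_id = unlist(docs$authors, use.names = FALSE)
  )
  out <- doc_entities |>
    dplyr::inner_join(doc_authors, by = "doc_id",
                      relationship = "many-to-many") |>
    distinct(.data$user_id, .data$entity_id, .data$doc_id) |>
    count(.data$user_id, .data$entity_id, name = "rating") |>
    rename(item_id = "entity_id") |>
    mutate(rating = as.integer(.data$rating))
  out[radix_order(out$user_id, out$item_id), , drop = FALSE]
}

#' Filter users by minimum number of rated items
#'
#' Retains exactly the users with at least `min_items` distinct rated items
#' (the evaluation protocol requires each retained user to have rated at
#' least 20 items by default).  The filter is applied once: items left with
#' no users simply disappear from the item universe, and no iterative
#' re-filtering takes place.
#'
#' @param ratings Ratings tibble.
#' @param min_items Minimum number of distinct rated items per user.
#' @return Filtered ratings tibble (possibly empty).
#' @export
filter_min_ratings <- function(ratings, min_items = 20) {
  ratings <- validate_ratings(ratings)
  min_items <- assert_count(min_items, "min_items")
  keep <- ratings |>
    count(.data$user_id, name = "n_items") |>
    filter(.data$n_items >= min_items) |>
    pull(.data$user_id)
  filter(ratings, .data$user_id %in% keep)
}

#' Dimensions of a ratings dataset
#'
#' @param ratings Ratings tibble.
#' @return One-row tibble with `n_users`, `n_items`, `n_ratings` (the counts
#'   conventionally reported for recommendation datasets).
#' @export
dataset_stats <- function(ratings) {
  require_columns(ratings, c("user_id", "item_id", "rating"), "`ratings`")
  tibble(
    n_users = n_distinct(ratings$user_id),
    n_items = n_distinct(ratings$item_id),
    n_ratings = nrow(ratings)
  )
}
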