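#' RelRA score of a candidate item for a set of liked items
#'
#' The RelRA (Relation Recommendation Algorithm) score of an unrated
#' candidate item is the number of the user's liked items it is related to in
#' the entity relation graph, divided by the total number of liked items:
#'
#' \deqn{score(c) = |\{l \in liked : \{c, l\} \in E\}| / |liked|}
#'
#' A candidate related to 2 of 6 liked items scores 2/6; one related to 3 of
#' 6 scores 3/6; a candidate sharing no relation with any liked item scores
#' 0.  Rating magnitudes play no role: "liked" means rated at least once, and
#' the denominator is the fixed size of the liked set.
#'
#' @param liked Character vector of liked item CURIEs (non-empty).
#' @param candidate Single candidate item CURIE, not among `liked`.
#' @param graph Relation graph (see [as_relation_graph()]).
#' @return A fraction in `[0, 1]`.  Items absent from the graph contribute
#'   nothing to the numerator.
#' @seealso [recommend()]
#' @export
relra_score <- function(liked, candidate, graph) {
  liked <- unique(as.character(liked))
  if (length(liked) == 0L) {
    abort("`liked` must be a non-empty set of item ids.")
  }
  assert_string(candidate, "candidate")
  if (candidate %in% liked) {
    abort("`candidate` must not be among the liked items.")
  }
  score_candidates(liked, candidate, graph)[[1L]]
}

# Vectorised RelRA scoring: numerator via the graph's edge list, denominator
# |liked|.  Candidates or liked items absent from the graph contribute 0.
score_candidates <- function(liked, candidates, graph) {
  if (length(candidates) == 0L) {
    return(numeric(0L))
  }
  hits <- integer(length(candidates))
  names(hits) <- candidates
  if (igraph::ecount(graph) > 0L) {
    el <- igraph::as_edgelist(graph)
    touch <- rbind(el, el[, 2:1, drop = FALSE]) # both orientations
    rel <- touch[touch[, 2L] %in% liked & touch[, 1L] %in% candidates, ,
                 drop = FALSE]
    if (nrow(rel) > 0L) {
      # simple graph: each (candidate, liked) edge appears once per direction
      tab <- table(rel[, 1L])
      hits[names(tab)] <- as.integer(tab)
    }
  }
  unname(hits) / length(liked)
}

# Liked (trained) item set of one user; errors on unknown users.
user_items <- function(ratings, user) {
  assert_string(user, "user")
  items <- ratings$item_id[ratings$user_id == user]
  if (length(items) == 0L) {
    abort(paste0("Unknown user '", user, "': no ratings in the dataset."))
  }
  radix_sort(unique(items))
}

#' Top-k RelRA recommendations for a user
#'
#' Scores every candidate item with [relra_score()] against the user's rated
#' item set, ranks candidates by score (descending, ties broken by item CURIE
#' in ascending C-locale order for reproducibility) and returns the top `k`.
#'
#' @param ratings Ratings tibble holding the user's training ratings.
#' @param user User id (must be present in `ratings`).
#' @param graph Relation graph (see [as_relation_graph()]).
#' @param candidates Candidate item pool; defaults to every item in
#'   `ratings` not rated by the user.  Items the user already rated are
#'   removed from the pool.
#' @param k Number of recommendations requested.
#' @param min_score Minimum score to keep (`score >= min_score`).  The
#'   default 0 returns the full ranking, zero-score items included; any
#'   `min_score > 0` excludes items unrelated to everything the user liked.
#' @return Tibble (`user_id`, `rank`, `item_id`, `score`) with at most `k`
#'   rows, scores non-increasing.
#' @export
recommend <- function(ratings, user, graph, candidates = NULL, k = 5,
                      min_score = 0) {
  ratings <- validate_ratings(ratings)
  k <- assert_count(k, "k")
  liked <- user_items(ratings, user)
  if (is.null(candidates)) {
    candidates <- unique(ratings$item_id)
  }
  candidates <- radix_sort(setdiff(unique(as.character(candidates)), liked))
  scores <- score_candidates(liked, candidates, graph)
  keep <- scores >= min_score
  candidates <- candidates[keep]
  scores <- scores[keep]
  ord <- radix_order(-scores, candidates)
  take <- head(ord, k)
  tibble(
    user_id = user,
    rank = seq_along(take),
    item_id = candidates[take],
    score = scores[take]
  )
}

#' Random baseline recommendations
#'
#' Uniform sample of candidate items without replacement — the baseline the
#' RelRA recommender is evaluated against.
#'
#' @inheritParams recommend
#' @param seed Integer seed; the sample is deterministic for a fixed seed.
#' @return Tibble (`user_id`, `rank`, `item_id`, `score`) with
#'   `min(k, |candidates|)` rows; scores are reported as 0.
#' @export
random_recommend <- function(ratings, user, candidates = NULL, k = 5,
                             seed = 1L) {
  ratings <- validate_ratings(ratings)
  k <- assert_count(k, "k")
  liked <- user_items(ratings, user)
  if (is.null(candidates)) {
    candidates <- unique(ratings$item_id)
  }
  candidates <- radix_sort(setdiff(unique(as.character(candidates)), liked))
  take <- withr::with_seed(seed, {
    sample(candidates, min(k, length(candidates)))
  })
  tibble(
    user_id = user,
    rank = seq_along(take),
    item_id = take,
    score = 0
  )
}
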