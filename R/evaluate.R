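#' Per-user train/test split of a ratings dataset
#'
#' Randomly partitions each user's rated items into a training part of
#' `ceiling(train_frac * n_items)` items and a test part holding the
#' remainder, so every user appears in both partitions and their union
#' reconstructs the input.  Deterministic for a fixed seed.
#'
#' @param ratings Ratings tibble; every user must have at least 2 items
#'   (apply [filter_min_ratings()] first).
#' @param train_frac Fraction of each user's items assigned to training
#'   (default 0.8, the conventional 80/20 protocol).
#' @param seed Integer seed for the per-user random assignment.
#' @return A list with ratings tibbles `train` and `test`.
#' @export
split_dataset <- function(ratings, train_frac = 0.8, seed = 1L) {
  ratings <- validate_ratings(ratings)
  train_frac <- assert_fraction(train_frac, "train_frac")
  counts <- count(ratings, .data$user_id)
  small <- counts$user_id[counts$n < 2L]
  if (length(small) > 0L) {
    abort(paste0(
      "Every user needs >= 2 rated items before splitting; filter the ",
      "dataset first (e.g. filter_min_ratings()). Offending user(s): ",
      paste(head(radix_sort(small), 10L), collapse = ", "), "."
    ))
  }
  ratings <- ratings[radix_order(ratings$user_id, ratings$item_id), ,
                     drop = FALSE]
  users <- radix_sort(unique(ratings$user_id))
  in_train <- withr::with_seed(seed, {
    unlist(purrr::map(users, function(u) {
      idx <- which(ratings$user_id == u)
      n_train <- ceiling(train_frac * length(idx))
      flag <- logical(length(idx))
      flag[sample(length(idx), n_train)] <- TRUE
      flag
    }), use.names = FALSE)
  })
  list(
    train = ratings[in_train, , drop = FALSE],
    test = ratings[!in_train, , drop = FALSE]
  )
}

#' Top-k ranking metrics
#'
#' Standard implicit-feedback metrics over a ranked recommendation list and
#' the set of relevant (held-out) items:
#' * `precision_at_k()` — relevant items among the top `k`, divided by `k`
#'   (the denominator stays `k` even when fewer items were returned);
#' * `recall_at_k()` — relevant items among the top `k`, divided by the
#'   number of relevant items;
#' * `mrr_at_k()` — reciprocal rank of the first relevant item within the
#'   top `k`, 0 when none appears.
#'
#' @param recommended Character vector of recommended items, best first,
#'   without duplicates.
#' @param relevant Character vector (set) of relevant items; must be
#'   non-empty for `recall_at_k()`.
#' @param k Evaluation depth.
#' @return A fraction in `[0, 1]`.
#' @export
precision_at_k <- function(recommended, relevant, k) {
  k <- assert_count(k, "k")
  check_ranked_list(recommended)
  top <- head(recommended, k)
  sum(top %in% relevant) / k
}

#' @rdname precision_at_k
#' @export
recall_at_k <- function(recommended, relevant, k) {
  k <- assert_count(k, "k")
  check_ranked_list(recommended)
  relevant <- unique(as.character(relevant))
  if (length(relevant) == 0L) {
    abort("`relevant` is empty: this user must be skipped, not scored.")
  }
  top <- head(recommended, k)
  sum(top %in% relevant) / length(relevant)
}

#' @rdname precision_at_k
#' @export
mrr_at_k <- function(recommended, relevant, k) {
  k <- assert_count(k, "k")
  check_ranked_list(recommended)
  top <- head(recommended, k)
  hit <- which(top %in% relevant)
  if (length(hit) == 0L) 0 else 1 / hit[[1L]]
}

check_ranked_list <- function(recommended) {
  if (anyDuplicated(recommended)) {
    abort("`recommended` must not contain duplicate items.")
  }
  invisible(recommended)
}

#' Evaluate recommenders under the top-k protocol
#'
#' Reproduces the standard offline protocol: filter the dataset so every
#' user has at least `min_items` rated items, split each user's items into
#' train/test (holdout by default, per-user k-fold via `folds`), have each
#' algorithm recommend `k` items per user from the candidate pool (all items
#' of the filtered dataset minus the user's training items) and score the
#' recommendations against the user's held-out items.  Reported metrics are
#' macro-averages over evaluated users (each user weighted equally); users
#' whose test split is empty are excluded and counted.
#'
#' @param ratings Ratings tibble.
#' @param graph Relation graph used by the RelRA algorithm.
#' @param algorithms Character vector among `"relra"` and `"random"`, or a
#'   named list mixing those tags with custom recommender functions of
#'   signature `function(user, train_items, candidates, k)` returning a
#'   ranked character vector.
#' @param k Recommendation list length (default 5, i.e. top@5).
#' @param min_items Minimum distinct rated items per retained user
#'   (default 20).
#' @param train_frac Fraction of items per user used for training
#'   (default 0.8).
#' @param seed Integer seed driving the split and the random baseline.
#' @param folds Optional number of per-user cross-validation folds; when
#'   given, each fold serves as the test part once and `train_frac` is
#'   ignored.
#' @return An object of class `relra_eval` with per-algorithm mean
#'   `precision`, `recall` and `mrr`, per-user records, and the protocol
#'   parameters.  See [tidy.relra_eval()], [glance.relra_eval()] and
#'   [autoplot.relra_eval()].
#' @export
evaluate <- function(ratings, graph, algorithms = c("relra", "random"),
                     k = 5, min_items = 20, train_frac = 0.8, seed = 1L,
                     folds = NULL) {
  k <- assert_count(k, "k")
  min_items <- assert_count(min_items, "min_items")
  ratings <- validate_ratings(ratings)
  if (nrow(ratings) == 0L) {
    abort("`ratings` is empty.")
  }
  algorithms <- normalize_algorithms(algorithms)

  filtered <- filter_min_ratings(ratings, min_items)
  if (nrow(filtered) == 0L) {
    abort(paste0(
      "No user has at least ", min_items,
      " rated items; nothing to evaluate."
    ))
  }

  splits <- if (is.null(folds)) {
    list(split_dataset(filtered, train_frac, seed))
  } else {
    folds <- assert_count(folds, "folds", min = 2L)
    split_folds(filtered, folds, seed)
  }
  universe <- radix_sort(unique(filtered$item_id))

  per_user <- purrr::imap(splits, function(sp, fold_i) {
    evaluate_split(sp, universe, graph, algorithms, k,
                   seed = seed + 7919L * (fold_i - 1L), fold = fold_i)
  })
  per_user <- bind_rows(per_user)

  n_skipped <- sum(!per_user$evaluated) / length(algorithms)
  scored <- filter(per_user, .data$evaluated)
  metrics <- scored |>
    group_by(algorithm = .data$algorithm) |>
    summarise(
      precision = mean(.data$precision),
      recall = mean(.data$recall),
      mrr = mean(.data$mrr),
      .groups = "drop"
    )

  structure(
    list(
      metrics = metrics,
      per_user = select(per_user, -"evaluated"),
      k = k,
      min_items = min_items,
      train_frac = if (is.null(folds)) train_frac else NA_real_,
      folds = folds,
      seed = seed,
      n_users_evaluated = n_distinct(scored$user_id),
      n_users_skipped = as.integer(n_skipped)
    ),
    class = "relra_eval"
  )
}

# Resolve the algorithms argument into a named list of tags / functions.
normalize_algorithms <- function(algorithms) {
  if (is.character(algorithms)) {
    algorithms <- setNames(as.list(algorithms), algorithms)
  }
  if (!is.list(algorithms) || length(algorithms) == 0L) {
    abort("`algorithms` must be a character vector or a named list.")
  }
  if (is.null(names(algorithms)) || any(!nzchar(names(algorithms)))) {
    abort("Every algorithm must be named.")
  }
  for (nm in names(algorithms)) {
    a <- algorithms[[nm]]
    if (!(is.function(a) || (is.character(a) && a %in% c("relra", "random")))) {
      abort(paste0(
        "Algorithm '", nm, "' must be \"relra\", \"random\" or a function ",
        "(user, train_items, candidates, k)."
      ))
    }
  }
  algorithms
}

# Per-user k-fold partitions: items dealt into `folds` groups per user; each
# fold acts as test once.
split_folds <- function(ratings, folds, seed) {
  ratings <- ratings[radix_order(ratings$user_id, ratings$item_id), ,
                     drop = FALSE]
  counts <- count(ratings, .data$user_id)
  small <- counts$user_id[counts$n < folds]
  if (length(small) > 0L) {
    abort(paste0(
      "Every user needs >= `folds` rated items for ", folds,
      "-fold evaluation; offending user(s): ",
      paste(head(radix_sort(small), 10L), collapse = ", "), "."
    ))
  }
  users <- radix_sort(unique(ratings$user_id))
  fold_of <- withr::with_seed(seed, {
    unlist(purrr::map(users, function(u) {
      n <- sum(ratings$user_id == u)
      sample(rep_len(seq_len(folds), n))
    }), use.names = FALSE)
  })
  purrr::map(seq_len(folds), function(f) {
    list(
      train = ratings[fold_of != f, , drop = FALSE],
      test = ratings[fold_of == f, , drop = FALSE]
    )
  })
}

# Evaluate all algorithms on one train/test split.
evaluate_split <- function(sp, universe, graph, algorithms, k, seed, fold) {
  train <- sp$train
  test <- sp$test
  users <- radix_sort(unique(train$user_id))
  test_items <- split(test$item_id, test$user_id)
  train_items <- split(train$item_id, train$user_id)

  purrr::imap_dfr(algorithms, function(algo, algo_name) {
    rows <- purrr::map(seq_along(users), function(ui) {
      u <- users[[ui]]
      liked <- radix_sort(unique(train_items[[u]]))
      relevant <- unique(test_items[[u]] %||% character())
      if (length(relevant) == 0L) {
        return(tibble(
          algorithm = algo_name, fold = fold, user_id = u,
          precision = NA_real_, recall = NA_real_, mrr = NA_real_,
          evaluated = FALSE
        ))
      }
      candidates <- setdiff(universe, liked)
      recs <- run_algorithm(algo, u, liked, candidates, k, graph,
                            seed + 131L * ui)
      tibble(
        algorithm = algo_name, fold = fold, user_id = u,
        precision = precision_at_k(recs, relevant, k),
        recall = recall_at_k(recs, relevant, k),
        mrr = mrr_at_k(recs, relevant, k),
        evaluated = TRUE
      )
    })
    bind_rows(rows)
  })
}

# Ranked top-k item vector from one algorithm for one user.
run_algorithm <- function(algo, user, liked, candidates, k, graph, seed) {
  if (is.function(algo)) {
    recs <- as.character(algo(user, liked, candidates, k))
    return(head(recs, k))
  }
  if (identical(algo, "relra")) {
    scores <- score_candidates(liked, candidates, graph)
    ord <- radix_order(-scores, candidates)
    return(candidates[head(ord, k)])
  }
  withr::with_seed(seed, sample(candidates, min(k, length(candidates))))
}

#' @export
print.relra_eval <- function(x, ...) {
  cat("<relra_eval>  top@", x$k, " evaluation\n", sep = "")
  cat("  users evaluated: ", x$n_users_evaluated,
      " (skipped: ", x$n_users_skipped, ")",
      "; min items/user: ", x$min_items, "\n", sep = "")
  if (is.null(x$folds)) {
    cat("  split: per-user holdout, train fraction ", x$train_frac,
        ", seed ", x$seed, "\n", sep = "")
  } else {
    cat("  split: per-user ", x$folds, "-fold, seed ", x$seed, "\n",
        sep = "")
  }
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-8s precision@%d %.4f  recall@%d %.4f  MRR %.4f\n",
                m$algorithm[i], x$k, m$precision[i], x$k, m$recall[i],
                m$mrr[i]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `relra_eval` object from [evaluate()].
#' @param ... Unused.
#' @return A long tibble with columns `algorithm`, `metric`
#'   (`precision`/`recall`/`mrr`) and `value`.
#' @exportS3Method generics::tidy
tidy.relra_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"algorithm", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.relra_eval
#' @return A one-row tibble with the protocol parameters and user counts.
#' @exportS3Method generics::glance
glance.relra_eval <- function(x, ...) {
  tibble(
    k = x$k,
    min_items = x$min_items,
    train_frac = x$train_frac,
    folds = x$folds %||% NA_integer_,
    seed = x$seed,
    n_algorithms = nrow(x$metrics),
    n_users_evaluated = x$n_users_evaluated,
    n_users_skipped = x$n_users_skipped
  )
}

#' Plot an evaluation report
#'
#' Bar chart comparing the algorithms on each metric (precision, recall,
#' MRR) at the evaluated depth `k`.
#'
#' @param object A `relra_eval` object from [evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.relra_eval <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(df$metric, levels = c("precision", "recall", "mrr"),
                      labels = c(paste0("Precision@", object$k),
                                 paste0("Recall@", object$k), "MRR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$algorithm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Mean over users", fill = "Algorithm") +
    ggplot2::theme_minimal()
}
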