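#' Collaboration strategies for combining a physician and an AI score
#'
#' Each strategy takes one reader's ratings (tibble `image_id`, `rating`)
#' and/or the AI score table (tibble `image_id`, `probability`) covering the
#' same images, and returns a `strategy_output`: per image a final score on
#' the 1-8 scale, the binary decision (4.5 threshold, inclusive), the
#' decision source, and the aggregate review burden — the percentage of
#' images requiring at least one physician read (200 means every image was
#' read twice).
#'
#' * `physician_alone()` — the reader's rating stands; burden 100.
#' * `ai_alone()` — the AI's rating-equivalent `1 + 7p` stands; burden 0.
#' * `ai_aided_physician()` — the reader reads every image, but equivocal
#'   reads (rating 4 or 5) are deferred to the AI; burden 100.
#' * `physician_aided_ai()` — the AI reads every image, but scores in the
#'   uncertainty band \eqn{[3.5, 5.5)} are deferred to the reader; burden is
#'   100 times the deferred fraction.
#' * `average_blend()` — the unweighted mean of rating and rating
#'   equivalent; burden 100.
#' * `weighted_blend()` — `w * rating + (1 - w) * rating_equiv` (see
#'   [select_weight()] for choosing `w`); burden 100.
#' * `audit_strategy()` — reader and AI both read; on binary disagreement a
#'   seeded uniformly-chosen second reader adjudicates; burden
#'   `100 + 100 * disagreement fraction`.
#'
#' Deferred AI decisions keep the AI's continuous rating equivalent as the
#' final score (not a snapped integer); binary decisions are unaffected and
#' downstream blending keeps full information.
#'
#' @param ratings tibble with `image_id` and integer `rating` for one
#'   reader (one row per image).
#' @param scores tibble with `image_id` and `probability` in \[0, 1\].
#' @param w_physician physician weight in \[0, 1\]; the AI weight is
#'   `1 - w_physician` exactly.
#' @param other_ratings long ratings tibble (`reader_id`, `image_id`,
#'   `rating`) of the other panel members, used for adjudication.
#' @param seed integer seed for the second-reader draw.
#' @return a `strategy_output` object: list with `strategy` (name),
#'   `decisions` (tibble `image_id`, `final_score`, `decision`, `source`)
#'   and `review_burden`.
#' @examples
#' ratings <- tibble::tibble(image_id = c("a", "b"), rating = c(4L, 7L))
#' scores <- tibble::tibble(image_id = c("a", "b"), probability = c(0.8, 0.1))
#' ai_aided_physician(ratings, scores)$decisions
#' @name strategies
NULL

new_strategy_output <- function(strategy, decisions, review_burden) {
  structure(
    list(strategy = strategy, decisions = decisions,
         review_burden = review_burden),
    class = "strategy_output"
  )
}

#' @export
print.strategy_output <- function(x, ...) {
  cat(sprintf("<strategy_output> %s: %d images, %.1f%% positive, burden %.1f\n",
              x$strategy, nrow(x$decisions), 100 * mean(x$decisions$decision),
              x$review_burden))
  invisible(x)
}

check_one_per_image <- function(tab, what) {
  if (anyDuplicated(tab$image_id)) {
    stop(sprintf("input error: duplicate image_id in %s", what), call. = FALSE)
  }
  invisible(tab)
}

align_reader_ai <- function(ratings, scores) {
  stopifnot(is.data.frame(ratings), is.data.frame(scores))
  check_one_per_image(ratings, "ratings")
  check_one_per_image(scores, "scores")
  missing_s <- setdiff(ratings$image_id, scores$image_id)
  missing_r <- setdiff(scores$image_id, ratings$image_id)
  if (length(missing_s) > 0 || length(missing_r) > 0) {
    stop(sprintf(
      "alignment error: %d image(s) missing from scores (%s); %d missing from ratings (%s)",
      length(missing_s), paste(utils::head(missing_s, 3), collapse = ", "),
      length(missing_r), paste(utils::head(missing_r, 3), collapse = ", ")
    ), call. = FALSE)
  }
  check_integer_rating(ratings$rating)
  check_range(scores$probability, 0, 1, "probability")
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(ratings), "image_id", "rating"),
    dplyr::select(tibble::as_tibble(scores), "image_id", "probability"),
    by = "image_id"
  ) |>
    dplyr::mutate(rating_equiv = prob_to_rating(.data$probability)) |>
    dplyr::arrange(.data$image_id)
}

#' @rdname strategies
#' @export
physician_alone <- function(ratings) {
  check_one_per_image(ratings, "ratings")
  check_integer_rating(ratings$rating)
  score <- as.numeric(ratings$rating)
  new_strategy_output(
    "physician",
    tibble::tibble(
      image_id = ratings$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = "reader"
    ),
    review_burden = 100
  )
}

#' @rdname strategies
#' @export
ai_alone <- function(scores) {
  check_one_per_image(scores, "scores")
  check_range(scores$probability, 0, 1, "probability")
  score <- prob_to_rating(scores$probability)
  new_strategy_output(
    "ai",
    tibble::tibble(
      image_id = scores$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = "ai"
    ),
    review_burden = 0
  )
}

#' @rdname strategies
#' @export
ai_aided_physician <- function(ratings, scores) {
  d <- align_reader_ai(ratings, scores)
  defer <- reader_is_uncertain(d$rating)
  score <- ifelse(defer, d$rating_equiv, as.numeric(d$rating))
  new_strategy_output(
    "ai_aided_physician",
    tibble::tibble(
      image_id = d$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = ifelse(defer, "ai", "reader")
    ),
    review_burden = 100 # the physician still reads every image
  )
}

#' @rdname strategies
#' @export
physician_aided_ai <- function(scores, ratings) {
  d <- align_reader_ai(ratings, scores)
  defer <- ai_is_uncertain(d$rating_equiv)
  score <- ifelse(defer, as.numeric(d$rating), d$rating_equiv)
  new_strategy_output(
    "physician_aided_ai",
    tibble::tibble(
      image_id = d$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = ifelse(defer, "reader", "ai")
    ),
    review_burden = 100 * mean(defer)
  )
}

#' @rdname strategies
#' @export
average_blend <- function(ratings, scores) {
  d <- align_reader_ai(ratings, scores)
  score <- (d$rating + d$rating_equiv) / 2
  new_strategy_output(
    "average",
    tibble::tibble(
      image_id = d$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = "blend"
    ),
    review_burden = 100
  )
}

#' @rdname strategies
#' @export
weighted_blend <- function(ratings, scores, w_physician) {
  stopifnot(is.numeric(w_physician), length(w_physician) == 1,
            w_physician >= 0, w_physician <= 1)
  d <- align_reader_ai(ratings, scores)
  score <- w_physician * d$rating + (1 - w_physician) * d$rating_equiv
  new_strategy_output(
    "weighted_average",
    tibble::tibble(
      image_id = d$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = "blend"
    ),
    review_burden = 100
  )
}

#' @rdname strategies
#' @export
audit_strategy <- function(ratings, scores, other_ratings, seed = 1) {
  d <- align_reader_ai(ratings, scores)
  other_ratings <- validate_ratings(other_ratings)
  disagree <- rating_to_binary(as.numeric(d$rating)) !=
    rating_to_binary(d$rating_equiv)

  need <- d$image_id[disagree]
  second <- withr::with_seed(seed, {
    vapply(need, function(img) {
      pool <- other_ratings[other_ratings$image_id == img, ]
      if (nrow(pool) == 0) return(NA_real_)
      pool$rating[sample.int(nrow(pool), 1)]
    }, numeric(1))
  })
  if (anyNA(second)) {
    stop(sprintf(
      "adjudication error: no second reviewer for image(s): %s",
      paste(utils::head(need[is.na(second)], 5), collapse = ", ")
    ), call. = FALSE)
  }

  score <- as.numeric(d$rating)
  score[match(need, d$image_id)] <- second
  new_strategy_output(
    "audit",
    tibble::tibble(
      image_id = d$image_id,
      final_score = score,
      decision = as.integer(rating_to_binary(score)),
      source = ifelse(disagree, "second_reader", "reader")
    ),
    review_burden = 100 + 100 * mean(disagree)
  )
}

#' Select the physician weight for the weighted-average strategy
#'
#' Chooses `w_physician` for one test reader by leave-one-physician-out
#' validation: for every candidate weight on the grid, every *other* reader's
#' weighted-blend decisions are scored on that reader's own reviewed subset
#' against that reader's own leave-one-out labels; the selected weight
#' maximises the mean of those accuracies. Grid ties break toward the
#' smallest `w_physician` (more AI weight), a deterministic rule.
#'
#' @param ratings long ratings tibble (`reader_id`, `image_id`, `rating`)
#'   for all readers.
#' @param scores AI score tibble (`image_id`, `probability`).
#' @param label_sets named list of `label_set` objects as produced by
#'   [loo_label_sets()].
#' @param test_reader the reader being evaluated (excluded from validation).
#' @param grid candidate weights in \[0, 1\]; default `seq(0, 1, 0.05)`
#'   (21 candidates).
#' @param validation_labels `"loo"` (default): each validation reader is
#'   scored against their own leave-one-out labels; `"all"`: against the
#'   all-reader consensus.
#' @return a list with `w_physician`, `w_ai` (`= 1 - w_physician`), `grid`,
#'   and `grid_accuracy` (mean validation accuracy per candidate).
#' @examples
#' study <- simulate_reader_study(cohort_config(n_patients = 12),
#'                                study_reader_panel(5),
#'                                panel_size_range = c(4, 5), seed = 7)
#' ls <- loo_label_sets(study$ratings, warn_small_panels = FALSE)
#' select_weight(study$ratings, study$scores, ls, "reader_01")$w_physician
#' @export
select_weight <- function(ratings, scores, label_sets, test_reader,
                          grid = seq(0, 1, by = 0.05),
                          validation_labels = c("loo", "all")) {
  validation_labels <- match.arg(validation_labels)
  ratings <- validate_ratings(ratings)
  if (length(grid) == 0) {
    stop("configuration error: empty weight grid", call. = FALSE)
  }
  check_range(grid, 0, 1, "grid")
  others <- setdiff(sort(unique(ratings$reader_id)), test_reader)
  if (length(others) < 2) {
    stop("need at least 2 readers besides the test reader", call. = FALSE)
  }

  acc_mat <- vapply(others, function(r) {
    own <- dplyr::filter(ratings, .data$reader_id == r)
    sc <- dplyr::filter(scores, .data$image_id %in% own$image_id)
    d <- align_reader_ai(own[c("image_id", "rating")], sc)
    lbl_tab <- if (validation_labels == "loo") label_sets[[r]] else
      label_sets$.all
    if (is.null(lbl_tab)) {
      stop(sprintf("no label set for validation reader %s", r), call. = FALSE)
    }
    lbl <- lbl_tab$label[match(d$image_id, lbl_tab$image_id)]
    if (anyNA(lbl)) {
      stop(sprintf("alignment error: labels missing for reader %s images", r),
           call. = FALSE)
    }
    # images x weights score matrix; accuracy per candidate weight
    blend <- outer(d$rating, grid) + outer(d$rating_equiv, 1 - grid)
    colMeans((blend >= 4.5) == (lbl == 1L))
  }, numeric(length(grid)))

  mean_acc <- rowMeans(acc_mat)
  best <- which.max(mean_acc) # first maximum = smallest weight on a tie
  list(
    w_physician = grid[best],
    w_ai = 1 - grid[best],
    grid = grid,
    grid_accuracy = mean_acc
  )
}
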