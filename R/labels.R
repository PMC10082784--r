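#' Consensus reference labels from a reader panel
#'
#' Builds the per-image binary reference standard from a long-format ratings
#' table. Each rating is binarised at the 4.5 threshold (integer ratings >= 5
#' are positive); the image label is the strict majority of binary reads.
#' Exact ties (possible on even panels) fall through to the mean raw rating:
#' a mean of at least 4.5 is positive, matching the inclusive decision
#' threshold used throughout the scale.
#'
#' When `excluded_reader` is given, that reader's reads are dropped before
#' voting, so the resulting labels can serve as an unbiased reference for
#' evaluating that reader (their own reads never influence the standard they
#' are tested against). Any image left with fewer than two reads after
#' exclusion is an error — silently dropping such images would desynchronise
#' per-reader evaluation subsets. Panels smaller than six reads (the design
#' size of the study this emulates) only trigger a warning, so small
#' fixtures remain usable; set `warn_small_panels = FALSE` to silence it.
#'
#' @param ratings tibble with columns `reader_id`, `image_id`, `rating`
#'   (integers 1-8); a `patient_id` column is carried along if present.
#' @param excluded_reader a reader id to drop before voting, or `NULL`.
#' @param warn_small_panels warn when a retained panel has fewer than 6
#'   reads (default TRUE).
#' @return a `label_set` object: a tibble with columns `image_id`, `label`
#'   (0/1), `panel_size`, `n_agree` (binary reads agreeing with the label),
#'   `n_disagree`, `mean_rating`, plus an `excluded_reader` attribute.
#' @examples
#' ratings <- tibble::tibble(
#'   reader_id = paste0("r", 1:6),
#'   image_id = "img1",
#'   rating = c(6L, 7L, 5L, 6L, 2L, 6L)
#' )
#' consensus_labels(ratings, warn_small_panels = FALSE)
#' @export
consensus_labels <- function(ratings, excluded_reader = NULL,
                             warn_small_panels = TRUE) {
  ratings <- validate_ratings(ratings)
  if (!is.null(excluded_reader)) {
    ratings <- dplyr::filter(ratings, .data$reader_id != excluded_reader)
  }
  sizes <- dplyr::count(ratings, .data$image_id)
  thin <- sizes$image_id[sizes$n < 2]
  if (length(thin) > 0 || nrow(ratings) == 0) {
    stop(sprintf(
      "insufficient panel after exclusion%s: images with < 2 reads: %s",
      if (is.null(excluded_reader)) "" else paste0(" of ", excluded_reader),
      if (nrow(ratings) == 0) "(all)" else
        paste(utils::head(thin, 5), collapse = ", ")
    ), call. = FALSE)
  }
  if (warn_small_panels && any(sizes$n < 6)) {
    warning(sprintf("%d image(s) have panels smaller than 6 reads",
                    sum(sizes$n < 6)), call. = FALSE)
  }

  out <- ratings |>
    dplyr::mutate(positive = rating_to_binary(.data$rating)) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      panel_size = dplyr::n(),
      n_pos = sum(.data$positive),
      mean_rating = mean(.data$rating),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$n_pos * 2 > .data$panel_size ~ 1L,
        .data$n_pos * 2 < .data$panel_size ~ 0L,
        .data$mean_rating >= 4.5 ~ 1L, # tie: mean-rating rule, 4.5 inclusive
        TRUE ~ 0L
      ),
      n_agree = ifelse(.data$label == 1L, .data$n_pos,
                       .data$panel_size - .data$n_pos),
      n_disagree = .data$panel_size - .data$n_agree
    ) |>
    dplyr::select("image_id", "label", "panel_size", "n_agree",
                  "n_disagree", "mean_rating")
  structure(out, class = c("label_set", class(out)),
            excluded_reader = excluded_reader %||% NA_character_)
}

#' Leave-one-reader-out label sets
#'
#' Builds, for every reader appearing in `ratings`, the consensus label set
#' computed with that reader's reads excluded, plus the all-reader label set
#' under the name `".all"`. A reader's leave-one-out (LOO) labels are the
#' reference against which that reader — and every collaboration strategy
#' built around that reader — is evaluated.
#'
#' @inheritParams consensus_labels
#' @return a named list of `label_set` objects: one per reader id, plus
#'   `".all"` for the no-exclusion consensus.
#' @examples
#' ratings <- tibble::tibble(
#'   reader_id = rep(paste0("r", 1:3), each = 2),
#'   image_id = rep(c("a", "b"), 3),
#'   rating = c(6L, 3L, 6L, 2L, 3L, 7L)
#' )
#' names(loo_label_sets(ratings, warn_small_panels = FALSE))
#' @export
loo_label_sets <- function(ratings, warn_small_panels = TRUE) {
  ratings <- validate_ratings(ratings)
  readers <- sort(unique(ratings$reader_id))
  out <- lapply(readers, function(r) {
    tryCatch(
      consensus_labels(ratings, excluded_reader = r,
                       warn_small_panels = warn_small_panels),
      error = function(e) {
        stop(sprintf("leave-one-out labels for reader %s: %s", r,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
  names(out) <- readers
  out$.all <- consensus_labels(ratings, warn_small_panels = warn_small_panels)
  out
}

#' Flag difficult images from panel disagreement
#'
#' An image is difficult when at least two of the retained panel's binary
#' reads disagree with its consensus label. The `label_set` must have been
#' built with the same reader exclusion as intended here (the evaluated
#' reader is excluded both from the labels and from the disagreement count).
#'
#' @param ratings ratings tibble (same schema as [consensus_labels()]).
#' @param label_set a `label_set` from [consensus_labels()].
#' @return a tibble `image_id`, `difficult` (logical), with the label set's
#'   `excluded_reader` attribute carried over.
#' @examples
#' ratings <- tibble::tibble(
#'   reader_id = paste0("r", 1:6), image_id = "img1",
#'   rating = c(6L, 6L, 6L, 3L, 3L, 6L)
#' )
#' ls <- consensus_labels(ratings, warn_small_panels = FALSE)
#' difficulty_flags(ratings, ls)
#' @export
difficulty_flags <- function(ratings, label_set) {
  stopifnot(inherits(label_set, "label_set"))
  ratings <- validate_ratings(ratings)
  excl <- attr(label_set, "excluded_reader")
  if (!is.na(excl)) {
    ratings <- dplyr::filter(ratings, .data$reader_id != excl)
  }
  if (!setequal(unique(ratings$image_id), label_set$image_id)) {
    stop("alignment error: ratings and label_set cover different images",
         call. = FALSE)
  }
  out <- ratings |>
    dplyr::mutate(positive = as.integer(rating_to_binary(.data$rating))) |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(label_set), "image_id", "label"),
      by = "image_id"
    ) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      difficult = sum(.data$positive != .data$label) >= 2,
      .groups = "drop"
    )
  attr(out, "excluded_reader") <- excl
  out
}

#' Per-reader uncertainty flags
#'
#' Flags, for one reader, the images they rated equivocally (rating 4 or 5).
#'
#' @param ratings ratings tibble.
#' @param reader_id the reader whose reads to flag.
#' @return a tibble `image_id`, `uncertain` (logical), one row per image the
#'   reader rated.
#' @examples
#' ratings <- tibble::tibble(reader_id = "r1",
#'                           image_id = c("a", "b"), rating = c(4L, 8L))
#' reader_uncertain_flags(ratings, "r1")
#' @export
reader_uncertain_flags <- function(ratings, reader_id) {
  ratings <- validate_ratings(ratings)
  own <- dplyr::filter(ratings, .data$reader_id == !!reader_id)
  if (nrow(own) == 0) {
    stop(sprintf("reader %s has no ratings", reader_id), call. = FALSE)
  }
  tibble::tibble(
    image_id = own$image_id,
    uncertain = reader_is_uncertain(own$rating)
  )
}

#' Label sets from simulation ground truth
#'
#' Wraps a synthetic cohort's true image labels as a list of `label_set`
#' objects (one per reader plus `".all"`), so strategies can be evaluated
#' against the generator's ground truth instead of a panel consensus — the
#' configuration used in simulation experiments where the true accuracy of
#' a strategy is known (e.g. bootstrap coverage studies).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param reader_ids character vector of reader ids to create entries for.
#' @return a named list of `label_set` objects, all identical to the truth.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5), seed = 1)
#' names(truth_label_sets(cohort, c("r1", "r2")))
#' @export
truth_label_sets <- function(cohort, reader_ids) {
  stopifnot(inherits(cohort, "synthetic_cohort"), length(reader_ids) >= 1)
  base <- tibble::tibble(
    image_id = cohort$images$image_id,
    label = cohort$images$true_label,
    panel_size = NA_integer_,
    n_agree = NA_integer_,
    n_disagree = NA_integer_,
    mean_rating = NA_real_
  )
  out <- lapply(c(reader_ids, ".all"), function(r) {
    structure(base, class = c("label_set", class(base)),
              excluded_reader = if (r == ".all") NA_character_ else r)
  })
  names(out) <- c(reader_ids, ".all")
  out
}

validate_ratings <- function(ratings) {
  need <- c("reader_id", "image_id", "rating")
  if (!is.data.frame(ratings) || !all(need %in% names(ratings))) {
    stop("ratings must have columns reader_id, image_id, rating",
         call. = FALSE)
  }
  check_integer_rating(ratings$rating)
  if (anyDuplicated(ratings[c("reader_id", "image_id")])) {
    stop("input error: a reader rated the same image more than once",
         call. = FALSE)
  }
  tibble::as_tibble(ratings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
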