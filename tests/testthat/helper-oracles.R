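# Literal, loop-based transcriptions of the labelling and strategy rules.
# These stay deliberately naive (per-image ifs, explicit tallies) so they are
# independent of the vectorised implementations they cross-check.

oracle_consensus_one <- function(ratings) {
  votes <- ratings >= 4.5
  n_pos <- 0L
  n_neg <- 0L
  for (v in votes) if (v) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
  if (n_pos > n_neg) return(1L)
  if (n_pos < n_neg) return(0L)
  if (mean(ratings) >= 4.5) 1L else 0L
}

oracle_difficult_one <- function(ratings, label) {
  n_disagree <- 0L
  for (r in ratings) {
    vote <- if (r >= 4.5) 1L else 0L
    if (vote != label) n_disagree <- n_disagree + 1L
  }
  n_disagree >= 2L
}

# final score for one image under each rule-based strategy
oracle_strategy_one <- function(strategy, rating, p, w = NULL,
                                second_rating = NULL) {
  ai_score <- 1 + 7 * p
  switch(
    strategy,
    physician = rating,
    ai = ai_score,
    ai_aided_physician = if (rating == 4 || rating == 5) ai_score else rating,
    physician_aided_ai = if (ai_score >= 3.5 && ai_score < 5.5) rating else
      ai_score,
    average = (rating + ai_score) / 2,
    weighted_average = w * rating + (1 - w) * ai_score,
    audit = {
      reader_call <- rating >= 4.5
      ai_call <- ai_score >= 4.5
      if (reader_call == ai_call) rating else second_rating
    },
    stop("unknown strategy")
  )
}

oracle_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
  }
  list(
    accuracy = (tp + tn) / length(pred),
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# a ratings tibble from a list of per-image integer rating vectors
panel_ratings <- function(panels, image_ids = NULL) {
  image_ids <- image_ids %||% sprintf("img%03d", seq_along(panels))
  dplyr::bind_rows(lapply(seq_along(panels), function(i) {
    tibble::tibble(
      reader_id = sprintf("r%02d", seq_along(panels[[i]])),
      image_id = image_ids[i],
      rating = as.integer(panels[[i]])
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all integer rating vectors of a given panel size (8^size rows)
enumerate_panels <- function(size) {
  grid <- do.call(expand.grid, rep(list(1:8), size))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}
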