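#' The 1-8 assessment scale and its probability correspondence
#'
#' Panel readers grade each chest X-ray on an ordinal 1-8 scale that encodes
#' both the binary call and the reader's confidence: 1 is a fully confident
#' negative (no ARDS findings), 8 a fully confident positive, and 4/5 are the
#' equivocal pair. Classifier probabilities are placed on the same axis by the
#' linear map \eqn{r = 1 + 7p}, so that \eqn{p = 0.5} lands exactly on the
#' 4.5 decision boundary.
#'
#' `prob_to_rating()` and `rating_to_prob()` are exact inverses.
#' `rating_to_binary()` applies the 4.5 threshold (inclusive: 4.5 is
#' positive). `reader_is_uncertain()` flags the equivocal integer pair
#' \{4, 5\}; `ai_is_uncertain()` flags the continuous half-open band
#' \eqn{[3.5, 5.5)}, i.e. probabilities in \eqn{[2.5/7, 4.5/7)} (0.357 to
#' 0.643 after rounding). The two uncertainty definitions are deliberately
#' separate functions: the reader band is a pair of integers, the AI band an
#' interval whose edge semantics differ (closed below, open above).
#' `confidence_level()` folds the scale around 4.5 into four confidence
#' levels, 1 (equivocal) through 4 (absolute).
#'
#' All functions are vectorised and validate their domain.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @param r numeric vector of ratings; integer 1-8 where a reader rating is
#'   required, any value in \[1, 8\] where a rating-scale equivalent is
#'   accepted.
#' @return `prob_to_rating()` a numeric vector in \[1, 8\];
#'   `rating_to_prob()` a numeric vector in \[0, 1\]; `rating_to_binary()`,
#'   `reader_is_uncertain()` and `ai_is_uncertain()` logical vectors;
#'   `confidence_level()` an integer vector in \{1, 2, 3, 4\}.
#' @examples
#' prob_to_rating(c(0, 0.5, 1))      # 1.0 4.5 8.0
#' rating_to_binary(c(4.499, 4.5))   # FALSE TRUE
#' reader_is_uncertain(1:8)          # TRUE only for 4 and 5
#' ai_is_uncertain(c(3.5, 5.5))      # TRUE FALSE: band is [3.5, 5.5)
#' confidence_level(1:8)             # 4 3 2 1 1 2 3 4
#' @name rating_scale
NULL

#' @rdname rating_scale
#' @export
prob_to_rating <- function(p) {
  check_range(p, 0, 1, "p")
  1 + 7 * p
}

#' @rdname rating_scale
#' @export
rating_to_prob <- function(r) {
  check_range(r, 1, 8, "r")
  (r - 1) / 7
}

#' @rdname rating_scale
#' @export
rating_to_binary <- function(r) {
  check_range(r, 1, 8, "r")
  r >= 4.5
}

#' @rdname rating_scale
#' @export
reader_is_uncertain <- function(r) {
  check_integer_rating(r)
  r == 4L | r == 5L
}

#' @rdname rating_scale
#' @export
ai_is_uncertain <- function(r) {
  check_range(r, 1, 8, "r")
  r >= 3.5 & r < 5.5
}

#' @rdname rating_scale
#' @export
confidence_level <- function(r) {
  check_integer_rating(r)
  as.integer(ceiling(abs(r - 4.5)))
}

check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  }
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf(
      "`%s` must lie in [%s, %s]; got %s", name, format(lo), format(hi),
      paste(format(utils::head(x[bad], 3)), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

check_integer_rating <- function(r) {
  if (!is.numeric(r)) stop("rating must be numeric", call. = FALSE)
  bad <- !is.na(r) & (r != floor(r) | r < 1 | r > 8)
  if (any(bad)) {
    stop(sprintf(
      "reader ratings must be integers in 1..8; got %s",
      paste(format(utils::head(r[bad], 3)), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(r)
}
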