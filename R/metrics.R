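#' Confusion-matrix metrics for binary decisions
#'
#' Computes accuracy, F1, sensitivity, specificity, PPV and NPV from aligned
#' binary decision and reference-label vectors. A metric whose denominator
#' is empty (e.g. sensitivity with no positive labels in the evaluated set)
#' is returned as `NA`, never as 0: an undefined proportion is information,
#' and zero-imputation would bias averages taken over readers or bootstrap
#' replicates.
#'
#' @param decisions integer/logical vector of predicted labels (1 = positive).
#' @param labels integer/logical vector of reference labels, same length.
#' @return a `metric_set`: a named list with `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, the confusion counts
#'   `tp`, `fp`, `fn`, `tn`, and `n`.
#' @examples
#' binary_metrics(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
#' @export
binary_metrics <- function(decisions, labels) {
  if (length(decisions) != length(labels)) {
    stop("alignment error: decisions and labels differ in length",
         call. = FALSE)
  }
  if (length(decisions) < 1) {
    stop("need at least one decision", call. = FALSE)
  }
  d <- as.integer(decisions)
  l <- as.integer(labels)
  stopifnot(all(d %in% 0:1), all(l %in% 0:1))
  counts <- confusion_counts(d, l)
  m <- metrics_from_counts(counts["tp"], counts["fp"], counts["fn"],
                           counts["tn"])
  structure(
    c(lapply(m, unname), as.list(counts), list(n = length(d))),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  vals <- unlist(x[c("accuracy", "f1", "sensitivity", "specificity",
                     "ppv", "npv")])
  cat("<metric_set> n =", x$n, "\n")
  print(round(vals, 4))
  invisible(x)
}

confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L),
    tn = sum(pred == 0L & truth == 0L))
}

# vectorised over equal-length count vectors; NA where the denominator is 0
metrics_from_counts <- function(tp, fp, fn, tn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- safe_div(tp, tp + fn)
  ppv <- safe_div(tp, tp + fp)
  list(
    accuracy = safe_div(tp + tn, tp + fp + fn + tn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    sensitivity = sens,
    specificity = safe_div(tn, tn + fp),
    ppv = ppv,
    npv = safe_div(tn, tn + fn)
  )
}

METRIC_NAMES <- c("accuracy", "f1", "sensitivity", "specificity", "ppv", "npv")
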