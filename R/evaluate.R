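#' Run all collaboration strategies under the per-reader protocol
#'
#' Evaluation follows the multi-reader protocol: each panel reader is in
#' turn the "test reader"; every strategy is built around that reader on the
#' subset of images that reader reviewed, and is later scored against that
#' reader's leave-one-out reference labels (so a reader's own reads never
#' shape the standard they are judged against). The AI-alone baseline is
#' likewise evaluated once per reader, on that reader's subset against that
#' reader's labels.
#'
#' @param ratings long ratings tibble: `reader_id`, `patient_id` (optional
#'   but required for cluster bootstrapping), `image_id`, `rating`.
#' @param scores AI score tibble: `image_id`, `probability`.
#' @param strategies character vector among `"physician"`, `"ai"`,
#'   `"ai_aided_physician"`, `"physician_aided_ai"`, `"average"`,
#'   `"weighted_average"`, `"audit"`.
#' @param label_mode `"loo"` (default) or `"all"`: which label set each
#'   reader is evaluated against.
#' @param weight_grid candidate `w_physician` grid for the weighted blend.
#' @param validation_labels passed to [select_weight()].
#' @param seed master seed; the audit adjudication for each reader uses the
#'   substream `"audit_<reader>"`.
#' @param warn_small_panels passed to the label-set construction.
#' @param label_sets optionally, a pre-built named list of `label_set`
#'   objects (one per reader plus `".all"`, as from [loo_label_sets()]) to
#'   evaluate against instead of labels computed from `ratings` — e.g. an
#'   external reference standard or simulation ground truth.
#' @return a `strategy_evaluation` object: list with
#'   `decisions` (tibble `strategy`, `reader_id`, `image_id`, `final_score`,
#'   `decision`, `source`), `burdens` (tibble `strategy`, `reader_id`,
#'   `review_burden`), `label_sets`, `weights` (per-reader selected
#'   `w_physician`), `image_patient` (image to patient map, if available),
#'   and the call parameters.
#' @examples
#' study <- simulate_reader_study(cohort_config(n_patients = 12),
#'                                study_reader_panel(5),
#'                                panel_size_range = c(4, 5), seed = 3)
#' ev <- evaluate_strategies(study$ratings, study$scores,
#'                           strategies = c("physician", "ai"), seed = 3)
#' per_reader_metrics(ev)
#' @export
evaluate_strategies <- function(ratings, scores,
                                strategies = c("physician", "ai",
                                               "ai_aided_physician",
                                               "physician_aided_ai",
                                               "average", "weighted_average",
                                               "audit"),
                                label_mode = c("loo", "all"),
                                weight_grid = seq(0, 1, by = 0.05),
                                validation_labels = c("loo", "all"),
                                seed = 1,
                                warn_small_panels = FALSE,
                                label_sets = NULL) {
  label_mode <- match.arg(label_mode)
  validation_labels <- match.arg(validation_labels)
  known <- c("physician", "ai", "ai_aided_physician", "physician_aided_ai",
             "average", "weighted_average", "audit")
  strategies <- match.arg(strategies, known, several.ok = TRUE)
  ratings <- validate_ratings(ratings)
  scores <- tibble::as_tibble(scores)
  check_one_per_image(scores, "scores")

  if (is.null(label_sets)) {
    label_sets <- loo_label_sets(ratings,
                                 warn_small_panels = warn_small_panels)
  }
  readers <- setdiff(names(label_sets), ".all")

  weights <- NULL
  if ("weighted_average" %in% strategies) {
    weights <- tibble::tibble(
      reader_id = readers,
      w_physician = vapply(readers, function(r) {
        select_weight(ratings, scores, label_sets, r, grid = weight_grid,
                      validation_labels = validation_labels)$w_physician
      }, numeric(1))
    )
  }

  all_dec <- list()
  all_bur <- list()
  for (r in readers) {
    own <- dplyr::filter(ratings, .data$reader_id == r)
    own_r <- own[c("image_id", "rating")]
    own_s <- dplyr::filter(scores, .data$image_id %in% own$image_id)
    for (s in strategies) {
      out <- switch(
        s,
        physician = physician_alone(own_r),
        ai = ai_alone(own_s),
        ai_aided_physician = ai_aided_physician(own_r, own_s),
        physician_aided_ai = physician_aided_ai(own_s, own_r),
        average = average_blend(own_r, own_s),
        weighted_average = weighted_blend(
          own_r, own_s,
          weights$w_physician[weights$reader_id == r]
        ),
        audit = audit_strategy(
          own_r, own_s,
          other_ratings = dplyr::filter(ratings, .data$reader_id != r),
          seed = substream_seed(seed, paste0("audit_", r))
        )
      )
      all_dec[[length(all_dec) + 1]] <-
        dplyr::mutate(out$decisions, strategy = s, reader_id = r,
                      .before = 1)
      all_bur[[length(all_bur) + 1]] <-
        tibble::tibble(strategy = s, reader_id = r,
                       review_burden = out$review_burden)
    }
  }

  image_patient <- if ("patient_id" %in% names(ratings)) {
    dplyr::distinct(ratings, .data$image_id, .data$patient_id)
  } else NULL

  structure(
    list(
      decisions = dplyr::bind_rows(all_dec),
      burdens = dplyr::bind_rows(all_bur),
      label_sets = label_sets,
      weights = weights,
      image_patient = image_patient,
      label_mode = label_mode,
      strategies = strategies,
      seed = seed
    ),
    class = "strategy_evaluation"
  )
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  cat(sprintf(
    "<strategy_evaluation> %d strategies x %d readers, label mode '%s'\n",
    length(x$strategies), length(setdiff(names(x$label_sets), ".all")),
    x$label_mode
  ))
  invisible(x)
}

labels_for_reader <- function(eval, reader) {
  if (eval$label_mode == "loo") eval$label_sets[[reader]] else
    eval$label_sets$.all
}

# decisions joined with each reader's evaluation labels
scored_decisions <- function(eval) {
  readers <- setdiff(names(eval$label_sets), ".all")
  dplyr::bind_rows(lapply(readers, function(r) {
    lbl <- labels_for_reader(eval, r)
    dplyr::filter(eval$decisions, .data$reader_id == r) |>
      dplyr::inner_join(
        dplyr::select(tibble::as_tibble(lbl), "image_id", "label"),
        by = "image_id"
      )
  }))
}

#' Per-reader metrics for every strategy
#'
#' Scores each (strategy, reader) decision set against that reader's
#' evaluation labels and reports the confusion-matrix metrics plus review
#' burden.
#'
#' @param eval a `strategy_evaluation` from [evaluate_strategies()].
#' @return a tibble: `strategy`, `reader_id`, `n_images`, `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `review_burden`. Undefined
#'   metrics are `NA`.
#' @export
per_reader_metrics <- function(eval) {
  stopifnot(inherits(eval, "strategy_evaluation"))
  scored_decisions(eval) |>
    dplyr::group_by(.data$strategy, .data$reader_id) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      tp = sum(.data$decision == 1L & .data$label == 1L),
      fp = sum(.data$decision == 1L & .data$label == 0L),
      fn = sum(.data$decision == 0L & .data$label == 1L),
      tn = sum(.data$decision == 0L & .data$label == 0L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tibble::as_tibble(metrics_from_counts(.data$tp, .data$fp, .data$fn,
                                            .data$tn))
    ) |>
    dplyr::left_join(eval$burdens, by = c("strategy", "reader_id")) |>
    dplyr::select("strategy", "reader_id", "n_images",
                  dplyr::all_of(METRIC_NAMES), "review_burden")
}

#' Across-reader mean metrics
#'
#' The study-level point estimate for each strategy: the across-reader mean
#' of the per-reader metrics (undefined per-reader values dropped per
#' metric) and the mean review burden.
#'
#' @param eval a `strategy_evaluation`.
#' @return a tibble: `strategy`, `metric`, `estimate`, `n_readers`.
#' @export
mean_reader_metrics <- function(eval) {
  per_reader_metrics(eval) |>
    tidyr::pivot_longer(dplyr::all_of(c(METRIC_NAMES, "review_burden")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$strategy, .data$metric) |>
    dplyr::summarise(
      estimate = mean(.data$value, na.rm = TRUE),
      n_readers = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Patient-level cluster bootstrap for strategy metrics
#'
#' Bootstraps the across-reader mean of each per-reader metric by resampling
#' *patients* with replacement: chest X-rays are clustered within patients,
#' so a patient drawn \eqn{k} times contributes all of their images \eqn{k}
#' times. Within each replicate, every reader's metrics are recomputed from
#' their resampled confusion counts and then averaged across readers — the
#' averaging order matters and matches the per-reader protocol. The 95%
#' interval is the 2.5th/97.5th percentile of the replicate means
#' (R's default linear-interpolation quantile, fixed for reproducibility).
#' Replicates where a metric is undefined for every reader are dropped for
#' that metric and counted; per-reader undefined values within a replicate
#' are dropped from that replicate's across-reader mean.
#'
#' The reported point estimate is the observed (non-bootstrap) across-reader
#' mean; the bootstrap supplies only the interval (bootstrap means are also
#' returned for inspection).
#'
#' @param eval a `strategy_evaluation` whose ratings carried `patient_id`.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed master seed; resampling uses its `"bootstrap"` substream.
#' @param conf_level confidence level for the percentile interval.
#' @return a `bootstrap_summary` object: list with `summary` (tibble
#'   `strategy`, `metric`, `estimate`, `boot_mean`, `ci_low`, `ci_high`,
#'   `n_replicates_used`, `n_replicates_undefined`, `B`, `seed`) and
#'   `replicates` (named list of strategy x replicate matrices, one per
#'   metric).
#' @examples
#' study <- simulate_reader_study(cohort_config(n_patients = 12),
#'                                study_reader_panel(5),
#'                                panel_size_range = c(4, 5), seed = 3)
#' ev <- evaluate_strategies(study$ratings, study$scores,
#'                           strategies = c("physician", "ai"), seed = 3)
#' cb <- cluster_bootstrap(ev, B = 50, seed = 3)
#' cb$summary
#' @export
cluster_bootstrap <- function(eval, B = 1000, seed = 1, conf_level = 0.95) {
  stopifnot(inherits(eval, "strategy_evaluation"), B >= 1)
  if (is.null(eval$image_patient)) {
    stop("cluster bootstrap needs patient_id on the ratings table",
         call. = FALSE)
  }
  counts <- patient_confusion_counts(eval)
  patients <- sort(unique(eval$image_patient$patient_id))
  n_pat <- length(patients)

  mult <- withr::with_seed(substream_seed(seed, "bootstrap"), {
    vapply(seq_len(B), function(b) {
      tabulate(sample.int(n_pat, n_pat, replace = TRUE), nbins = n_pat)
    }, integer(n_pat))
  }) # n_pat x B

  groups <- dplyr::distinct(counts, .data$strategy, .data$reader_id)
  strategies <- unique(groups$strategy)

  # per (strategy, reader): replicate confusion counts via matrix product
  rep_metrics <- array(
    NA_real_,
    dim = c(nrow(groups), B, length(METRIC_NAMES)),
    dimnames = list(NULL, NULL, METRIC_NAMES)
  )
  for (g in seq_len(nrow(groups))) {
    cg <- counts[counts$strategy == groups$strategy[g] &
                   counts$reader_id == groups$reader_id[g], ]
    cm <- matrix(0, n_pat, 4,
                 dimnames = list(patients, c("tp", "fp", "fn", "tn")))
    cm[match(cg$patient_id, patients), ] <-
      as.matrix(cg[c("tp", "fp", "fn", "tn")])
    boot_counts <- crossprod(cm, mult) # 4 x B
    m <- metrics_from_counts(boot_counts["tp", ], boot_counts["fp", ],
                             boot_counts["fn", ], boot_counts["tn", ])
    for (metric in METRIC_NAMES) rep_metrics[g, , metric] <- m[[metric]]
  }

  alpha <- (1 - conf_level) / 2
  observed <- mean_reader_metrics(eval)
  replicates <- list()
  rows <- list()
  for (metric in METRIC_NAMES) {
    mm <- rep_metrics[, , metric, drop = FALSE][, , 1]
    if (is.null(dim(mm))) mm <- matrix(mm, nrow = nrow(groups))
    # across-reader mean within each replicate, per strategy
    strat_rep <- t(vapply(strategies, function(s) {
      colMeans(mm[groups$strategy == s, , drop = FALSE], na.rm = TRUE)
    }, numeric(B)))
    strat_rep[is.nan(strat_rep)] <- NA_real_
    rownames(strat_rep) <- strategies
    replicates[[metric]] <- strat_rep
    for (s in strategies) {
      reps <- strat_rep[s, ]
      used <- sum(!is.na(reps))
      est <- observed$estimate[observed$strategy == s &
                                 observed$metric == metric]
      ci <- if (used > 0) {
        stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
      } else c(NA_real_, NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        strategy = s, metric = metric,
        estimate = if (length(est) == 1) est else NA_real_,
        boot_mean = if (used > 0) mean(reps, na.rm = TRUE) else NA_real_,
        ci_low = ci[1], ci_high = ci[2],
        n_replicates_used = used,
        n_replicates_undefined = B - used,
        B = B, seed = seed
      )
    }
  }

  structure(
    list(summary = dplyr::bind_rows(rows), replicates = replicates,
         B = B, seed = seed),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> B = %d, seed = %d\n", x$B, x$seed))
  print(x$summary, n = 20)
  invisible(x)
}

patient_confusion_counts <- function(eval) {
  scored_decisions(eval) |>
    dplyr::inner_join(eval$image_patient, by = "image_id") |>
    dplyr::group_by(.data$strategy, .data$reader_id, .data$patient_id) |>
    dplyr::summarise(
      tp = sum(.data$decision == 1L & .data$label == 1L),
      fp = sum(.data$decision == 1L & .data$label == 0L),
      fn = sum(.data$decision == 0L & .data$label == 1L),
      tn = sum(.data$decision == 0L & .data$label == 0L),
      .groups = "drop"
    )
}

#' One-sided paired bootstrap comparison of two strategies
#'
#' Tests whether strategy A outperforms strategy B on a metric using the
#' cluster-bootstrap replicates: with the paired construction (default) both
#' strategies are evaluated on the *same* patient resamples and the p-value
#' is the proportion of replicates in which A's across-reader mean does not
#' exceed B's (ties count against A — conservative and deterministic). The
#' `"independent"` construction resamples patients separately for the two
#' strategies.
#'
#' @param eval a `strategy_evaluation`.
#' @param strategy_a,strategy_b strategy names present in `eval` (the
#'   alternative hypothesis is A better than B).
#' @param metric one of the confusion-matrix metrics (default
#'   `"accuracy"`).
#' @param B number of bootstrap replicates.
#' @param seed master seed.
#' @param method `"paired"` (default) or `"independent"`.
#' @return a list: `p_value`, `n_replicates_used`, `n_replicates_dropped`,
#'   `metric`, `method`, `B`, `seed`.
#' @export
one_sided_bootstrap_test <- function(eval, strategy_a, strategy_b,
                                     metric = "accuracy", B = 1000, seed = 1,
                                     method = c("paired", "independent")) {
  method <- match.arg(method)
  stopifnot(metric %in% METRIC_NAMES)
  stopifnot(all(c(strategy_a, strategy_b) %in% eval$strategies))
  if (method == "paired") {
    boot <- cluster_bootstrap(eval, B = B, seed = seed)
    ra <- boot$replicates[[metric]][strategy_a, ]
    rb <- boot$replicates[[metric]][strategy_b, ]
  } else {
    boot_a <- cluster_bootstrap(eval, B = B,
                                seed = substream_seed(seed, "test_a"))
    boot_b <- cluster_bootstrap(eval, B = B,
                                seed = substream_seed(seed, "test_b"))
    ra <- boot_a$replicates[[metric]][strategy_a, ]
    rb <- boot_b$replicates[[metric]][strategy_b, ]
  }
  ok <- !is.na(ra) & !is.na(rb)
  if (!any(ok)) stop("no replicate with both metrics defined", call. = FALSE)
  list(
    p_value = mean(ra[ok] <= rb[ok]),
    n_replicates_used = sum(ok),
    n_replicates_dropped = B - sum(ok),
    metric = metric, method = method, B = B, seed = seed
  )
}

#' Reader-vs-AI accuracy stratified by difficulty and certainty
#'
#' Reproduces the stratified view of reader and AI strengths: accuracy of
#' each reader and of the AI on that reader's reviewed subset, against that
#' reader's leave-one-out labels, within strata defined by (a) image
#' difficulty (two or more panel disagreements with the consensus), (b) the
#' reader's own uncertainty (rating 4/5), (c) the AI's uncertainty band
#' (\eqn{[3.5, 5.5)}), (d) the reader's confidence level 1-4, and (e) the
#' AI's confidence mapped to four equal-width bands of \eqn{|p - 0.5|}
#' mirroring the reader levels. Empty strata are reported with `n = 0`
#' rather than erroring.
#'
#' @param ratings long ratings tibble (with `reader_id`, `image_id`,
#'   `rating`).
#' @param scores AI score tibble (`image_id`, `probability`).
#' @param label_sets named list from [loo_label_sets()].
#' @return a list with `per_reader` (tibble `stratification`, `stratum`,
#'   `reader_id`, `n`, `reader_accuracy`, `ai_accuracy`) and `summary`
#'   (across-reader means and total stratum sizes).
#' @examples
#' study <- simulate_reader_study(cohort_config(n_patients = 12),
#'                                study_reader_panel(5),
#'                                panel_size_range = c(4, 5), seed = 3)
#' ls <- loo_label_sets(study$ratings, warn_small_panels = FALSE)
#' rep <- stratified_report(study$ratings, study$scores, ls)
#' rep$summary
#' @export
stratified_report <- function(ratings, scores, label_sets) {
  ratings <- validate_ratings(ratings)
  scores <- tibble::as_tibble(scores)
  readers <- setdiff(names(label_sets), ".all")

  per_reader <- dplyr::bind_rows(lapply(readers, function(r) {
    own <- dplyr::filter(ratings, .data$reader_id == r)
    lbl <- label_sets[[r]]
    flags <- difficulty_flags(ratings, lbl)
    d <- own |>
      dplyr::inner_join(
        dplyr::select(tibble::as_tibble(lbl), "image_id", "label"),
        by = "image_id") |>
      dplyr::inner_join(
        dplyr::select(scores, "image_id", "probability"), by = "image_id") |>
      dplyr::inner_join(flags, by = "image_id") |>
      dplyr::mutate(
        reader_pos = as.integer(rating_to_binary(as.numeric(.data$rating))),
        ai_pos = as.integer(rating_to_binary(prob_to_rating(
          .data$probability))),
        reader_unc = reader_is_uncertain(.data$rating),
        ai_unc = ai_is_uncertain(prob_to_rating(.data$probability)),
        conf = confidence_level(.data$rating),
        ai_conf = pmin(4L, 1L + as.integer(abs(.data$probability - 0.5) /
                                             0.125))
      )
    strata <- list(
      difficulty = split(d, ifelse(d$difficult, "difficult", "non_difficult")),
      reader_uncertainty = split(d, ifelse(d$reader_unc, "uncertain",
                                           "certain")),
      ai_uncertainty = split(d, ifelse(d$ai_unc, "uncertain", "certain")),
      reader_confidence = split(d, paste0("level_", d$conf)),
      ai_confidence = split(d, paste0("level_", d$ai_conf))
    )
    dplyr::bind_rows(lapply(names(strata), function(sn) {
      dplyr::bind_rows(lapply(names(strata[[sn]]), function(lv) {
        sub <- strata[[sn]][[lv]]
        tibble::tibble(
          stratification = sn, stratum = lv, reader_id = r,
          n = nrow(sub),
          reader_accuracy = if (nrow(sub) > 0)
            mean(sub$reader_pos == sub$label) else NA_real_,
          ai_accuracy = if (nrow(sub) > 0)
            mean(sub$ai_pos == sub$label) else NA_real_
        )
      }))
    }))
  }))

  summary <- per_reader |>
    dplyr::group_by(.data$stratification, .data$stratum) |>
    dplyr::summarise(
      n_readers = sum(.data$n > 0),
      mean_n = mean(.data$n),
      reader_accuracy = mean(.data$reader_accuracy, na.rm = TRUE),
      ai_accuracy = mean(.data$ai_accuracy, na.rm = TRUE),
      .groups = "drop"
    )
  list(per_reader = per_reader, summary = summary)
}
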