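#' Generate a clustered synthetic patient/image cohort
#'
#' Draws patients, their condition status, a zero-truncated negative-binomial
#' number of chest X-rays per patient, per-image interpretation difficulty,
#' and per-image true labels. A configurable fraction of positive patients
#' are "late onset": their first \eqn{\lceil k/2 \rceil} of \eqn{k} images
#' are negative, emulating patients whose initial X-rays precede the
#' development of ARDS (only patients with at least two images are eligible).
#' Negative patients never have positive images.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is drawn from the `"cohort"`
#'   substream of this master seed (see [substream_seed()]).
#' @return a `synthetic_cohort` object: a list with tibbles `patients`
#'   (`patient_id`, `status`) and `images` (`image_id`, `patient_id`,
#'   `true_label`, `difficulty`), plus the `config` and `seed` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 10), seed = 1)
#' cohort$patients
#' @export
generate_cohort <- function(config = study_cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(substream_seed(seed, "cohort"), {
    n <- config$n_patients
    patient_id <- sprintf("P%04d", seq_len(n))
    status <- stats::rbinom(n, 1, config$patient_prevalence)

    k <- r_ztnbinom(n, config$images_per_patient$size,
                    config$images_per_patient$mu)
    n_img <- sum(k)
    pid_img <- rep(patient_id, k)
    img_idx <- unlist(lapply(k, seq_len), use.names = FALSE)
    image_id <- sprintf("%s_I%02d", pid_img, img_idx)

    difficulty <- stats::rbeta(n_img, config$difficulty$shape1,
                               config$difficulty$shape2)

    true_label <- rep(status, k)
    pos <- which(status == 1L & k >= 2L)
    n_late <- round(config$late_onset_fraction * sum(status == 1L))
    late <- if (length(pos) > 0 && n_late > 0) {
      pos[sample.int(length(pos), min(n_late, length(pos)))]
    } else integer(0)
    if (length(late) > 0) {
      late_set <- patient_id[late]
      first_half <- img_idx <= ceiling(rep(k, k) / 2)
      true_label[pid_img %in% late_set & first_half] <- 0L
    }

    structure(
      list(
        patients = tibble::tibble(patient_id = patient_id,
                                  status = as.integer(status)),
        images = tibble::tibble(image_id = image_id,
                                patient_id = pid_img,
                                true_label = as.integer(true_label),
                                difficulty = difficulty),
        config = config,
        seed = seed
      ),
      class = "synthetic_cohort"
    )
  })
}

# zero-truncated negative binomial via inverse-CDF sampling on 1..kmax
r_ztnbinom <- function(n, size, mu) {
  kmax <- max(10, stats::qnbinom(1 - 1e-12, size = size, mu = mu))
  x <- seq_len(kmax)
  p <- stats::dnbinom(x, size = size, mu = mu)
  sample(x, n, replace = TRUE, prob = p / sum(p))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients (%d positive), %d images (%d positive)\n",
    nrow(x$patients), sum(x$patients$status), nrow(x$images),
    sum(x$images$true_label)
  ))
  invisible(x)
}

#' Generate panel ratings for a synthetic cohort
#'
#' Assigns a random reader panel to every patient (or image) and draws one
#' ordinal 1-8 rating per (reader, image) pair from each reader's accuracy
#' and confidence model.
#'
#' Each read is correct with probability
#' `clamp(base_accuracy - difficulty_slope * difficulty, 0.5, 1)`; the binary
#' direction of the rating equals the true label when correct and its
#' complement otherwise. Whether the read is emitted as equivocal (rating 4
#' or 5) depends on correctness: incorrect reads are `1 + calibration` times
#' as likely to be equivocal as correct ones, normalised so the marginal
#' equivocal rate equals `uncertain_rate_target` exactly in expectation.
#' Because incorrect reads concentrate on difficult images, reader
#' uncertainty and AI uncertainty co-occur more often than independence
#' would predict, as observed in real panels. Non-equivocal reads get a
#' confidence level in \{2, 3, 4\} from `confidence_profile`, tilted toward
#' high confidence when correct (and low when incorrect) with strength
#' `log1p(calibration) / 2` per level. The rating is then
#' `4.5 + s * (level - 0.5)` with `s = +1` for a positive-direction read.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param readers list of [reader_model()] objects; must contain at least
#'   `max(panel_size_range)` readers.
#' @param panel_size_range integer pair `(min, max)`; each panel size is
#'   drawn uniformly from this range. `min` must be >= 2.
#' @param seed integer master seed; ratings use its `"ratings"` substream.
#' @param assignment `"patient"` (default: a reader reads all of an assigned
#'   patient's images, mirroring patient-level reviewer assignment) or
#'   `"image"` (panels drawn per image).
#' @return a tibble of rating records: `reader_id`, `patient_id`,
#'   `image_id`, `rating` (integer 1-8).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5), seed = 1)
#' readers <- study_reader_panel(4)
#' generate_ratings(cohort, readers, panel_size_range = c(2, 4), seed = 1)
#' @export
generate_ratings <- function(cohort, readers, panel_size_range = c(6, 9),
                             seed = 1, assignment = c("patient", "image")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  assignment <- match.arg(assignment)
  if (!is.list(readers) || !all(vapply(readers, inherits, logical(1),
                                       "reader_model"))) {
    stop("`readers` must be a list of reader_model objects", call. = FALSE)
  }
  pmin_ <- panel_size_range[1]; pmax_ <- panel_size_range[2]
  if (pmin_ < 2) stop("config error: panel minimum must be >= 2", call. = FALSE)
  if (pmax_ > length(readers)) {
    stop(sprintf(
      "config error: panel_size_range max (%d) exceeds reader pool (%d)",
      pmax_, length(readers)
    ), call. = FALSE)
  }
  reader_ids <- vapply(readers, `[[`, character(1), "reader_id")
  if (anyDuplicated(reader_ids)) {
    stop("config error: duplicate reader_id in reader pool", call. = FALSE)
  }

  withr::with_seed(substream_seed(seed, "ratings"), {
    imgs <- cohort$images
    units <- if (assignment == "patient") cohort$patients$patient_id else
      imgs$image_id
    panel_sizes <- sample(seq(pmin_, pmax_), length(units), replace = TRUE)
    panels <- lapply(panel_sizes, function(s)
      reader_ids[sample.int(length(reader_ids), s)])

    if (assignment == "patient") {
      per_unit <- tibble::tibble(
        patient_id = rep(units, panel_sizes),
        reader_id = unlist(panels, use.names = FALSE)
      )
      reads <- dplyr::inner_join(per_unit, imgs, by = "patient_id",
                                 relationship = "many-to-many")
    } else {
      per_unit <- tibble::tibble(
        image_id = rep(units, panel_sizes),
        reader_id = unlist(panels, use.names = FALSE)
      )
      reads <- dplyr::inner_join(per_unit, imgs, by = "image_id")
    }
    reads <- dplyr::arrange(reads, .data$image_id, .data$reader_id)

    # per-reader parameter lookup
    par <- tibble::tibble(
      reader_id = reader_ids,
      base = vapply(readers, `[[`, numeric(1), "base_accuracy"),
      slope = vapply(readers, `[[`, numeric(1), "difficulty_slope"),
      kappa = vapply(readers, `[[`, numeric(1), "calibration"),
      u_target = vapply(readers, `[[`, numeric(1), "uncertain_rate_target")
    )
    conf <- do.call(rbind, lapply(readers, `[[`, "confidence_profile"))
    rownames(conf) <- reader_ids
    reads <- dplyr::left_join(reads, par, by = "reader_id")

    acc <- pmin(1, pmax(0.5, reads$base - reads$slope * reads$difficulty))
    # cohort-wide expected accuracy per reader, used to normalise the
    # equivocal-rate tilt so the marginal equals u_target
    abar_tbl <- vapply(seq_along(readers), function(i) {
      mean(pmin(1, pmax(0.5, par$base[i] - par$slope[i] * imgs$difficulty)))
    }, numeric(1))
    names(abar_tbl) <- reader_ids
    abar <- abar_tbl[reads$reader_id]

    correct <- stats::rbinom(nrow(reads), 1, acc)
    direction <- ifelse(correct == 1, reads$true_label, 1L - reads$true_label)

    r_correct <- 1 / (abar + (1 - abar) * (1 + reads$kappa))
    p_unc <- reads$u_target * r_correct *
      ifelse(correct == 1, 1, 1 + reads$kappa)
    p_unc <- pmin(1, p_unc)
    uncertain <- stats::rbinom(nrow(reads), 1, p_unc)

    # confidence level for non-equivocal reads: profile tilted by correctness
    lambda <- log1p(reads$kappa) / 2
    tilt <- (2 * correct - 1)
    w2 <- conf[reads$reader_id, 1] * exp(lambda * (2 - 3) * tilt)
    w3 <- conf[reads$reader_id, 2]
    w4 <- conf[reads$reader_id, 3] * exp(lambda * (4 - 3) * tilt)
    tot <- w2 + w3 + w4
    u <- stats::runif(nrow(reads))
    level <- ifelse(u < w2 / tot, 2L, ifelse(u < (w2 + w3) / tot, 3L, 4L))
    level[uncertain == 1] <- 1L

    rating <- 4.5 + (2 * direction - 1) * (level - 0.5)

    tibble::tibble(
      reader_id = reads$reader_id,
      patient_id = reads$patient_id,
      image_id = reads$image_id,
      rating = as.integer(rating)
    )
  })
}

#' Generate AI probability scores for a synthetic cohort
#'
#' Draws one classifier probability per image from a latent-signal model:
#' the latent score is \eqn{m = (2y - 1)\,\Phi^{-1}(a(d)) + \sigma\epsilon}
#' with \eqn{y} the true label, \eqn{a(d)} the configured accuracy at the
#' image's difficulty \eqn{d}, \eqn{\sigma} the `score_noise` and
#' \eqn{\epsilon} standard normal; the reported probability is
#' \eqn{p = \mathrm{logistic}(m / T)} with \eqn{T} the calibration
#' temperature. At `score_noise = 1` the accuracy of thresholding \eqn{p} at
#' 0.5 equals \eqn{a(d)} exactly; the temperature only spreads the
#' probabilities (and hence the share falling in the \eqn{[3.5, 5.5)}
#' rating-equivalent uncertainty band), never the ranking.
#'
#' @param cohort a `synthetic_cohort`.
#' @param ai an [ai_model()].
#' @param seed integer master seed; scores use its `"scores"` substream.
#' @return a tibble of score records: `image_id`, `probability`,
#'   `rating_equiv` (`= 1 + 7 * probability`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5), seed = 1)
#' generate_ai_scores(cohort, study_ai_model(), seed = 1)
#' @export
generate_ai_scores <- function(cohort, ai = study_ai_model(), seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(ai, "ai_model"))
  withr::with_seed(substream_seed(seed, "scores"), {
    imgs <- cohort$images
    acc <- pmin(1, pmax(0.5, ai$base_accuracy -
                          ai$difficulty_slope * imgs$difficulty))
    mu <- stats::qnorm(acc) # Inf when acc == 1: degenerate perfect separation
    m <- (2 * imgs$true_label - 1) * mu +
      ai$score_noise * stats::rnorm(nrow(imgs))
    p <- stats::plogis(m / ai$calibration_temperature)
    tibble::tibble(
      image_id = imgs$image_id,
      probability = p,
      rating_equiv = 1 + 7 * p
    )
  })
}

#' Simulate a complete synthetic reader study
#'
#' Convenience wrapper running [generate_cohort()], [generate_ratings()] and
#' [generate_ai_scores()] from one master seed (each stage on its own named
#' substream, so stages are independently reproducible).
#'
#' @inheritParams generate_ratings
#' @param config a [cohort_config()].
#' @param ai an [ai_model()].
#' @param seed integer master seed.
#' @return a list with `cohort`, `ratings`, `scores`.
#' @examples
#' study <- simulate_reader_study(cohort_config(n_patients = 8),
#'                                study_reader_panel(6),
#'                                panel_size_range = c(3, 5), seed = 42)
#' names(study)
#' @export
simulate_reader_study <- function(config = study_cohort_config(),
                                  readers = study_reader_panel(),
                                  ai = study_ai_model(),
                                  panel_size_range = c(6, 9),
                                  seed = 1,
                                  assignment = c("patient", "image")) {
  assignment <- match.arg(assignment)
  cohort <- generate_cohort(config, seed = seed)
  ratings <- generate_ratings(cohort, readers, panel_size_range, seed = seed,
                              assignment = assignment)
  scores <- generate_ai_scores(cohort, ai, seed = seed)
  list(cohort = cohort, ratings = ratings, scores = scores)
}
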