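#' Configuration objects for the synthetic reader study
#'
#' `cohort_config()` describes a clustered patient/image cohort: how many
#' patients, what fraction develop ARDS, how many chest X-rays each patient
#' contributes (a zero-truncated negative binomial, so every patient has at
#' least one image), what fraction of ARDS patients present late (their
#' earliest images are still negative), and the distribution of per-image
#' interpretation difficulty on \[0, 1\].
#'
#' `reader_model()` describes one panel physician: accuracy at difficulty
#' zero, a linear accuracy decrement per unit difficulty, a calibration
#' parameter coupling stated confidence to actual correctness (0 means
#' confidence is independent of correctness; larger values make incorrect
#' reads increasingly likely to be rated equivocal and correct reads
#' increasingly confident), and the marginal fraction of reads emitted as the
#' equivocal ratings 4 or 5.
#'
#' `ai_model()` describes the classifier output-score distribution: accuracy
#' at difficulty zero and its decrement per unit difficulty, the dispersion
#' of the latent score (at `score_noise = 1` the accuracy at the 0.5
#' threshold equals the configured accuracy exactly), and a logistic
#' temperature that spreads or sharpens the probabilities — and thereby
#' controls how often scores fall in the \eqn{[3.5, 5.5)} uncertainty band.
#'
#' @param n_patients number of patients (>= 1).
#' @param patient_prevalence probability a patient develops the condition.
#' @param images_per_patient list with `size` and `mu` of the (zero-truncated)
#'   negative binomial image count per patient.
#' @param late_onset_fraction fraction of positive patients whose earliest
#'   images are negative (requires >= 2 images; eligible patients only).
#' @param difficulty list with `shape1`, `shape2` of the Beta difficulty
#'   distribution on \[0, 1\].
#' @param reader_id identifier string for the reader.
#' @param base_accuracy probability of a correct call at difficulty 0, in
#'   (0.5, 1\].
#' @param difficulty_slope accuracy decrement per unit difficulty (accuracy
#'   is clamped to \[0.5, 1\]).
#' @param calibration non-negative scalar; see Details.
#' @param uncertain_rate_target marginal fraction of reads rated 4 or 5, in
#'   \[0, 1).
#' @param confidence_profile length-3 positive weights for confidence levels
#'   2, 3, 4 among non-equivocal reads (normalised internally).
#' @param score_noise non-negative latent-score dispersion.
#' @param calibration_temperature positive logistic temperature.
#' @return a `cohort_config`, `reader_model` or `ai_model` object (a
#'   validated list).
#' @seealso [generate_cohort()], [generate_ratings()], [generate_ai_scores()],
#'   and [study_cohort_config()] for defaults calibrated to the published
#'   multi-reader ARDS study marginals.
#' @examples
#' cohort_config(n_patients = 20, patient_prevalence = 0.25)
#' reader_model("attending_1", base_accuracy = 0.95, difficulty_slope = 0.4)
#' @export
cohort_config <- function(n_patients = 115,
                          patient_prevalence = 30 / 115,
                          images_per_patient = list(size = 3.5, mu = 3.2),
                          late_onset_fraction = 12 / 30,
                          difficulty = list(shape1 = 0.33, shape2 = 2.0)) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1 ||
      n_patients != floor(n_patients)) {
    stop("config error in `n_patients`: must be a single integer >= 1",
         call. = FALSE)
  }
  check_probability(patient_prevalence, "patient_prevalence")
  check_probability(late_onset_fraction, "late_onset_fraction")
  if (!is.list(images_per_patient) ||
      !all(c("size", "mu") %in% names(images_per_patient)) ||
      !all(vapply(images_per_patient[c("size", "mu")], function(x)
        is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1)))) {
    stop("config error in `images_per_patient`: need positive `size` and `mu`",
         call. = FALSE)
  }
  if (!is.list(difficulty) ||
      !all(c("shape1", "shape2") %in% names(difficulty)) ||
      !all(vapply(difficulty[c("shape1", "shape2")], function(x)
        is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1)))) {
    stop("config error in `difficulty`: need positive `shape1` and `shape2`",
         call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      patient_prevalence = patient_prevalence,
      images_per_patient = images_per_patient[c("size", "mu")],
      late_onset_fraction = late_onset_fraction,
      difficulty = difficulty[c("shape1", "shape2")]
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
reader_model <- function(reader_id,
                         base_accuracy = 0.93,
                         difficulty_slope = 0.40,
                         calibration = 1.5,
                         uncertain_rate_target = 0.056,
                         confidence_profile = c(0.30, 0.35, 0.35)) {
  stopifnot(is.character(reader_id) || is.numeric(reader_id),
            length(reader_id) == 1)
  if (!is.numeric(base_accuracy) || base_accuracy <= 0.5 || base_accuracy > 1) {
    stop("config error in `base_accuracy`: must lie in (0.5, 1]", call. = FALSE)
  }
  if (!is.numeric(difficulty_slope) || difficulty_slope < 0) {
    stop("config error in `difficulty_slope`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(calibration) || calibration < 0) {
    stop("config error in `calibration`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(uncertain_rate_target) || uncertain_rate_target < 0 ||
      uncertain_rate_target >= 1) {
    stop("config error in `uncertain_rate_target`: must lie in [0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(confidence_profile) || length(confidence_profile) != 3 ||
      any(confidence_profile < 0) || sum(confidence_profile) <= 0) {
    stop("config error in `confidence_profile`: need 3 non-negative weights",
         call. = FALSE)
  }
  structure(
    list(
      reader_id = as.character(reader_id),
      base_accuracy = base_accuracy,
      difficulty_slope = difficulty_slope,
      calibration = calibration,
      uncertain_rate_target = uncertain_rate_target,
      confidence_profile = confidence_profile / sum(confidence_profile)
    ),
    class = "reader_model"
  )
}

#' @rdname cohort_config
#' @export
ai_model <- function(base_accuracy = 0.999,
                     difficulty_slope = 1.10,
                     score_noise = 1,
                     calibration_temperature = 1.095) {
  if (!is.numeric(base_accuracy) || base_accuracy <= 0.5 || base_accuracy > 1) {
    stop("config error in `base_accuracy`: must lie in (0.5, 1]", call. = FALSE)
  }
  if (!is.numeric(difficulty_slope) || difficulty_slope < 0) {
    stop("config error in `difficulty_slope`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(score_noise) || score_noise < 0) {
    stop("config error in `score_noise`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(calibration_temperature) || calibration_temperature <= 0) {
    stop("config error in `calibration_temperature`: must be > 0",
         call. = FALSE)
  }
  structure(
    list(
      base_accuracy = base_accuracy,
      difficulty_slope = difficulty_slope,
      score_noise = score_noise,
      calibration_temperature = calibration_temperature
    ),
    class = "ai_model"
  )
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("config error in `%s`: must be a probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Study-calibrated defaults for the synthetic generator
#'
#' Ready-made configuration objects whose parameters were calibrated, once,
#' so that large synthetic cohorts reproduce the marginal statistics of the
#' published multi-reader ARDS chest X-ray study: 115 patients with 30
#' positive, ~3.6 images per patient (median 3, IQR about 2-4.5), 12/30
#' positive patients presenting late, reader reads rated equivocal ~5.6% of
#' the time, AI scores inside the uncertainty band ~20.8% of the time, about
#' a quarter of images "difficult" (two or more panel disagreements with the
#' consensus), and the reader/AI accuracy split across difficulty strata.
#' The calibration rationale is described in the package vignette.
#'
#' @param n_readers number of panel readers (default 9).
#' @return `study_cohort_config()` a [cohort_config()]; `study_reader_panel()`
#'   a list of [reader_model()] objects; `study_ai_model()` an [ai_model()].
#' @examples
#' study_cohort_config()
#' length(study_reader_panel())
#' @export
study_cohort_config <- function() {
  cohort_config()
}

#' @rdname study_cohort_config
#' @export
study_reader_panel <- function(n_readers = 9) {
  stopifnot(n_readers >= 1)
  # heterogeneous panel: a spread of stronger and weaker readers, as real
  # panels mixing radiologists, attendings and fellows show
  base <- rep(c(0.96, 0.95, 0.94, 0.93, 0.92, 0.91, 0.87, 0.84, 0.81),
              length.out = n_readers)
  lapply(seq_len(n_readers), function(i) {
    reader_model(
      reader_id = sprintf("reader_%02d", i),
      base_accuracy = base[i]
    )
  })
}

#' @rdname study_cohort_config
#' @export
study_ai_model <- function() {
  ai_model()
}
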