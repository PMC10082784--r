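#' Load and validate reader-study tables from CSV
#'
#' Reads the long-format ratings table, the AI score table, and optionally
#' the patients table, enforcing the interchange schemas: `ratings.csv`
#' (`reader_id`, `patient_id`, `image_id`, `rating`), `scores.csv`
#' (`image_id`, `probability`), `patients.csv` (`patient_id`, `status`).
#' Ratings must be integers 1-8 and probabilities in \[0, 1\]; offending
#' rows are reported by file, row number and column. When a patients table
#' is supplied, every rating's `patient_id` must exist in it (referential
#' integrity).
#'
#' @param ratings_path,scores_path,patients_path CSV file paths
#'   (`patients_path` optional).
#' @return a list of validated tibbles: `ratings`, `scores`, and `patients`
#'   (NULL if not supplied).
#' @export
load_reader_study <- function(ratings_path, scores_path,
                              patients_path = NULL) {
  ratings <- read_checked(ratings_path,
                          c("reader_id", "image_id", "rating"))
  bad <- which(is.na(ratings$rating) | ratings$rating != floor(ratings$rating) |
                 ratings$rating < 1 | ratings$rating > 8)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: column 'rating' must be an integer in 1..8; offending row(s): %s",
      ratings_path, paste(utils::head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }
  ratings$rating <- as.integer(ratings$rating)

  scores <- read_checked(scores_path, c("image_id", "probability"))
  bad <- which(is.na(scores$probability) | scores$probability < 0 |
                 scores$probability > 1)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: column 'probability' must lie in [0, 1]; offending row(s): %s",
      scores_path, paste(utils::head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }

  patients <- NULL
  if (!is.null(patients_path)) {
    patients <- read_checked(patients_path, c("patient_id", "status"))
    if ("patient_id" %in% names(ratings)) {
      orphan <- setdiff(ratings$patient_id, patients$patient_id)
      if (length(orphan) > 0) {
        stop(sprintf(
          "%s: referential-integrity error: patient_id(s) %s not in %s",
          ratings_path, paste(utils::head(orphan, 5), collapse = ", "),
          patients_path
        ), call. = FALSE)
      }
    }
  }
  list(ratings = ratings, scores = scores, patients = patients)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Write a synthetic reader study to the CSV interchange format
#'
#' Emits `patients.csv`, `images.csv`, `ratings.csv` and `scores.csv` with
#' the fixed column names used throughout the package.
#'
#' @param study a list with `cohort`, `ratings`, `scores` as produced by
#'   [simulate_reader_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reader_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    images = file.path(dir, "images.csv"),
    ratings = file.path(dir, "ratings.csv"),
    scores = file.path(dir, "scores.csv")
  )
  readr::write_csv(study$cohort$patients, paths["patients"])
  readr::write_csv(study$cohort$images, paths["images"])
  readr::write_csv(study$ratings, paths["ratings"])
  readr::write_csv(study$scores[c("image_id", "probability")],
                   paths["scores"])
  invisible(paths)
}

#' Run the full pipeline: generate, label, strategise, evaluate
#'
#' Orchestrates the end-to-end analysis from a single configuration:
#' generate a synthetic cohort (or load CSV tables), build leave-one-out
#' reference labels, run the collaboration strategies around every reader,
#' compute per-reader and across-reader metrics, patient-level
#' cluster-bootstrap intervals, and the stratified reader-vs-AI report.
#' All artifacts are written as CSV plus a JSON manifest recording the
#' configuration and seed, so every output is regenerable from the manifest
#' alone.
#'
#' @param config either a path to a YAML file or a list, with (all optional)
#'   entries: `cohort` (arguments to [cohort_config()]), `n_readers`,
#'   `panel_size_range`, `ai` (arguments to [ai_model()]), `tables` (paths
#'   for [load_reader_study()], used instead of generating), `strategies`,
#'   `label_mode`, `weight_grid`, `bootstrap_reps` (0 disables the
#'   bootstrap), `seed`, `out_dir`.
#' @param verbose print stage progress (default FALSE).
#' @return invisibly, a list with `evaluation`, `results` (per-reader
#'   metrics), `summary` (across-reader means), `bootstrap` (or NULL),
#'   `strata`, and `paths` of the artifacts written.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(
#'   cohort = list(n_patients = 12), n_readers = 5,
#'   panel_size_range = c(4, 5),
#'   strategies = c("physician", "ai"),
#'   bootstrap_reps = 50, seed = 1, out_dir = tempfile()
#' ))
#' res$summary
#' }
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strategies <- config$strategies %||%
    c("physician", "ai", "ai_aided_physician", "physician_aided_ai",
      "average", "weighted_average", "audit")
  B <- config$bootstrap_reps %||% 1000

  paths <- character(0)
  if (!is.null(config$tables)) {
    say("stage load: reading CSV tables")
    tabs <- do.call(load_reader_study, config$tables)
    ratings <- tabs$ratings
    scores <- tabs$scores
  } else {
    say("stage generate: synthesising cohort (seed %d)", seed)
    cc <- do.call(cohort_config, config$cohort %||% list())
    study <- simulate_reader_study(
      config = cc,
      readers = study_reader_panel(config$n_readers %||% 9),
      ai = do.call(ai_model, config$ai %||% list()),
      panel_size_range = unlist(config$panel_size_range %||% c(6, 9)),
      seed = seed
    )
    ratings <- study$ratings
    scores <- study$scores
    paths <- c(paths, write_reader_study(study, out_dir))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial artifacts in %s)",
                   stage, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  say("stage strategies: %s", paste(strategies, collapse = ", "))
  ev <- run_stage("strategies", evaluate_strategies(
    ratings, scores, strategies = strategies,
    label_mode = config$label_mode %||% "loo",
    weight_grid = config$weight_grid %||% seq(0, 1, by = 0.05),
    seed = seed
  ))

  say("stage evaluate: per-reader metrics")
  results <- run_stage("evaluate", per_reader_metrics(ev))
  summary <- mean_reader_metrics(ev)

  boot <- NULL
  if (B > 0) {
    say("stage bootstrap: B = %d", B)
    boot <- run_stage("bootstrap", cluster_bootstrap(ev, B = B, seed = seed))
  }

  say("stage stratify")
  strata <- run_stage("stratify",
                      stratified_report(ratings, scores, ev$label_sets))

  # artifacts
  lbl_all <- tibble::as_tibble(ev$label_sets$.all)
  lbl_all$excluded_reader <- NA_character_
  p <- function(name) file.path(out_dir, name)
  readr::write_csv(lbl_all, p("labels.csv"))
  flags_all <- difficulty_flags(ratings, ev$label_sets$.all)
  flags_all$excluded_reader <- NA_character_
  readr::write_csv(flags_all, p("difficulty.csv"))
  readr::write_csv(ev$decisions, p("decisions.csv"))
  readr::write_csv(ev$burdens, p("burdens.csv"))
  readr::write_csv(results, p("results.csv"))
  readr::write_csv(summary, p("summary.csv"))
  if (!is.null(boot)) readr::write_csv(boot$summary, p("summaries.csv"))
  readr::write_csv(strata$summary, p("strata.csv"))
  jsonlite::write_json(
    list(config = config, seed = seed,
         package_version = as.character(utils::packageVersion("ardsdefer")),
         r_version = R.version.string),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  writeLines(render_report_md(summary, boot), p("report.md"))
  paths <- c(paths, vapply(
    c("labels.csv", "difficulty.csv", "decisions.csv", "burdens.csv",
      "results.csv", "summary.csv", "strata.csv", "manifest.json",
      "report.md"),
    p, character(1)))

  invisible(list(evaluation = ev, results = results, summary = summary,
                 bootstrap = boot, strata = strata, paths = paths))
}

render_report_md <- function(summary, boot = NULL) {
  wide <- tidyr::pivot_wider(summary[c("strategy", "metric", "estimate")],
                             names_from = "strategy",
                             values_from = "estimate")
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
  lines <- c(
    "# Strategy performance (across-reader means)", "",
    paste0("| metric | ", paste(names(wide)[-1], collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  )
  for (i in seq_len(nrow(wide))) {
    lines <- c(lines, paste0(
      "| ", wide$metric[i], " | ",
      paste(fmt(as.numeric(wide[i, -1])), collapse = " | "), " |"
    ))
  }
  if (!is.null(boot)) {
    lines <- c(lines, "",
               sprintf("95%% CIs from %d patient-level cluster-bootstrap replicates (seed %d).",
                       boot$B, boot$seed))
  }
  lines
}
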