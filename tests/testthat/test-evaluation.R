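test_that("confusion metrics follow their closed forms and undefined rules", {
  # TP=3, FP=1, FN=2, TN=4
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- binary_metrics(pred, truth)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # f1 equals the harmonic mean of ppv and sensitivity
  expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
  # all correct
  perf <- binary_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)
  # empty denominators stay undefined, never zero
  no_pos <- binary_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_false(is.na(no_pos$specificity))
  expect_true(is.na(binary_metrics(c(0, 0), c(1, 1))$ppv))
  expect_error(binary_metrics(1, c(1, 0)), "alignment")
})

test_that("metric identities hold against a brute-force tally", {
  tables <- withr::with_seed(55, {
    lapply(1:50, function(i) {
      n <- sample(3:40, 1)
      list(pred = sample(0:1, n, replace = TRUE),
           truth = sample(0:1, n, replace = TRUE))
    })
  })
  for (tb in tables) {
    got <- binary_metrics(tb$pred, tb$truth)
    want <- oracle_metrics(tb$pred, tb$truth)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], info = nm)
  }
})

test_that("per-reader protocol scores each reader on their own subset", {
  study <- simulate_reader_study(cohort_config(n_patients = 25),
                                 study_reader_panel(5),
                                 panel_size_range = c(4, 5), seed = 14)
  ev <- evaluate_strategies(study$ratings, study$scores,
                            strategies = c("physician", "ai",
                                           "ai_aided_physician"),
                            seed = 14)
  pr <- per_reader_metrics(ev)
  # every reader was evaluated on exactly the images they rated
  counts <- dplyr::count(study$ratings, reader_id)
  got <- dplyr::distinct(pr, reader_id, n_images)
  chk <- dplyr::inner_join(counts, got, by = "reader_id")
  expect_equal(chk$n_images, chk$n)
  # a reader with no equivocal reads: aided strategy equals the solo one
  no_unc <- study$ratings |>
    dplyr::group_by(reader_id) |>
    dplyr::summarise(any_unc = any(rating %in% 4:5))
  for (r in no_unc$reader_id[!no_unc$any_unc]) {
    a <- pr[pr$reader_id == r & pr$strategy == "physician", ]
    b <- pr[pr$reader_id == r & pr$strategy == "ai_aided_physician", ]
    expect_equal(a$accuracy, b$accuracy)
  }
  # deterministic: same inputs, same metrics
  ev2 <- evaluate_strategies(study$ratings, study$scores,
                             strategies = c("physician", "ai",
                                            "ai_aided_physician"),
                             seed = 14)
  expect_identical(pr, per_reader_metrics(ev2))
})

test_that("replicate statistic is the across-reader mean, never pooled", {
  # reader A: 2 images, both correct; reader B: 4 images, half correct.
  # across-reader mean accuracy = (1 + 0.5) / 2 = 0.75; pooled = 4/6.
  ratings <- tibble::tibble(
    reader_id = c("A", "A", "B", "B", "B", "B"),
    patient_id = "P1",
    image_id = c("i1", "i2", "i1", "i2", "i3", "i4"),
    rating = c(8L, 8L, 8L, 8L, 1L, 1L)
  )
  labels <- tibble::tibble(
    image_id = c("i1", "i2", "i3", "i4"),
    label = c(1L, 1L, 1L, 1L),
    panel_size = NA_integer_, n_agree = NA_integer_,
    n_disagree = NA_integer_, mean_rating = NA_real_
  )
  lsets <- lapply(c("A", "B", ".all"), function(r)
    structure(labels, class = c("label_set", class(labels)),
              excluded_reader = NA_character_))
  names(lsets) <- c("A", "B", ".all")
  scores <- tibble::tibble(image_id = paste0("i", 1:4),
                           probability = rep(0.9, 4))
  ev <- evaluate_strategies(ratings, scores, strategies = "physician",
                            seed = 1, label_sets = lsets)
  mm <- mean_reader_metrics(ev)
  expect_equal(mm$estimate[mm$metric == "accuracy"], 0.75)
  # the bootstrap replicates (single patient, so every resample is the
  # whole cohort) reproduce the same averaging order
  cb <- cluster_bootstrap(ev, B = 20, seed = 1)
  expect_true(all(cb$replicates$accuracy["physician", ] == 0.75))
})

test_that("cluster bootstrap is seeded, sized and degenerate-safe", {
  study <- simulate_reader_study(cohort_config(n_patients = 20),
                                 study_reader_panel(5),
                                 panel_size_range = c(4, 5), seed = 8)
  ev <- evaluate_strategies(study$ratings, study$scores,
                            strategies = c("physician", "ai"), seed = 8)
  cb1 <- cluster_bootstrap(ev, B = 100, seed = 5)
  cb2 <- cluster_bootstrap(ev, B = 100, seed = 5)
  expect_identical(cb1$summary, cb2$summary)
  expect_false(identical(cb1$summary,
                         cluster_bootstrap(ev, B = 100, seed = 6)$summary))
  row <- cb1$summary[cb1$summary$strategy == "physician" &
                       cb1$summary$metric == "accuracy", ]
  expect_equal(row$n_replicates_used + row$n_replicates_undefined, 100L)
  expect_true(row$ci_low <= row$estimate && row$estimate <= row$ci_high)
  # perfect readers: every replicate is exactly 1, CI collapses to [1, 1]
  perfect <- lapply(1:4, function(i)
    reader_model(paste0("p", i), base_accuracy = 1, difficulty_slope = 0,
                 uncertain_rate_target = 0))
  st2 <- simulate_reader_study(cohort_config(n_patients = 15), perfect,
                               panel_size_range = c(3, 4), seed = 2)
  ev2 <- evaluate_strategies(st2$ratings, st2$scores,
                             strategies = "physician", seed = 2)
  cb <- cluster_bootstrap(ev2, B = 50, seed = 2)
  acc <- cb$summary[cb$summary$metric == "accuracy", ]
  expect_equal(acc$ci_low, 1)
  expect_equal(acc$ci_high, 1)
})

test_that("undefined replicate metrics are dropped and counted", {
  # one rare positive patient: resamples omitting it have no positive
  # labels, so sensitivity is undefined there
  ratings <- tibble::tibble(
    reader_id = rep(c("A", "B"), each = 4),
    patient_id = rep(c("P1", "P2", "P3", "P4"), 2),
    image_id = rep(c("i1", "i2", "i3", "i4"), 2),
    rating = rep(c(8L, 1L, 1L, 1L), 2)
  )
  labels <- tibble::tibble(
    image_id = paste0("i", 1:4), label = c(1L, 0L, 0L, 0L),
    panel_size = NA_integer_, n_agree = NA_integer_,
    n_disagree = NA_integer_, mean_rating = NA_real_
  )
  lsets <- stats::setNames(lapply(1:3, function(i)
    structure(labels, class = c("label_set", class(labels)),
              excluded_reader = NA_character_)), c("A", "B", ".all"))
  scores <- tibble::tibble(image_id = paste0("i", 1:4),
                           probability = c(0.9, 0.1, 0.1, 0.1))
  ev <- evaluate_strategies(ratings, scores, strategies = "physician",
                            seed = 3, label_sets = lsets)
  cb <- cluster_bootstrap(ev, B = 200, seed = 3)
  sens <- cb$summary[cb$summary$metric == "sensitivity", ]
  expect_gt(sens$n_replicates_undefined, 0)
  expect_equal(sens$n_replicates_used + sens$n_replicates_undefined, 200L)
  # accuracy is always defined
  acc <- cb$summary[cb$summary$metric == "accuracy", ]
  expect_equal(acc$n_replicates_undefined, 0L)
})

test_that("patient-level resampling widens CIs under strong clustering", {
  # correctness perfectly clustered: a reader is right on every image of
  # half the patients and wrong on every image of the rest
  n_pat <- 30
  imgs_per <- 4
  ratings <- dplyr::bind_rows(lapply(c("A", "B"), function(r) {
    tibble::tibble(
      reader_id = r,
      patient_id = rep(sprintf("P%02d", 1:n_pat), each = imgs_per),
      image_id = paste0(rep(sprintf("P%02d", 1:n_pat), each = imgs_per),
                        "_", 1:imgs_per),
      rating = rep(ifelse(seq_len(n_pat) %% 2 == 0, 8L, 1L),
                   each = imgs_per)
    )
  }))
  labels <- tibble::tibble(
    image_id = unique(ratings$image_id), label = 1L,
    panel_size = NA_integer_, n_agree = NA_integer_,
    n_disagree = NA_integer_, mean_rating = NA_real_
  )
  lsets <- stats::setNames(lapply(1:3, function(i)
    structure(labels, class = c("label_set", class(labels)),
              excluded_reader = NA_character_)), c("A", "B", ".all"))
  scores <- tibble::tibble(image_id = labels$image_id, probability = 0.9)
  ev <- evaluate_strategies(ratings, scores, strategies = "physician",
                            seed = 4, label_sets = lsets)
  cb_pat <- cluster_bootstrap(ev, B = 400, seed = 4)
  # naive image-level resampling: pretend every image is its own patient
  ev_img <- ev
  ev_img$image_patient <- dplyr::mutate(ev$image_patient,
                                        patient_id = image_id)
  cb_img <- cluster_bootstrap(ev_img, B = 400, seed = 4)
  wp <- with(cb_pat$summary[cb_pat$summary$metric == "accuracy", ],
             ci_high - ci_low)
  wi <- with(cb_img$summary[cb_img$summary$metric == "accuracy", ],
             ci_high - ci_low)
  expect_gt(wp, wi * 1.5)
})

test_that("one-sided paired bootstrap test behaves at its extremes", {
  study <- simulate_reader_study(cohort_config(n_patients = 25),
                                 study_reader_panel(5),
                                 panel_size_range = c(4, 5), seed = 16)
  lsets <- truth_label_sets(study$cohort,
                            sort(unique(study$ratings$reader_id)))
  # A strictly better than B everywhere: perfect readers vs inverted AI
  ratings <- study$ratings
  truth <- study$cohort$images
  ratings$rating <- ifelse(
    truth$true_label[match(ratings$image_id, truth$image_id)] == 1L, 8L, 1L)
  scores <- tibble::tibble(
    image_id = truth$image_id,
    probability = ifelse(truth$true_label == 1L, 0.05, 0.95)
  )
  ev <- evaluate_strategies(ratings, scores,
                            strategies = c("physician", "ai"),
                            seed = 16, label_sets = lsets)
  sep <- one_sided_bootstrap_test(ev, "physician", "ai", B = 100, seed = 16)
  expect_equal(sep$p_value, 0)
  # the paired self-comparison is all ties, counted conservatively
  tie <- one_sided_bootstrap_test(ev, "ai", "ai", B = 50, seed = 16)
  expect_equal(tie$p_value, 1)
  # identically distributed but independently resampled replicates of a
  # noisy strategy: p near 1/2 (slightly above, ties count as <=)
  ev_noisy <- evaluate_strategies(study$ratings, study$scores,
                                  strategies = "physician", seed = 16)
  null <- one_sided_bootstrap_test(ev_noisy, "physician", "physician",
                                   B = 400, seed = 16,
                                   method = "independent")
  expect_gt(null$p_value, 0.35)
  expect_lt(null$p_value, 0.75)
})

test_that("AI outperforms readers with p < 0.05 in most calibrated runs", {
  # a panel whose leave-one-out accuracies sit near the published pair
  # (readers ~0.81, AI ~0.85): the one-sided cluster-bootstrap comparison
  # should reach p < 0.05 in the majority of study repetitions
  base <- c(0.95, 0.94, 0.93, 0.92, 0.91, 0.90, 0.86, 0.83, 0.80)
  readers <- lapply(1:9, function(i)
    reader_model(sprintf("reader_%02d", i), base[i], 0.40))
  wins <- 0
  gaps <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_reader_study(readers = readers, seed = 500 + s)
    ev <- evaluate_strategies(sim$ratings, sim$scores,
                              strategies = c("physician", "ai"),
                              seed = 500 + s)
    mm <- mean_reader_metrics(ev)
    acc <- with(mm[mm$metric == "accuracy", ], setNames(estimate, strategy))
    gaps <- c(gaps, acc[["ai"]] - acc[["physician"]])
    p <- one_sided_bootstrap_test(ev, "ai", "physician", B = 400,
                                  seed = 500 + s)$p_value
    wins <- wins + (p < 0.05)
  }
  expect_gt(mean(gaps), 0.02)
  expect_gte(wins, 6)
})

test_that("stratified report partitions the subset and tracks difficulty", {
  study <- simulate_reader_study(cohort_config(n_patients = 400), seed = 44)
  ls <- loo_label_sets(study$ratings, warn_small_panels = FALSE)
  rep <- stratified_report(study$ratings, study$scores, ls)
  # strata partition each reader's reviewed subset
  tot <- rep$per_reader |>
    dplyr::group_by(stratification, reader_id) |>
    dplyr::summarise(n = sum(n), .groups = "drop") |>
    dplyr::inner_join(dplyr::count(study$ratings, reader_id),
                      by = "reader_id")
  expect_true(all(tot$n.x == tot$n.y))
  sm <- rep$summary
  diffic <- sm[sm$stratification == "difficulty", ]
  # the calibrated generator reproduces the reader/AI crossover:
  # AI ahead on non-difficult images, readers ahead on difficult ones
  expect_gt(diffic$ai_accuracy[diffic$stratum == "non_difficult"],
            diffic$reader_accuracy[diffic$stratum == "non_difficult"])
  expect_gt(diffic$reader_accuracy[diffic$stratum == "difficult"],
            diffic$ai_accuracy[diffic$stratum == "difficult"])
  # each side is more accurate where the other is uncertain
  ru <- sm[sm$stratification == "reader_uncertainty" &
             sm$stratum == "uncertain", ]
  expect_gt(ru$ai_accuracy, ru$reader_accuracy)
  au <- sm[sm$stratification == "ai_uncertainty" & sm$stratum == "uncertain", ]
  expect_gt(au$reader_accuracy, au$ai_accuracy)
})

test_that("a flat-difficulty AI is equally accurate in every stratum", {
  cc <- cohort_config(n_patients = 700)
  cohort <- generate_cohort(cc, seed = 9)
  readers <- study_reader_panel(9)
  ratings <- generate_ratings(cohort, readers, c(6, 9), seed = 9)
  flat_ai <- ai_model(base_accuracy = 0.9, difficulty_slope = 0)
  scores <- generate_ai_scores(cohort, flat_ai, seed = 9)
  ls <- loo_label_sets(ratings, warn_small_panels = FALSE)
  # against the truth (not the panel consensus, which is itself
  # difficulty-dependent) the flat AI shows no difficulty gradient
  truth <- cohort$images
  flags <- difficulty_flags(ratings, ls$.all)
  d <- dplyr::inner_join(scores, truth, by = "image_id") |>
    dplyr::inner_join(flags, by = "image_id") |>
    dplyr::mutate(correct = as.integer(rating_to_binary(rating_equiv)) ==
                    true_label)
  acc <- tapply(d$correct, d$difficult, mean)
  expect_lt(abs(acc[["TRUE"]] - acc[["FALSE"]]), 0.05)
})
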