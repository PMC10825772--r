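small_config <- function(...) {
  calibrated_sim_config(group_sizes = stats::setNames(rep(10L, 5), c(
    "CP-RX", "CP-nonRX", "OUD-DX", "OUD-TX", "Control")), ...)
}

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config()
  s1 <- simulate_corpus(cfg, seed = 5)
  s2 <- simulate_corpus(cfg, seed = 5)
  expect_identical(s1$truth, s2$truth)
  for (part in c("patients", "encounters", "notes", "sentences", "annotations")) {
    expect_identical(s1$corpus[[part]], s2$corpus[[part]])
  }
  s3 <- simulate_corpus(cfg, seed = 6)
  expect_false(identical(s1$corpus$annotations, s3$corpus$annotations))
  expect_error(simulate_corpus(cfg), "seed")
})

test_that("simulated corpora validate and serialize round trip", {
  sim <- simulate_corpus(small_config(), seed = 9)
  expect_s3_class(validate_corpus(sim$corpus), "oud_corpus")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(sim$corpus, path)
  back <- suppressMessages(read_corpus(path))
  expect_equal(nrow(back$annotations), nrow(sim$corpus$annotations))
  expect_setequal(back$patients$patient_id, sim$corpus$patients$patient_id)
})

test_that("scoring a dropout-free simulation recovers every true category", {
  cw <- default_crosswalk()
  sim <- simulate_corpus(small_config(), cw, seed = 21)
  scored <- score_corpus(sim$corpus, cw)
  merged <- dplyr::inner_join(scored$scores, sim$truth, by = "patient_id")
  expect_equal(nrow(merged), sum(sim$truth$annotatable))
  expect_equal(merged$score, merged$true_score)
  expect_equal(as.character(merged$category), as.character(merged$true_category))
  expect_equal(merged$forced.x, merged$forced.y)
  # patients without annotatable content are reported unscored
  expect_setequal(scored$unscored$patient_id,
                  sim$truth$patient_id[!sim$truth$annotatable])
})

test_that("note dropout only ever lowers scores, never raises them", {
  cw <- default_crosswalk()
  dropped <- simulate_corpus(small_config(dropout = 0.4), cw, seed = 33)
  deg <- score_corpus(dropped$corpus, cw)$scores
  merged <- dplyr::inner_join(deg, dropped$truth, by = "patient_id")
  expect_gt(nrow(merged), 0)
  expect_true(all(merged$score <= merged$true_score))
  expect_true(all(as.integer(merged$category) <= as.integer(merged$true_category)))
})

test_that("controls never receive scoring classes", {
  cw <- default_crosswalk()
  control_only <- calibrated_sim_config(
    group_sizes = c("CP-RX" = 0L, "CP-nonRX" = 0L, "OUD-DX" = 0L,
                    "OUD-TX" = 0L, "Control" = 30L))
  sim <- simulate_corpus(control_only, cw, seed = 13)
  scored <- score_corpus(sim$corpus, cw)
  expect_true(all(scored$scores$score == 0))
  expect_true(all(scored$scores$category == "none"))
  expect_true(all(sim$truth$true_score == 0))
})

test_that("generator recovers configured marginals at large n", {
  cw <- default_crosswalk()
  n <- 400L
  cfg <- calibrated_sim_config(group_sizes = stats::setNames(rep(n, 5), c(
    "CP-RX", "CP-nonRX", "OUD-DX", "OUD-TX", "Control")))
  sim <- simulate_corpus(cfg, cw, seed = 77)
  # annotatable fraction per group within 3 Monte-Carlo SEs
  frac <- tapply(sim$truth$annotatable, sim$truth$group, mean)
  for (g in names(cfg$p_annotatable)) {
    p <- cfg$p_annotatable[[g]]
    se <- sqrt(p * (1 - p) / n)
    expect_lte(abs(frac[[g]] - p), max(3 * se, 1e-9))
  }
  # mean annotated sentences per annotated note, per note type, within 3 SEs
  tab <- annotation_table(sim$corpus, "gold")
  per_note <- tab |>
    dplyr::distinct(note_type, note_id, sentence_id) |>
    dplyr::count(note_type, note_id)
  stats_nt <- per_note |>
    dplyr::group_by(note_type) |>
    dplyr::summarise(m = mean(n), s = stats::sd(n), k = dplyr::n())
  for (r in seq_len(nrow(stats_nt))) {
    target <- cfg$sentence_means[[stats_nt$note_type[r]]]
    se <- stats_nt$s[r] / sqrt(stats_nt$k[r])
    expect_lte(abs(stats_nt$m[r] - target), max(3 * se, 1e-9))
  }
})

test_that("annotator disagreement layers support agreement analysis", {
  cw <- default_crosswalk()
  sim <- simulate_corpus(small_config(
    disagreement = list(miss = 0.2, relabel = 0.1)), cw, seed = 55)
  annotators <- unique(sim$corpus$annotations$annotator_id)
  expect_setequal(annotators, c("gold", "A1", "A2"))
  iaa <- iaa_by_batch(sim$corpus, "A1", "A2")
  expect_true(all(iaa$agreement_pct >= 0 & iaa$agreement_pct <= 100))
  expect_true(any(iaa$agreement_pct < 100))
  # gold layer is untouched by the disagreement machinery
  scored <- score_corpus(sim$corpus, cw)
  merged <- dplyr::inner_join(scored$scores, sim$truth, by = "patient_id")
  expect_equal(merged$score, merged$true_score)
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(p_annotatable = c("CP-RX" = 1.2)), "missing group")
  expect_error(small_config(dropout = 1.5), "\\[0, 1\\]")
  expect_error(
    sim_config(note_type_mix = list(ED = c(ed = 0.5))), "sum to 1")
  expect_error(sim_config(sentence_means = c(progress = 0.5)), ">= 1")
})
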