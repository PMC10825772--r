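# Two-annotator tables over one batch, built from unit specs of
# (sentence, class) pairs.
two_annotator_corpus <- function(units_a1, units_a2, note_type = "progress") {
  mk <- function(units, who) {
    tibble::tibble(
      patient_id = "P1",
      class = vapply(units, `[[`, character(1), 2),
      sentence_id = vapply(units, `[[`, character(1), 1),
      annotator_id = who,
      note_type = note_type
    )
  }
  make_corpus(dplyr::bind_rows(mk(units_a1, "A1"), mk(units_a2, "A2")))
}

test_that("agreement matches the hand-counted oracle", {
  # |A| = 8, |B| = 6, |A intersect B| = 5:
  # positive agreement 5/9 = 55.6%, F1 = 10/14 = 71.4%
  a_units <- lapply(1:8, function(i) c(paste0("S", i), "A"))
  b_units <- lapply(c(1:5, 9), function(i) c(paste0("S", i), "A"))
  corpus <- two_annotator_corpus(a_units, b_units)
  t1 <- annotation_table(corpus, "A1")
  t2 <- annotation_table(corpus, "A2")
  pa <- batch_agreement(t1, t2, "positive_agreement")
  expect_equal(pa$n_units_a1, 8)
  expect_equal(pa$n_units_a2, 6)
  expect_equal(pa$n_agree, 5)
  expect_equal(round_half_up(pa$agreement_pct, 1), 55.6)
  f1 <- batch_agreement(t1, t2, "f1")
  expect_equal(round_half_up(f1$agreement_pct, 1), 71.4)
})

test_that("identical, disjoint and empty unit sets hit the boundary values", {
  same <- lapply(1:10, function(i) c(paste0("S", i), "A"))
  corpus <- two_annotator_corpus(same, same)
  t1 <- annotation_table(corpus, "A1"); t2 <- annotation_table(corpus, "A2")
  expect_equal(batch_agreement(t1, t2)$agreement_pct, 100)
  expect_equal(batch_agreement(t1, t2, "f1")$agreement_pct, 100)

  # same sentence, different class: fully discordant under both metrics
  corpus <- two_annotator_corpus(list(c("S1", "A")), list(c("S1", "B")))
  t1 <- annotation_table(corpus, "A1"); t2 <- annotation_table(corpus, "A2")
  expect_equal(batch_agreement(t1, t2)$agreement_pct, 0)
  expect_equal(batch_agreement(t1, t2, "f1")$agreement_pct, 0)

  # both empty: agreement defined as 100
  empty <- annotation_table(make_corpus(
    tibble::tibble(patient_id = "P1", class = "A")), "gold")[0, ]
  expect_equal(batch_agreement(empty, empty)$agreement_pct, 100)
})

test_that("agreement is symmetric, Jaccard <= Dice, and improves with agreed units", {
  set.seed(303)
  for (i in 1:15) {
    a <- sample(1:12, sample(2:10, 1))
    b <- sample(1:12, sample(2:10, 1))
    corpus <- two_annotator_corpus(
      lapply(a, function(i) c(paste0("S", i), "A")),
      lapply(b, function(i) c(paste0("S", i), "A"))
    )
    t1 <- annotation_table(corpus, "A1"); t2 <- annotation_table(corpus, "A2")
    pa_ab <- batch_agreement(t1, t2)$agreement_pct
    pa_ba <- batch_agreement(t2, t1)$agreement_pct
    expect_equal(pa_ab, pa_ba)
    f1 <- batch_agreement(t1, t2, "f1")$agreement_pct
    expect_lte(pa_ab, f1)

    # adding one unit agreed by both never lowers either metric
    extra <- tibble::tibble(patient_id = "P1", group = "OUD-DX",
                            index_reason = "oud_diagnosis", position = "index",
                            setting = "OPT", note_type = "progress",
                            note_id = t1$note_id[1], sentence_id = "S99",
                            class = "B", attributes = list(list()))
    expect_gte(batch_agreement(rbind(t1, extra), rbind(t2, extra))$agreement_pct,
               pa_ab)
    expect_gte(batch_agreement(rbind(t1, extra), rbind(t2, extra), "f1")$agreement_pct,
               f1)
  }
})

test_that("strict attribute mode detects attribute-only discordance", {
  ann <- tibble::tibble(
    patient_id = "P1",
    class = c("psychiatric condition", "psychiatric condition"),
    sentence_id = c("S1", "S1"),
    annotator_id = c("A1", "A2"),
    attributes = list(list(temporality = "current"),
                      list(temporality = "historic"))
  )
  corpus <- make_corpus(ann)
  t1 <- annotation_table(corpus, "A1"); t2 <- annotation_table(corpus, "A2")
  expect_equal(batch_agreement(t1, t2)$agreement_pct, 100)
  expect_equal(batch_agreement(t1, t2, strict_attributes = TRUE)$agreement_pct, 0)
})

test_that("discordance_report lists exactly the symmetric difference", {
  a_units <- list(c("S1", "A"), c("S2", "A"), c("S3", "B"))
  b_units <- list(c("S1", "A"), c("S2", "B"), c("S4", "A"))
  corpus <- two_annotator_corpus(a_units, b_units)
  t1 <- annotation_table(corpus, "A1"); t2 <- annotation_table(corpus, "A2")
  rep <- discordance_report(t1, t2)
  expect_equal(nrow(rep), 4)
  expect_setequal(paste(rep$sentence_id, rep$class, rep$only),
                  c("S2 A A1", "S3 B A1", "S2 B A2", "S4 A A2"))
  expect_equal(nrow(discordance_report(t1, t1)), 0)
})

test_that("batches spanning several note types are rejected", {
  ann <- tibble::tibble(
    patient_id = "P1", class = "A",
    note_type = c("progress", "ed"), annotator_id = c("A1", "A2"),
    setting = c("OPT", "ED"), position = c("index", "new")
  )
  corpus <- make_corpus(ann)
  expect_error(
    batch_agreement(annotation_table(corpus, "A1"),
                    annotation_table(corpus, "A2")),
    "multiple note types")
})

test_that("iaa_by_batch produces one row per note type", {
  ann <- tibble::tibble(
    patient_id = "P1",
    class = c("A", "A", "B", "B"),
    sentence_id = c("S1", "S1", "S2", "S2"),
    note_type = c("progress", "progress", "ed", "ed"),
    setting = c("OPT", "OPT", "ED", "ED"),
    position = c("index", "index", "new", "new"),
    annotator_id = c("A1", "A2", "A1", "A2")
  )
  corpus <- make_corpus(ann)
  iaa <- iaa_by_batch(corpus, "A1", "A2")
  expect_equal(sort(iaa$note_type), c("ed", "progress"))
  expect_equal(iaa$agreement_pct, c(100, 100))
})
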