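test_that("frequency matrices cross-tabulate class events over closed axes", {
  tab <- annotation_table(make_corpus(tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    class = c("A", "A", "B"),
    note_type = c("progress", "ed", "progress"),
    setting = c("OPT", "ED", "OPT"),
    position = c("index", "new", "index")
  )), "gold")
  m <- frequency_matrix(tab, "note_type")
  expect_equal(dim(m), c(2L, 11L))
  expect_equal(m["A", "progress"], 1L)
  expect_equal(m["A", "ed"], 1L)
  expect_equal(sum(m), 3L)
  expect_equal(attr(m, "col_totals")[["lactation"]], 0L)

  # all three axes share the grand total of class events
  expect_equal(sum(frequency_matrix(tab, "setting")), sum(m))
  expect_equal(sum(frequency_matrix(tab, "position")), sum(m))

  # empty table with a fixed class set: zero matrix with full column set
  m0 <- frequency_matrix(tab[0, ], "setting", classes = c("A", "B"))
  expect_equal(dim(m0), c(2L, 4L))
  expect_true(all(m0 == 0L))

  # a class seen only at the index encounter has all its mass there
  m_pos <- frequency_matrix(tab, "position")
  expect_equal(m_pos["B", "index"], sum(m_pos["B", ]))
})

test_that("note_yield reproduces the published yield statistics", {
  ny <- note_yield(reference_note_yield_corpus())
  progress <- ny[ny$note_type == "progress", ]
  expect_equal(progress$n_notes, 92)
  expect_equal(progress$n_annotated_notes, 62)
  expect_equal(progress$n_sentences_annotated, 574)
  expect_equal(round_half_up(progress$mean_sentences, 1), 9.3)
  hp <- ny[ny$note_type == "h_and_p", ]
  expect_equal(hp$pct_annotated, 90)
  expect_equal(hp$n_ED_to_IPT, 13)
  expect_equal(sum(ny$n_sentences_annotated), 1436)
  expect_equal(sum(ny$n_notes), 320)
  expect_equal(sum(ny$n_annotated_notes), 186)
  # single annotated lactation note: mean defined, SD not
  lact <- ny[ny$note_type == "lactation", ]
  expect_equal(lact$mean_sentences, 1)
  expect_true(is.na(lact$sd_sentences))
})

test_that("note types absent from a corpus appear with zeros and NA means", {
  ny <- note_yield(make_corpus(tibble::tibble(patient_id = "P1", class = "A")))
  lact <- ny[ny$note_type == "lactation", ]
  expect_equal(lact$n_notes, 0)
  expect_true(is.na(lact$mean_sentences))
  expect_true(is.na(lact$sd_sentences))
})

test_that("pair correlation matches a closed-form oracle on a toy matrix", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,   # proportional to row 1
                5, 1, 0, 2,
                3, 3, 3, 3),  # zero variance
              nrow = 4, byrow = TRUE,
              dimnames = list(class = c("w", "x", "y", "z"),
                              note_type = paste0("t", 1:4)))
  pc <- pair_correlation(m)
  expect_equal(pc["w", "x"], 1)
  expect_equal(pc["w", "w"], 1)
  # independently hand-computed Pearson correlation of rows w and y
  oracle <- stats::cor(c(1, 2, 3, 4), c(5, 1, 0, 2))
  expect_equal(pc["w", "y"], oracle)
  expect_equal(pc, t(pc))
  # zero-variance row flagged as undefined, not zeroed
  expect_true(all(is.na(pc["z", ])))
  expect_equal(attr(pc, "undefined_classes"), "z")
  # invariant under column reordering
  pc2 <- pair_correlation(m[, c(3, 1, 4, 2)])
  expect_equal(pc2, pc, ignore_attr = TRUE)

  expect_error(pair_correlation(m[, 1, drop = FALSE]), "at least 2")
  s <- pair_correlation(m, method = "spearman")
  expect_equal(s["w", "x"], 1)
})

test_that("patient co-occurrence equals the brute-force double loop", {
  set.seed(404)
  classes <- LETTERS[1:6]
  ann <- tibble::tibble(
    patient_id = sample(sprintf("P%02d", 1:20), 120, replace = TRUE),
    class = sample(classes, 120, replace = TRUE)
  )
  tab <- annotation_table(make_corpus(ann), "gold")
  m <- patient_cooccurrence(tab, classes = classes)

  patients <- unique(tab$patient_id)
  for (i in classes) {
    for (j in classes) {
      brute <- sum(vapply(patients, function(p) {
        cls <- tab$class[tab$patient_id == p]
        (i %in% cls) && (j %in% cls)
      }, logical(1)))
      expect_equal(m[i, j], brute)
    }
  }
  expect_equal(m, t(m))
  # pair counts never exceed the marginal patient counts
  for (i in classes) for (j in classes) {
    expect_lte(m[i, j], min(m[i, i], m[j, j]))
  }
})

test_that("single-patient and absent-class co-occurrence behave", {
  tab <- annotation_table(make_corpus(tibble::tibble(
    patient_id = "P1", class = c("A", "B"))), "gold")
  m <- patient_cooccurrence(tab, classes = c("A", "B", "C"))
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["A", "A"], 1L)
  expect_true(all(m["C", ] == 0L))
})

test_that("write_patterns emits the full analytics file set", {
  dir <- withr::local_tempdir()
  corpus <- make_corpus(tibble::tibble(
    patient_id = c("P1", "P2"), class = c("A", "B"),
    note_type = c("progress", "ed"), setting = c("OPT", "ED"),
    position = c("index", "index")))
  files <- write_patterns(corpus, dir)
  expect_true(all(file.exists(files)))
  freq <- utils::read.csv(files["freq_by_notetype"], row.names = 1)
  expect_equal(sum(freq), 2)
})
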