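test_that("shipped crosswalk has the documented shape", {
  cw <- default_crosswalk()
  ct <- crosswalk_counts(cw)
  expect_equal(ct$total_classes, 27)
  expect_equal(ct$scoring_classes, 18)
  expect_equal(ct$attributed_classes, 12)
  expect_true("OUD treatment" %in% force_severe_classes(cw))
  # the 18 scoring classes jointly cover every DSM-5 criterion (computed by
  # brute-force union over the shipped config)
  expect_equal(criteria_for(scoring_classes(cw), cw), 1:11)
})

test_that("crosswalk validation rejects malformed configs", {
  minimal <- list(version = "t", classes = list(
    list(name = "X", category = "other", scoring = FALSE)))
  expect_s3_class(as_crosswalk(minimal), "oud_crosswalk")

  bad_crit <- minimal
  bad_crit$classes[[1]] <- list(name = "X", category = "other",
                                scoring = TRUE, criteria = 12L)
  expect_error(as_crosswalk(bad_crit), "outside 1..11",
               class = "oudseverity_validation_error")

  dup <- list(version = "t", classes = list(
    list(name = "X", category = "other", scoring = FALSE),
    list(name = "X", category = "other", scoring = FALSE)))
  expect_error(as_crosswalk(dup), "duplicate class",
               class = "oudseverity_validation_error")

  no_grant <- list(version = "t", classes = list(
    list(name = "X", category = "other", scoring = TRUE)))
  expect_error(as_crosswalk(no_grant), "neither criteria nor force_category",
               class = "oudseverity_validation_error")

  bad_counts <- list(version = "t",
                     expected_counts = list(total_classes = 5),
                     classes = list(list(name = "X", category = "other",
                                         scoring = FALSE)))
  expect_error(as_crosswalk(bad_counts), "expected_counts")
})

test_that("criteria_for unions class mappings and respects restrictions", {
  cw <- toy_crosswalk()
  expect_equal(criteria_for(character(0), cw), integer(0))
  expect_equal(criteria_for(c("A", "B"), cw), c(1L, 2L, 3L))
  expect_equal(criteria_for(c("B", "C"), cw), 2:4)
  expect_equal(criteria_for(c("A", "A", "D"), cw), 1L)
  expect_error(criteria_for("nope", cw), "unknown annotation class",
               class = "oudseverity_lookup_error")

  # a mapping restricted to temporality=current is withheld for historic
  restricted <- as_crosswalk(list(version = "t", classes = list(
    list(name = "A", category = "opioid_misuse", scoring = TRUE,
         criteria = 4L,
         attributes = list(temporality = list("current", "historic")),
         restrict = list(attribute = "temporality", values = list("current")))
  )))
  expect_equal(criteria_for("A", restricted,
                            attributes = list(list(temporality = "current"))), 4L)
  expect_equal(criteria_for("A", restricted,
                            attributes = list(list(temporality = "historic"))),
               integer(0))
  # annotations lacking the attribute still grant the criterion
  expect_equal(criteria_for("A", restricted, attributes = list(list())), 4L)
})

test_that("criteria_for is monotone under set growth and bounded by 11", {
  cw <- default_crosswalk()
  all_classes <- names(cw$classes)
  set.seed(101)
  for (i in 1:25) {
    t_set <- sample(all_classes, sample(3:15, 1))
    s_set <- sample(t_set, sample(seq_along(t_set), 1))
    cs <- criteria_for(s_set, cw)
    ct <- criteria_for(t_set, cw)
    expect_true(all(cs %in% ct))
    expect_lte(length(ct), 11)
  }
})

test_that("crosswalk round trips through YAML", {
  cw <- default_crosswalk()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_crosswalk(cw, path)
  expect_equal(load_crosswalk(path), cw, ignore_attr = FALSE)

  toy <- toy_crosswalk()
  write_crosswalk(toy, path)
  expect_equal(load_crosswalk(path)$classes, toy$classes)
})

test_that("force_severe_classes returns exactly the forced classes", {
  none <- as_crosswalk(list(version = "t", classes = list(
    list(name = "X", category = "other", scoring = FALSE))))
  expect_equal(force_severe_classes(none), character(0))
  two <- as_crosswalk(list(version = "t", classes = list(
    list(name = "X", category = "opioid_misuse", scoring = TRUE,
         force_category = "severe"),
    list(name = "Y", category = "opioid_misuse", scoring = TRUE,
         force_category = "severe"),
    list(name = "Z", category = "opioid_misuse", scoring = TRUE, criteria = 1L))))
  expect_setequal(force_severe_classes(two), c("X", "Y"))
})
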