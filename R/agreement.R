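# Interannotator agreement over (sentence, class) units.
#
# The agreement unit is a (note_id, sentence_id, class) triple -- a single
# multi-label assignment -- optionally extended with attribute values
# ("strict" mode). Chance-corrected coefficients are deliberately absent:
# kappa is ill-defined for open multi-label sentence annotation, so positive
# (Jaccard) percent agreement is the default and F1/Dice the alternative.

agreement_units <- function(tab, strict_attributes = FALSE) {
  key <- paste(tab$note_id, tab$sentence_id, tab$class, sep = "\r")
  if (strict_attributes) {
    at <- vapply(tab$attributes, function(x) {
      if (!length(x)) return("")
      ord <- order(names(x))
      paste(names(x)[ord], unlist(x)[ord], sep = "=", collapse = ";")
    }, character(1))
    key <- paste(key, at, sep = "\r")
  }
  unique(key)
}

agreement_pct <- function(n_a, n_b, n_agree, metric) {
  if (n_a == 0L && n_b == 0L) return(100)
  switch(metric,
    positive_agreement = 100 * n_agree / (n_a + n_b - n_agree),
    f1 = 100 * 2 * n_agree / (n_a + n_b),
    stop_validation(sprintf("unknown agreement metric '%s'", metric))
  )
}

#' Agreement between two annotators on one batch of notes
#'
#' Computes percent agreement over `(sentence, class)` units for a batch.
#' `positive_agreement` is the Jaccard form `100 |A ∩ B| / |A ∪ B|`;
#' `f1` is the Dice form `100 * 2|A ∩ B| / (|A| + |B|)`. Both are 100
#' when neither annotator produced a unit.
#'
#' @param tab_a1,tab_a2 Annotation tables (see [annotation_table()]) for the
#'   two annotators, restricted to the same batch of notes.
#' @param metric `"positive_agreement"` (default) or `"f1"`.
#' @param strict_attributes If `TRUE`, attribute values are part of the
#'   agreement unit, so a class agreed with discordant attributes counts as
#'   disagreement.
#' @param batch_id Optional batch label carried into the result.
#' @return One-row tibble: `batch_id`, `note_type`, `n_notes`, `n_units_a1`,
#'   `n_units_a2`, `n_agree`, `agreement_pct`, `metric`.
#' @export
batch_agreement <- function(tab_a1, tab_a2, metric = "positive_agreement",
                            strict_attributes = FALSE, batch_id = NA_character_) {
  types <- union(unique(tab_a1$note_type), unique(tab_a2$note_type))
  if (length(types) > 1L) {
    stop_validation(sprintf(
      "annotation sets span multiple note types (%s); batches are per note type",
      paste(types, collapse = ", ")))
  }
  a <- agreement_units(tab_a1, strict_attributes)
  b <- agreement_units(tab_a2, strict_attributes)
  n_agree <- length(intersect(a, b))
  tibble::tibble(
    batch_id = batch_id,
    note_type = if (length(types)) types else NA_character_,
    n_notes = dplyr::n_distinct(c(tab_a1$note_id, tab_a2$note_id)),
    n_units_a1 = length(a),
    n_units_a2 = length(b),
    n_agree = n_agree,
    agreement_pct = agreement_pct(length(a), length(b), n_agree, metric),
    metric = metric
  )
}

#' Per-batch agreement across a corpus
#'
#' Batches follow the annotation workflow: each note type is one batch.
#'
#' @param corpus An `oud_corpus` carrying at least two annotator layers.
#' @param a1,a2 Annotator ids.
#' @inheritParams batch_agreement
#' @return Tibble with one [batch_agreement()] row per note type present.
#' @export
iaa_by_batch <- function(corpus, a1, a2, metric = "positive_agreement",
                         strict_attributes = FALSE) {
  t1 <- annotation_table(corpus, a1)
  t2 <- annotation_table(corpus, a2)
  types <- sort(union(unique(t1$note_type), unique(t2$note_type)))
  purrr::map_dfr(types, function(tt) {
    batch_agreement(
      t1[t1$note_type == tt, ], t2[t2$note_type == tt, ],
      metric = metric, strict_attributes = strict_attributes, batch_id = tt
    )
  })
}

#' Discordant units between two annotators
#'
#' The symmetric difference of the two unit sets, for adjudication: every
#' `(sentence, class)` assignment made by exactly one annotator, ordered by
#' note then sentence.
#'
#' @inheritParams batch_agreement
#' @return Tibble: `note_id`, `sentence_id`, `class`, `only` (`"A1"` or
#'   `"A2"`), `text` (sentence text when present in the source table).
#' @export
discordance_report <- function(tab_a1, tab_a2, strict_attributes = FALSE) {
  key_cols <- c("note_id", "sentence_id", "class")
  u1 <- dplyr::distinct(tab_a1[, key_cols])
  u2 <- dplyr::distinct(tab_a2[, key_cols])
  only1 <- dplyr::anti_join(u1, u2, by = key_cols)
  only2 <- dplyr::anti_join(u2, u1, by = key_cols)
  out <- dplyr::bind_rows(
    if (nrow(only1)) dplyr::mutate(only1, only = "A1"),
    if (nrow(only2)) dplyr::mutate(only2, only = "A2")
  )
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(note_id = character(0), sentence_id = character(0),
                          class = character(0), only = character(0)))
  }
  dplyr::arrange(out, .data$note_id, .data$sentence_id, .data$class)
}
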