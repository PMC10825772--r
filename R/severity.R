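# Severity thresholds: number of endorsed DSM-5 criteria -> category.
# 0-1 none, 2-3 mild, 4-5 moderate, >= SEVERE_MIN severe. The lower bound of
# "severe" is an explicit, overridable constant because the DSM-5 convention
# places a count of 6 in the severe band.
SEVERE_MIN <- 6L

#' Map a severity score to a severity category
#'
#' DSM-5 grading by endorsed-criterion count: 0-1 no OUD, 2-3 mild, 4-5
#' moderate, 6-11 severe. A forced classification (e.g. documented OUD
#' treatment) yields "severe" regardless of the count.
#'
#' @param score Integer vector of scores in 0..11.
#' @param forced Logical (recycled): force the severe category.
#' @param severe_min Lower score bound of the severe band (default 6).
#' @return Factor with levels `none < mild < moderate < severe`.
#' @export
#' @examples
#' categorize(c(0, 2, 5, 6))
#' categorize(0, forced = TRUE)
categorize <- function(score, forced = FALSE, severe_min = SEVERE_MIN) {
  if (any(is.na(score)) || any(score < 0L | score > N_CRITERIA) ||
      any(score != as.integer(score))) {
    stop_validation(sprintf("score must be an integer in 0..%d", N_CRITERIA))
  }
  out <- cut(as.integer(score),
             breaks = c(-1L, 1L, 3L, severe_min - 1L, N_CRITERIA),
             labels = CATEGORIES)
  out[rep_len(forced, length(out))] <- "severe"
  factor(out, levels = CATEGORIES, ordered = TRUE)
}

#' Score one patient's pooled annotations
#'
#' Criterion endorsement is binary per patient over the whole chart: the
#' distinct annotated classes (pooled across all notes and encounters) are
#' mapped through the crosswalk and the endorsed criteria unioned, so
#' repeated documentation of one class never inflates the score.
#'
#' @param classes Character vector of annotated class names (a multiset;
#'   duplicates are harmless).
#' @param crosswalk An `oud_crosswalk`.
#' @param attributes Optional list parallel to `classes` of attribute
#'   assignments, consulted only by crosswalk `restrict` clauses.
#' @return A one-row tibble: `endorsed_criteria` (list column of integer
#'   ids), `score`, `category`, `forced`.
#' @export
score_patient <- function(classes, crosswalk, attributes = NULL) {
  endorsed <- criteria_for(classes, crosswalk, attributes)
  forced <- any(classes %in% force_severe_classes(crosswalk))
  score <- length(endorsed)
  tibble::tibble(
    endorsed_criteria = list(endorsed),
    score = score,
    category = categorize(score, forced),
    forced = forced
  )
}

#' Score every patient in a corpus
#'
#' @param corpus An `oud_corpus`.
#' @param crosswalk An `oud_crosswalk`.
#' @param annotator_id Annotation layer to score; defaults to the
#'   adjudicated `"gold"` layer.
#' @return A list with
#'   * `scores`: one row per patient *with* annotations -- `patient_id`,
#'     `group`, `index_reason`, `score`, `category`, `forced`,
#'     `endorsed_criteria` (list column), `n_notes_annotated`,
#'     `n_sentences_annotated`;
#'   * `unscored`: patients without any annotation in that layer (they
#'     receive no score).
#' @export
score_corpus <- function(corpus, crosswalk, annotator_id = "gold") {
  tab <- annotation_table(corpus, annotator_id)
  unknown <- setdiff(unique(tab$class), names(crosswalk$classes))
  if (length(unknown)) {
    stop_lookup(sprintf("corpus contains class(es) absent from crosswalk: %s",
                        paste(unknown, collapse = ", ")))
  }
  scored_ids <- unique(tab$patient_id)
  if (!nrow(tab)) {
    empty <- tibble::tibble(
      patient_id = character(0), group = character(0),
      index_reason = character(0), score = integer(0),
      category = categorize(integer(0)), forced = logical(0),
      endorsed_criteria = list(), n_notes_annotated = integer(0),
      n_sentences_annotated = integer(0))
    return(list(scores = empty,
                unscored = dplyr::arrange(corpus$patients, .data$patient_id)))
  }
  scores <- tab %>%
    dplyr::group_by(.data$patient_id, .data$group, .data$index_reason) %>%
    dplyr::group_modify(function(d, key) {
      res <- score_patient(d$class, crosswalk, d$attributes)
      res$n_notes_annotated <- dplyr::n_distinct(d$note_id)
      res$n_sentences_annotated <- nrow(dplyr::distinct(d, .data$note_id,
                                                        .data$sentence_id))
      res
    }) %>%
    dplyr::ungroup() %>%
    dplyr::select("patient_id", "group", "index_reason", "score", "category",
                  "forced", "endorsed_criteria", "n_notes_annotated",
                  "n_sentences_annotated") %>%
    dplyr::arrange(.data$patient_id)
  unscored <- corpus$patients %>%
    dplyr::filter(!.data$patient_id %in% scored_ids) %>%
    dplyr::arrange(.data$patient_id)
  list(scores = scores, unscored = unscored)
}

#' Write a scores table to CSV
#'
#' @param scored Result of [score_corpus()] (the list) or its `scores`
#'   tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scored, path) {
  scores <- if (is.data.frame(scored)) scored else scored$scores
  scores$endorsed_criteria <- vapply(scores$endorsed_criteria,
                                     paste, character(1), collapse = ";")
  scores$category <- as.character(scores$category)
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
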