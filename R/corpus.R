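#' The annotated-corpus data model
#'
#' A corpus is the hierarchical Patient -> Encounter -> Note -> Sentence ->
#' Annotation structure held as a set of linked tibbles:
#'
#' * `patients`: `patient_id`, `group` (one of CP-RX, CP-nonRX, OUD-DX,
#'   OUD-TX, Control), `index_reason` (`oud_diagnosis` or `opioid_order`).
#' * `encounters`: `encounter_id`, `patient_id`, `position` (`historic`,
#'   `index`, `new` -- relative to the index encounter), `setting` (`ED`,
#'   `ED_to_IPT`, `OPT`, `IPT`), optional `date`.
#' * `notes`: `note_id`, `encounter_id`, `note_type` (closed set of 11).
#' * `sentences`: `note_id`, `sentence_id`, optional `text` (sentence text
#'   is optional so corpora can be fully de-identified).
#' * `annotations`: `note_id`, `sentence_id`, `annotator_id`, `class`,
#'   `attributes` (list column of named lists; may be empty).
#'
#' @param patients,encounters,notes,sentences,annotations Tibbles as above.
#' @param meta Named list of provenance metadata (e.g. `source`, `seed`).
#' @return An object of class `oud_corpus`.
#' @export
new_corpus <- function(patients = NULL, encounters = NULL, notes = NULL,
                       sentences = NULL, annotations = NULL, meta = list()) {
  corpus <- structure(
    list(
      patients = as_tbl(patients, c(patient_id = "character",
                                    group = "character",
                                    index_reason = "character")),
      encounters = as_tbl(encounters, c(encounter_id = "character",
                                        patient_id = "character",
                                        position = "character",
                                        setting = "character")),
      notes = as_tbl(notes, c(note_id = "character",
                              encounter_id = "character",
                              note_type = "character")),
      sentences = as_tbl(sentences, c(note_id = "character",
                                      sentence_id = "character",
                                      text = "character")),
      annotations = as_tbl(annotations, c(note_id = "character",
                                          sentence_id = "character",
                                          annotator_id = "character",
                                          class = "character"),
                           list_cols = "attributes"),
      meta = meta
    ),
    class = "oud_corpus"
  )
  validate_corpus(corpus)
}

as_tbl <- function(x, cols, list_cols = character(0)) {
  if (is.null(x)) {
    x <- tibble::as_tibble(
      stats::setNames(rep(list(character(0)), length(cols)), names(cols))
    )
  } else {
    x <- tibble::as_tibble(x)
  }
  for (nm in names(cols)) {
    if (!nm %in% names(x)) x[[nm]] <- rep(NA_character_, nrow(x))
    x[[nm]] <- as.character(x[[nm]])
  }
  for (nm in list_cols) {
    if (!nm %in% names(x)) x[[nm]] <- rep(list(list()), nrow(x))
  }
  x[, c(names(cols), list_cols), drop = FALSE]
}

#' Validate a corpus
#'
#' Checks the closed vocabularies, id uniqueness, referential integrity of
#' every link, and the encounter-design constraints (at most one encounter
#' per position per patient; the OUD-diagnosis groups are indexed on a
#' diagnosis and controls on an opioid order).
#'
#' @param corpus An `oud_corpus`.
#' @return The corpus, invisibly usable, after passing all checks.
#' @export
validate_corpus <- function(corpus) {
  p <- corpus$patients; e <- corpus$encounters
  n <- corpus$notes; s <- corpus$sentences; a <- corpus$annotations

  assert_one_of(p$group, GROUPS, "study group")
  assert_one_of(p$index_reason, INDEX_REASONS, "index_reason")
  assert_one_of(e$position, POSITIONS, "encounter position")
  assert_one_of(e$setting, SETTINGS, "encounter setting")
  assert_one_of(n$note_type, NOTE_TYPES, "note_type")

  for (chk in list(list(p$patient_id, "patient_id"),
                   list(e$encounter_id, "encounter_id"),
                   list(n$note_id, "note_id"))) {
    if (anyDuplicated(chk[[1]])) {
      stop_validation(sprintf("duplicate %s: %s", chk[[2]],
                              paste(unique(chk[[1]][duplicated(chk[[1]])]),
                                    collapse = ", ")))
    }
  }
  if (nrow(s) && anyDuplicated(s[, c("note_id", "sentence_id")])) {
    stop_validation("duplicate sentence_id within a note")
  }

  check_ref(e$patient_id, p$patient_id, "encounter", "patient_id")
  check_ref(n$encounter_id, e$encounter_id, "note", "encounter_id")
  check_ref(s$note_id, n$note_id, "sentence", "note_id")
  if (nrow(a)) {
    sent_keys <- paste(s$note_id, s$sentence_id, sep = "\r")
    ann_keys <- paste(a$note_id, a$sentence_id, sep = "\r")
    if (!all(ann_keys %in% sent_keys)) {
      stop_validation("annotation refers to a sentence that does not exist")
    }
  }

  # Design consistency: index reason is determined by group for the
  # diagnosis-defined groups and for controls.
  bad <- (p$group %in% c("OUD-DX", "OUD-TX") & p$index_reason != "oud_diagnosis") |
    (p$group == "Control" & p$index_reason != "opioid_order")
  if (any(bad)) {
    stop_validation(sprintf(
      "group/index_reason inconsistent for patient(s): %s",
      paste(p$patient_id[bad], collapse = ", ")))
  }
  if (nrow(e)) {
    per <- table(e$patient_id, factor(e$position, POSITIONS))
    if (any(per > 1L)) {
      stop_validation("a patient has more than one encounter at the same position")
    }
    has_any <- rownames(per)[rowSums(per) > 0L]
    no_index <- has_any[per[has_any, "index"] == 0L]
    if (length(no_index)) {
      stop_validation(sprintf("patient(s) with encounters but no index encounter: %s",
                              paste(no_index, collapse = ", ")))
    }
  }
  corpus
}

check_ref <- function(child, parent, what, field) {
  missing <- setdiff(unique(child), parent)
  if (length(missing)) {
    stop_validation(sprintf("%s refers to unknown %s: %s",
                            what, field, paste(missing, collapse = ", ")))
  }
}

#' @export
print.oud_corpus <- function(x, ...) {
  cat(sprintf(
    "<oud_corpus: %d patients, %d encounters, %d notes, %d sentences, %d annotations>\n",
    nrow(x$patients), nrow(x$encounters), nrow(x$notes),
    nrow(x$sentences), nrow(x$annotations)
  ))
  invisible(x)
}

#' Read an annotated corpus from JSONL
#'
#' One JSON object per note per line:
#' `{"patient": {...}, "encounter": {...}, "note": {...}, "sentences":
#' [{"sentence_id", "text"?, "annotations": [{"annotator_id", "class",
#' "attributes"?}]}]}`. Patients and encounters repeated across lines must
#' agree; validation failures report the offending line.
#'
#' @param path Path to a JSONL corpus file.
#' @return An `oud_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  pat <- list(); enc <- list(); nts <- list(); sen <- list(); ann <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop_validation(
        sprintf("line %d: invalid JSON (%s)", i, conditionMessage(e)))
    )
    tryCatch({
      pat[[i]] <- tibble::tibble(
        patient_id = rec$patient$patient_id,
        group = rec$patient$group,
        index_reason = rec$patient$index_reason
      )
      enc[[i]] <- tibble::tibble(
        encounter_id = rec$encounter$encounter_id,
        patient_id = rec$patient$patient_id,
        position = rec$encounter$position,
        setting = rec$encounter$setting
      )
      nts[[i]] <- tibble::tibble(
        note_id = rec$note$note_id,
        encounter_id = rec$encounter$encounter_id,
        note_type = rec$note$note_type
      )
      sents <- rec$sentences %||% list()
      if (length(sents)) {
        sen[[i]] <- tibble::tibble(
          note_id = rec$note$note_id,
          sentence_id = vapply(sents, function(s) as.character(s$sentence_id),
                               character(1)),
          text = vapply(sents, function(s) {
            if (is.null(s$text)) NA_character_ else as.character(s$text)
          }, character(1))
        )
        ann[[i]] <- purrr::map_dfr(sents, function(s) {
          anns <- s$annotations %||% list()
          if (!length(anns)) return(NULL)
          tibble::tibble(
            note_id = rec$note$note_id,
            sentence_id = as.character(s$sentence_id),
            annotator_id = vapply(anns, function(x) as.character(x$annotator_id),
                                  character(1)),
            class = vapply(anns, function(x) as.character(x$class), character(1)),
            attributes = lapply(anns, function(x) x$attributes %||% list())
          )
        })
      }
    }, error = function(e) {
      if (inherits(e, "oudseverity_error")) stop(e)
      stop_validation(sprintf("line %d: malformed record (%s)", i,
                              conditionMessage(e)))
    })
  }

  if (!length(lines)) {
    corpus <- new_corpus(meta = list(source = path))
    message("read corpus: 0 patients, 0 notes, 0 sentences, 0 annotations")
    return(corpus)
  }
  patients <- dplyr::distinct(dplyr::bind_rows(pat))
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)]
    stop_validation(sprintf("patient %s described inconsistently across lines",
                            paste(unique(dup), collapse = ", ")))
  }
  encounters <- dplyr::distinct(dplyr::bind_rows(enc))
  if (anyDuplicated(encounters$encounter_id)) {
    dup <- encounters$encounter_id[duplicated(encounters$encounter_id)]
    stop_validation(sprintf("encounter %s described inconsistently across lines",
                            paste(unique(dup), collapse = ", ")))
  }
  corpus <- new_corpus(
    patients = patients,
    encounters = encounters,
    notes = dplyr::bind_rows(nts),
    sentences = dplyr::bind_rows(sen),
    annotations = dplyr::bind_rows(ann),
    meta = list(source = path)
  )
  message(sprintf(
    "read corpus: %d patients, %d notes, %d sentences, %d annotations",
    nrow(corpus$patients), nrow(corpus$notes),
    nrow(corpus$sentences), nrow(corpus$annotations)
  ))
  corpus
}

#' Write a corpus to JSONL
#'
#' Emits one note per line with a deterministic field order, so identical
#' corpora serialize to identical bytes.
#'
#' @param corpus An `oud_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  n <- corpus$notes
  e <- corpus$encounters
  p <- corpus$patients
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!nrow(n)) return(invisible(path))

  ord <- order(n$note_id)
  for (idx in ord) {
    note_id <- n$note_id[idx]
    enc <- e[e$encounter_id == n$encounter_id[idx], ]
    patient <- p[p$patient_id == enc$patient_id, ]
    sents <- corpus$sentences[corpus$sentences$note_id == note_id, ]
    anns <- corpus$annotations[corpus$annotations$note_id == note_id, ]
    sent_list <- lapply(seq_len(nrow(sents)), function(j) {
      sid <- sents$sentence_id[j]
      aj <- anns[anns$sentence_id == sid, ]
      out <- list(sentence_id = sid)
      if (!is.na(sents$text[j])) out$text <- sents$text[j]
      out$annotations <- lapply(seq_len(nrow(aj)), function(k) {
        rec <- list(annotator_id = aj$annotator_id[k], class = aj$class[k])
        at <- aj$attributes[[k]]
        if (length(at)) rec$attributes <- at
        rec
      })
      out
    })
    rec <- list(
      patient = list(patient_id = patient$patient_id, group = patient$group,
                     index_reason = patient$index_reason),
      encounter = list(encounter_id = enc$encounter_id,
                       position = enc$position, setting = enc$setting),
      note = list(note_id = note_id, note_type = n$note_type[idx]),
      sentences = sent_list
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Flatten one annotator's layer to a tidy table
#'
#' The workhorse table feeding every downstream module: one row per
#' annotation (a `(sentence, class)` assignment), carrying the patient,
#' encounter and note context. A sentence bearing k classes contributes k
#' rows ("class-frequency events") but counts once as an annotated sentence;
#' see [count_annotated_sentences()].
#'
#' @param corpus An `oud_corpus`.
#' @param annotator_id Annotator layer to extract; `"gold"` is the
#'   adjudicated consensus layer.
#' @return Tibble with columns `patient_id`, `group`, `index_reason`,
#'   `position`, `setting`, `note_type`, `note_id`, `sentence_id`, `class`,
#'   `attributes` (list column).
#' @export
annotation_table <- function(corpus, annotator_id = "gold") {
  known <- unique(corpus$annotations$annotator_id)
  if (!identical(annotator_id, "gold") && !(annotator_id %in% known)) {
    stop_lookup(sprintf("unknown annotator '%s' (present: %s)", annotator_id,
                        paste(known, collapse = ", ")))
  }
  a <- corpus$annotations[corpus$annotations$annotator_id == annotator_id, ]
  a %>%
    dplyr::left_join(corpus$notes, by = "note_id") %>%
    dplyr::left_join(corpus$encounters, by = "encounter_id") %>%
    dplyr::left_join(corpus$patients, by = "patient_id") %>%
    dplyr::select("patient_id", "group", "index_reason", "position",
                  "setting", "note_type", "note_id", "sentence_id",
                  "class", "attributes")
}

#' Count distinct annotated sentences in an annotation table
#'
#' @param tab A table from [annotation_table()].
#' @return Number of distinct `(note_id, sentence_id)` pairs.
#' @export
count_annotated_sentences <- function(tab) {
  nrow(dplyr::distinct(tab, .data$note_id, .data$sentence_id))
}

#' Export an annotation table to CSV
#'
#' Attributes are flattened to `key=value` pairs joined by `;`.
#'
#' @param tab A table from [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(tab, path) {
  tab$attributes <- vapply(tab$attributes, function(at) {
    if (!length(at)) return("")
    paste(names(at), unlist(at), sep = "=", collapse = ";")
  }, character(1))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
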