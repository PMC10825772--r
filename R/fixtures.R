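# Reference fixtures.
#
# The framework was characterized on a five-group, 100-patient chart-review
# study. Its published summary tables are arithmetic constraints every
# faithful implementation must reproduce, so they are shipped here as data
# constructors: count tables, plus fixture corpora that realize those
# counts exactly. The corpora are synthetic realizations of the printed
# margins -- the underlying clinical notes are not (and cannot be)
# distributed -- but any statistic that is determined by the margins
# (severity distributions, PPVs, sentence totals, note-yield means) is
# exact.

#' Reference severity-category counts by study group
#'
#' Per (group, index reason): patients with annotations in each severity
#' category. The cross-classification by index reason is the unique
#' assignment consistent with both the per-group and the per-index-reason
#' published margins.
#'
#' @return Tibble: `group`, `index_reason`, `n_none`, `n_mild`,
#'   `n_moderate`, `n_severe`.
#' @export
reference_severity_counts <- function() {
  tibble::tribble(
    ~group,      ~index_reason,   ~n_none, ~n_mild, ~n_moderate, ~n_severe,
    "CP-RX",     "oud_diagnosis",       0,       0,           1,         7,
    "CP-RX",     "opioid_order",        8,       0,           0,         0,
    "CP-nonRX",  "oud_diagnosis",       4,       0,           1,         9,
    "CP-nonRX",  "opioid_order",        3,       0,           0,         1,
    "OUD-DX",    "oud_diagnosis",       3,       1,           1,        14,
    "OUD-TX",    "oud_diagnosis",       1,       1,           1,        17,
    "Control",   "opioid_order",        9,       0,           0,         0
  )
}

#' Reference per-group annotation counts
#'
#' Patients with annotations (and their index-reason split), annotated
#' notes, and annotated sentences per study group; 82 patients, 186 notes
#' and 1436 sentences in total, out of 100 sampled patients.
#'
#' @return Tibble: `group`, `n_patients`, `n_index_oud_dx`,
#'   `n_index_order`, `n_notes`, `n_sentences`.
#' @export
reference_annotation_counts <- function() {
  tibble::tribble(
    ~group,     ~n_patients, ~n_index_oud_dx, ~n_index_order, ~n_notes, ~n_sentences,
    "CP-RX",             16,               8,              8,       29,          170,
    "CP-nonRX",          18,              14,              4,       32,          277,
    "OUD-DX",            19,              19,              0,       50,          363,
    "OUD-TX",            20,              20,              0,       61,          602,
    "Control",            9,               0,              9,       14,           24
  )
}

#' Reference note-yield counts by note type
#'
#' Per note type: notes reviewed, notes with annotated sentences (split by
#' encounter setting), and annotated sentences.
#'
#' @return Tibble: `note_type`, `n_notes`, `n_annotated`, `n_ED`,
#'   `n_ED_to_IPT`, `n_OPT`, `n_IPT`, `n_sentences`.
#' @export
reference_note_yield_counts <- function() {
  tibble::tribble(
    ~note_type,           ~n_notes, ~n_annotated, ~n_ED, ~n_ED_to_IPT, ~n_OPT, ~n_IPT, ~n_sentences,
    "progress",                 92,           62,     1,            7,      3,     51,          574,
    "h_and_p",                  30,           27,     8,           13,      6,      0,          196,
    "ed",                       32,           25,    21,            4,      0,      0,          237,
    "ed_provider",              28,           23,    18,            5,      0,      0,          177,
    "discharge_summary",        26,           23,     5,           10,      8,      0,          172,
    "ed_triage",                26,            9,     9,            0,      0,      0,           22,
    "ancillary_progress",       30,            9,     2,            4,      3,      0,           19,
    "communication",            12,            3,     0,            2,      1,      0,            5,
    "outpatient_clinic",         4,            2,     0,            0,      0,      2,           26,
    "ed_support_staff",         38,            2,     1,            1,      0,      0,            7,
    "lactation",                 2,            1,     0,            0,      1,      0,            1
  )
}

# Classes realizing a given severity score under the default crosswalk:
# the first `score` singleton-mapped classes endorse criteria 1..score.
classes_for_score <- function(score) {
  if (score == 0L) "history of substance misuse" else COVER_CLASS[seq_len(score)]
}

#' Fixture corpus realizing the reference severity distribution
#'
#' Builds a 100-patient corpus whose scored severity categories reproduce
#' [reference_severity_counts()] exactly: each annotated patient carries
#' classes endorsing a representative criterion count for their category
#' (none 0, mild 2, moderate 4, severe 7), and the 18 patients without
#' annotations (4 CP-RX, 2 CP-nonRX, 1 OUD-DX, 11 Control) carry notes with
#' no annotated sentences.
#'
#' @return An `oud_corpus`.
#' @export
reference_severity_corpus <- function() {
  counts <- reference_severity_counts()
  target_score <- c(none = 0L, mild = 2L, moderate = 4L, severe = 7L)
  unannotated <- tibble::tribble(
    ~group,     ~index_reason,   ~n,
    "CP-RX",    "opioid_order",   4,
    "CP-nonRX", "oud_diagnosis",  1,
    "CP-nonRX", "opioid_order",   1,
    "OUD-DX",   "oud_diagnosis",  1,
    "Control",  "opioid_order",  11
  )

  pats <- list(); encs <- list(); nts <- list(); sens <- list(); anns <- list()
  k <- 0L
  add_patient <- function(group, index_reason, classes) {
    k <<- k + 1L
    pid <- sprintf("R%03d", k)
    pats[[k]] <<- tibble::tibble(patient_id = pid, group = group,
                                 index_reason = index_reason)
    eid <- paste0(pid, "-E1"); nid <- paste0(pid, "-N1")
    encs[[k]] <<- tibble::tibble(encounter_id = eid, patient_id = pid,
                                 position = "index", setting = "OPT")
    nts[[k]] <<- tibble::tibble(note_id = nid, encounter_id = eid,
                                note_type = "progress")
    if (length(classes)) {
      sens[[k]] <<- tibble::tibble(note_id = nid,
                                   sentence_id = paste0("S", seq_along(classes)),
                                   text = NA_character_)
      anns[[k]] <<- tibble::tibble(note_id = nid,
                                   sentence_id = paste0("S", seq_along(classes)),
                                   annotator_id = "gold", class = classes,
                                   attributes = rep(list(list()), length(classes)))
    }
  }
  for (r in seq_len(nrow(counts))) {
    for (cat in CATEGORIES) {
      n <- counts[[paste0("n_", cat)]][r]
      for (i in seq_len(n)) {
        add_patient(counts$group[r], counts$index_reason[r],
                    classes_for_score(target_score[[cat]]))
      }
    }
  }
  for (r in seq_len(nrow(unannotated))) {
    for (i in seq_len(unannotated$n[r])) {
      add_patient(unannotated$group[r], unannotated$index_reason[r], character(0))
    }
  }
  new_corpus(dplyr::bind_rows(pats), dplyr::bind_rows(encs),
             dplyr::bind_rows(nts), dplyr::bind_rows(sens),
             dplyr::bind_rows(anns),
             meta = list(source = "reference_severity_corpus"))
}

#' Fixture corpus realizing the reference annotation counts
#'
#' Builds a 100-patient corpus reproducing [reference_annotation_counts()]
#' exactly: per group, the annotated patients (with the published
#' index-reason split), annotated notes dealt round-robin to patients, and
#' annotated sentences dealt round-robin to notes, one gold annotation per
#' sentence.
#'
#' @return An `oud_corpus`.
#' @export
reference_annotation_corpus <- function() {
  counts <- reference_annotation_counts()
  unann <- c("CP-RX" = 4L, "CP-nonRX" = 2L, "OUD-DX" = 1L, "OUD-TX" = 0L,
             "Control" = 11L)
  unann_dx <- c("CP-RX" = 0L, "CP-nonRX" = 1L, "OUD-DX" = 1L, "OUD-TX" = 0L,
                "Control" = 0L)

  pats <- list(); encs <- list(); nts <- list(); sens <- list(); anns <- list()
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    g <- counts$group[r]
    p <- counts$n_patients[r]
    reasons <- rep(c("oud_diagnosis", "opioid_order"),
                   c(counts$n_index_oud_dx[r], counts$n_index_order[r]))
    pid <- sprintf("%s-P%02d", gsub("[^A-Za-z]", "", g), seq_len(p))
    note_owner <- rep_len(seq_len(p), counts$n_notes[r])
    sent_note <- rep_len(seq_len(counts$n_notes[r]), counts$n_sentences[r])
    k <- k + 1L
    pats[[k]] <- tibble::tibble(patient_id = pid, group = g,
                                index_reason = reasons)
    encs[[k]] <- tibble::tibble(encounter_id = paste0(pid, "-E1"),
                                patient_id = pid, position = "index",
                                setting = "OPT")
    note_id <- sprintf("%s-N%03d", gsub("[^A-Za-z]", "", g),
                       seq_len(counts$n_notes[r]))
    nts[[k]] <- tibble::tibble(
      note_id = note_id,
      encounter_id = paste0(pid[note_owner], "-E1"),
      note_type = "progress"
    )
    sid <- unlist(lapply(table(factor(sent_note, seq_len(counts$n_notes[r]))),
                         function(n) paste0("S", seq_len(n))), use.names = FALSE)
    sens[[k]] <- tibble::tibble(
      note_id = note_id[sort(sent_note)],
      sentence_id = sid,
      text = NA_character_
    )
    anns[[k]] <- tibble::tibble(
      note_id = sens[[k]]$note_id,
      sentence_id = sens[[k]]$sentence_id,
      annotator_id = "gold",
      class = "history of substance misuse",
      attributes = rep(list(list()), nrow(sens[[k]]))
    )
    # Sampled patients whose notes yielded nothing.
    if (unann[[g]] > 0L) {
      k <- k + 1L
      upid <- sprintf("%s-U%02d", gsub("[^A-Za-z]", "", g), seq_len(unann[[g]]))
      ureason <- rep(c("oud_diagnosis", "opioid_order"),
                     c(unann_dx[[g]], unann[[g]] - unann_dx[[g]]))
      pats[[k]] <- tibble::tibble(patient_id = upid, group = g,
                                  index_reason = ureason)
      encs[[k]] <- tibble::tibble(encounter_id = paste0(upid, "-E1"),
                                  patient_id = upid, position = "index",
                                  setting = "OPT")
      nts[[k]] <- tibble::tibble(note_id = paste0(upid, "-N1"),
                                 encounter_id = paste0(upid, "-E1"),
                                 note_type = "progress")
    }
  }
  new_corpus(dplyr::bind_rows(pats), dplyr::bind_rows(encs),
             dplyr::bind_rows(nts), dplyr::bind_rows(sens),
             dplyr::bind_rows(anns),
             meta = list(source = "reference_annotation_corpus"))
}

#' Fixture corpus realizing the reference note-yield counts
#'
#' One note per patient-encounter; annotated notes carry the published
#' encounter settings, and each note type's annotated sentences are dealt
#' as evenly as possible so the per-type totals (hence means) are exact.
#'
#' @return An `oud_corpus`.
#' @export
reference_note_yield_corpus <- function() {
  counts <- reference_note_yield_counts()
  pats <- list(); encs <- list(); nts <- list(); sens <- list(); anns <- list()
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    tt <- counts$note_type[r]
    settings <- c(rep("ED", counts$n_ED[r]),
                  rep("ED_to_IPT", counts$n_ED_to_IPT[r]),
                  rep("OPT", counts$n_OPT[r]),
                  rep("IPT", counts$n_IPT[r]),
                  rep("OPT", counts$n_notes[r] - counts$n_annotated[r]))
    n_ann <- counts$n_annotated[r]
    s_tot <- counts$n_sentences[r]
    per_note <- rep(s_tot %/% n_ann, n_ann)
    extra <- s_tot %% n_ann
    if (extra > 0L) per_note[seq_len(extra)] <- per_note[seq_len(extra)] + 1L
    per_note <- c(per_note, rep(0L, counts$n_notes[r] - n_ann))
    for (j in seq_along(settings)) {
      k <- k + 1L
      pid <- sprintf("Y%03d", k)
      eid <- paste0(pid, "-E1"); nid <- paste0(pid, "-N1")
      pats[[k]] <- tibble::tibble(patient_id = pid, group = "OUD-TX",
                                  index_reason = "oud_diagnosis")
      encs[[k]] <- tibble::tibble(encounter_id = eid, patient_id = pid,
                                  position = "index", setting = settings[j])
      nts[[k]] <- tibble::tibble(note_id = nid, encounter_id = eid,
                                 note_type = tt)
      if (per_note[j] > 0L) {
        sid <- paste0("S", seq_len(per_note[j]))
        sens[[k]] <- tibble::tibble(note_id = nid, sentence_id = sid,
                                    text = NA_character_)
        anns[[k]] <- tibble::tibble(note_id = nid, sentence_id = sid,
                                    annotator_id = "gold",
                                    class = "history of substance misuse",
                                    attributes = rep(list(list()), length(sid)))
      }
    }
  }
  new_corpus(dplyr::bind_rows(pats), dplyr::bind_rows(encs),
             dplyr::bind_rows(nts), dplyr::bind_rows(sens),
             dplyr::bind_rows(anns),
             meta = list(source = "reference_note_yield_corpus"))
}
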