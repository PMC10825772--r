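# Shared builders for tests: a small crosswalk with known structure and a
# corpus constructor driven by a flat annotation data frame.

toy_crosswalk <- function() {
  as_crosswalk(list(
    version = "toy",
    classes = list(
      list(name = "A", category = "opioid_misuse", scoring = TRUE,
           criteria = c(1L)),
      list(name = "B", category = "opioid_misuse", scoring = TRUE,
           criteria = c(2L, 3L)),
      list(name = "C", category = "consequence", scoring = TRUE,
           criteria = c(3L, 4L)),
      list(name = "D", category = "substance_use_nonopioid", scoring = FALSE),
      list(name = "E", category = "opioid_misuse", scoring = TRUE,
           force_category = "severe")
    )
  ))
}

# Build a corpus from a flat annotation table. `ann` is a data frame with a
# `patient_id` and `class` column; everything else has sensible defaults.
# One note per (patient, position, setting, note_type); one sentence per row
# unless `sentence_id` is given (repeating a sentence_id yields multi-label
# sentences).
make_corpus <- function(ann, patients = NULL) {
  ann <- tibble::as_tibble(ann)
  defaults <- list(group = "OUD-DX", index_reason = "oud_diagnosis",
                   position = "index", setting = "OPT",
                   note_type = "progress", annotator_id = "gold")
  for (nm in names(defaults)) {
    if (!nm %in% names(ann)) ann[[nm]] <- defaults[[nm]]
  }
  if (!"attributes" %in% names(ann)) ann$attributes <- rep(list(list()), nrow(ann))

  if (is.null(patients)) {
    patients <- dplyr::distinct(ann, patient_id, group, index_reason)
  }
  encounters <- dplyr::distinct(ann, patient_id, position, setting) |>
    dplyr::group_by(patient_id, position) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(encounter_id = paste(patient_id, position, sep = "-"))
  # every patient needs an index encounter
  need_idx <- setdiff(patients$patient_id, encounters$patient_id[encounters$position == "index"])
  if (length(need_idx)) {
    encounters <- dplyr::bind_rows(encounters, tibble::tibble(
      patient_id = need_idx, position = "index", setting = "OPT",
      encounter_id = paste(need_idx, "index", sep = "-")))
  }
  ann <- dplyr::left_join(
    ann, encounters[, c("patient_id", "position", "encounter_id", "setting")],
    by = c("patient_id", "position"), suffix = c("", ".enc"))
  ann$note_id <- paste(ann$encounter_id, ann$note_type, sep = "-")
  notes <- dplyr::distinct(ann, note_id, encounter_id, note_type)
  if (!"sentence_id" %in% names(ann)) {
    ann <- ann |>
      dplyr::group_by(note_id) |>
      dplyr::mutate(sentence_id = paste0("S", dplyr::row_number())) |>
      dplyr::ungroup()
  }
  sentences <- dplyr::distinct(ann, note_id, sentence_id) |>
    dplyr::mutate(text = NA_character_)
  new_corpus(
    patients = patients,
    encounters = encounters[, c("encounter_id", "patient_id", "position", "setting")],
    notes = notes,
    sentences = sentences,
    annotations = ann[, c("note_id", "sentence_id", "annotator_id", "class",
                          "attributes")],
    meta = list(source = "test")
  )
}
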