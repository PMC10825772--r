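# Documentation-pattern analytics: where in the chart OUD-relevant
# information lives. All cross-tabulations count class-frequency events (a
# sentence bearing k classes contributes k events); note_yield counts
# distinct annotated sentences, the two conventions the corpus model
# exposes side by side.

axis_levels <- function(axis) {
  switch(axis,
    note_type = NOTE_TYPES,
    setting = SETTINGS,
    position = POSITIONS,
    stop_validation(sprintf("unknown axis '%s' (use note_type, setting or position)",
                            axis))
  )
}

#' Class-frequency matrix over a documentation axis
#'
#' Cross-tabulates class-frequency events against one of the closed
#' documentation axes: the 11 note types, the 4 encounter settings, or the
#' 3 encounter positions (historic/index/new). Absent columns are
#' zero-filled so matrices from different corpora are always conformable.
#'
#' @param tab Annotation table for a single annotator layer
#'   ([annotation_table()]).
#' @param axis `"note_type"`, `"setting"` or `"position"`.
#' @param classes Optional character vector fixing the row set (e.g.
#'   `names(crosswalk$classes)`); defaults to the classes observed.
#' @return Integer matrix, classes x axis levels, with `row_totals` and
#'   `col_totals` attributes.
#' @export
frequency_matrix <- function(tab, axis = c("note_type", "setting", "position"),
                             classes = NULL) {
  axis <- match.arg(axis)
  cols <- axis_levels(axis)
  if (is.null(classes)) classes <- sort(unique(tab$class))
  m <- table(
    factor(tab$class, levels = classes),
    factor(tab[[axis]], levels = cols)
  )
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = stats::setNames(list(classes, cols), c("class", axis)))
  structure(m, row_totals = rowSums(m), col_totals = colSums(m), axis = axis)
}

#' Note yield by note type
#'
#' Per note type: how many notes exist, how many contain at least one
#' annotated sentence, the annotated-sentence totals, the mean/SD annotated
#' sentences per *annotated* note, and where (by encounter setting) the
#' annotated notes sit. Undefined statistics (no annotated notes, or a
#' single one for the SD) are `NA`, never 0.
#'
#' @param corpus An `oud_corpus`.
#' @param annotator_id Annotation layer (default `"gold"`).
#' @return Tibble with one row per note type (all 11, including absent
#'   ones): `note_type`, `n_notes`, `n_annotated_notes`, `pct_annotated`,
#'   `n_sentences_annotated`, `mean_sentences`, `sd_sentences`, and one
#'   `n_<setting>` column per encounter setting.
#' @export
note_yield <- function(corpus, annotator_id = "gold") {
  tab <- annotation_table(corpus, annotator_id)
  notes <- dplyr::left_join(corpus$notes, corpus$encounters, by = "encounter_id")

  per_note <- tab %>%
    dplyr::distinct(.data$note_id, .data$sentence_id) %>%
    dplyr::count(.data$note_id, name = "n_sent")
  notes <- dplyr::left_join(notes, per_note, by = "note_id")
  notes$n_sent[is.na(notes$n_sent)] <- 0L

  purrr::map_dfr(NOTE_TYPES, function(tt) {
    nt <- notes[notes$note_type == tt, ]
    annotated <- nt[nt$n_sent > 0L, ]
    row <- tibble::tibble(
      note_type = tt,
      n_notes = nrow(nt),
      n_annotated_notes = nrow(annotated),
      pct_annotated = if (nrow(nt)) 100 * nrow(annotated) / nrow(nt) else NA_real_,
      n_sentences_annotated = sum(annotated$n_sent),
      mean_sentences = if (nrow(annotated)) mean(annotated$n_sent) else NA_real_,
      sd_sentences = if (nrow(annotated) > 1L) stats::sd(annotated$n_sent) else NA_real_
    )
    for (st in SETTINGS) {
      row[[paste0("n_", st)]] <- sum(annotated$setting == st)
    }
    row
  })
}

#' Class-pair correlation across note types
#'
#' Correlates each pair of class frequency profiles across the note-type
#' columns: a high value means two classes are documented with similar
#' frequency distributions across note types. Zero-variance profiles have
#' no defined correlation; their cells are `NA` and the affected classes are
#' reported in the `undefined_classes` attribute rather than silently
#' zeroed.
#'
#' @param freq A class-by-note-type matrix from
#'   `frequency_matrix(tab, "note_type")`.
#' @param method `"pearson"` (default) or `"spearman"`. Correlations are
#'   computed on raw counts; Spearman is offered because count scales differ
#'   by orders of magnitude across classes.
#' @return Symmetric class x class correlation matrix with unit diagonal
#'   where defined; attribute `undefined_classes` lists zero-variance rows.
#' @export
pair_correlation <- function(freq, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(freq) < 2L) {
    stop_validation("pair_correlation needs at least 2 axis columns")
  }
  flat <- matrix(as.numeric(freq), nrow = nrow(freq), dimnames = dimnames(freq))
  zero_var <- apply(flat, 1, function(r) stats::var(r) == 0)
  out <- suppressWarnings(stats::cor(t(flat), method = method))
  out[zero_var, ] <- NA_real_
  out[, zero_var] <- NA_real_
  diag(out)[!zero_var] <- 1
  structure(out, undefined_classes = rownames(flat)[zero_var], method = method)
}

#' Patient-level class co-occurrence
#'
#' Cell (i, j) counts the patients with at least one annotation of class i
#' AND at least one of class j; the diagonal is the per-class patient count.
#'
#' @param tab Annotation table ([annotation_table()]).
#' @param classes Optional character vector fixing the class set.
#' @return Symmetric integer matrix, classes x classes.
#' @export
patient_cooccurrence <- function(tab, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(tab$class))
  patients <- sort(unique(tab$patient_id))
  inc <- matrix(0L, nrow = length(patients), ncol = length(classes),
                dimnames = list(patients, classes))
  if (nrow(tab)) {
    keep <- tab$class %in% classes
    inc[cbind(match(tab$patient_id[keep], patients),
              match(tab$class[keep], classes))] <- 1L
  }
  m <- crossprod(inc)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(class = classes, class = classes)
  m
}

#' Write all pattern analytics for one corpus
#'
#' @param corpus An `oud_corpus`.
#' @param out_dir Output directory (created if needed).
#' @param annotator_id Annotation layer.
#' @param classes Optional fixed class set for the matrices.
#' @return Named character vector of the files written, invisibly.
#' @export
write_patterns <- function(corpus, out_dir, annotator_id = "gold",
                           classes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- annotation_table(corpus, annotator_id)
  files <- c(
    freq_by_notetype = "freq_by_notetype.csv",
    freq_by_setting = "freq_by_setting.csv",
    freq_by_position = "freq_by_position.csv",
    note_yield = "note_yield.csv",
    pair_correlation = "pair_correlation.csv",
    patient_cooccurrence = "patient_cooccurrence.csv"
  )
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_mat <- function(m, path) {
    utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  }
  fm_note <- frequency_matrix(tab, "note_type", classes)
  write_mat(fm_note, paths["freq_by_notetype"])
  write_mat(frequency_matrix(tab, "setting", classes), paths["freq_by_setting"])
  write_mat(frequency_matrix(tab, "position", classes), paths["freq_by_position"])
  utils::write.csv(note_yield(corpus, annotator_id), paths["note_yield"],
                   row.names = FALSE)
  if (ncol(fm_note) >= 2L && nrow(fm_note) >= 1L) {
    write_mat(pair_correlation(fm_note), paths["pair_correlation"])
  }
  write_mat(patient_cooccurrence(tab, classes), paths["patient_cooccurrence"])
  invisible(paths)
}
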