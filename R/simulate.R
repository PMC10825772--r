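# Synthetic annotated-corpus generator.
#
# The generator emulates the five-group chart-review design: per group, a
# probability that a patient's notes contain any annotatable content; a
# latent DSM-5 criterion set per patient (zero-inflated truncated Poisson
# count, criteria drawn uniformly); scoring classes chosen to cover exactly
# the latent set (covering-set sampling restricted to classes whose
# criteria lie inside the set, so the true score is recoverable); shared
# non-scoring "noise" classes that induce broad co-occurrence; and class
# events distributed over up to three encounters (historic/index/new, with
# index-heavy mass), settings, note types and sentences. Ground truth per
# patient is recorded at generation time.

# Classes used to cover each latent criterion: one singleton-mapped class
# per criterion under the default crosswalk.
COVER_CLASS <- c(
  "OUD", "unsuccessful cutback", "drug seeking", "opioid craving",
  "vocational consequences", "social consequences", "activities given up",
  "opioid misuse-illicit", "opioid-related medical issues",
  "opioid tolerance", "withdrawal"
)

# Optional extra scoring classes, added only when their criteria are inside
# the latent set (so they never change the true score).
EXTRA_CLASSES <- list(
  list(class = "opioid misuse-prescription", needs = 1L, p = 0.5),
  list(class = "excessive opioid use", needs = 1L, p = 0.2),
  list(class = "time spent obtaining opioids", needs = 3L, p = 0.3),
  list(class = "intoxication", needs = 8L, p = 0.3),
  list(class = "naloxone", needs = 8L, p = 0.2),
  list(class = "overdose history", needs = 8L, p = 0.3)
)

#' Simulation configuration
#'
#' Builds and validates the parameter set driving [simulate_corpus()]. The
#' defaults of [calibrated_sim_config()] encode the reference study design:
#' 5 groups of 20 patients, group-specific probabilities of annotatable
#' content, group-shifted latent severity, and per-note-type annotated
#' sentence counts.
#'
#' @param group_sizes Named integer vector of patients per study group.
#' @param p_annotatable Named per-group probability that a patient's notes
#'   contain any annotatable content.
#' @param p_index_oud_dx Named per-group probability that the index
#'   encounter is anchored on an OUD diagnosis (the complement is an opioid
#'   analgesic order). Forced to 1 for OUD-DX/OUD-TX and 0 for Control.
#' @param severity Named per-group list `p_zero` (probability of an empty
#'   latent criterion set), `lambda` (Poisson rate of the positive criterion
#'   count, truncated to 1..11) and `p_moud` (probability that OUD
#'   treatment is documented, forcing the severe category).
#' @param noise_rates Named per-class prevalence of the non-scoring noise
#'   classes among annotatable patients.
#' @param position_weights Mass of class events on historic/index/new
#'   encounters.
#' @param setting_probs Encounter-setting distribution.
#' @param note_type_mix Per-setting note-type mixtures (each sums to 1).
#' @param sentence_means Named per-note-type mean annotated sentences per
#'   annotated note. Counts are drawn as `1 + NegBin(mu = mean - 1, size)`,
#'   a positive-count model whose mean is exactly the configured value.
#' @param nb_size Negative-binomial dispersion for sentence counts.
#' @param p_second_note Probability an encounter yields a second note.
#' @param p_note_annotated Probability a given note of an annotatable
#'   patient carries annotations (the index encounter always keeps at least
#'   one annotated note).
#' @param p_multilabel Probability a sentence receives a second class.
#' @param dropout Note-dropout probability applied after generation
#'   (scores computed on the degraded corpus can only fall below truth).
#' @param disagreement `NULL`, or `list(miss, relabel)`: emit annotator
#'   layers "A1" (= gold) and "A2" (gold with units dropped at rate `miss`
#'   and relabelled at rate `relabel`) for exercising agreement analyses.
#' @return A validated list of class `oud_sim_config`.
#' @export
sim_config <- function(group_sizes = stats::setNames(rep(20L, 5), GROUPS),
                       p_annotatable = c("CP-RX" = 0.80, "CP-nonRX" = 0.90,
                                         "OUD-DX" = 0.95, "OUD-TX" = 1.00,
                                         "Control" = 0.45),
                       p_index_oud_dx = c("CP-RX" = 0.50, "CP-nonRX" = 0.78,
                                          "OUD-DX" = 1.00, "OUD-TX" = 1.00,
                                          "Control" = 0.00),
                       severity = list(
                         "CP-RX" = list(p_zero = 0.50, lambda = 7.0, p_moud = 0.00),
                         "CP-nonRX" = list(p_zero = 0.40, lambda = 7.5, p_moud = 0.00),
                         "OUD-DX" = list(p_zero = 0.16, lambda = 7.0, p_moud = 0.05),
                         "OUD-TX" = list(p_zero = 0.05, lambda = 8.0, p_moud = 0.85),
                         "Control" = list(p_zero = 1.00, lambda = 0.0, p_moud = 0.00)
                       ),
                       noise_rates = c("history of substance misuse" = 0.60,
                                       "psychiatric condition" = 0.45,
                                       "daily tobacco use" = 0.35,
                                       "other illicit drug use" = 0.20,
                                       "alcohol misuse" = 0.15,
                                       "chronic pain" = 0.20,
                                       "polysubstance misuse" = 0.10,
                                       "family history of substance misuse" = 0.05,
                                       "social context" = 0.05),
                       position_weights = c(historic = 0.20, index = 0.55,
                                            new = 0.25),
                       setting_probs = c(ED = 0.35, ED_to_IPT = 0.22,
                                         OPT = 0.28, IPT = 0.15),
                       note_type_mix = default_note_type_mix(),
                       sentence_means = c(progress = 9.3, ancillary_progress = 2.1,
                                          h_and_p = 7.3, discharge_summary = 7.5,
                                          ed = 9.5, ed_provider = 7.7,
                                          ed_triage = 2.4, ed_support_staff = 3.5,
                                          communication = 1.7,
                                          outpatient_clinic = 13.0, lactation = 1.0),
                       nb_size = 1.2,
                       p_second_note = 0.30,
                       p_note_annotated = 0.70,
                       p_multilabel = 0.10,
                       dropout = 0,
                       disagreement = NULL) {
  cfg <- structure(
    list(group_sizes = group_sizes, p_annotatable = p_annotatable,
         p_index_oud_dx = p_index_oud_dx, severity = severity,
         noise_rates = noise_rates, position_weights = position_weights,
         setting_probs = setting_probs, note_type_mix = note_type_mix,
         sentence_means = sentence_means, nb_size = nb_size,
         p_second_note = p_second_note, p_note_annotated = p_note_annotated,
         p_multilabel = p_multilabel, dropout = dropout,
         disagreement = disagreement),
    class = "oud_sim_config"
  )
  validate_sim_config(cfg)
}

default_note_type_mix <- function() {
  list(
    ED = c(ed = 0.30, ed_provider = 0.25, ed_triage = 0.20,
           ed_support_staff = 0.20, communication = 0.05),
    ED_to_IPT = c(h_and_p = 0.30, discharge_summary = 0.30, ed = 0.10,
                  ed_provider = 0.10, progress = 0.15, ancillary_progress = 0.05),
    OPT = c(progress = 0.45, ancillary_progress = 0.25,
            outpatient_clinic = 0.15, communication = 0.10, lactation = 0.05),
    IPT = c(progress = 0.70, h_and_p = 0.15, discharge_summary = 0.10,
            ancillary_progress = 0.05)
  )
}

validate_sim_config <- function(cfg) {
  for (nm in c("group_sizes", "p_annotatable", "p_index_oud_dx")) {
    missing <- setdiff(GROUPS, names(cfg[[nm]]))
    if (length(missing)) {
      stop_validation(sprintf("%s missing group(s): %s", nm,
                              paste(missing, collapse = ", ")))
    }
  }
  probs <- c(cfg$p_annotatable, cfg$p_index_oud_dx, cfg$noise_rates,
             cfg$p_second_note, cfg$p_note_annotated, cfg$p_multilabel,
             cfg$dropout)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("all probabilities must lie in [0, 1]")
  }
  for (nm in names(cfg$note_type_mix)) {
    mix <- cfg$note_type_mix[[nm]]
    assert_one_of(names(mix), NOTE_TYPES, "note_type in mixture", nm)
    if (abs(sum(mix) - 1) > 1e-8) {
      stop_validation(sprintf("note_type_mix[%s] does not sum to 1", nm))
    }
  }
  assert_one_of(names(cfg$note_type_mix), SETTINGS, "setting in note_type_mix")
  if (abs(sum(cfg$setting_probs) - 1) > 1e-8 ||
      abs(sum(cfg$position_weights) - 1) > 1e-8) {
    stop_validation("setting_probs and position_weights must each sum to 1")
  }
  if (any(cfg$sentence_means < 1)) {
    stop_validation("sentence_means must be >= 1 (an annotated note has >= 1 sentence)")
  }
  for (g in GROUPS) {
    s <- cfg$severity[[g]]
    if (is.null(s) || s$p_zero < 0 || s$p_zero > 1 || s$lambda < 0 ||
        s$p_moud < 0 || s$p_moud > 1) {
      stop_validation(sprintf("invalid severity parameters for group %s", g))
    }
  }
  cfg
}

#' The study-calibrated default configuration
#'
#' Defaults match the reference study design marginals: 20 patients per
#' group; annotatable-content probabilities of 16/20 (CP-RX), 18/20
#' (CP-nonRX), 19/20 (OUD-DX), 20/20 (OUD-TX) and 9/20 (Control); index
#' anchored on an OUD diagnosis for 8/16 CP-RX and 14/18 CP-nonRX patients,
#' always for the diagnosis-defined groups and never for controls; and mean
#' annotated sentences per annotated note per note type matching the
#' observed note-yield table (progress 9.3, H&P 7.3, ...).
#'
#' @param ... Overrides passed to [sim_config()].
#' @return An `oud_sim_config`.
#' @export
calibrated_sim_config <- function(...) {
  sim_config(...)
}

#' Simulate an annotated corpus with known ground truth
#'
#' @param config An `oud_sim_config` (see [sim_config()]).
#' @param crosswalk An `oud_crosswalk`; the default crosswalk must be able
#'   to cover any latent criterion set (checked up front).
#' @param seed Integer seed; mandatory, so corpora are reproducible.
#' @return A list:
#'   * `corpus`: an `oud_corpus` with a `"gold"` annotation layer (plus
#'     "A1"/"A2" layers when `config$disagreement` is set);
#'   * `truth`: tibble `patient_id`, `group`, `index_reason`, `annotatable`,
#'     `true_criteria` (list column), `true_score`, `true_category`,
#'     `forced`.
#' @export
simulate_corpus <- function(config, crosswalk = default_crosswalk(), seed) {
  if (missing(seed) || is.null(seed)) stop_validation("seed is mandatory")
  validate_sim_config(config)
  covered <- criteria_for(intersect(COVER_CLASS, names(crosswalk$classes)),
                          crosswalk)
  if (!all(seq_len(N_CRITERIA) %in% covered)) {
    stop_validation(sprintf(
      "crosswalk cannot cover criteria: %s",
      paste(setdiff(seq_len(N_CRITERIA), covered), collapse = ", ")))
  }
  bad_noise <- intersect(names(config$noise_rates), scoring_classes(crosswalk))
  if (length(bad_noise)) {
    stop_validation(sprintf("noise classes must be non-scoring: %s",
                            paste(bad_noise, collapse = ", ")))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  pats <- list(); encs <- list(); nts <- list(); sens <- list(); anns <- list()
  truth <- list()
  k <- 0L
  for (g in GROUPS) {
    for (i in seq_len(config$group_sizes[[g]])) {
      k <- k + 1L
      res <- simulate_patient(sprintf("P%03d", k), g, config, crosswalk)
      pats[[k]] <- res$patient; encs[[k]] <- res$encounters
      nts[[k]] <- res$notes; sens[[k]] <- res$sentences
      anns[[k]] <- res$annotations; truth[[k]] <- res$truth
    }
  }
  notes <- dplyr::bind_rows(nts)
  sentences <- dplyr::bind_rows(sens)
  annotations <- dplyr::bind_rows(anns)

  if (config$dropout > 0 && nrow(notes)) {
    keep <- stats::runif(nrow(notes)) >= config$dropout
    notes <- notes[keep, ]
    sentences <- sentences[sentences$note_id %in% notes$note_id, ]
    annotations <- annotations[annotations$note_id %in% notes$note_id, ]
    encs_all <- dplyr::bind_rows(encs)
    encs_all <- encs_all[encs_all$encounter_id %in%
                           c(notes$encounter_id,
                             encs_all$encounter_id[encs_all$position == "index"]), ]
  } else {
    encs_all <- dplyr::bind_rows(encs)
  }

  corpus <- new_corpus(
    patients = dplyr::bind_rows(pats),
    encounters = encs_all,
    notes = notes,
    sentences = sentences,
    annotations = annotations,
    meta = list(source = "simulate_corpus", seed = as.integer(seed))
  )
  list(corpus = corpus, truth = dplyr::bind_rows(truth))
}

simulate_patient <- function(pid, group, config, crosswalk) {
  index_reason <- if (group %in% c("OUD-DX", "OUD-TX")) {
    "oud_diagnosis"
  } else if (group == "Control") {
    "opioid_order"
  } else if (stats::runif(1) < config$p_index_oud_dx[[group]]) {
    "oud_diagnosis"
  } else {
    "opioid_order"
  }
  annotatable <- stats::runif(1) < config$p_annotatable[[group]]

  # Latent severity and the classes realizing it.
  sev <- config$severity[[group]]
  forced <- annotatable && stats::runif(1) < sev$p_moud
  n_crit <- 0L
  if (annotatable && stats::runif(1) >= sev$p_zero) {
    repeat {
      n_crit <- stats::rpois(1, sev$lambda)
      if (n_crit >= 1L && n_crit <= N_CRITERIA) break
    }
  }
  crit_set <- sort(sample.int(N_CRITERIA, n_crit))
  classes <- COVER_CLASS[crit_set]
  for (ex in EXTRA_CLASSES) {
    if (ex$needs %in% crit_set && stats::runif(1) < ex$p) {
      classes <- c(classes, ex$class)
    }
  }
  if (forced) classes <- c(classes, "OUD treatment")
  noise_on <- stats::runif(length(config$noise_rates)) < config$noise_rates
  classes <- c(classes, names(config$noise_rates)[noise_on])
  if (annotatable && !length(classes)) {
    classes <- "history of substance misuse"
  }

  # Encounters: annotatable patients get all three positions; others a
  # reduced chart (index always present).
  positions <- if (annotatable) {
    POSITIONS
  } else {
    c("index", if (stats::runif(1) < 0.5) "historic")
  }
  encounters <- tibble::tibble(
    encounter_id = paste0(pid, "-E", seq_along(positions)),
    patient_id = pid,
    position = positions,
    setting = sample(names(config$setting_probs), length(positions),
                     replace = TRUE, prob = config$setting_probs)
  )
  # Unannotated charts never come from the inpatient setting.
  if (!annotatable) {
    encounters$setting[encounters$setting %in% c("IPT", "ED_to_IPT")] <- "OPT"
  }

  notes <- purrr::map_dfr(seq_len(nrow(encounters)), function(j) {
    n_notes <- 1L + (stats::runif(1) < config$p_second_note)
    mix <- config$note_type_mix[[encounters$setting[j]]]
    tibble::tibble(
      note_id = paste0(encounters$encounter_id[j], "-N", seq_len(n_notes)),
      encounter_id = encounters$encounter_id[j],
      note_type = sample(names(mix), n_notes, replace = TRUE, prob = mix),
      position = encounters$position[j]
    )
  })

  sentences <- tibble::tibble(note_id = character(0), sentence_id = character(0),
                              text = character(0))
  annotations <- tibble::tibble(note_id = character(0), sentence_id = character(0),
                                annotator_id = character(0), class = character(0),
                                attributes = list())
  if (annotatable) {
    ann_note <- stats::runif(nrow(notes)) < config$p_note_annotated
    idx_notes <- which(notes$position == "index")
    if (!any(ann_note[idx_notes])) {
      ann_note[sample(idx_notes, 1L)] <- TRUE
    }
    akt <- notes[ann_note, ]
    n_sent <- vapply(akt$note_type, function(tt) {
      mu <- config$sentence_means[[tt]] - 1
      if (mu <= 0) 1L else 1L + as.integer(stats::rnbinom(1, size = config$nb_size,
                                                          mu = mu))
    }, integer(1))
    sentences <- tibble::tibble(
      note_id = rep(akt$note_id, n_sent),
      sentence_id = unlist(lapply(n_sent, function(n) paste0("S", seq_len(n))),
                           use.names = FALSE),
      text = NA_character_
    )
    sent_pos <- rep(akt$position, n_sent)
    sent_w <- config$position_weights[sent_pos]

    # Every sentence draws one class from the patient's multiset; every
    # chosen class is then guaranteed a sentence (position-weighted), so the
    # emitted chart realizes the full latent class set.
    assign_class <- sample(classes, nrow(sentences), replace = TRUE)
    anchor <- sample.int(nrow(sentences), length(classes), replace = TRUE,
                         prob = sent_w)
    pairs <- tibble::tibble(
      sent = c(seq_len(nrow(sentences)), anchor),
      class = c(assign_class, classes)
    )
    second <- stats::runif(nrow(sentences)) < config$p_multilabel
    if (any(second) && length(classes) > 1L) {
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        sent = which(second),
        class = sample(classes, sum(second), replace = TRUE)
      ))
    }
    pairs <- dplyr::distinct(pairs)
    annotations <- tibble::tibble(
      note_id = sentences$note_id[pairs$sent],
      sentence_id = sentences$sentence_id[pairs$sent],
      annotator_id = "gold",
      class = pairs$class,
      attributes = lapply(pairs$class, function(cl) {
        draw_attributes(cl, crosswalk)
      })
    )
    if (!is.null(config$disagreement)) {
      annotations <- dplyr::bind_rows(
        annotations,
        annotator_layers(annotations, classes, config$disagreement)
      )
    }
  }

  true_score <- length(crit_set)
  list(
    patient = tibble::tibble(patient_id = pid, group = group,
                             index_reason = index_reason),
    encounters = encounters,
    notes = notes[, c("note_id", "encounter_id", "note_type")],
    sentences = sentences,
    annotations = annotations,
    truth = tibble::tibble(
      patient_id = pid, group = group, index_reason = index_reason,
      annotatable = annotatable,
      true_criteria = list(crit_set),
      true_score = true_score,
      true_category = categorize(true_score, forced),
      forced = forced
    )
  )
}

draw_attributes <- function(class, crosswalk) {
  attrs <- crosswalk$classes[[class]]$attributes
  if (!length(attrs)) return(list())
  out <- lapply(attrs, function(values) {
    if (identical(sort(unlist(values)), c("current", "historic"))) {
      sample(c("current", "historic"), 1L, prob = c(0.8, 0.2))
    } else {
      sample(unlist(values), 1L)
    }
  })
  out
}

# Two annotator layers derived from gold: A1 is gold verbatim; A2 drops
# units at rate `miss` and relabels at rate `relabel`.
annotator_layers <- function(gold, classes, dis) {
  a1 <- dplyr::mutate(gold, annotator_id = "A1")
  a2 <- dplyr::mutate(gold, annotator_id = "A2")
  keep <- stats::runif(nrow(a2)) >= (dis$miss %||% 0)
  a2 <- a2[keep, ]
  if (nrow(a2) && length(classes) > 1L) {
    flip <- stats::runif(nrow(a2)) < (dis$relabel %||% 0)
    if (any(flip)) {
      a2$class[flip] <- vapply(a2$class[flip], function(cl) {
        sample(setdiff(classes, cl), 1L)
      }, character(1))
    }
  }
  out <- dplyr::bind_rows(a1, dplyr::distinct(
    a2, .data$note_id, .data$sentence_id, .data$annotator_id, .data$class,
    .keep_all = TRUE
  ))
  out
}
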