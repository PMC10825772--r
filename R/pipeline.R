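#' Run the full analysis pipeline on one simulated corpus
#'
#' Orchestrates the stages end to end: simulate an annotated corpus, score
#' it against the crosswalk, evaluate severity distributions and PPVs,
#' compute per-batch interannotator agreement (when the simulation emits
#' annotator layers), and write the documentation-pattern analytics. All
#' outputs are plain JSONL/CSV; no stage mutates its inputs, and re-running
#' with the same seed reproduces identical output files. A `manifest.json`
#' records the seed, package version and an MD5 of every file written.
#'
#' @param out_dir Output directory (created if needed).
#' @param config An `oud_sim_config`; the default enables a light annotator
#'   disagreement so agreement outputs are non-trivial.
#' @param crosswalk An `oud_crosswalk`.
#' @param seed Integer seed for the simulation.
#' @return Invisibly, a list with the `corpus`, `truth`, `scored`
#'   results and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = calibrated_sim_config(
                           disagreement = list(miss = 0.1, relabel = 0.05)),
                         crosswalk = default_crosswalk(),
                         seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_corpus(config, crosswalk, seed = seed)
  corpus_path <- file.path(out_dir, "corpus.jsonl")
  write_corpus(sim$corpus, corpus_path)
  truth <- sim$truth
  truth$true_criteria <- vapply(truth$true_criteria, paste, character(1),
                                collapse = ";")
  truth$true_category <- as.character(truth$true_category)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

  scored <- score_corpus(sim$corpus, crosswalk)
  write_scores_csv(scored, file.path(out_dir, "scores.csv"))

  design <- tibble::tibble(stratum = names(config$group_sizes),
                           n_sampled = as.integer(config$group_sizes))
  dist <- severity_distribution(scored$scores, "group", design)
  ppv_out <- dplyr::bind_rows(
    ppv(dist, "annotated"), pooled_ppv(dist, "annotated"),
    ppv(dist, "all_sampled"), pooled_ppv(dist, "all_sampled")
  )
  utils::write.csv(ppv_out, file.path(out_dir, "ppv.csv"), row.names = FALSE)

  annotators <- unique(sim$corpus$annotations$annotator_id)
  if (all(c("A1", "A2") %in% annotators)) {
    iaa <- iaa_by_batch(sim$corpus, "A1", "A2")
    utils::write.csv(iaa, file.path(out_dir, "iaa.csv"), row.names = FALSE)
  }

  write_patterns(sim$corpus, file.path(out_dir, "patterns"),
                 classes = names(crosswalk$classes))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    command = "run_pipeline",
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("oudseverity")),
    crosswalk_version = crosswalk$version,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(corpus = sim$corpus, truth = sim$truth, scored = scored,
                 manifest = manifest))
}
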