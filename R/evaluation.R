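#' Severity-category distribution by stratum
#'
#' Tabulates scored patients into the four severity categories per study
#' group or per index-encounter reason. Stratifying by `index_reason`
#' excludes the control group: the index-reason contrast asks whether a
#' diagnosis-anchored chart scores differently from an opioid-order-anchored
#' one among patients with some evidence of problematic use, and controls
#' are order-anchored by design.
#'
#' @param scores The `scores` tibble from [score_corpus()] (or the full
#'   list).
#' @param stratifier `"group"` or `"index_reason"`.
#' @param design Optional tibble `stratum`, `n_sampled` giving the number of
#'   patients sampled per stratum (the all-sampled PPV denominator). Use
#'   [study_design()] for the five-group, 20-per-group design.
#' @return Tibble: `stratum`, `n_none`, `n_mild`, `n_moderate`, `n_severe`,
#'   `n_annotated`, `n_sampled` (`NA` when no design row is supplied).
#' @export
severity_distribution <- function(scores, stratifier = c("group", "index_reason"),
                                  design = NULL) {
  stratifier <- match.arg(stratifier)
  if (!is.data.frame(scores)) scores <- scores$scores
  if (!nrow(scores)) {
    return(tibble::tibble(stratum = character(0), n_none = integer(0),
                          n_mild = integer(0), n_moderate = integer(0),
                          n_severe = integer(0), n_annotated = integer(0),
                          n_sampled = integer(0)))
  }
  if (stratifier == "index_reason") {
    scores <- scores[scores$group != "Control", ]
    levels <- INDEX_REASONS
  } else {
    levels <- GROUPS
  }
  strata <- factor(scores[[stratifier]], levels = levels)
  counts <- table(strata, factor(scores$category, CATEGORIES))
  present <- rownames(counts)[rowSums(counts) > 0L]
  out <- tibble::tibble(
    stratum = rownames(counts),
    n_none = as.integer(counts[, "none"]),
    n_mild = as.integer(counts[, "mild"]),
    n_moderate = as.integer(counts[, "moderate"]),
    n_severe = as.integer(counts[, "severe"])
  )
  out$n_annotated <- out$n_none + out$n_mild + out$n_moderate + out$n_severe
  out <- out[out$stratum %in% present, ]
  if (!is.null(design)) {
    out <- dplyr::left_join(out, design[, c("stratum", "n_sampled")],
                            by = "stratum")
    short <- !is.na(out$n_sampled) & out$n_sampled < out$n_annotated
    if (any(short)) {
      stop_validation(sprintf(
        "n_sampled < n_annotated for stratum(s): %s",
        paste(out$stratum[short], collapse = ", ")))
    }
  } else {
    out$n_sampled <- NA_integer_
  }
  out
}

#' The five-group sampling design
#'
#' @param n_per_group Patients sampled per study group (default 20).
#' @return Tibble `stratum`, `n_sampled` usable as the `design` argument of
#'   [severity_distribution()].
#' @export
study_design <- function(n_per_group = 20L) {
  tibble::tibble(stratum = GROUPS, n_sampled = as.integer(n_per_group))
}

#' Positive predictive value per stratum
#'
#' PPV for detecting moderate-or-severe OUD: the number of patients whose
#' inferred category is moderate or severe (i.e. severity score >= 4, or a
#' forced severe classification) over either the patients with annotations
#' (`denominator_mode = "annotated"`) or all sampled patients
#' (`"all_sampled"`, the conservative denominator counting patients whose
#' notes yielded nothing).
#'
#' @param distribution Output of [severity_distribution()].
#' @param denominator_mode `"annotated"` or `"all_sampled"`.
#' @param threshold_category Lowest category counted as positive (default
#'   `"moderate"`).
#' @return Tibble: `stratum`, `denominator_mode`, `numerator`,
#'   `denominator`, `ppv` (rounded half-up to 2 decimals; `NA` with
#'   `undefined = TRUE` when the denominator is 0 or unknown).
#' @export
ppv <- function(distribution, denominator_mode = c("annotated", "all_sampled"),
                threshold_category = "moderate") {
  denominator_mode <- match.arg(denominator_mode)
  assert_one_of(threshold_category, CATEGORIES, "threshold_category")
  pos_cats <- CATEGORIES[seq_along(CATEGORIES) >=
                           match(threshold_category, CATEGORIES)]
  numerator <- rowSums(as.matrix(
    distribution[, paste0("n_", pos_cats), drop = FALSE]))
  denominator <- if (denominator_mode == "annotated") {
    distribution$n_annotated
  } else {
    distribution$n_sampled
  }
  undefined <- is.na(denominator) | denominator == 0L
  tibble::tibble(
    stratum = distribution$stratum,
    denominator_mode = denominator_mode,
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    ppv = ifelse(undefined, NA_real_,
                 round_half_up(numerator / denominator, 2)),
    undefined = undefined
  )
}

#' Pooled positive predictive value across strata
#'
#' Sums numerators and denominators across the (non-control) strata before
#' dividing, so the pooled PPV is the patient-weighted aggregate rather than
#' a mean of stratum PPVs.
#'
#' @inheritParams ppv
#' @return One-row tibble in the same shape as [ppv()] with
#'   `stratum = "pooled"`.
#' @export
pooled_ppv <- function(distribution, denominator_mode = c("annotated", "all_sampled"),
                       threshold_category = "moderate") {
  denominator_mode <- match.arg(denominator_mode)
  distribution <- distribution[distribution$stratum != "Control", ]
  if (!nrow(distribution)) {
    stop_validation("pooled_ppv needs at least one non-control stratum")
  }
  per <- ppv(distribution, denominator_mode, threshold_category)
  num <- sum(per$numerator[!per$undefined])
  den <- sum(per$denominator[!per$undefined])
  tibble::tibble(
    stratum = "pooled",
    denominator_mode = denominator_mode,
    numerator = as.integer(num),
    denominator = as.integer(den),
    ppv = if (den == 0L) NA_real_ else round_half_up(num / den, 2),
    undefined = den == 0L
  )
}

#' PPV table straight from scores
#'
#' Convenience wrapper: stratify, tabulate and compute per-stratum plus
#' pooled PPVs in one call. `strict_gt4` applies the verbatim "score > 4"
#' reading of the positivity rule instead of the moderate-or-severe category
#' rule (score >= 4 or forced); the two differ for patients with a score of
#' exactly 4.
#'
#' @inheritParams severity_distribution
#' @inheritParams ppv
#' @param strict_gt4 Count only patients with score > 4 (forced severe still
#'   counts) as positive.
#' @return Tibble of per-stratum rows plus a `"pooled"` row.
#' @export
ppv_table <- function(scores, stratifier = c("group", "index_reason"),
                      denominator_mode = c("annotated", "all_sampled"),
                      design = NULL, strict_gt4 = FALSE) {
  stratifier <- match.arg(stratifier)
  denominator_mode <- match.arg(denominator_mode)
  if (!is.data.frame(scores)) scores <- scores$scores
  if (strict_gt4) {
    scores <- dplyr::mutate(
      scores,
      category = categorize(ifelse(.data$score > 4L, 6L, 0L), .data$forced)
    )
  }
  dist <- severity_distribution(scores, stratifier, design)
  dplyr::bind_rows(
    ppv(dist, denominator_mode),
    pooled_ppv(dist, denominator_mode)
  )
}
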