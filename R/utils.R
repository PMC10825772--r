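#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Closed vocabularies of the corpus model. Every reader/validator and every
# cross-tabulation uses these, so absent levels are zero-filled rather than
# silently dropped.
GROUPS <- c("CP-RX", "CP-nonRX", "OUD-DX", "OUD-TX", "Control")
INDEX_REASONS <- c("oud_diagnosis", "opioid_order")
POSITIONS <- c("historic", "index", "new")
SETTINGS <- c("ED", "ED_to_IPT", "OPT", "IPT")
NOTE_TYPES <- c(
  "progress", "ancillary_progress", "h_and_p", "discharge_summary",
  "ed", "ed_provider", "ed_triage", "ed_support_staff",
  "communication", "outpatient_clinic", "lactation"
)
CATEGORIES <- c("none", "mild", "moderate", "severe")
CLASS_CATEGORIES <- c(
  "opioid_misuse", "substance_use_nonopioid", "contributing_factor",
  "consequence", "lack_of_control", "other"
)
N_CRITERIA <- 11L

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.005 -> 0.01`), matching the
#' convention used for reported positive predictive values. Base `round()`
#' rounds half to even, which would turn 0.835 into 0.83.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(0.835, 2) # 0.84
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stop with a classed condition so tests can target the failure mode.
stop_validation <- function(msg, class = "oudseverity_validation_error") {
  abort(msg, class = c(class, "oudseverity_error"))
}

stop_lookup <- function(msg) {
  stop_validation(msg, class = "oudseverity_lookup_error")
}

assert_one_of <- function(x, allowed, what, context = NULL) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad)) {
    stop_validation(sprintf(
      "invalid %s: %s (allowed: %s)%s",
      what, paste(bad, collapse = ", "), paste(allowed, collapse = ", "),
      if (is.null(context)) "" else paste0(" [", context, "]")
    ))
  }
  invisible(x)
}
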