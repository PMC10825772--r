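#' The annotation schema / DSM-5 crosswalk
#'
#' The crosswalk is the configured mapping from annotation classes (semantic
#' labels assigned to full sentences of a clinical note) to the 11 DSM-5
#' diagnostic criteria for opioid use disorder. It is data, not code: a YAML
#' file lists every class with its category, whether it scores, which
#' criteria it maps to, its attributes (qualifiers such as
#' `temporality: current/historic`), and an optional `force_category`
#' override (e.g. documented medication treatment for OUD forces the
#' "severe" classification regardless of the criterion count).
#'
#' @param path Path to a crosswalk YAML file.
#' @return An object of class `oud_crosswalk`: a list with `version`,
#'   `expected_counts` (possibly `NULL`) and `classes`, a named list of
#'   class definitions.
#' @seealso [default_crosswalk()] for the configuration shipped with the
#'   package, [criteria_for()] and [force_severe_classes()] for queries.
#' @export
#' @examples
#' cw <- default_crosswalk()
#' length(cw$classes)
#' criteria_for(c("opioid craving", "withdrawal"), cw)
load_crosswalk <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("crosswalk file not found: %s", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop_validation(sprintf("failed to parse crosswalk YAML '%s': %s",
                              path, conditionMessage(e)))
    }
  )
  as_crosswalk(raw)
}

#' @rdname load_crosswalk
#' @export
default_crosswalk <- function() {
  load_crosswalk(system.file("extdata", "crosswalk.yaml",
                             package = "oudseverity", mustWork = TRUE))
}

#' Construct and validate a crosswalk from a plain list
#'
#' @param x A list with elements `version`, `classes` and optionally
#'   `expected_counts`, as produced by reading a crosswalk YAML file.
#' @return A validated `oud_crosswalk`.
#' @export
as_crosswalk <- function(x) {
  if (!is.list(x) || is.null(x$classes)) {
    stop_validation("crosswalk must be a list with a 'classes' element")
  }
  classes <- lapply(x$classes, normalize_class)
  names(classes) <- vapply(classes, `[[`, character(1), "name")
  if (anyDuplicated(names(classes))) {
    dup <- unique(names(classes)[duplicated(names(classes))])
    stop_validation(sprintf("duplicate class name(s): %s",
                            paste(dup, collapse = ", ")))
  }
  cw <- structure(
    list(
      version = as.character(x$version %||% "unversioned"),
      expected_counts = x$expected_counts,
      classes = classes
    ),
    class = "oud_crosswalk"
  )
  validate_crosswalk(cw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_class <- function(cl) {
  if (is.null(cl$name) || !nzchar(cl$name)) {
    stop_validation("every crosswalk class needs a non-empty 'name'")
  }
  list(
    name = as.character(cl$name),
    category = as.character(cl$category %||% "other"),
    scoring = isTRUE(cl$scoring),
    attributes = cl$attributes %||% list(),
    criteria = sort(unique(as.integer(unlist(cl$criteria)))),
    force_category = cl$force_category,
    # Optional restriction of the criterion grant to particular attribute
    # values, e.g. restrict: {attribute: temporality, values: [current]}.
    restrict = cl$restrict
  )
}

validate_crosswalk <- function(cw) {
  for (cl in cw$classes) {
    assert_one_of(cl$category, CLASS_CATEGORIES, "class category", cl$name)
    if (length(cl$criteria) &&
        (any(cl$criteria < 1L) || any(cl$criteria > N_CRITERIA))) {
      stop_validation(sprintf(
        "class '%s' maps to criterion outside 1..%d: %s",
        cl$name, N_CRITERIA,
        paste(setdiff(cl$criteria, seq_len(N_CRITERIA)), collapse = ", ")
      ))
    }
    if (!is.null(cl$force_category)) {
      assert_one_of(cl$force_category, CATEGORIES, "force_category", cl$name)
    }
    has_grant <- length(cl$criteria) > 0L || !is.null(cl$force_category)
    if (cl$scoring && !has_grant) {
      stop_validation(sprintf(
        "class '%s' is marked scoring but has neither criteria nor force_category",
        cl$name
      ))
    }
    if (!cl$scoring && has_grant) {
      stop_validation(sprintf(
        "class '%s' is marked scoring=false but declares criteria or force_category",
        cl$name
      ))
    }
    if (length(cl$attributes)) {
      empty <- names(cl$attributes)[lengths(cl$attributes) == 0L]
      if (length(empty)) {
        stop_validation(sprintf(
          "class '%s' declares attribute(s) with no allowed values: %s",
          cl$name, paste(empty, collapse = ", ")
        ))
      }
    }
    if (!is.null(cl$restrict)) {
      if (is.null(cl$restrict$attribute) || is.null(cl$restrict$values)) {
        stop_validation(sprintf(
          "class '%s': restrict needs 'attribute' and 'values'", cl$name))
      }
    }
  }
  ec <- cw$expected_counts
  if (!is.null(ec)) {
    got <- crosswalk_counts(cw)
    for (k in intersect(names(ec), names(got))) {
      if (got[[k]] != ec[[k]]) {
        stop_validation(sprintf(
          "crosswalk %s is %d, expected_counts says %d",
          k, got[[k]], as.integer(ec[[k]])
        ))
      }
    }
  }
  cw
}

#' Summary counts of a crosswalk
#'
#' @param crosswalk An `oud_crosswalk`.
#' @return Named list with `total_classes`, `scoring_classes` and
#'   `attributed_classes`.
#' @export
crosswalk_counts <- function(crosswalk) {
  cls <- crosswalk$classes
  list(
    total_classes = length(cls),
    scoring_classes = sum(vapply(cls, `[[`, logical(1), "scoring")),
    attributed_classes = sum(vapply(cls, function(cl) length(cl$attributes) > 0L,
                                    logical(1)))
  )
}

#' Write a crosswalk back to YAML
#'
#' Serializes in the same structure that [load_crosswalk()] reads, so a
#' load/write/load round trip is the identity.
#'
#' @param crosswalk An `oud_crosswalk`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crosswalk <- function(crosswalk, path) {
  out <- list(
    version = crosswalk$version,
    expected_counts = crosswalk$expected_counts,
    classes = unname(lapply(crosswalk$classes, function(cl) {
      x <- list(name = cl$name, category = cl$category, scoring = cl$scoring)
      if (length(cl$attributes)) x$attributes <- cl$attributes
      if (length(cl$criteria)) x$criteria <- as.integer(cl$criteria)
      if (!is.null(cl$force_category)) x$force_category <- cl$force_category
      if (!is.null(cl$restrict)) x$restrict <- cl$restrict
      x
    }))
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.oud_crosswalk <- function(x, ...) {
  ct <- crosswalk_counts(x)
  cat(sprintf(
    "<oud_crosswalk v%s: %d classes (%d scoring, %d with attributes)>\n",
    x$version, ct$total_classes, ct$scoring_classes, ct$attributed_classes
  ))
  invisible(x)
}

#' Map annotated classes to endorsed DSM-5 criteria
#'
#' Takes the classes annotated for a patient (optionally with their
#' attribute values) and returns the union of the DSM-5 criterion ids those
#' classes map to under the crosswalk. A mapping declared with a `restrict`
#' clause is granted only when the annotation's attribute value is among the
#' permitted ones (annotations lacking the attribute still grant it).
#'
#' @param classes Character vector of class names (may contain duplicates;
#'   endorsement is set-valued).
#' @param crosswalk An `oud_crosswalk`.
#' @param attributes Optional list, parallel to `classes`, of named lists of
#'   attribute values for each annotation.
#' @return Sorted integer vector of criterion ids, a subset of 1..11.
#' @export
criteria_for <- function(classes, crosswalk, attributes = NULL) {
  if (length(classes) == 0L) return(integer(0))
  unknown <- setdiff(unique(classes), names(crosswalk$classes))
  if (length(unknown)) {
    stop_lookup(sprintf("unknown annotation class(es): %s",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(attributes) && length(attributes) != length(classes)) {
    stop_validation("attributes must be parallel to classes")
  }
  crit <- integer(0)
  for (i in seq_along(classes)) {
    cl <- crosswalk$classes[[classes[i]]]
    if (!length(cl$criteria)) next
    if (!is.null(cl$restrict) && !is.null(attributes)) {
      val <- attributes[[i]][[cl$restrict$attribute]]
      if (!is.null(val) && !(val %in% cl$restrict$values)) next
    }
    crit <- c(crit, cl$criteria)
  }
  sort(unique(crit))
}

#' Classes that force the severe category
#'
#' @param crosswalk An `oud_crosswalk`.
#' @return Character vector of class names whose presence forces
#'   `category = "severe"` (e.g. documented OUD treatment).
#' @export
force_severe_classes <- function(crosswalk) {
  keep <- vapply(crosswalk$classes, function(cl) {
    identical(cl$force_category, "severe")
  }, logical(1))
  names(crosswalk$classes)[keep]
}

#' Names of scoring classes
#'
#' @param crosswalk An `oud_crosswalk`.
#' @return Character vector of the classes with `scoring = TRUE`.
#' @export
scoring_classes <- function(crosswalk) {
  keep <- vapply(crosswalk$classes, `[[`, logical(1), "scoring")
  names(crosswalk$classes)[keep]
}
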