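#' Read a structured guideline table
#'
#' The guideline table encodes, per sub-indication, the recommended empiric
#' regimens: a list of first-choice regimens and a list of second-choice
#' regimens, each regimen being a set of ATC level-5 codes (so combination
#' recommendations, e.g. a beta-lactam plus a fluoroquinolone for severe
#' CAP, are expressible). Sub-indications of the kind "other" are marked
#' `assessable: false` and are never scored.
#'
#' File format (YAML, or JSON by file extension): a top-level mapping
#' `sub_indication -> {assessable, first_choice, second_choice,
#' route_constraint}` where each choice list is a list of ATC-code lists
#' and `route_constraint` (optional) maps an ATC code to the required
#' route.
#'
#' Validation is strict: an unknown sub-indication code, a regimen that is
#' duplicated within or across the two choice lists of one sub-indication,
#' an empty or duplicate-containing agent set, or an assessable
#' sub-indication without a first choice are all configuration errors.
#'
#' @param path Path to a YAML or JSON guideline file.
#' @param taxonomy Taxonomy the sub-indication codes are checked against;
#'   defaults to [default_indication_taxonomy()].
#' @return A named list of class `guideline_table`; each element has fields
#'   `assessable`, `first_choice`, `second_choice`, `route_constraint`.
#' @export
#' @examples
#' path <- system.file("extdata", "guideline_synthetic_swab_like.yaml",
#'                     package = "stewardaudit")
#' gl <- read_guideline_table(path)
#' names(gl)
read_guideline_table <- function(path, taxonomy = default_indication_taxonomy()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0 || is.null(names(raw))) {
    stop("guideline file is empty or not a mapping: ", path, call. = FALSE)
  }
  as_guideline_table(raw, taxonomy)
}

#' Build a guideline table from a list
#'
#' @param x Named list in the structure documented at
#'   [read_guideline_table()].
#' @inheritParams read_guideline_table
#' @return A validated `guideline_table`.
#' @export
as_guideline_table <- function(x, taxonomy = default_indication_taxonomy()) {
  unknown <- setdiff(names(x), taxonomy$code)
  if (length(unknown) > 0) {
    stop("unknown sub-indication code(s) in guideline table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  norm_choice <- function(ch, code, which) {
    if (is.null(ch)) return(list())
    if (!is.list(ch)) ch <- list(ch)
    out <- lapply(ch, function(reg) as.character(unlist(reg, use.names = FALSE)))
    for (reg in out) {
      if (length(reg) == 0) {
        stop("empty agent set in ", which, " of '", code, "'", call. = FALSE)
      }
      if (anyDuplicated(reg)) {
        stop("duplicate agent within a regimen in ", which, " of '", code,
             "'", call. = FALSE)
      }
    }
    keys <- vapply(out, function(r) paste(sort(r), collapse = ";"), character(1))
    if (anyDuplicated(keys)) {
      stop("duplicate regimen in ", which, " of '", code, "'", call. = FALSE)
    }
    out
  }
  entries <- lapply(names(x), function(code) {
    e <- x[[code]]
    assessable <- isTRUE(e$assessable) || is.null(e$assessable)
    first <- norm_choice(e$first_choice, code, "first_choice")
    second <- norm_choice(e$second_choice, code, "second_choice")
    k1 <- vapply(first, function(r) paste(sort(r), collapse = ";"), character(1))
    k2 <- vapply(second, function(r) paste(sort(r), collapse = ";"), character(1))
    shared <- intersect(k1, k2)
    if (length(shared) > 0) {
      stop("regimen(s) present in both first and second choice of '", code,
           "': ", paste(shared, collapse = " / "), call. = FALSE)
    }
    if (assessable && length(first) == 0) {
      stop("assessable sub-indication '", code,
           "' has no first-choice regimen", call. = FALSE)
    }
    rc <- e$route_constraint
    if (!is.null(rc)) {
      rc <- vapply(rc, as.character, character(1))
      bad <- setdiff(unname(rc), .route_levels)
      if (length(bad) > 0) {
        stop("invalid route in route_constraint of '", code, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    list(assessable = assessable, first_choice = first,
         second_choice = second, route_constraint = rc)
  })
  names(entries) <- names(x)
  structure(entries, class = "guideline_table")
}

#' Write a guideline table to YAML
#'
#' Inverse of [read_guideline_table()]: `read(write(x))` reproduces `x`.
#'
#' @param guideline A `guideline_table`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_guideline_table <- function(guideline, path) {
  stopifnot(inherits(guideline, "guideline_table"))
  out <- lapply(unclass(guideline), function(e) {
    x <- list(
      assessable = e$assessable,
      first_choice = lapply(e$first_choice, as.list),
      second_choice = lapply(e$second_choice, as.list)
    )
    if (!is.null(e$route_constraint)) {
      x$route_constraint <- as.list(e$route_constraint)
    }
    x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.guideline_table <- function(x, ...) {
  cat("<guideline_table> ", length(x), " sub-indications (",
      sum(vapply(x, function(e) e$assessable, logical(1))),
      " assessable)\n", sep = "")
  for (code in names(x)) {
    e <- x[[code]]
    cat(sprintf("  %-22s %s first: %d, second: %d\n", code,
                if (e$assessable) "A/B/C" else "  --  ",
                length(e$first_choice), length(e$second_choice)))
  }
  invisible(x)
}
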