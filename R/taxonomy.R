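#' Indication taxonomy
#'
#' The registration tool forces prescribers to pick a focus of infection,
#' first on tract level (respiratory, urinary, or other), then a
#' sub-indication. This function returns the default taxonomy used
#' throughout the package: one row per sub-indication with its tract and a
#' display label.
#'
#' Hospitals may configure a reduced taxonomy (e.g. an EMR without the
#' "other" option within a tract, or without the mild/severe CAP split);
#' any data frame with columns `tract`, `code`, `label` that passes
#' [validate_taxonomy()] can be used wherever a taxonomy is accepted.
#'
#' @return A tibble with columns `tract` (`"RTI"`/`"UTI"`), `code`
#'   (sub-indication code) and `label` (display text).
#' @export
#' @examples
#' default_indication_taxonomy()
default_indication_taxonomy <- function() {
  tibble::tribble(
    ~tract, ~code,                  ~label,
    "RTI",  "CAP",                  "Community-acquired pneumonia (severity unspecified)",
    "RTI",  "CAP-m",                "Community-acquired pneumonia, mild to moderate-severe",
    "RTI",  "CAP-s",                "Community-acquired pneumonia, severe",
    "RTI",  "HAP",                  "Hospital-acquired pneumonia",
    "RTI",  "COPD-exacerbation",    "Exacerbation of COPD",
    "RTI",  "aspiration-pneumonia", "Aspiration pneumonia",
    "RTI",  "bronchitis",           "Acute bronchitis",
    "RTI",  "other-RTI",            "Other respiratory tract infection",
    "UTI",  "cystitis",             "Cystitis",
    "UTI",  "complicated-UTI",      "Complicated UTI (urosepsis / pyelonephritis)",
    "UTI",  "chronic-prostatitis",  "Chronic bacterial prostatitis",
    "UTI",  "other-UTI",            "Other urinary tract infection"
  )
}

#' Validate an indication taxonomy
#'
#' Checks that sub-indication codes are unique and that every code maps to
#' exactly one tract. A tract without an "other" member is allowed (some
#' EMR configurations lack it) but triggers a warning, because prescribers
#' then tend to select the second-best option.
#'
#' @param taxonomy A data frame with columns `tract`, `code`, `label`.
#' @return The taxonomy, invisibly, if valid; otherwise an error.
#' @export
validate_taxonomy <- function(taxonomy) {
  required <- c("tract", "code", "label")
  missing <- setdiff(required, names(taxonomy))
  if (length(missing) > 0) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(taxonomy$code[duplicated(taxonomy$code)])
  if (length(dup) > 0) {
    stop("duplicate sub-indication code(s) in taxonomy: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (tr in unique(taxonomy$tract)) {
    codes <- taxonomy$code[taxonomy$tract == tr]
    if (!any(grepl("^other", codes))) {
      warning("tract '", tr, "' has no 'other' sub-indication; ",
              "mis-selections into neighbouring codes become more likely",
              call. = FALSE)
    }
  }
  invisible(taxonomy)
}

# Enum domains shared by readers and the generator.
.route_levels <- c("oral", "iv", "im", "other")
.indication_class_levels <- c("empiric", "targeted", "prophylaxis")
.tract_levels <- c("RTI", "UTI", "other")
.stratum_levels <- c("RTI", "UTI", "random_other")

#' Marker used in chart-review tables for indications outside RTI/UTI
#' @keywords internal
.non_rti_uti <- "non_RTI_UTI"

#' Marker used in chart-review tables when the documented indication could
#' not be assessed (missing or inaccessible documentation)
#' @keywords internal
.unassessable <- "unassessable"
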