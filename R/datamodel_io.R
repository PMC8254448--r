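#' @importFrom rlang .data
NULL

# Canonical schema of the prescription extract. `mandatory` columns must be
# present (possibly via column_map); optional columns are filled with NA.
.rx_mandatory <- c(
  "record_id", "patient_id", "admission_id", "atc_code",
  "start_ts", "stop_ts", "route", "indication_class",
  "focus_tract", "sub_indication"
)
.rx_optional <- c("agent_name", "dose_text", "prescriber_specialty", "ward")
.rx_columns <- c(
  "record_id", "patient_id", "admission_id", "atc_code", "agent_name",
  "start_ts", "stop_ts", "route", "dose_text", "prescriber_specialty",
  "ward", "indication_class", "focus_tract", "sub_indication"
)

.adm_columns <- c(
  "patient_id", "admission_id", "admit_ts", "discharge_ts",
  "age_years", "ward_type"
)
.ward_type_levels <- c("general", "icu", "other")

# All timestamps live on a single timezone-naive timeline, represented as
# POSIXct in UTC. Empty strings are absent values (only stop_ts may be
# absent); an unparseable non-empty string is a parse failure.
.parse_ts <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- suppressWarnings(readr::parse_datetime(
    x,
    locale = readr::locale(tz = "UTC")
  ))
  # date-only values ("2019-05-14") are accepted at midnight
  miss <- !is.na(x) & is.na(out)
  if (any(miss)) {
    out2 <- suppressWarnings(readr::parse_date(x[miss]))
    out[miss] <- as.POSIXct(out2, tz = "UTC")
  }
  attr(out, "problems") <- NULL
  out
}

.detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return(",")
  if (lengths(regmatches(header, gregexpr(";", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- .detect_delim(path)
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), show_col_types = FALSE, progress = FALSE
  )
}

# Rename source columns to canonical schema names and apply per-field value
# translations. `column_map`: named character vector, names = canonical
# field, values = source column name. `value_map`: named list keyed by
# canonical field; each element a named character vector source -> canonical.
.apply_maps <- function(raw, column_map, value_map) {
  if (!is.null(column_map)) {
    for (field in names(column_map)) {
      src <- column_map[[field]]
      if (!src %in% names(raw)) {
        stop("column_map points field '", field, "' at missing column '",
             src, "'", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- field
    }
  }
  if (!is.null(value_map)) {
    for (field in names(value_map)) {
      if (!field %in% names(raw)) next
      tr <- value_map[[field]]
      hit <- raw[[field]] %in% names(tr)
      raw[[field]][hit] <- unname(tr[raw[[field]][hit]])
    }
  }
  raw
}

#' Read a prescription extract
#'
#' Reads a delimited EMR extract with one row per systemic antibiotic (ATC
#' class J01) prescription. The delimiter (comma or semicolon) is detected
#' from the header row. Because extract layouts differ between hospitals
#' (EPIC sites in particular customise column names and coded values), a
#' per-hospital `column_map` and `value_map` translate the source file into
#' the canonical schema.
#'
#' Rows that cannot be parsed (bad timestamp, unknown route, unknown
#' indication class or focus tract, empty ATC code, or a missing
#' sub-indication for an RTI/UTI record) are never silently dropped: they
#' are returned in the `rejects` tibble with a reason, so that
#' `nrow(records) + nrow(rejects)` always equals the number of data rows.
#'
#' @param path Path to the delimited extract (UTF-8, header row).
#' @param column_map Optional named character vector mapping canonical field
#'   names (names) to source column names (values), e.g.
#'   `c(atc_code = "ATC")`.
#' @param value_map Optional named list of value translations per canonical
#'   field, e.g. `list(indication_class = c(profylaxe = "prophylaxis"))`.
#' @return A list of class `rx_extract` with elements `records` (tibble in
#'   the canonical schema, timestamps as POSIXct UTC) and `rejects` (tibble
#'   of raw rows plus a `reason` column).
#' @export
read_prescription_extract <- function(path, column_map = NULL, value_map = NULL) {
  raw <- .read_delim_auto(path)
  raw <- .apply_maps(raw, column_map, value_map)

  missing <- setdiff(.rx_mandatory, names(raw))
  if (length(missing) > 0) {
    stop("extract is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(.rx_optional, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, .rx_columns]

  n <- nrow(raw)
  start_ts <- .parse_ts(raw$start_ts)
  stop_ts <- .parse_ts(raw$stop_ts)
  blank <- function(x) is.na(x) | trimws(as.character(x)) == ""

  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(blank(raw$start_ts) | is.na(start_ts), "timestamp")
  reason <- flag(!blank(raw$stop_ts) & is.na(stop_ts), "timestamp")
  reason <- flag(blank(raw$atc_code), "atc_code")
  reason <- flag(!raw$route %in% .route_levels, "route")
  reason <- flag(!raw$indication_class %in% .indication_class_levels,
                 "indication_class")
  reason <- flag(!raw$focus_tract %in% .tract_levels, "focus_tract")
  reason <- flag(raw$focus_tract %in% c("RTI", "UTI") &
                   blank(raw$sub_indication), "sub_indication")

  ok <- is.na(reason)
  records <- tibble::as_tibble(raw[ok, , drop = FALSE])
  records$start_ts <- start_ts[ok]
  records$stop_ts <- stop_ts[ok]
  records$sub_indication[blank(records$sub_indication)] <- NA_character_
  for (col in .rx_optional) {
    records[[col]][blank(records[[col]])] <- NA_character_
  }

  rejects <- tibble::as_tibble(raw[!ok, , drop = FALSE])
  rejects$reason <- reason[!ok]

  structure(list(records = records, rejects = rejects), class = "rx_extract")
}

#' Write a prescription extract
#'
#' Writes records back to the canonical delimited format, so that
#' `read_prescription_extract(write_prescription_extract(x))` round-trips
#' (audit outputs must be re-ingestable).
#'
#' @param records Tibble of prescription records in the canonical schema.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `";"`.
#' @return `path`, invisibly.
#' @export
write_prescription_extract <- function(records, path, delim = ",") {
  out <- records[, .rx_columns]
  out$start_ts <- format(out$start_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$stop_ts <- ifelse(is.na(out$stop_ts), "",
                        format(out$stop_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Read an admissions table
#'
#' The admissions table is authoritative for admission boundaries, patient
#' age at admission, and ward type; prescriptions are linked to it via
#' `admission_id`. Invariant violations (discharge before admit, negative
#' age) are hard errors, because downstream selection rules would silently
#' misbehave on such rows.
#'
#' @param path Path to the delimited admissions table with columns
#'   `patient_id`, `admission_id`, `admit_ts`, `discharge_ts`, `age_years`,
#'   `ward_type` (`general`/`icu`/`other`).
#' @param column_map Optional mapping as in [read_prescription_extract()].
#' @return Tibble with parsed timestamps and integer ages.
#' @export
read_admissions <- function(path, column_map = NULL) {
  raw <- .read_delim_auto(path)
  raw <- .apply_maps(raw, column_map, NULL)
  missing <- setdiff(.adm_columns, names(raw))
  if (length(missing) > 0) {
    stop("admissions table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  adm <- tibble::as_tibble(raw[, .adm_columns])
  adm$admit_ts <- .parse_ts(adm$admit_ts)
  adm$discharge_ts <- .parse_ts(adm$discharge_ts)
  adm$age_years <- as.integer(adm$age_years)
  if (anyNA(adm$admit_ts) || anyNA(adm$discharge_ts)) {
    stop("admissions table contains unparseable timestamps", call. = FALSE)
  }
  if (any(adm$discharge_ts < adm$admit_ts)) {
    stop("admissions with discharge before admission: ",
         paste(utils::head(adm$admission_id[adm$discharge_ts < adm$admit_ts], 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(adm$age_years) || any(adm$age_years < 0)) {
    stop("admissions table contains missing or negative ages", call. = FALSE)
  }
  if (any(!adm$ward_type %in% .ward_type_levels)) {
    bad <- unique(adm$ward_type[!adm$ward_type %in% .ward_type_levels])
    stop("unknown ward_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(adm$admission_id)) {
    stop("duplicate admission_id in admissions table", call. = FALSE)
  }
  adm
}

#' Write an admissions table
#' @param admissions Tibble as returned by [read_admissions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(admissions, path) {
  out <- admissions[, .adm_columns]
  out$admit_ts <- format(out$admit_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$discharge_ts <- format(out$discharge_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a chart-review table
#'
#' Chart reviews compare, for each sampled prescription record, the
#' indication the prescriber selected in the order-entry screen
#' (`selected_indication`) with the diagnosis documented in the patient
#' notes (`documented_indication`). Records outside RTI/UTI carry the
#' marker `"non_RTI_UTI"`; reviews where the documentation was missing or
#' inaccessible carry `documented_indication = "unassessable"`.
#'
#' @param path Delimited file with columns `record_id`, `stratum`
#'   (`RTI`/`UTI`/`random_other`), `selected_indication`,
#'   `documented_indication`.
#' @return Tibble of chart-review records.
#' @export
read_chart_reviews <- function(path) {
  raw <- .read_delim_auto(path)
  need <- c("record_id", "stratum", "selected_indication", "documented_indication")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("chart-review table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rev <- tibble::as_tibble(raw[, need])
  if (any(!rev$stratum %in% .stratum_levels)) {
    bad <- unique(rev$stratum[!rev$stratum %in% .stratum_levels])
    stop("unknown stratum label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inconsistent <- (rev$stratum == "random_other" &
                     rev$selected_indication != .non_rti_uti) |
    (rev$stratum != "random_other" & rev$selected_indication == .non_rti_uti)
  if (any(inconsistent)) {
    stop("stratum inconsistent with selected_indication for record(s): ",
         paste(utils::head(rev$record_id[inconsistent], 5), collapse = ", "),
         call. = FALSE)
  }
  rev
}

#' Cross-check an extract against the admissions table
#'
#' A reporting-only inspection pass run before selection: it flags orphan
#' prescriptions (admission identifier absent from the admissions table),
#' records whose stop precedes their start, records started before their
#' admission (these are deliberately NOT removed here -- they feed the
#' erroneous-prescription exclusion during cohort selection), and records
#' whose ATC code is not in class J01.
#'
#' @param records Tibble of prescription records.
#' @param admissions Tibble of admissions.
#' @return Tibble with columns `record_id`, `issue`; empty when the extract
#'   is internally consistent.
#' @export
validate_extract <- function(records, admissions) {
  issues <- list()
  orphan <- !records$admission_id %in% admissions$admission_id
  if (any(orphan)) {
    issues$orphan <- tibble::tibble(
      record_id = records$record_id[orphan], issue = "orphan_admission")
  }
  rev <- !is.na(records$stop_ts) & records$stop_ts < records$start_ts
  if (any(rev)) {
    issues$rev <- tibble::tibble(
      record_id = records$record_id[rev], issue = "stop_before_start")
  }
  adm_ts <- admissions$admit_ts[match(records$admission_id, admissions$admission_id)]
  early <- !is.na(adm_ts) & records$start_ts < adm_ts
  if (any(early)) {
    issues$early <- tibble::tibble(
      record_id = records$record_id[early], issue = "start_before_admission")
  }
  nonj01 <- !startsWith(records$atc_code, "J01")
  if (any(nonj01)) {
    issues$nonj01 <- tibble::tibble(
      record_id = records$record_id[nonj01], issue = "non_J01")
  }
  if (length(issues) == 0) {
    return(tibble::tibble(record_id = character(), issue = character()))
  }
  dplyr::bind_rows(issues)
}
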