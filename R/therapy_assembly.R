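#' Merge simultaneous prescriptions into combination regimens
#'
#' Antibiotics prescribed simultaneously for the same registered
#' sub-indication constitute combination therapy and are merged into one
#' regimen per `(admission_id, sub_indication)` pair -- the unit at which
#' appropriateness is assessed. Simultaneity is already guaranteed by the
#' empiric snapshot (all records of an admission are active at the same
#' evaluation instant), so merging keys only on admission and
#' sub-indication. Duplicate agent/route pairs collapse under set
#' semantics.
#'
#' @param records Empiric prescription records, typically
#'   `run_selection(...)$records`. Every record must carry a
#'   `sub_indication`.
#' @return A tibble with one row per regimen: `admission_id`,
#'   `sub_indication`, `agents` (list column of tibbles with `atc_code`,
#'   `route`), `agent_key` (sorted, semicolon-joined `"ATC:route"` tokens
#'   -- a canonical identifier of the combination), `atc_key` (sorted ATC
#'   codes only), `n_agents`, `n_source_records` and `source_record_ids`
#'   (list column).
#' @export
assemble_regimens <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      admission_id = character(), sub_indication = character(),
      agents = list(), agent_key = character(), atc_key = character(),
      n_agents = integer(), n_source_records = integer(),
      source_record_ids = list()))
  }
  if (anyNA(records$sub_indication)) {
    stop("records without a sub_indication cannot form a regimen",
         call. = FALSE)
  }
  if ("patient_id" %in% names(records)) {
    pp <- unique(records[, c("admission_id", "patient_id")])
    clash <- pp$admission_id[duplicated(pp$admission_id)]
    if (length(clash) > 0) {
      stop("admission identifier(s) shared by multiple patients: ",
           paste(unique(clash), collapse = ", "), call. = FALSE)
    }
  }
  records |>
    dplyr::group_by(.data$admission_id, .data$sub_indication) |>
    dplyr::summarise(
      agents = list({
        a <- unique(data.frame(atc_code = .data$atc_code,
                               route = .data$route))
        tibble::as_tibble(a[order(a$atc_code, a$route), ])
      }),
      agent_key = paste(sort(unique(paste0(.data$atc_code, ":", .data$route))),
                        collapse = ";"),
      atc_key = paste(sort(unique(.data$atc_code)), collapse = ";"),
      n_source_records = dplyr::n(),
      source_record_ids = list(.data$record_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_agents = vapply(.data$agents, nrow, integer(1))) |>
    dplyr::select("admission_id", "sub_indication", "agents", "agent_key",
                  "atc_key", "n_agents", "n_source_records",
                  "source_record_ids") |>
    dplyr::arrange(.data$admission_id, .data$sub_indication)
}

#' Write a regimen table
#'
#' Canonical CSV output: agents serialised as the sorted `agent_key`
#' tokens, so identical combinations always serialise identically.
#'
#' @param regimens Output of [assemble_regimens()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regimens <- function(regimens, path) {
  out <- regimens[, c("admission_id", "sub_indication", "agent_key",
                      "n_agents", "n_source_records")]
  readr::write_csv(out, path)
  invisible(path)
}
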