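#' Classify one regimen against the guideline
#'
#' A regimen is category `A` when its agent set equals (set equality,
#' order- and duplication-insensitive) any first-choice recommended
#' regimen for its sub-indication, `B` when it equals any second-choice
#' regimen, and `C` (discordant) otherwise. First choice takes precedence:
#' a regimen is never both. Regimens for a non-assessable sub-indication
#' (the "other" catch-alls) return `NOT_ASSESSED`. Under the default
#' exact-set matching, a recommended regimen plus an extra agent is
#' discordant; set `allow_extra_agents = TRUE` for the laxer superset
#' reading.
#'
#' @param atc_codes Character vector of ATC level-5 codes in the regimen.
#' @param sub_indication Sub-indication code of the regimen.
#' @param guideline A `guideline_table` (see [read_guideline_table()]).
#' @param routes Optional character vector of routes parallel to
#'   `atc_codes`; only used when `route_strict = TRUE`.
#' @param route_strict When `TRUE`, a match additionally requires every
#'   agent with a route constraint in the guideline to be given by that
#'   route. Off by default: national recommendations are matched on agent
#'   identity only.
#' @param allow_extra_agents When `TRUE`, a regimen containing a
#'   recommended regimen as a subset also matches. Default `FALSE`.
#' @return One of `"A"`, `"B"`, `"C"`, `"NOT_ASSESSED"`.
#' @export
classify_regimen <- function(atc_codes, sub_indication, guideline,
                             routes = NULL, route_strict = FALSE,
                             allow_extra_agents = FALSE) {
  entry <- guideline[[sub_indication]]
  if (is.null(entry)) {
    stop("sub-indication '", sub_indication, "' not in guideline table",
         call. = FALSE)
  }
  if (!entry$assessable) return("NOT_ASSESSED")
  have <- sort(unique(atc_codes))

  routes_ok <- function() {
    rc <- entry$route_constraint
    if (!route_strict || is.null(rc) || is.null(routes)) return(TRUE)
    for (atc in intersect(names(rc), have)) {
      if (!all(routes[atc_codes == atc] == rc[[atc]])) return(FALSE)
    }
    TRUE
  }
  matches <- function(choice) {
    any(vapply(choice, function(reg) {
      reg <- sort(unique(reg))
      if (allow_extra_agents) all(reg %in% have) else identical(reg, have)
    }, logical(1)))
  }
  if (matches(entry$first_choice) && routes_ok()) return("A")
  if (matches(entry$second_choice) && routes_ok()) return("B")
  "C"
}

#' Classify a regimen table
#'
#' Vectorised version of [classify_regimen()] over the output of
#' [assemble_regimens()].
#'
#' @param regimens Regimen tibble from [assemble_regimens()].
#' @inheritParams classify_regimen
#' @return `regimens` with a `category` column appended
#'   (`A`/`B`/`C`/`NOT_ASSESSED`).
#' @export
classify_regimens <- function(regimens, guideline, route_strict = FALSE,
                              allow_extra_agents = FALSE) {
  regimens$category <- vapply(seq_len(nrow(regimens)), function(i) {
    ag <- regimens$agents[[i]]
    classify_regimen(ag$atc_code, regimens$sub_indication[i], guideline,
                     routes = ag$route, route_strict = route_strict,
                     allow_extra_agents = allow_extra_agents)
  }, character(1))
  regimens
}

#' Summarise guideline adherence
#'
#' Computes, per sub-indication, the number of regimens and the
#' proportions in categories A, B and C (over assessable regimens; the
#' three proportions sum to one), the adherence rate, and the
#' agent-combination frequency table with rare combinations pooled as
#' "other". The adherence rate defaults to A+B -- treatment with either a
#' first- or a second-choice recommendation counts as guideline-adherent
#' -- and can be restricted to first choice only.
#'
#' @param regimens Classified regimen tibble ([classify_regimens()]), or
#'   an unclassified one together with `categories`.
#' @param categories Optional character vector of categories parallel to
#'   `regimens` rows (used when `regimens` lacks a `category` column).
#' @param display_threshold Combinations prescribed in less than this
#'   fraction of a sub-indication's regimens are pooled into "other" in
#'   the display table. Default 0.05.
#' @param adherence_tier `"AB"` (default) counts categories A and B as
#'   adherent; `"A"` counts first choice only.
#' @param hospital Optional hospital label carried into reports.
#' @return A list of class `adherence_report` with elements
#'   `by_subindication`, `overall`, `combinations` (pooled display
#'   table), `combinations_detail` (unpooled) and `n_not_assessed`.
#' @export
adherence_summary <- function(regimens, categories = NULL,
                              display_threshold = 0.05,
                              adherence_tier = c("AB", "A"),
                              hospital = NULL) {
  adherence_tier <- match.arg(adherence_tier)
  if (!is.null(categories)) regimens$category <- categories
  if (!"category" %in% names(regimens)) {
    stop("regimens carry no category; run classify_regimens() first",
         call. = FALSE)
  }
  assess <- regimens[regimens$category %in% c("A", "B", "C"), , drop = FALSE]

  rate <- function(pA, pB) if (adherence_tier == "AB") pA + pB else pA
  by_sub <- assess |>
    dplyr::group_by(.data$sub_indication) |>
    dplyr::summarise(
      n = dplyr::n(),
      prop_A = mean(.data$category == "A"),
      prop_B = mean(.data$category == "B"),
      prop_C = mean(.data$category == "C"),
      .groups = "drop"
    ) |>
    dplyr::mutate(adherence_rate = rate(.data$prop_A, .data$prop_B)) |>
    dplyr::arrange(.data$sub_indication)

  overall <- tibble::tibble(
    n = nrow(assess),
    prop_A = if (nrow(assess)) mean(assess$category == "A") else NA_real_,
    prop_B = if (nrow(assess)) mean(assess$category == "B") else NA_real_,
    prop_C = if (nrow(assess)) mean(assess$category == "C") else NA_real_
  )
  overall$adherence_rate <- rate(overall$prop_A, overall$prop_B)

  detail <- assess |>
    dplyr::group_by(.data$sub_indication, combination = .data$atc_key,
                    .data$category) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$sub_indication) |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sub_indication, dplyr::desc(.data$n),
                   .data$combination)

  pooled <- detail |>
    dplyr::mutate(
      combination = ifelse(.data$share < display_threshold, "other",
                           .data$combination),
      category = ifelse(.data$share < display_threshold, "other",
                        .data$category)
    ) |>
    dplyr::group_by(.data$sub_indication, .data$combination, .data$category) |>
    dplyr::summarise(n = sum(.data$n), share = sum(.data$share),
                     .groups = "drop") |>
    dplyr::arrange(.data$sub_indication, dplyr::desc(.data$n),
                   .data$combination)

  structure(
    list(by_subindication = by_sub, overall = overall,
         combinations = pooled, combinations_detail = detail,
         n_not_assessed = sum(regimens$category == "NOT_ASSESSED"),
         adherence_tier = adherence_tier,
         display_threshold = display_threshold,
         hospital = hospital),
    class = "adherence_report"
  )
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("<adherence_report>",
      if (!is.null(x$hospital)) paste0(" hospital ", x$hospital), " ",
      x$overall$n, " assessable regimen(s), ",
      x$n_not_assessed, " not assessed; overall adherence (",
      x$adherence_tier, ") ",
      sprintf("%.1f%%", 100 * x$overall$adherence_rate), "\n", sep = "")
  print(x$by_subindication)
  invisible(x)
}

#' Cross-hospital benchmark table
#'
#' Binds per-hospital adherence reports into one long table (hospital,
#' sub-indication, n, A/B/C percentages, adherence percentage) and a
#' min-max adherence range per sub-indication -- the between-hospital
#' variation the audit exists to surface. Hospitals whose EMR lacks a
#' sub-indication (e.g. no mild/severe CAP split) simply contribute no row
#' for it.
#'
#' @param reports Named list of `adherence_report` objects, keyed by
#'   hospital label.
#' @param taxonomy Taxonomy used to flag unmapped sub-indication codes
#'   (warning, not error).
#' @return A list of class `benchmark_table` with `by_hospital` and
#'   `adherence_range` tibbles.
#' @export
benchmark_table <- function(reports, taxonomy = default_indication_taxonomy()) {
  if (is.null(names(reports)) || any(names(reports) == "")) {
    stop("reports must be a named list keyed by hospital", call. = FALSE)
  }
  rows <- purrr::imap(reports, function(rep, hosp) {
    b <- rep$by_subindication
    tibble::tibble(
      hospital = hosp, sub_indication = b$sub_indication, n = b$n,
      pct_A = 100 * b$prop_A, pct_B = 100 * b$prop_B, pct_C = 100 * b$prop_C,
      adherence_pct = 100 * b$adherence_rate)
  })
  by_hospital <- dplyr::bind_rows(rows)
  unmapped <- setdiff(unique(by_hospital$sub_indication), taxonomy$code)
  if (length(unmapped) > 0) {
    warning("sub-indication code(s) not in the shared taxonomy: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  rng <- by_hospital |>
    dplyr::group_by(.data$sub_indication) |>
    dplyr::summarise(n_hospitals = dplyr::n(),
                     min_adherence_pct = min(.data$adherence_pct),
                     max_adherence_pct = max(.data$adherence_pct),
                     .groups = "drop")
  structure(list(by_hospital = by_hospital, adherence_range = rng),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table> ", length(unique(x$by_hospital$hospital)),
      " hospital(s)\n", sep = "")
  print(x$adherence_range)
  invisible(x)
}
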