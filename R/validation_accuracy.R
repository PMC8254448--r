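#' Draw a stratified chart-review sample
#'
#' Selects record identifiers for manual chart review, stratified on the
#' *selected* (registered) indication: the `RTI` and `UTI` strata verify
#' that selected RTI/UTI indications match the documented diagnosis; the
#' `random_other` stratum screens records registered outside RTI/UTI for
#' missed RTI/UTI prescriptions. Sampling is uniform without replacement
#' within stratum and reproducible given `seed`. When a stratum holds
#' fewer records than requested the whole stratum is returned as a census
#' (flagged in the output), mirroring small-hospital practice where every
#' eligible record is reviewed.
#'
#' @param records Prescription records; the stratum is derived from
#'   `focus_tract` (`RTI`/`UTI`, anything else is `random_other`) unless
#'   the table already has a `stratum` column.
#' @param strata_sizes Named integer vector, e.g.
#'   `c(RTI = 100, UTI = 100, random_other = 100)`.
#' @param seed Integer seed; the only source of randomness. Strata are
#'   drawn in sorted name order from one stream.
#' @return Tibble with columns `stratum`, `record_id`, `census`.
#' @export
draw_validation_sample <- function(records, strata_sizes, seed) {
  if (is.null(names(strata_sizes)) || any(names(strata_sizes) == "")) {
    stop("strata_sizes must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(strata_sizes), .stratum_levels)
  if (length(unknown) > 0) {
    stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"stratum" %in% names(records)) {
    records$stratum <- ifelse(records$focus_tract %in% c("RTI", "UTI"),
                              records$focus_tract, "random_other")
  }
  withr::with_seed(seed, {
    out <- lapply(sort(names(strata_sizes)), function(s) {
      ids <- records$record_id[records$stratum == s]
      n <- strata_sizes[[s]]
      if (length(ids) <= n) {
        tibble::tibble(stratum = s, record_id = ids, census = TRUE)
      } else {
        tibble::tibble(stratum = s, record_id = sample(ids, n),
                       census = FALSE)
      }
    })
    dplyr::bind_rows(out)
  })
}

#' Compute indication-registration accuracy from chart reviews
#'
#' Scores each reviewed record as an error when the selected indication
#' differs from the documented one at the sub-indication level: a
#' tract-level match with a sub-indication mismatch (cystitis selected,
#' complicated UTI documented) IS an error, because guideline
#' classification keys on the sub-indication. Records whose documentation
#' could not be assessed are removed from the denominator rather than
#' counted as errors. Per stratum and overall,
#' `agreement_pct + error_rate_pct == 100` exactly, and the overall
#' numerator and denominator are the sums over strata.
#'
#' @param reviews Chart-review tibble (see [read_chart_reviews()]).
#' @param taxonomy Taxonomy used to recognise documented RTI/UTI diagnoses
#'   in the `random_other` stratum (missed-target count).
#' @return A list of class `accuracy_report` with elements `strata` (per
#'   stratum: `n_screened`, `n_unassessable`, `n_errors`,
#'   `error_rate_pct`, `agreement_pct`), `overall` (same columns pooled),
#'   `confusion` (selected vs documented mismatch counts, descending) and
#'   `missed_target_count`.
#' @export
compute_accuracy <- function(reviews, taxonomy = default_indication_taxonomy()) {
  if (is.null(reviews) || nrow(reviews) == 0) {
    stop("no chart-review records supplied", call. = FALSE)
  }
  unassessable <- reviews$documented_indication == .unassessable
  err <- !unassessable &
    reviews$selected_indication != reviews$documented_indication

  per <- reviews |>
    dplyr::mutate(unassessable = unassessable, err = err) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_screened = dplyr::n(),
      n_unassessable = sum(.data$unassessable),
      n_errors = sum(.data$err),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      error_rate_pct = 100 * .data$n_errors /
        (.data$n_screened - .data$n_unassessable),
      agreement_pct = 100 - .data$error_rate_pct
    )

  overall <- tibble::tibble(
    n_screened = sum(per$n_screened),
    n_unassessable = sum(per$n_unassessable),
    n_errors = sum(per$n_errors)
  )
  overall$error_rate_pct <- 100 * overall$n_errors /
    (overall$n_screened - overall$n_unassessable)
  overall$agreement_pct <- 100 - overall$error_rate_pct

  confusion <- reviews[err, , drop = FALSE] |>
    dplyr::count(selected = .data$selected_indication,
                 documented = .data$documented_indication,
                 name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$selected, .data$documented)

  rti_uti_codes <- taxonomy$code[taxonomy$tract %in% c("RTI", "UTI")]
  missed <- sum(reviews$stratum == "random_other" &
                  reviews$documented_indication %in% rti_uti_codes)

  structure(list(strata = per, overall = overall, confusion = confusion,
                 missed_target_count = missed,
                 sampling_unit = "prescription record"),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> unit: ", x$sampling_unit, "\n", sep = "")
  print(x$strata)
  cat(sprintf("overall agreement %.1f%% (error rate %d/%d)\n",
              x$overall$agreement_pct, x$overall$n_errors,
              x$overall$n_screened - x$overall$n_unassessable))
  if (x$missed_target_count > 0) {
    cat("missed RTI/UTI prescriptions in the random stratum: ",
        x$missed_target_count, "\n", sep = "")
  }
  invisible(x)
}

#' Exact binomial confidence interval for an error rate
#'
#' Clopper-Pearson two-sided interval, for monitoring the registration
#' error rate over repeated (e.g. yearly) validation rounds.
#'
#' @param n_errors Number of errors observed (vectorised).
#' @param n_screened Number of assessable screened records.
#' @param level Confidence level, default 0.95.
#' @return Tibble with columns `n_errors`, `n_screened`, `estimate`,
#'   `lower`, `upper`, `level`.
#' @export
estimate_error_ci <- function(n_errors, n_screened, level = 0.95) {
  if (any(n_screened <= 0) || any(n_errors < 0) ||
      any(n_errors > n_screened)) {
    stop("need 0 <= n_errors <= n_screened and n_screened > 0",
         call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lower <- ifelse(n_errors == 0, 0,
                  stats::qbeta(alpha / 2, n_errors, n_screened - n_errors + 1))
  upper <- ifelse(n_errors == n_screened, 1,
                  stats::qbeta(1 - alpha / 2, n_errors + 1,
                               n_screened - n_errors))
  tibble::tibble(n_errors = n_errors, n_screened = n_screened,
                 estimate = n_errors / n_screened,
                 lower = lower, upper = upper, level = level)
}
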