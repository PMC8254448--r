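#' Selection parameters
#'
#' Bundles the tunable inclusion/exclusion thresholds of the audit. The
#' defaults are the study conditions of the underlying audit design: adult
#' patients (18+), hospitalised for at least 12 hours on a general ward,
#' empiric therapy read off at the 24-hour snapshot, readmissions within 30
#' days excluded, and prophylaxis-registered prescriptions removed before
#' snapshotting. Targeted-registered prescriptions are kept by default
#' because the empiric definition is time-based, not registration-based;
#' add `"targeted"` to `exclude_indication_classes` to drop them.
#'
#' @param min_age_years Minimum age at admission (inclusive). Default 18.
#' @param min_stay_hours Minimum length of stay in hours for a patient to
#'   count as hospitalised. Default 12.
#' @param snapshot_hours Hours after admission at which the active regimen
#'   is read off as the empiric therapy. Default 24. Stays between
#'   `min_stay_hours` and `snapshot_hours` use the last prescribed therapy
#'   before discharge instead.
#' @param readmission_window_days An admission starting within this many
#'   days after a previous discharge of the same patient is excluded as a
#'   readmission. Default 30.
#' @param indication_exclusion_windows Optional data frame with columns
#'   `tract`, `window_start` and (optionally) `window_end`: prescriptions
#'   for that tract started inside `[window_start, window_end)` are
#'   excluded. The motivating use is dropping respiratory prescriptions
#'   after the start of the COVID-19 pandemic, when no empiric guideline
#'   existed, e.g. `data.frame(tract = "RTI", window_start = "2020-03-01")`
#'   (a missing `window_end` leaves the window open-ended).
#' @param exclude_indication_classes Registered indication classes removed
#'   before the snapshot. Default `"prophylaxis"`.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(min_age_years = 18,
                             min_stay_hours = 12,
                             snapshot_hours = 24,
                             readmission_window_days = 30,
                             indication_exclusion_windows = NULL,
                             exclude_indication_classes = "prophylaxis") {
  stopifnot(min_age_years >= 0, min_stay_hours > 0, snapshot_hours > 0,
            readmission_window_days >= 0)
  if (min_stay_hours > snapshot_hours) {
    stop("min_stay_hours must not exceed snapshot_hours", call. = FALSE)
  }
  bad_class <- setdiff(exclude_indication_classes, .indication_class_levels)
  if (length(bad_class) > 0) {
    stop("unknown indication class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  win <- indication_exclusion_windows
  if (!is.null(win)) {
    if (!all(c("tract", "window_start") %in% names(win))) {
      stop("indication_exclusion_windows needs columns tract, window_start",
           call. = FALSE)
    }
    win <- tibble::as_tibble(win)
    if (!"window_end" %in% names(win)) win$window_end <- NA_character_
    win$window_start <- .parse_ts(win$window_start)
    win$window_end <- .parse_ts(win$window_end)
    if (anyNA(win$window_start)) {
      stop("unparseable window_start in indication_exclusion_windows",
           call. = FALSE)
    }
    if (any(!is.na(win$window_end) & win$window_end <= win$window_start)) {
      stop("window_end must be after window_start", call. = FALSE)
    }
    if (any(!win$tract %in% .tract_levels)) {
      stop("unknown tract in indication_exclusion_windows", call. = FALSE)
    }
  }
  structure(
    list(min_age_years = min_age_years,
         min_stay_hours = min_stay_hours,
         snapshot_hours = snapshot_hours,
         readmission_window_days = readmission_window_days,
         indication_exclusion_windows = win,
         exclude_indication_classes = exclude_indication_classes),
    class = "selection_params"
  )
}

.stay_hours <- function(admissions) {
  as.numeric(difftime(admissions$discharge_ts, admissions$admit_ts,
                      units = "hours"))
}

#' Flag readmissions
#'
#' An admission is flagged as a readmission when the same patient has a
#' prior admission whose discharge falls less than `window_days` days
#' before the new admission. A patient's first admission is never flagged;
#' only the later admission of a qualifying pair is, since it is the
#' readmission for which guideline-recommended empiric treatment is
#' usually not applicable. Overlapping admissions of one patient trigger a
#' warning and are resolved on discharge order.
#'
#' @param admissions Admissions tibble (see [read_admissions()]).
#' @param window_days Readmission window in days (default 30).
#' @return `admissions` with a logical `readmission` column appended.
#' @export
flag_readmissions <- function(admissions, window_days = 30) {
  n <- nrow(admissions)
  flag <- logical(n)
  multi <- split(seq_len(n), admissions$patient_id)
  overlap <- FALSE
  for (idx in multi) {
    if (length(idx) < 2) next
    a <- admissions$admit_ts[idx]
    d <- admissions$discharge_ts[idx]
    ord <- order(a, d)
    if (any(utils::head(d[ord], -1) > utils::tail(a[ord], -1))) overlap <- TRUE
    for (k in seq_along(idx)) {
      gap_days <- as.numeric(difftime(a[k], d, units = "days"))
      prior <- d <= a[k] & gap_days < window_days
      prior[k] <- FALSE
      if (any(prior)) flag[idx[k]] <- TRUE
    }
  }
  if (overlap) {
    warning("overlapping admissions for at least one patient; ",
            "readmission flags computed on discharge order", call. = FALSE)
  }
  admissions$readmission <- flag
  admissions
}

# First failing admission-level rule, in the fixed attribution order
# age -> ward -> stay -> readmission; NA when eligible.
.first_failing_rule <- function(admissions, params) {
  stay <- .stay_hours(admissions)
  dplyr::case_when(
    admissions$age_years < params$min_age_years ~ "age",
    admissions$ward_type != "general" ~ "ward",
    stay < params$min_stay_hours ~ "stay",
    admissions$readmission ~ "readmission",
    TRUE ~ NA_character_
  )
}

#' Select eligible admissions
#'
#' Applies the admission-level inclusion rules (adult, general ward, stay
#' of at least `min_stay_hours`, not a readmission) in a fixed attribution
#' order -- age, ward, stay, readmission -- so that each excluded admission
#' is counted exactly once, under the first rule it fails. This makes
#' flowcharts reproducible across runs and hospitals.
#'
#' @param admissions Admissions tibble with the `readmission` flag (see
#'   [flag_readmissions()]).
#' @param params A [selection_params()] object.
#' @return A list with `admissions` (the kept rows) and `flowchart` (a
#'   tibble with columns `stage`, `input`, `kept`, `excluded`).
#' @export
select_eligible_admissions <- function(admissions, params = selection_params()) {
  if (!"readmission" %in% names(admissions)) {
    stop("admissions lack the readmission flag; run flag_readmissions() first",
         call. = FALSE)
  }
  fail <- .first_failing_rule(admissions, params)
  stages <- c("age", "ward", "stay", "readmission")
  rows <- vector("list", length(stages))
  cur <- admissions
  cur_fail <- fail
  for (i in seq_along(stages)) {
    drop <- !is.na(cur_fail) & cur_fail == stages[i]
    rows[[i]] <- tibble::tibble(
      stage = stages[i], input = nrow(cur),
      kept = sum(!drop), excluded = sum(drop))
    cur <- cur[!drop, , drop = FALSE]
    cur_fail <- cur_fail[!drop]
  }
  list(admissions = cur, flowchart = dplyr::bind_rows(rows))
}

# Vectorised snapshot rule over a record tibble. Returns a logical keep
# vector plus per-record evaluation timestamp. Assumes every record's
# admission is present in `admissions` and has stay >= min_stay_hours.
.snapshot_keep <- function(records, admissions, params) {
  i <- match(records$admission_id, admissions$admission_id)
  admit <- admissions$admit_ts[i]
  discharge <- admissions$discharge_ts[i]
  stay <- as.numeric(difftime(discharge, admit, units = "hours"))
  long <- stay >= params$snapshot_hours

  t_snap <- admit + params$snapshot_hours * 3600
  eval_ts <- t_snap
  eval_ts[!long] <- discharge[!long]

  keep <- logical(nrow(records))
  # >= snapshot_hours branch: half-open interval containment start <= t < stop;
  # an absent stop means the prescription ran through discharge and counts
  # as active at the snapshot.
  keep[long] <- records$start_ts[long] <= t_snap[long] &
    (is.na(records$stop_ts[long]) | t_snap[long] < records$stop_ts[long])

  # 12-24 h branch: the last prescribed therapy before discharge; ties at
  # the maximal start time all kept (they form a combination).
  if (any(!long)) {
    idx <- which(!long)
    cand <- records$start_ts[idx] <= discharge[idx]
    started <- records$start_ts[idx]
    started[!cand] <- as.POSIXct(NA)
    grp_max <- stats::ave(as.numeric(started), records$admission_id[idx],
                          FUN = function(x) {
                            if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
                          })
    keep[idx] <- !is.na(started) & as.numeric(started) == grp_max
  }
  list(keep = keep, evaluation_ts = eval_ts, stay = stay)
}

#' Derive the empiric regimen of one admission (24-hour snapshot rule)
#'
#' For stays of at least `snapshot_hours`, the empiric therapy is the set
#' of prescriptions active at `admit_ts + snapshot_hours`, with the
#' half-open activity convention `start_ts <= t < stop_ts` (an absent
#' `stop_ts` means active through discharge). For stays between
#' `min_stay_hours` and `snapshot_hours` it is the last prescribed therapy
#' before discharge: the record(s) with the latest `start_ts`, ties all
#' kept. The selection may be empty (no antibiotic active at the
#' snapshot).
#'
#' Prescriptions whose registered class is excluded by
#' `params$exclude_indication_classes` (prophylaxis by default) must be
#' removed before calling; [run_selection()] does this for you.
#'
#' @param records Prescription records of this admission.
#' @param admission One-row admissions tibble.
#' @param params A [selection_params()] object.
#' @return A list of class `empiric_selection` with fields `admission_id`,
#'   `evaluation_ts`, `records` and `tracts_present`.
#' @export
snapshot_empiric <- function(records, admission, params = selection_params()) {
  stopifnot(nrow(admission) == 1)
  if (nrow(records) > 0 && any(records$admission_id != admission$admission_id)) {
    stop("records do not all belong to the given admission", call. = FALSE)
  }
  stay <- .stay_hours(admission)
  if (stay < params$min_stay_hours) {
    stop("admission ", admission$admission_id, " stayed ", round(stay, 1),
         " h (< min_stay_hours); it should have been excluded", call. = FALSE)
  }
  if (nrow(records) == 0) {
    eval_ts <- if (stay >= params$snapshot_hours) {
      admission$admit_ts + params$snapshot_hours * 3600
    } else {
      admission$discharge_ts
    }
    return(structure(list(admission_id = admission$admission_id,
                          evaluation_ts = eval_ts,
                          records = records,
                          tracts_present = character()),
                     class = "empiric_selection"))
  }
  snap <- .snapshot_keep(records, admission, params)
  kept <- records[snap$keep, , drop = FALSE]
  structure(list(admission_id = admission$admission_id,
                 evaluation_ts = snap$evaluation_ts[1],
                 records = kept,
                 tracts_present = sort(unique(kept$focus_tract))),
            class = "empiric_selection")
}

# Window-match helper: TRUE for records whose focus tract matches a window
# and whose start falls inside [window_start, window_end).
.in_exclusion_window <- function(records, windows) {
  if (is.null(windows) || nrow(records) == 0) return(logical(nrow(records)))
  hit <- logical(nrow(records))
  for (w in seq_len(nrow(windows))) {
    m <- records$focus_tract == windows$tract[w] &
      records$start_ts >= windows$window_start[w] &
      (is.na(windows$window_end[w]) | records$start_ts < windows$window_end[w])
    hit <- hit | m
  }
  hit
}

#' Apply prescription-level exclusions to an empiric selection
#'
#' Removes, in a fixed order: (1) erroneous prescriptions, whose start
#' precedes the admission timestamp (a registration artefact); (2) all
#' RTI/UTI prescriptions of admissions whose snapshot contains both an RTI
#' and a UTI prescription, since such prescriptions cannot be attributed
#' to either group; (3) prescriptions started inside a configured
#' indication exclusion window. Each removal is counted once, under the
#' first applicable rule.
#'
#' @param selection An `empiric_selection` from [snapshot_empiric()].
#' @param admission One-row admissions tibble for the same admission.
#' @param params A [selection_params()] object.
#' @return A list with `records` (kept rows) and `flowchart` (stages
#'   `erroneous`, `dual_tract`, `indication_window`).
#' @export
apply_prescription_exclusions <- function(selection, admission,
                                          params = selection_params()) {
  stopifnot(inherits(selection, "empiric_selection"), nrow(admission) == 1)
  cur <- selection$records
  rows <- vector("list", 3)

  err <- if (nrow(cur) > 0) cur$start_ts < admission$admit_ts else logical(0)
  rows[[1]] <- tibble::tibble(stage = "erroneous", input = nrow(cur),
                              kept = sum(!err), excluded = sum(err))
  cur <- cur[!err, , drop = FALSE]

  dual <- all(c("RTI", "UTI") %in% selection$tracts_present)
  drop <- if (nrow(cur) > 0 && dual) cur$focus_tract %in% c("RTI", "UTI") else logical(nrow(cur))
  rows[[2]] <- tibble::tibble(stage = "dual_tract", input = nrow(cur),
                              kept = sum(!drop), excluded = sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  win <- .in_exclusion_window(cur, params$indication_exclusion_windows)
  rows[[3]] <- tibble::tibble(stage = "indication_window", input = nrow(cur),
                              kept = sum(!win), excluded = sum(win))
  cur <- cur[!win, , drop = FALSE]

  list(records = cur, flowchart = dplyr::bind_rows(rows))
}

#' Run the full cohort selection
#'
#' Composes the whole selection pipeline and emits a conservation-checked
#' flowchart: unlinked records, admission eligibility (age, ward, stay,
#' readmission), removal of excluded registration classes (prophylaxis by
#' default), the 24-hour empiric snapshot, restriction to RTI/UTI, and the
#' prescription-level exclusions (erroneous starts, dual-tract admissions,
#' indication exclusion windows). At every stage `input = kept + excluded`
#' and consecutive stages telescope.
#'
#' @param records Prescription records tibble.
#' @param admissions Admissions tibble.
#' @param params A [selection_params()] object.
#' @return A list of class `selection_result` with `records` (the empiric
#'   RTI/UTI prescriptions), `flowchart`, and `selections` (one row per
#'   eligible admission with its `evaluation_ts`).
#' @export
run_selection <- function(records, admissions, params = selection_params()) {
  admissions <- flag_readmissions(admissions, params$readmission_window_days)
  fail <- .first_failing_rule(admissions, params)
  fail_of <- fail[match(records$admission_id, admissions$admission_id)]

  stages <- list()
  cur <- records

  drop <- !cur$admission_id %in% admissions$admission_id
  stages$unlinked <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]
  fail_of <- fail_of[!drop]

  for (rule in c("age", "ward", "stay", "readmission")) {
    drop <- !is.na(fail_of) & fail_of == rule
    stages[[rule]] <- c(nrow(cur), sum(drop))
    cur <- cur[!drop, , drop = FALSE]
    fail_of <- fail_of[!drop]
  }

  drop <- cur$indication_class %in% params$exclude_indication_classes
  stages$indication_class <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  # eligible admissions only from here on
  eligible <- admissions[is.na(fail), , drop = FALSE]
  if (nrow(cur) > 0) {
    snap <- .snapshot_keep(cur, eligible, params)
    keep <- snap$keep
  } else {
    keep <- logical(0)
    snap <- list(evaluation_ts = as.POSIXct(character(), tz = "UTC"))
  }
  stages$snapshot <- c(nrow(cur), sum(!keep))

  # tract sets at snapshot time drive the dual-tract rule below
  snapped <- cur[keep, , drop = FALSE]
  dual_adm <- if (nrow(snapped) > 0) {
    tr <- unique(snapped[snapped$focus_tract %in% c("RTI", "UTI"),
                         c("admission_id", "focus_tract")])
    both <- table(tr$admission_id)
    names(both)[both == 2L]
  } else character()
  cur <- snapped

  drop <- !cur$focus_tract %in% c("RTI", "UTI")
  stages$tract <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  admit_of <- eligible$admit_ts[match(cur$admission_id, eligible$admission_id)]
  drop <- cur$start_ts < admit_of
  stages$erroneous <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  drop <- cur$admission_id %in% dual_adm
  stages$dual_tract <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  drop <- .in_exclusion_window(cur, params$indication_exclusion_windows)
  stages$indication_window <- c(nrow(cur), sum(drop))
  cur <- cur[!drop, , drop = FALSE]

  flowchart <- tibble::tibble(
    stage = names(stages),
    input = unname(vapply(stages, `[`, numeric(1), 1)),
    excluded = unname(vapply(stages, `[`, numeric(1), 2))
  )
  flowchart$kept <- flowchart$input - flowchart$excluded
  flowchart <- flowchart[, c("stage", "input", "kept", "excluded")]

  stay <- .stay_hours(eligible)
  eval_ts <- eligible$admit_ts + params$snapshot_hours * 3600
  short <- stay < params$snapshot_hours
  eval_ts[short] <- eligible$discharge_ts[short]
  selections <- tibble::tibble(admission_id = eligible$admission_id,
                               evaluation_ts = eval_ts)

  structure(list(records = cur, flowchart = flowchart,
                 selections = selections),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", nrow(x$records),
      " empiric RTI/UTI prescription(s) kept\n", sep = "")
  print(x$flowchart)
  invisible(x)
}
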