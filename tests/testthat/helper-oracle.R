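# Independent brute-force re-derivation of the empiric selection: explicit
# per-admission loops and interval tests, no shared code with
# run_selection(). Returns the sorted record ids of the final empiric
# RTI/UTI set.
brute_force_selection <- function(records, admissions,
                                  params = selection_params()) {
  n_adm <- nrow(admissions)
  readmit <- logical(n_adm)
  for (i in seq_len(n_adm)) {
    for (j in seq_len(n_adm)) {
      if (i == j) next
      if (admissions$patient_id[j] != admissions$patient_id[i]) next
      d <- admissions$discharge_ts[j]
      a <- admissions$admit_ts[i]
      if (d <= a &&
          as.numeric(difftime(a, d, units = "days")) <
            params$readmission_window_days) {
        readmit[i] <- TRUE
      }
    }
  }

  kept <- character()
  for (i in seq_len(n_adm)) {
    adm <- admissions[i, ]
    stay_h <- as.numeric(difftime(adm$discharge_ts, adm$admit_ts,
                                  units = "hours"))
    if (adm$age_years < params$min_age_years) next
    if (adm$ward_type != "general") next
    if (stay_h < params$min_stay_hours) next
    if (readmit[i]) next

    rx <- records[records$admission_id == adm$admission_id, , drop = FALSE]
    rx <- rx[!rx$indication_class %in% params$exclude_indication_classes, ,
             drop = FALSE]
    if (nrow(rx) == 0) next

    sel <- logical(nrow(rx))
    if (stay_h >= params$snapshot_hours) {
      t <- adm$admit_ts + params$snapshot_hours * 3600
      for (k in seq_len(nrow(rx))) {
        sel[k] <- rx$start_ts[k] <= t &&
          (is.na(rx$stop_ts[k]) || t < rx$stop_ts[k])
      }
    } else {
      cand <- rx$start_ts <= adm$discharge_ts
      if (any(cand)) {
        mx <- max(rx$start_ts[cand])
        sel <- cand & rx$start_ts == mx
      }
    }
    snap <- rx[sel, , drop = FALSE]
    tracts <- unique(snap$focus_tract)
    out <- snap[snap$focus_tract %in% c("RTI", "UTI"), , drop = FALSE]
    out <- out[out$start_ts >= adm$admit_ts, , drop = FALSE]
    if (all(c("RTI", "UTI") %in% tracts)) out <- out[0, , drop = FALSE]
    w <- params$indication_exclusion_windows
    if (!is.null(w) && nrow(out) > 0) {
      drop <- rep(FALSE, nrow(out))
      for (k in seq_len(nrow(out))) {
        for (q in seq_len(nrow(w))) {
          if (out$focus_tract[k] == w$tract[q] &&
              out$start_ts[k] >= w$window_start[q] &&
              (is.na(w$window_end[q]) ||
                 out$start_ts[k] < w$window_end[q])) {
            drop[k] <- TRUE
          }
        }
      }
      out <- out[!drop, , drop = FALSE]
    }
    kept <- c(kept, out$record_id)
  }
  sort(kept)
}

# Messy random instances that stress boundary semantics: stays across the
# 12 h / 24 h thresholds, starts before admission, absent stops, ties at
# the latest start, multiple tracts, readmissions and orphan-free linkage.
random_instance <- function(n_adm = sample(1:50, 1)) {
  n_pat <- max(1, ceiling(n_adm * 0.7))
  base <- ts("2020-01-01 00:00:00")
  admissions <- tibble::tibble(
    patient_id = sprintf("P%03d", sample.int(n_pat, n_adm, replace = TRUE)),
    admission_id = sprintf("A%03d", seq_len(n_adm)),
    admit_ts = base + round(stats::runif(n_adm, 0, 60 * 86400) / 60) * 60,
    age_years = sample(15:90, n_adm, replace = TRUE),
    ward_type = sample(c("general", "icu", "other"), n_adm, replace = TRUE,
                       prob = c(0.8, 0.1, 0.1)))
  los_h <- stats::runif(n_adm, 1, 200)
  exact <- stats::runif(n_adm) < 0.1
  los_h[exact] <- sample(c(12, 24), sum(exact), replace = TRUE)
  admissions$discharge_ts <- admissions$admit_ts + round(los_h * 3600)

  tax <- default_indication_taxonomy()
  n_rx <- stats::rpois(n_adm, 1.6)
  rows <- list()
  rid <- 0
  for (i in seq_len(n_adm)) {
    if (n_rx[i] == 0) next
    for (k in seq_len(n_rx[i])) {
      rid <- rid + 1
      tract <- sample(c("RTI", "UTI", "other"), 1, prob = c(0.4, 0.3, 0.3))
      sub <- if (tract == "other") NA_character_ else
        sample(tax$code[tax$tract == tract], 1)
      start <- admissions$admit_ts[i] +
        round(stats::runif(1, -30, 80) * 3600 / 60) * 60
      if (stats::runif(1) < 0.25) start <- admissions$admit_ts[i] + 5 * 3600
      if (stats::runif(1) < 0.05) start <- admissions$admit_ts[i] + 24 * 3600
      stopt <- if (stats::runif(1) < 0.15) {
        ts(NA_character_)
      } else {
        start + round(stats::runif(1, 1, 100) * 3600 / 60) * 60
      }
      rows[[rid]] <- make_rx(
        record_id = sprintf("R%04d", rid),
        admission_id = admissions$admission_id[i],
        patient_id = admissions$patient_id[i],
        start = format(start, tz = "UTC"), stop = NA,
        atc_code = sample(c("J01CA04", "J01DD04", "J01DC02", "J01XE01"), 1),
        route = sample(c("iv", "oral"), 1),
        indication_class = sample(c("empiric", "targeted", "prophylaxis"), 1,
                                  prob = c(0.7, 0.15, 0.15)),
        focus_tract = tract, sub_indication = sub)
      rows[[rid]]$stop_ts <- stopt
    }
  }
  records <- if (rid == 0) empty_rx() else dplyr::bind_rows(rows)
  list(records = records, admissions = admissions)
}
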