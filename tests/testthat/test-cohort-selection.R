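test_that("readmissions within the window are flagged, later admission only", {
  adm <- dplyr::bind_rows(
    make_adm("A1", "2018-12-20 10:00:00", "2019-01-01 10:00:00",
             patient_id = "P1"),
    make_adm("A2", "2019-01-20 09:00:00", "2019-01-25 09:00:00",
             patient_id = "P1"),              # 19 days after discharge
    make_adm("B1", "2018-12-25 10:00:00", "2019-01-01 10:00:00",
             patient_id = "P2"),
    make_adm("B2", "2019-03-15 10:00:00", "2019-03-20 10:00:00",
             patient_id = "P2"),              # 73 days after discharge
    make_adm("C1", "2019-05-01 10:00:00", "2019-05-04 10:00:00",
             patient_id = "P3"))
  got <- flag_readmissions(adm, 30)
  expect_equal(got$readmission,
               c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("a gap of exactly the window length is not a readmission", {
  adm <- dplyr::bind_rows(
    make_adm("A1", "2019-01-01 10:00:00", "2019-01-05 10:00:00",
             patient_id = "P1"),
    make_adm("A2", "2019-02-04 10:00:00", "2019-02-10 10:00:00",
             patient_id = "P1"))              # exactly 30 days
  expect_equal(flag_readmissions(adm, 30)$readmission, c(FALSE, FALSE))
})

test_that("overlapping admissions warn and flags are still computed", {
  adm <- dplyr::bind_rows(
    make_adm("A1", "2019-01-01 10:00:00", "2019-01-10 10:00:00",
             patient_id = "P1"),
    make_adm("A2", "2019-01-05 10:00:00", "2019-01-20 10:00:00",
             patient_id = "P1"))
  expect_warning(got <- flag_readmissions(adm, 30), "overlapping")
  expect_type(got$readmission, "logical")
})

test_that("eligibility exclusions attribute to the first failing rule in order", {
  adm <- dplyr::bind_rows(
    make_adm("A1", "2019-01-01 00:00:00", "2019-01-03 00:00:00",
             age_years = 17L),                           # age
    make_adm("A2", "2019-01-01 00:00:00", "2019-01-03 00:00:00",
             age_years = 17L, ward_type = "icu"),        # still age first
    make_adm("A3", "2019-01-01 00:00:00", "2019-01-03 00:00:00",
             ward_type = "icu"),                         # ward
    make_adm("A4", "2019-01-01 00:00:00", "2019-01-01 10:00:00"),  # 10 h stay
    make_adm("A5", "2019-01-01 00:00:00", "2019-01-04 00:00:00"))  # kept
  adm <- flag_readmissions(adm, 30)
  got <- select_eligible_admissions(adm, selection_params())
  expect_equal(got$admissions$admission_id, "A5")
  fc <- got$flowchart
  expect_equal(fc$excluded[fc$stage == "age"], 2)
  expect_equal(fc$excluded[fc$stage == "ward"], 1)
  expect_equal(fc$excluded[fc$stage == "stay"], 1)
  expect_equal(fc$input, fc$kept + fc$excluded)
  expect_equal(utils::head(fc$kept, -1), utils::tail(fc$input, -1))
})

test_that("the 24-hour snapshot keeps exactly the records covering admit + 24 h", {
  adm <- make_adm("A1", "2019-01-01 00:00:00", "2019-01-04 00:00:00")  # 72 h
  rx <- dplyr::bind_rows(
    make_rx("RA", "A1", "2019-01-01 02:00:00", "2019-01-03 00:00:00"),
    make_rx("RB", "A1", "2019-01-02 06:00:00", "2019-01-03 12:00:00"))
  sel <- snapshot_empiric(rx, adm, selection_params())
  expect_equal(sel$records$record_id, "RA")
  expect_equal(sel$evaluation_ts, ts("2019-01-02 00:00:00"))

  # half-open convention: a record stopping exactly at +24 h is not active
  rx2 <- make_rx("RC", "A1", "2019-01-01 02:00:00", "2019-01-02 00:00:00")
  expect_equal(nrow(snapshot_empiric(rx2, adm)$records), 0)
  # but one starting exactly at +24 h is
  rx3 <- make_rx("RD", "A1", "2019-01-02 00:00:00", NA)
  expect_equal(snapshot_empiric(rx3, adm)$records$record_id, "RD")
})

test_that("12-24 h stays use the last prescribed therapy, ties all kept", {
  adm <- make_adm("A1", "2019-01-01 00:00:00", "2019-01-01 18:00:00")  # 18 h
  rx <- dplyr::bind_rows(
    make_rx("RA", "A1", "2019-01-01 01:00:00", NA),
    make_rx("RB", "A1", "2019-01-01 10:00:00", NA),
    make_rx("RC", "A1", "2019-01-01 10:00:00", NA, atc_code = "J01MA02"))
  sel <- snapshot_empiric(rx, adm, selection_params())
  expect_setequal(sel$records$record_id, c("RB", "RC"))
  expect_equal(sel$evaluation_ts, adm$discharge_ts)
})

test_that("an admission with nothing active at the snapshot yields an empty selection", {
  adm <- make_adm("A1", "2019-01-01 00:00:00", "2019-01-04 00:00:00")
  rx <- make_rx("RA", "A1", "2019-01-03 00:00:00", NA)
  expect_equal(nrow(snapshot_empiric(rx, adm)$records), 0)
  expect_equal(nrow(snapshot_empiric(empty_rx(), adm)$records), 0)
})

test_that("sub-minimum stays are a contract violation for the snapshot", {
  adm <- make_adm("A1", "2019-01-01 00:00:00", "2019-01-01 08:00:00")
  expect_error(snapshot_empiric(empty_rx(), adm), "excluded")
})

test_that("prescription-level exclusions remove erroneous, dual-tract and windowed records in order", {
  params <- selection_params(
    indication_exclusion_windows = data.frame(tract = "RTI",
                                              window_start = "2020-03-01"))
  adm <- make_adm("A1", "2020-04-10 00:00:00", "2020-04-20 00:00:00")
  rx <- dplyr::bind_rows(
    make_rx("R-err", "A1", "2020-04-09 18:00:00", NA,
            focus_tract = "RTI", sub_indication = "HAP"),
    make_rx("R-win", "A1", "2020-04-10 06:00:00", NA,
            focus_tract = "RTI", sub_indication = "CAP"))
  sel <- snapshot_empiric(rx, adm, params)
  got <- apply_prescription_exclusions(sel, adm, params)
  fc <- got$flowchart
  expect_equal(fc$excluded[fc$stage == "erroneous"], 1)
  expect_equal(fc$excluded[fc$stage == "indication_window"], 1)
  expect_equal(nrow(got$records), 0)

  # an admission holding both RTI and UTI therapy loses both
  rx2 <- dplyr::bind_rows(
    make_rx("R-rti", "A1", "2020-04-10 02:00:00", NA,
            focus_tract = "RTI", sub_indication = "CAP"),
    make_rx("R-uti", "A1", "2020-04-10 03:00:00", NA,
            focus_tract = "UTI", sub_indication = "cystitis"))
  sel2 <- snapshot_empiric(rx2, adm, selection_params())
  got2 <- apply_prescription_exclusions(sel2, adm, selection_params())
  expect_equal(got2$flowchart$excluded[got2$flowchart$stage == "dual_tract"], 2)
  expect_equal(nrow(got2$records), 0)
})

test_that("an empty extract flows through with all-zero counts", {
  got <- run_selection(empty_rx(),
                       make_adm("A1", "2019-01-01 00:00:00",
                                "2019-01-04 00:00:00"))
  expect_equal(nrow(got$records), 0)
  expect_true(all(got$flowchart$input == 0 | got$flowchart$stage == "unlinked"))
  expect_true(all(got$flowchart$excluded == 0))
})

test_that("run_selection recovers planted per-rule contamination exactly", {
  co <- generate_cohort(sim_config(n_patients = 300, seed = 7))
  sel <- run_selection(co$prescriptions, co$admissions)
  fc <- sel$flowchart
  truth_counts <- table(co$truth$exclusion_reason)
  cnt <- function(x) unname(truth_counts[x]) |> (\(v) ifelse(is.na(v), 0, v))()
  expect_equal(fc$excluded[fc$stage == "age"], cnt("age"))
  expect_equal(fc$excluded[fc$stage == "ward"], cnt("ward"))
  expect_equal(fc$excluded[fc$stage == "stay"], cnt("stay"))
  expect_equal(fc$excluded[fc$stage == "readmission"], cnt("readmission"))
  expect_equal(fc$excluded[fc$stage == "indication_class"], cnt("prophylaxis"))
  expect_equal(fc$excluded[fc$stage == "tract"], cnt("other_tract"))
  expect_equal(fc$excluded[fc$stage == "erroneous"], cnt("erroneous"))
  expect_equal(fc$excluded[fc$stage == "dual_tract"], cnt("dual_tract"))
  expect_equal(nrow(sel$records), cnt("none"))
  expect_setequal(sel$records$record_id,
                  co$truth$record_id[co$truth$exclusion_reason == "none"])
})

test_that("run_selection agrees with the brute-force oracle on random instances", {
  withr::local_seed(2024)
  for (rep in 1:20) {
    inst <- random_instance()
    got <- suppressWarnings(run_selection(inst$records, inst$admissions))
    want <- suppressWarnings(
      brute_force_selection(inst$records, inst$admissions))
    expect_equal(sort(got$records$record_id), want)
    check_flowchart(got$flowchart)
  }
})

test_that("widening the readmission window never increases the kept set", {
  withr::local_seed(99)
  inst <- random_instance(40)
  kept <- vapply(c(0, 10, 30, 90), function(w) {
    p <- selection_params(readmission_window_days = w)
    nrow(suppressWarnings(run_selection(inst$records, inst$admissions, p))$records)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("selection is deterministic", {
  co <- generate_cohort(sim_config(n_patients = 100, seed = 5))
  a <- run_selection(co$prescriptions, co$admissions)
  b <- run_selection(co$prescriptions, co$admissions)
  expect_identical(a, b)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(selection_params(min_stay_hours = 48, snapshot_hours = 24),
               "must not exceed")
  expect_error(selection_params(exclude_indication_classes = "unknown"),
               "unknown")
  expect_error(
    selection_params(indication_exclusion_windows =
                       data.frame(tract = "RTI",
                                  window_start = "2020-03-01",
                                  window_end = "2020-02-01")),
    "after window_start")
})
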