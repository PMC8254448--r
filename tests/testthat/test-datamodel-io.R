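test_that("a valid extract reads completely and round-trips through the writer", {
  rx <- dplyr::bind_rows(
    make_rx("R1", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00"),
    make_rx("R2", "A1", "2019-02-01 09:30:00", NA, atc_code = "J01DD04",
            focus_tract = "UTI", sub_indication = "complicated-UTI"),
    make_rx("R3", "A2", "2019-03-10 22:00:00", "2019-03-12 10:00:00",
            indication_class = "targeted", focus_tract = "other",
            sub_indication = NA_character_))
  f <- withr::local_tempfile(fileext = ".csv")
  write_prescription_extract(rx, f)
  got <- read_prescription_extract(f)
  expect_equal(nrow(got$records), 3)
  expect_equal(nrow(got$rejects), 0)
  expect_equal(got$records$record_id, rx$record_id)
  expect_equal(got$records$start_ts, rx$start_ts)
  expect_equal(got$records$stop_ts, rx$stop_ts)
  expect_equal(got$records$sub_indication, rx$sub_indication)

  # semicolon-delimited variant is autodetected
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_prescription_extract(rx, f2, delim = ";")
  got2 <- read_prescription_extract(f2)
  expect_equal(got2$records, got$records)
})

test_that("column and value maps translate hospital-specific exports", {
  rx <- make_rx("R1", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00")
  f <- withr::local_tempfile(fileext = ".csv")
  raw <- rx
  raw$indication_class <- "profylaxe"
  names(raw)[names(raw) == "atc_code"] <- "ATC"
  readr::write_csv(raw, f, na = "")
  got <- read_prescription_extract(
    f, column_map = c(atc_code = "ATC"),
    value_map = list(indication_class = c(profylaxe = "prophylaxis")))
  expect_equal(got$records$indication_class, "prophylaxis")
  expect_equal(got$records$atc_code, "J01CA04")

  # round-trip of the translated record through writer and reader
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_prescription_extract(got$records, f2)
  again <- read_prescription_extract(f2)
  expect_equal(again$records, got$records)
})

test_that("unparseable rows are rejected with reasons, never dropped", {
  rx <- dplyr::bind_rows(
    make_rx("R1", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00"),
    make_rx("R2", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00"),
    make_rx("R3", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00"),
    make_rx("R4", "A1", "2019-02-01 08:00:00", "2019-02-05 08:00:00"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_prescription_extract(rx, f)
  lines <- readLines(f)
  lines[2] <- sub("2019-02-01T08:00:00", "not-a-date", lines[2])
  lines[3] <- sub(",iv,", ",intrathecal,", lines[3])
  lines[4] <- sub(",RTI,CAP", ",RTI,", lines[4])
  writeLines(lines, f)
  got <- read_prescription_extract(f)
  expect_equal(nrow(got$records) + nrow(got$rejects), 4)
  expect_equal(got$records$record_id, "R4")
  expect_equal(got$rejects$reason[got$rejects$record_id == "R1"], "timestamp")
  expect_equal(got$rejects$reason[got$rejects$record_id == "R2"], "route")
  expect_equal(got$rejects$reason[got$rejects$record_id == "R3"],
               "sub_indication")
})

test_that("missing mandatory columns raise a schema error naming them", {
  rx <- make_rx("R1", "A1", "2019-02-01 08:00:00", NA)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rx[, setdiff(names(rx), "atc_code")], f, na = "")
  expect_error(read_prescription_extract(f), "atc_code")
})

test_that("admissions reader enforces its invariants", {
  adm <- make_adm("A1", "2019-02-01 00:00:00", "2019-02-05 00:00:00")
  f <- withr::local_tempfile(fileext = ".csv")
  write_admissions(adm, f)
  got <- read_admissions(f)
  expect_equal(got$admit_ts, adm$admit_ts)
  expect_equal(got$age_years, 40L)

  bad <- adm
  bad$discharge_ts <- ts("2019-01-31 00:00:00")
  write_admissions(bad, f)
  expect_error(read_admissions(f), "discharge before admission")

  bad2 <- adm
  bad2$ward_type <- "day-clinic"
  write_admissions(bad2, f)
  expect_error(read_admissions(f), "ward_type")
})

test_that("extract validation flags orphans, inverted intervals, early starts and non-J01 codes", {
  adm <- make_adm("A1", "2019-02-01 12:00:00", "2019-02-10 12:00:00")
  rx <- dplyr::bind_rows(
    make_rx("R1", "A1", "2019-02-01 06:00:00", "2019-02-05 08:00:00"),
    make_rx("R2", "A1", "2019-02-03 08:00:00", "2019-02-02 08:00:00"),
    make_rx("R3", "A9", "2019-02-02 08:00:00", NA),
    make_rx("R4", "A1", "2019-02-02 08:00:00", NA, atc_code = "N02BE01"))
  iss <- validate_extract(rx, adm)
  expect_equal(iss$issue[iss$record_id == "R1"], "start_before_admission")
  expect_equal(iss$issue[iss$record_id == "R2"], "stop_before_start")
  expect_equal(iss$issue[iss$record_id == "R3"], "orphan_admission")
  expect_equal(iss$issue[iss$record_id == "R4"], "non_J01")

  clean <- make_rx("R5", "A1", "2019-02-02 08:00:00", "2019-02-04 08:00:00")
  expect_equal(nrow(validate_extract(clean, adm)), 0)
})

test_that("chart-review reader enforces stratum consistency", {
  rev <- tibble::tibble(
    record_id = c("R1", "R2"),
    stratum = c("RTI", "random_other"),
    selected_indication = c("CAP", "non_RTI_UTI"),
    documented_indication = c("CAP", "non_RTI_UTI"))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rev, f)
  expect_equal(nrow(read_chart_reviews(f)), 2)

  rev$selected_indication[2] <- "cystitis"
  readr::write_csv(rev, f)
  expect_error(read_chart_reviews(f), "inconsistent")
})

test_that("guideline table reads, validates and round-trips", {
  gl <- synthetic_guideline()
  expect_false(gl[["other-RTI"]]$assessable)
  expect_false(gl[["other-UTI"]]$assessable)
  expect_true(gl[["CAP"]]$assessable)
  expect_true(length(gl[["CAP-s"]]$first_choice[[1]]) == 2)

  f <- withr::local_tempfile(fileext = ".yaml")
  write_guideline_table(gl, f)
  expect_equal(read_guideline_table(f), gl)
})

test_that("guideline configuration errors are caught at load", {
  expect_error(
    as_guideline_table(list(
      CAP = list(assessable = TRUE,
                 first_choice = list("J01CA04"),
                 second_choice = list("J01CA04")))),
    "both first and second")
  expect_error(
    as_guideline_table(list(
      `made-up-code` = list(assessable = TRUE,
                            first_choice = list("J01CA04")))),
    "made-up-code")
  expect_error(
    as_guideline_table(list(
      CAP = list(assessable = TRUE, first_choice = list()))),
    "no first-choice")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_error(read_guideline_table(f), "empty")
})
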