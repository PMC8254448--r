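# Builders for small in-memory fixtures; all tests generate their data in
# code so suites are self-contained.

ts <- function(x) as.POSIXct(x, tz = "UTC")

empty_rx <- function() {
  tibble::tibble(
    record_id = character(), patient_id = character(),
    admission_id = character(), atc_code = character(),
    agent_name = character(),
    start_ts = ts(character()), stop_ts = ts(character()),
    route = character(), dose_text = character(),
    prescriber_specialty = character(), ward = character(),
    indication_class = character(), focus_tract = character(),
    sub_indication = character())
}

make_rx <- function(record_id, admission_id, start, stop = NA,
                    patient_id = paste0("P-", admission_id),
                    atc_code = "J01CA04", route = "iv",
                    indication_class = "empiric", focus_tract = "RTI",
                    sub_indication = if (focus_tract %in% c("RTI", "UTI")) {
                      if (focus_tract == "RTI") "CAP" else "cystitis"
                    } else NA_character_) {
  tibble::tibble(
    record_id = record_id, patient_id = patient_id,
    admission_id = admission_id, atc_code = atc_code,
    agent_name = NA_character_,
    start_ts = ts(start),
    stop_ts = if (length(stop) == 1 && is.na(stop)) ts(NA_character_) else ts(stop),
    route = route, dose_text = NA_character_,
    prescriber_specialty = NA_character_, ward = NA_character_,
    indication_class = indication_class, focus_tract = focus_tract,
    sub_indication = sub_indication)
}

make_adm <- function(admission_id, admit, discharge,
                     patient_id = paste0("P-", admission_id),
                     age_years = 40L, ward_type = "general") {
  tibble::tibble(patient_id = patient_id, admission_id = admission_id,
                 admit_ts = ts(admit), discharge_ts = ts(discharge),
                 age_years = as.integer(age_years), ward_type = ward_type)
}

# Chart-review stratum builder: k mismatches (sel vs doc), u unassessable,
# remainder agreeing on `agree_code`.
make_review_stratum <- function(stratum, n, k, sel, doc, u = 0,
                                agree_code = "CAP", prefix = stratum) {
  sel <- rep_len(sel, k)
  doc <- rep_len(doc, k)
  agree <- if (stratum == "random_other") "non_RTI_UTI" else agree_code
  selected <- c(sel, rep(agree, n - k - u), rep(agree, u))
  documented <- c(doc, rep(agree, n - k - u), rep("unassessable", u))
  tibble::tibble(
    record_id = sprintf("%s-%03d", prefix, seq_len(n)),
    stratum = stratum,
    selected_indication = selected,
    documented_indication = documented)
}

# Reconstructions of the published verification tallies (selected vs
# documented indication per stratum) used as worked arithmetic examples.
hospital_A_reviews <- function() {
  dplyr::bind_rows(
    make_review_stratum("RTI", 100, 4,
                        sel = c("CAP-m", "CAP-m", "CAP-m", "CAP"),
                        doc = c("COPD-exacerbation", "COPD-exacerbation",
                                "COPD-exacerbation", "bronchitis"),
                        agree_code = "CAP", prefix = "A-RTI"),
    make_review_stratum("UTI", 100, 6,
                        sel = c(rep("cystitis", 5), "chronic-prostatitis"),
                        doc = c(rep("complicated-UTI", 6)),
                        agree_code = "complicated-UTI", prefix = "A-UTI"),
    make_review_stratum("random_other", 100, 0, sel = character(),
                        doc = character(), prefix = "A-RND"))
}

hospital_B_reviews <- function() {
  dplyr::bind_rows(
    make_review_stratum("RTI", 70, 7,
                        sel = c("CAP", "CAP", "CAP", "CAP", "CAP-s",
                                "bronchitis", "bronchitis"),
                        doc = c("other-RTI", "other-RTI", "other-RTI",
                                "other-RTI", "CAP-m", "COPD-exacerbation",
                                "CAP"),
                        agree_code = "CAP", prefix = "B-RTI"),
    make_review_stratum("UTI", 73, 39,
                        sel = c(rep("cystitis", 37), "other-UTI",
                                "chronic-prostatitis"),
                        doc = c(rep("complicated-UTI", 39)),
                        agree_code = "complicated-UTI", prefix = "B-UTI"),
    make_review_stratum("random_other", 100, 7,
                        sel = rep("non_RTI_UTI", 7),
                        doc = c(rep("cystitis", 4), rep("CAP", 3)),
                        prefix = "B-RND"))
}

hospital_C_reviews <- function() {
  dplyr::bind_rows(
    make_review_stratum("RTI", 100, 17,
                        sel = c(rep("CAP-m", 7), rep("HAP", 3),
                                rep("CAP", 3), "CAP-s", "aspiration-pneumonia",
                                "CAP-m", "COPD-exacerbation"),
                        doc = c(rep("COPD-exacerbation", 7),
                                rep("other-RTI", 3),
                                rep("aspiration-pneumonia", 3), "CAP-m",
                                "CAP-s", "HAP", "CAP-m"),
                        u = 1, agree_code = "CAP", prefix = "C-RTI"),
    make_review_stratum("UTI", 100, 20,
                        sel = rep("cystitis", 20),
                        doc = rep("complicated-UTI", 20),
                        u = 1, agree_code = "complicated-UTI",
                        prefix = "C-UTI"),
    make_review_stratum("random_other", 100, 2,
                        sel = rep("non_RTI_UTI", 2),
                        doc = c("cystitis", "CAP"), prefix = "C-RND"))
}
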