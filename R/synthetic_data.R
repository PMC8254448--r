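#' @importFrom rlang %||%
NULL

#' Default mis-selection confusion structure
#'
#' Row-stochastic confusion over sub-indication codes: given that a
#' prescription's true (documented) sub-indication is the row code and a
#' mis-selection occurs, the registered code is drawn from the row. The
#' default places its dominant urinary mass on true complicated UTI
#' registered as cystitis -- the error pattern seen when prescribers pick
#' the milder diagnosis for urosepsis/pyelonephritis patients -- and
#' neighbour-confusions within the respiratory tract (CAP vs COPD
#' exacerbation vs bronchitis, severity-level swaps).
#'
#' @return Named list: code -> named probability vector over target codes
#'   (each row sums to 1; no self mass).
#' @export
default_confusion <- function() {
  list(
    "CAP" = c("COPD-exacerbation" = 0.4, "bronchitis" = 0.3,
              "aspiration-pneumonia" = 0.3),
    "CAP-m" = c("COPD-exacerbation" = 0.5, "HAP" = 0.3, "CAP-s" = 0.2),
    "CAP-s" = c("CAP-m" = 0.7, "aspiration-pneumonia" = 0.3),
    "HAP" = c("other-RTI" = 0.6, "CAP-m" = 0.4),
    "COPD-exacerbation" = c("CAP-m" = 0.7, "bronchitis" = 0.3),
    "aspiration-pneumonia" = c("CAP-s" = 0.5, "CAP" = 0.5),
    "bronchitis" = c("COPD-exacerbation" = 0.6, "CAP" = 0.4),
    "other-RTI" = c("bronchitis" = 1),
    "cystitis" = c("complicated-UTI" = 1),
    "complicated-UTI" = c("cystitis" = 0.85, "chronic-prostatitis" = 0.10,
                          "other-UTI" = 0.05),
    "chronic-prostatitis" = c("complicated-UTI" = 1),
    "other-UTI" = c("cystitis" = 1)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions under which the pipeline is
#' exercised: a one-year admission stream with planted, labelled anomalies
#' for every exclusion rule, guideline-drawn or deliberately discordant
#' regimens, and an indication mis-selection process with a configurable
#' confusion structure. Defaults emulate the qualitative shape of a
#' teaching-hospital audit: roughly 30% of prescriptions registered for
#' RTI or UTI (RTI ~1.5x UTI), about half of assessable regimens
#' guideline-adherent, a 13% mis-selection rate dominated by complicated
#' UTI registered as cystitis, and small planted fractions of underage,
#' ICU, short-stay, readmission, dual-tract and erroneous-start
#' contamination. With the default `n_patients = 800` a run yields on the
#' order of 1000 prescription rows.
#'
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; the generator uses one pseudo-random stream
#'   seeded once.
#' @param guideline Optional `guideline_table` regimens are drawn from;
#'   defaults to the packaged synthetic table.
#' @param taxonomy Indication taxonomy.
#' @param underage_fraction,icu_fraction,short_stay_fraction,readmission_fraction
#'   Fractions of patients planted with, respectively, age < 18, an ICU
#'   stay, a stay under 12 h, and a second admission within 30 days of the
#'   first discharge. Mutually exclusive plants, so recovered exclusion
#'   counts are unambiguous.
#' @param boundary_stay_fraction,mid_stay_fraction Mass of stays exactly
#'   at the 12 h/24 h boundaries and strictly between them (the
#'   last-therapy-at-discharge branch); remaining stays are >= 24 h.
#' @param class_mix Probabilities of the registered indication class
#'   (empiric/targeted/prophylaxis) per episode.
#' @param tract_mix Probabilities of the registered focus tract
#'   (RTI/UTI/other) per episode.
#' @param sub_indication_mix Named list (`RTI`, `UTI`) of probability
#'   vectors over sub-indication codes.
#' @param combination_prob Probability that a discordant or non-assessed
#'   regimen has two agents rather than one (adherent regimens take their
#'   size from the guideline entry drawn).
#' @param adherent_fraction Probability that a planted assessable regimen
#'   is drawn from the guideline (A or B) rather than a discordant pool.
#' @param first_choice_share Among adherent regimens, probability of the
#'   first-choice tier.
#' @param misselection_rate Per-prescription probability that the
#'   registered sub-indication differs from the true one.
#' @param confusion Confusion structure, see [default_confusion()].
#' @param erroneous_start_fraction Probability that a clean empiric
#'   RTI/UTI regimen is planted with a start before admission.
#' @param dual_tract_fraction Probability that a clean long-stay admission
#'   carries both an RTI and a UTI empiric regimen.
#' @param ongoing_stop_fraction Probability that a long-stay prescription
#'   has no recorded stop (active through discharge).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 800,
                       seed = 1,
                       guideline = NULL,
                       taxonomy = default_indication_taxonomy(),
                       underage_fraction = 0.02,
                       icu_fraction = 0.05,
                       short_stay_fraction = 0.05,
                       readmission_fraction = 0.08,
                       boundary_stay_fraction = 0.02,
                       mid_stay_fraction = 0.08,
                       class_mix = c(empiric = 0.75, targeted = 0.15,
                                     prophylaxis = 0.10),
                       tract_mix = c(RTI = 0.18, UTI = 0.12, other = 0.70),
                       sub_indication_mix = list(
                         RTI = c("CAP" = 0.05, "CAP-m" = 0.25, "CAP-s" = 0.15,
                                 "HAP" = 0.15, "COPD-exacerbation" = 0.15,
                                 "aspiration-pneumonia" = 0.05,
                                 "bronchitis" = 0.10, "other-RTI" = 0.10),
                         UTI = c("cystitis" = 0.30, "complicated-UTI" = 0.45,
                                 "chronic-prostatitis" = 0.05,
                                 "other-UTI" = 0.20)),
                       combination_prob = 0.12,
                       adherent_fraction = 0.5,
                       first_choice_share = 0.6,
                       misselection_rate = 0.13,
                       confusion = default_confusion(),
                       erroneous_start_fraction = 0.02,
                       dual_tract_fraction = 0.02,
                       ongoing_stop_fraction = 0.10) {
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  fr <- c(underage_fraction, icu_fraction, short_stay_fraction,
          readmission_fraction, boundary_stay_fraction, mid_stay_fraction,
          combination_prob, adherent_fraction, first_choice_share,
          misselection_rate, erroneous_start_fraction, dual_tract_fraction,
          ongoing_stop_fraction)
  if (!all(vapply(fr, frac_ok, logical(1)))) {
    stop("all fractions must be single values in [0, 1]", call. = FALSE)
  }
  if (underage_fraction + icu_fraction + short_stay_fraction +
      readmission_fraction >= 1) {
    stop("planted anomaly fractions must sum to < 1", call. = FALSE)
  }
  if (boundary_stay_fraction + mid_stay_fraction >= 1) {
    stop("stay-distribution fractions must sum to < 1", call. = FALSE)
  }
  chk_mix <- function(m, what) {
    if (abs(sum(m) - 1) > 1e-8 || any(m < 0)) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  chk_mix(class_mix, "class_mix")
  chk_mix(tract_mix, "tract_mix")
  chk_mix(sub_indication_mix$RTI, "sub_indication_mix$RTI")
  chk_mix(sub_indication_mix$UTI, "sub_indication_mix$UTI")
  .check_confusion(confusion)
  stopifnot(n_patients >= 0, is.numeric(seed))
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         guideline = guideline, taxonomy = taxonomy,
         underage_fraction = underage_fraction, icu_fraction = icu_fraction,
         short_stay_fraction = short_stay_fraction,
         readmission_fraction = readmission_fraction,
         boundary_stay_fraction = boundary_stay_fraction,
         mid_stay_fraction = mid_stay_fraction,
         class_mix = class_mix, tract_mix = tract_mix,
         sub_indication_mix = sub_indication_mix,
         combination_prob = combination_prob,
         adherent_fraction = adherent_fraction,
         first_choice_share = first_choice_share,
         misselection_rate = misselection_rate, confusion = confusion,
         erroneous_start_fraction = erroneous_start_fraction,
         dual_tract_fraction = dual_tract_fraction,
         ongoing_stop_fraction = ongoing_stop_fraction),
    class = "sim_config"
  )
}

.check_confusion <- function(confusion) {
  for (code in names(confusion)) {
    row <- confusion[[code]]
    if (abs(sum(row) - 1) > 1e-8 || any(row < 0)) {
      stop("confusion row for '", code, "' must sum to 1", call. = FALSE)
    }
  }
  invisible(confusion)
}

#' Packaged synthetic guideline table
#'
#' Convenience accessor for the packaged synthetic, illustrative guideline
#' fixture (see `inst/extdata/guideline_synthetic_swab_like.yaml`). It is
#' a stand-in in the national-recommendation style, not the published
#' national guideline.
#'
#' @return A `guideline_table`.
#' @export
synthetic_guideline <- function() {
  read_guideline_table(system.file("extdata",
                                   "guideline_synthetic_swab_like.yaml",
                                   package = "stewardaudit"))
}

# Agents given orally in the generator; everything else is IV.
.oral_agents <- c("J01AA02", "J01XE01", "J01XX01", "J01EA01", "J01EE01",
                  "J01MA14")
.extra_discordant_agents <- c("J01DC02", "J01CR02")

.regimen_key <- function(agents) paste(sort(unique(agents)), collapse = ";")

# Per-sub-indication pools of deliberately discordant regimens: singles and
# unordered pairs from the global agent pool that do not equal any
# recommended regimen of that sub-indication.
.discordant_pools <- function(guideline, combination_prob) {
  all_agents <- sort(unique(c(
    unlist(lapply(guideline, function(e) unlist(c(e$first_choice,
                                                  e$second_choice)))),
    .extra_discordant_agents)))
  pair_idx <- utils::combn(all_agents, 2, simplify = FALSE)
  pools <- lapply(names(guideline), function(code) {
    e <- guideline[[code]]
    rec <- vapply(c(e$first_choice, e$second_choice), .regimen_key,
                  character(1))
    singles <- all_agents[!all_agents %in% rec]
    pairs <- pair_idx[!vapply(pair_idx, .regimen_key, character(1)) %in% rec]
    if (e$assessable) {
      if (combination_prob < 1 && length(singles) == 0) {
        stop("no discordant single agent available for '", code,
             "'; infeasible configuration", call. = FALSE)
      }
      if (combination_prob > 0 && length(pairs) == 0) {
        stop("combination probability > 0 but no discordant combination ",
             "available for '", code, "'", call. = FALSE)
      }
    }
    list(singles = singles, pairs = pairs)
  })
  names(pools) <- names(guideline)
  pools$.all_agents <- all_agents
  pools$.all_pairs <- pair_idx
  pools
}

.empty_cohort <- function(guideline, config) {
  rx <- tibble::as_tibble(stats::setNames(
    rep(list(character()), length(.rx_columns)), .rx_columns))
  rx$start_ts <- as.POSIXct(character(), tz = "UTC")
  rx$stop_ts <- as.POSIXct(character(), tz = "UTC")
  adm <- tibble::tibble(patient_id = character(), admission_id = character(),
                        admit_ts = as.POSIXct(character(), tz = "UTC"),
                        discharge_ts = as.POSIXct(character(), tz = "UTC"),
                        age_years = integer(), ward_type = character())
  truth <- tibble::tibble(
    record_id = character(), patient_id = character(),
    admission_id = character(), indication_class = character(),
    true_focus_tract = character(), true_sub_indication = character(),
    registered_focus_tract = character(),
    registered_sub_indication = character(), misselected = logical(),
    planted_category = character(), exclusion_reason = character())
  structure(list(admissions = adm, prescriptions = rx, truth = truth,
                 guideline = guideline, config = config),
            class = "synthetic_cohort")
}

#' Generate a synthetic audit cohort with ground truth
#'
#' Simulates an admissions table and a prescription extract in the
#' canonical schema, together with a per-record ground-truth table in
#' which every planted anomaly is labelled: underage patients, ICU stays,
#' sub-12 h stays, 30-day readmissions, prescriptions started before
#' admission, admissions carrying both an RTI and a UTI regimen, and
#' prophylaxis registrations. Regimens are drawn from the guideline table
#' (categories A/B by tier) with probability `adherent_fraction`,
#' otherwise from a discordant pool (category C); registered
#' sub-indications are then perturbed by the mis-selection process. All
#' admissions without a planted anomaly carry a regimen active at the
#' 24-hour snapshot.
#'
#' Determinism: one pseudo-random stream seeded once from `config$seed`,
#' with a fixed draw order (admission anomalies, times and ages; episode
#' class/tract/sub-indication/adherence; agent sets and timings in
#' admission order; mis-selection last), so outputs are byte-identical
#' across runs for the same configuration.
#'
#' The `exclusion_reason` truth labels state which flowchart stage should
#' remove each record under the default [selection_params()], using the
#' pipeline's fixed attribution order; `"none"` marks records expected in
#' the final empiric RTI/UTI set.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `admissions`,
#'   `prescriptions`, `truth`, `guideline` and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  guideline <- config$guideline %||% synthetic_guideline()
  pools <- .discordant_pools(guideline, config$combination_prob)
  if (config$n_patients == 0) return(.empty_cohort(guideline, config))
  withr::with_seed(config$seed,
                   .generate_impl(config, guideline, pools))
}

.generate_impl <- function(config, guideline, pools) {
  n <- config$n_patients
  taxonomy <- config$taxonomy
  patient_id <- sprintf("P%05d", seq_len(n))

  p_anom <- c(none = 1 - config$underage_fraction - config$icu_fraction -
                config$short_stay_fraction - config$readmission_fraction,
              underage = config$underage_fraction,
              icu = config$icu_fraction,
              short_stay = config$short_stay_fraction,
              readmission = config$readmission_fraction)
  anomaly <- sample(names(p_anom), n, replace = TRUE, prob = p_anom)

  base <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  admit <- base + round(stats::runif(n, 0, 364 * 86400) / 60) * 60

  long_stay <- function(k) 24 + stats::rgamma(k, shape = 2, scale = 60)
  los <- numeric(n)
  comp <- stats::runif(n)
  b <- config$boundary_stay_fraction
  m <- config$mid_stay_fraction
  los[comp < b] <- sample(c(12, 24), sum(comp < b), replace = TRUE)
  mid <- comp >= b & comp < b + m
  los[mid] <- stats::runif(sum(mid), 12.5, 23.5)
  rest <- comp >= b + m
  los[rest] <- long_stay(sum(rest))
  los[anomaly == "short_stay"] <- stats::runif(sum(anomaly == "short_stay"),
                                               2, 11.5)
  # readmission patients need an eligible pair of long stays
  los[anomaly == "readmission"] <- long_stay(sum(anomaly == "readmission"))

  age <- sample(18:95, n, replace = TRUE)
  age[anomaly == "underage"] <- sample(16:17, sum(anomaly == "underage"),
                                       replace = TRUE)
  ward <- ifelse(anomaly == "icu", "icu", "general")

  adm <- tibble::tibble(
    patient_id = patient_id,
    admission_id = sprintf("A%05d", seq_len(n)),
    admit_ts = admit,
    discharge_ts = admit + round(los * 3600),
    age_years = as.integer(age),
    ward_type = ward,
    anomaly = ifelse(anomaly == "readmission", "none", anomaly))

  re <- which(anomaly == "readmission")
  if (length(re) > 0) {
    gap <- stats::runif(length(re), 0.5, 25) * 86400
    admit2 <- adm$discharge_ts[re] + round(gap / 60) * 60
    los2 <- long_stay(length(re))
    adm2 <- tibble::tibble(
      patient_id = patient_id[re],
      admission_id = sprintf("A%05d", n + seq_along(re)),
      admit_ts = admit2,
      discharge_ts = admit2 + round(los2 * 3600),
      age_years = adm$age_years[re],
      ward_type = "general",
      anomaly = "readmission")
    adm <- dplyr::bind_rows(adm, adm2)
  }

  stay <- as.numeric(difftime(adm$discharge_ts, adm$admit_ts, units = "hours"))
  n_adm <- nrow(adm)

  # episodes: one per admission; clean long-stay admissions may carry a
  # planted dual-tract pair (one RTI + one UTI, both empiric)
  dual_ok <- adm$anomaly == "none" & stay >= 24
  dual <- dual_ok & stats::runif(n_adm) < config$dual_tract_fraction

  ep_adm <- c(seq_len(n_adm), which(dual))
  ep_dual <- c(dual, rep(TRUE, sum(dual)))
  ep_class <- sample(names(config$class_mix), length(ep_adm), replace = TRUE,
                     prob = config$class_mix)
  ep_tract <- sample(names(config$tract_mix), length(ep_adm), replace = TRUE,
                     prob = config$tract_mix)
  ep_class[ep_dual] <- "empiric"
  ep_tract[seq_len(n_adm)][dual] <- "RTI"
  ep_tract[-seq_len(n_adm)] <- "UTI"

  ep_sub <- rep(NA_character_, length(ep_adm))
  for (tr in c("RTI", "UTI")) {
    k <- ep_tract == tr
    mix <- config$sub_indication_mix[[tr]]
    ep_sub[k] <- sample(names(mix), sum(k), replace = TRUE, prob = mix)
  }
  ep_adherent <- stats::runif(length(ep_adm)) < config$adherent_fraction
  ep_first <- stats::runif(length(ep_adm)) < config$first_choice_share
  ep_err <- adm$anomaly[ep_adm] == "none" & !ep_dual &
    ep_class == "empiric" & ep_tract %in% c("RTI", "UTI") &
    stay[ep_adm] >= 24 &
    stats::runif(length(ep_adm)) < config$erroneous_start_fraction

  # order episodes by admission so record ids follow the admission stream
  ord <- order(ep_adm)
  ep <- tibble::tibble(adm_i = ep_adm, dual = ep_dual, class = ep_class,
                       tract = ep_tract, sub = ep_sub,
                       adherent = ep_adherent, first = ep_first,
                       erroneous = ep_err)[ord, ]

  assessable_of <- vapply(guideline, function(e) e$assessable, logical(1))
  pick <- function(lst) lst[[sample.int(length(lst), 1)]]

  n_ep <- nrow(ep)
  v_adm <- ep$adm_i; v_dual <- ep$dual; v_class <- ep$class
  v_tract <- ep$tract; v_sub <- ep$sub; v_adh <- ep$adherent
  v_first <- ep$first; v_err <- ep$erroneous
  admit_num <- as.numeric(adm$admit_ts)

  ep_agents <- vector("list", n_ep)
  ep_cat <- rep(NA_character_, n_ep)
  ep_start <- numeric(n_ep)
  ep_stop <- numeric(n_ep)
  for (i in seq_len(n_ep)) {
    if (v_tract[i] %in% c("RTI", "UTI") && isTRUE(assessable_of[[v_sub[i]]])) {
      gl <- guideline[[v_sub[i]]]
      if (v_adh[i]) {
        tier1 <- length(gl$first_choice) > 0 &&
          (v_first[i] || length(gl$second_choice) == 0)
        ep_agents[[i]] <- if (tier1) pick(gl$first_choice) else
          pick(gl$second_choice)
        ep_cat[i] <- if (tier1) "A" else "B"
      } else {
        pool <- pools[[v_sub[i]]]
        two <- stats::runif(1) < config$combination_prob
        ep_agents[[i]] <- if (two && length(pool$pairs) > 0) {
          pick(pool$pairs)
        } else {
          pool$singles[sample.int(length(pool$singles), 1)]
        }
        ep_cat[i] <- "C"
      }
    } else {
      two <- stats::runif(1) < config$combination_prob
      ep_agents[[i]] <- if (two) pick(pools$.all_pairs) else
        pools$.all_agents[sample.int(length(pools$.all_agents), 1)]
    }

    a <- v_adm[i]
    st <- stay[a]
    if (v_err[i]) {
      start <- admit_num[a] - round(stats::runif(1, 1, 48) * 3600)
      stop <- start + round(stats::runif(1, 100, 200) * 3600)
    } else if (st >= 24) {
      start <- admit_num[a] + round(stats::runif(1, 0, 12) * 3600)
      stop <- start + round(stats::runif(1, 60, 160) * 3600)
      if (stats::runif(1) < config$ongoing_stop_fraction) stop <- NA_real_
    } else {
      start <- admit_num[a] + round(stats::runif(1, 0.1, 0.8) * st * 3600)
      stop <- start + round(stats::runif(1, 48, 120) * 3600)
    }
    ep_start[i] <- start
    ep_stop[i] <- stop
  }

  n_ag <- lengths(ep_agents)
  ri <- rep(seq_len(n_ep), n_ag)
  agents_flat <- unlist(ep_agents, use.names = FALSE)
  rec <- tibble::tibble(
    adm_i = v_adm[ri],
    atc_code = agents_flat,
    route = ifelse(agents_flat %in% .oral_agents, "oral", "iv"),
    start_ts = as.POSIXct(ep_start[ri], origin = "1970-01-01", tz = "UTC"),
    stop_ts = as.POSIXct(ep_stop[ri], origin = "1970-01-01", tz = "UTC"),
    indication_class = v_class[ri],
    focus_tract = v_tract[ri],
    sub_indication = ifelse(v_tract[ri] %in% c("RTI", "UTI"), v_sub[ri],
                            NA_character_),
    planted_category = ep_cat[ri],
    erroneous = v_err[ri], dual = v_dual[ri])
  rec$record_id <- sprintf("R%06d", seq_len(nrow(rec)))

  # truth labels follow the pipeline's fixed attribution order under the
  # default selection parameters
  adm_reason <- dplyr::case_when(
    adm$anomaly == "underage" ~ "age",
    adm$anomaly == "icu" ~ "ward",
    adm$anomaly == "short_stay" ~ "stay",
    adm$anomaly == "readmission" ~ "readmission",
    TRUE ~ NA_character_)
  reason <- adm_reason[rec$adm_i]
  reason <- ifelse(is.na(reason) & rec$indication_class == "prophylaxis",
                   "prophylaxis", reason)
  reason <- ifelse(is.na(reason) & !rec$focus_tract %in% c("RTI", "UTI"),
                   "other_tract", reason)
  reason <- ifelse(is.na(reason) & rec$erroneous, "erroneous", reason)
  reason <- ifelse(is.na(reason) & rec$dual, "dual_tract", reason)
  reason[is.na(reason)] <- "none"

  prescriptions <- tibble::tibble(
    record_id = rec$record_id,
    patient_id = adm$patient_id[rec$adm_i],
    admission_id = adm$admission_id[rec$adm_i],
    atc_code = rec$atc_code,
    agent_name = rec$atc_code,
    start_ts = rec$start_ts,
    stop_ts = rec$stop_ts,
    route = rec$route,
    dose_text = NA_character_,
    prescriber_specialty = NA_character_,
    ward = adm$ward_type[rec$adm_i],
    indication_class = rec$indication_class,
    focus_tract = rec$focus_tract,
    sub_indication = rec$sub_indication)

  truth <- tibble::tibble(
    record_id = rec$record_id,
    patient_id = adm$patient_id[rec$adm_i],
    admission_id = adm$admission_id[rec$adm_i],
    indication_class = rec$indication_class,
    true_focus_tract = rec$focus_tract,
    true_sub_indication = rec$sub_indication,
    registered_focus_tract = rec$focus_tract,
    registered_sub_indication = rec$sub_indication,
    misselected = FALSE,
    planted_category = rec$planted_category,
    exclusion_reason = reason)

  mis <- .misselect(prescriptions, truth, config$misselection_rate,
                    config$confusion, taxonomy)

  admissions <- adm[, c("patient_id", "admission_id", "admit_ts",
                        "discharge_ts", "age_years", "ward_type")]
  structure(list(admissions = admissions, prescriptions = mis$extract,
                 truth = mis$truth, guideline = guideline, config = config),
            class = "synthetic_cohort")
}

# Perturb registered sub-indications in place; assumes an active RNG
# stream. Mis-selection applies to every prescription whose true focus is
# RTI or UTI, independently with probability `rate`.
.misselect <- function(extract, truth, rate, confusion, taxonomy) {
  idx <- which(truth$true_focus_tract %in% c("RTI", "UTI"))
  if (length(idx) > 0 && rate > 0) {
    hit <- idx[stats::runif(length(idx)) < rate]
    for (i in hit) {
      code <- truth$true_sub_indication[i]
      row <- confusion[[code]]
      if (is.null(row)) {
        stop("no confusion row for sub-indication '", code, "'",
             call. = FALSE)
      }
      new <- sample(names(row), 1, prob = row)
      truth$registered_sub_indication[i] <- new
      tract <- taxonomy$tract[match(new, taxonomy$code)]
      if (!is.na(tract)) truth$registered_focus_tract[i] <- tract
      extract$sub_indication[i] <- new
      extract$focus_tract[i] <- truth$registered_focus_tract[i]
    }
  }
  truth$misselected <- !is.na(truth$true_sub_indication) &
    truth$registered_sub_indication != truth$true_sub_indication
  list(extract = extract, truth = truth)
}

#' Inject indication mis-selections into an extract
#'
#' Perturbs the registered sub-indication of RTI/UTI prescriptions:
#' each one is independently mis-selected with probability `rate`, the
#' replacement drawn from the confusion row of its true sub-indication.
#' The ground-truth table is updated consistently (the `misselected` flag
#' holds exactly when registered differs from true).
#'
#' @param extract Prescription tibble (canonical schema).
#' @param truth Matching ground-truth tibble (see [generate_cohort()]).
#' @param rate Per-prescription mis-selection probability.
#' @param confusion Confusion structure, see [default_confusion()].
#' @param seed Integer seed.
#' @param taxonomy Indication taxonomy.
#' @return List with perturbed `extract` and updated `truth`.
#' @export
inject_misselection <- function(extract, truth, rate,
                                confusion = default_confusion(), seed = 1,
                                taxonomy = default_indication_taxonomy()) {
  stopifnot(rate >= 0, rate <= 1)
  .check_confusion(confusion)
  withr::with_seed(seed, .misselect(extract, truth, rate, confusion, taxonomy))
}

#' Build chart-review records from synthetic ground truth
#'
#' Pairs each prescription's registered (selected) indication with its
#' true (documented) one, yielding a chart-review table as a perfect
#' reviewer would produce it: strata follow the registered indication,
#' the `random_other` stratum carries the non-RTI/UTI marker as selected
#' indication. Use `strata_sizes` to review a stratified sample instead of
#' the census.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param strata_sizes Optional named vector passed to
#'   [draw_validation_sample()]; `NULL` (default) reviews every record.
#' @param seed Seed for the sampling step (unused for a census).
#' @return A chart-review tibble as read by [read_chart_reviews()].
#' @export
simulate_chart_reviews <- function(cohort, strata_sizes = NULL, seed = 1) {
  truth <- cohort$truth
  reviews <- tibble::tibble(
    record_id = truth$record_id,
    stratum = ifelse(truth$registered_focus_tract %in% c("RTI", "UTI"),
                     truth$registered_focus_tract, "random_other"),
    selected_indication = ifelse(
      truth$registered_focus_tract %in% c("RTI", "UTI"),
      truth$registered_sub_indication, .non_rti_uti),
    documented_indication = ifelse(
      truth$true_focus_tract %in% c("RTI", "UTI"),
      truth$true_sub_indication, .non_rti_uti))
  if (is.null(strata_sizes)) return(reviews)
  sel <- draw_validation_sample(
    dplyr::mutate(reviews, focus_tract = .data$stratum), strata_sizes, seed)
  reviews[match(sel$record_id, reviews$record_id), ]
}

#' Write a synthetic cohort to disk
#'
#' Emits the extract, admissions, truth and guideline files of a
#' synthetic cohort into a directory, in the same plain-text formats the
#' readers consume.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    extract = file.path(dir, "prescriptions.csv"),
    admissions = file.path(dir, "admissions.csv"),
    truth = file.path(dir, "truth.csv"),
    guideline = file.path(dir, "guideline.yaml"))
  write_prescription_extract(cohort$prescriptions, paths[["extract"]])
  write_admissions(cohort$admissions, paths[["admissions"]])
  readr::write_csv(cohort$truth, paths[["truth"]], na = "")
  write_guideline_table(cohort$guideline, paths[["guideline"]])
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$admissions), " admissions, ",
      nrow(x$prescriptions), " prescriptions (seed ", x$config$seed, ")\n",
      sep = "")
  print(table(x$truth$exclusion_reason))
  invisible(x)
}
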